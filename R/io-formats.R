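#' Read a MaxQuant-dialect protein-groups table
#'
#' Parses a tab-separated protein-group file as produced by common label-free
#' search engines: per-sample quantification columns are recognised
#' case-insensitively by the prefixes \code{"Intensity "} (raw) and
#' \code{"LFQ intensity "}; the quality-flag columns \code{Reverse},
#' \code{Potential contaminant} and \code{Only identified by site} hold
#' \code{"+"} for flagged rows and are blank otherwise.  The first accession
#' of the semicolon-joined \code{Protein IDs} entry becomes the row's primary
#' ID.
#'
#' When only raw intensity columns are present the LFQ assay mirrors them (a
#' note is kept in \code{metadata()}); when both families are present their
#' sample sets must be identical.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A \code{\link{ProteinGroups}} object.
#' @export
readProteinGroups <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  cn <- names(df)
  lower <- tolower(cn)
  isLfq <- startsWith(lower, "lfq intensity ")
  isRaw <- startsWith(lower, "intensity ") & !isLfq
  rawSamples <- substring(cn[isRaw], nchar("Intensity ") + 1L)
  lfqSamples <- substring(cn[isLfq], nchar("LFQ intensity ") + 1L)
  if (!any(isRaw) && !any(isLfq))
    stop("no 'Intensity <sample>' or 'LFQ intensity <sample>' columns found")
  if (anyDuplicated(rawSamples) || anyDuplicated(lfqSamples))
    stop("duplicated sample names among intensity columns")
  if (any(isRaw) && any(isLfq) && !setequal(rawSamples, lfqSamples))
    stop("raw and LFQ intensity columns name different sample sets")

  getMatrix <- function(idx, samples) {
    m <- as.matrix(df[, idx, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) m[is.na(m)] <- 0
    colnames(m) <- samples
    m
  }
  mirrored <- FALSE
  if (any(isRaw)) {
    raw <- getMatrix(which(isRaw), rawSamples)
  }
  if (any(isLfq)) {
    lfq <- getMatrix(which(isLfq), lfqSamples)
  }
  if (!any(isLfq)) { lfq <- raw; mirrored <- TRUE }
  if (!any(isRaw)) { raw <- lfq; mirrored <- TRUE }
  lfq <- lfq[, colnames(raw), drop = FALSE]

  pickCol <- function(name) {
    i <- match(tolower(name), lower)
    if (is.na(i)) NULL else df[[i]]
  }
  flag <- function(name) {
    v <- pickCol(name)
    if (is.null(v)) rep(FALSE, nrow(df)) else trimws(as.character(v)) == "+"
  }
  ids <- pickCol("Protein IDs")
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(df)))
  pg <- ProteinGroups(
    intensity = raw, lfq = lfq, proteinIds = ids,
    geneNames = pickCol("Gene names"),
    reverse = flag("Reverse"),
    potentialContaminant = flag("Potential contaminant"),
    onlyIdentifiedBySite = flag("Only identified by site"))
  if (mirrored)
    S4Vectors::metadata(pg)$lfqMirrorsRaw <- TRUE
  pg
}

#' Write a protein-groups table
#'
#' Inverse of \code{\link{readProteinGroups}}: writes the canonical column
#' layout (\code{Protein IDs}, \code{Gene names}, per-sample
#' \code{Intensity}/\code{LFQ intensity} columns, \code{"+"}-flag columns).
#'
#' @param pg a \code{ProteinGroups} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinGroups <- function(pg, path) {
  stopifnot(methods::is(pg, "ProteinGroups"))
  rd <- rowData(pg)
  raw <- assay(pg, "intensity")
  lfq <- assay(pg, "lfq")
  flagCol <- function(v) ifelse(v, "+", "")
  out <- data.frame(`Protein IDs` = rd$proteinIds,
                    `Gene names` = ifelse(is.na(rd$geneNames), "",
                                          rd$geneNames),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(raw)) out[[paste0("Intensity ", s)]] <- raw[, s]
  for (s in colnames(lfq)) out[[paste0("LFQ intensity ", s)]] <- lfq[, s]
  out[["Reverse"]] <- flagCol(rd$reverse)
  out[["Potential contaminant"]] <- flagCol(rd$potentialContaminant)
  out[["Only identified by site"]] <- flagCol(rd$onlyIdentifiedBySite)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove flagged rows from a protein-groups table
#'
#' Drops every row flagged as a reverse (decoy) hit, a potential contaminant,
#' or only identified by a modification site, preserving the order of the
#' remaining rows.  A row carrying several flags is counted once.  The number
#' of rows removed is stored in \code{metadata()} under
#' \code{nFlaggedRemoved}.
#'
#' @param pg a \code{ProteinGroups} object.
#' @return The filtered \code{ProteinGroups}.
#' @export
filterFlagged <- function(pg) {
  stopifnot(methods::is(pg, "ProteinGroups"))
  rd <- rowData(pg)
  bad <- rd$reverse | rd$potentialContaminant | rd$onlyIdentifiedBySite
  out <- pg[!bad, ]
  S4Vectors::metadata(out)$nFlaggedRemoved <- sum(bad)
  out
}

#' Read protein sequences from FASTA
#'
#' The ID is the header token before the first whitespace; sequences are
#' upper-cased.  Duplicate IDs and empty sequences are rejected.
#'
#' @param path path to a FASTA file.
#' @return A named character vector of amino-acid sequences.
#' @export
readFastaSeqs <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicated FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for ID: ", paste(ids[nchar(seqs) == 0], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector (or AAStringSet) of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path) {
  v <- .asSequenceVector(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(v), path)
  invisible(path)
}

#' Read a complex catalog from a YAML config
#'
#' The file must contain a top-level \code{complexes} list whose entries have
#' keys \code{name}, \code{members}, \code{direct_binders} and optionally
#' \code{stoichiometry} (a member -> expected-copies map).  Unknown keys are
#' rejected, as is a direct binder that is not a member.
#'
#' @param path path to the YAML file.
#' @return A \code{\link{ComplexCatalog}}.
#' @export
readComplexCatalog <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(names(y), "complexes"))
    stop("catalog must have a single top-level key 'complexes'")
  allowed <- c("name", "members", "direct_binders", "stoichiometry")
  complexes <- lapply(y$complexes, function(cx) {
    unknown <- setdiff(names(cx), allowed)
    if (length(unknown))
      stop("unknown catalog keys: ", paste(unknown, collapse = ", "))
    list(name = cx$name,
         members = as.character(unlist(cx$members)),
         directBinders = as.character(unlist(cx$direct_binders)),
         stoichiometry = if (is.null(cx$stoichiometry)) NULL else
           unlist(cx$stoichiometry))
  })
  ComplexCatalog(complexes)
}

#' Write a complex catalog to YAML
#'
#' @param catalog a \code{ComplexCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeComplexCatalog <- function(catalog, path) {
  stopifnot(methods::is(catalog, "ComplexCatalog"))
  y <- list(complexes = lapply(catalog@complexes, function(cx) {
    out <- list(name = cx$name, members = as.list(cx$members),
                direct_binders = as.list(cx$directBinders))
    if (!is.null(cx$stoichiometry))
      out$stoichiometry <- as.list(cx$stoichiometry)
    out
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a results table with a provenance header
#'
#' Writes a tab-separated table preceded by a single \code{#} comment line
#' recording the package version and any parameters supplied.
#'
#' @param df a data frame.
#' @param path output path.
#' @param params named list of parameters to record in the header.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(df, path, params = list()) {
  hdr <- sprintf("# baitquant %s", as.character(utils::packageVersion("baitquant")))
  if (length(params))
    hdr <- paste0(hdr, "; ", paste(sprintf("%s=%s", names(params),
                                           vapply(params, format, character(1))),
                                   collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by \code{writeResultsTable}
#'
#' @param path path to the file.
#' @return A data frame (the header comment is skipped).
#' @export
readResultsTable <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a sample design table
#'
#' @param path tab-separated file with columns \code{sample} and \code{group}.
#' @return A data frame with columns \code{sample}, \code{group}.
#' @export
readDesign <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("design file needs columns 'sample' and 'group'")
  df[c("sample", "group")]
}
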