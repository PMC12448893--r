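# ---------------------------------------------------------------------------
# Acetyl-site-level quantification of derivatized (propionylated) histone
# peptides.  Propionylation of free lysines blocks tryptic cleavage at Lys,
# so digestion is Arg-C-like and the classic histone tail peptides appear;
# site labels use mature-protein numbering (initiator Met removed), the
# community convention behind names like "H3 K18ac".
# ---------------------------------------------------------------------------

# Mature (Met-clipped) core histone sequences packaged for simulation and
# coordinate mapping: H3 (H3.1) and H4 are the canonical mammalian
# sequences; H2B is a representative mouse H2B type-1 sequence.
.HISTONE_REFS <- c(
  H3 = paste0("ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKS",
              "TELLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHA",
              "KRVTIMPKDIQLARRIRGERA"),
  H4 = paste0("SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGV",
              "LKVFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG"),
  H2B = paste0("PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSK",
               "AMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEG",
               "TKAVTKYTSSK")
)

#' Packaged mature histone reference sequences
#'
#' Mature (initiator-Met-clipped) sequences of histones H3, H4 and a
#' representative H2B, used as the default coordinate reference for site
#' mapping and as the substrate of \code{\link{simulateHistonePeptides}}.
#' Supply your own named vector to either function to override.
#'
#' @return Named character vector of sequences.
#' @export
histoneReferences <- function() .HISTONE_REFS

# Parse a site-combination key like "H3 K18ac" or "H3 K18ac+K23ac".
.parseSiteKey <- function(key, refs) {
  parts <- strsplit(trimws(key), " ", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed site key '", key, "' (expected '<histone> <sites>')")
  histone <- parts[1]
  if (!histone %in% names(refs))
    stop("unknown histone '", histone, "' in key '", key, "'")
  sites <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
  pos <- suppressWarnings(as.integer(sub("^K([0-9]+)ac$", "\\1", sites)))
  if (anyNA(pos) || any(!grepl("^K[0-9]+ac$", sites)))
    stop("malformed site(s) in key '", key, "'")
  seqChars <- strsplit(refs[[histone]], "")[[1]]
  bad <- pos[pos > length(seqChars) | seqChars[pmin(pos, length(seqChars))] != "K"]
  if (length(bad))
    stop("site(s) K", paste(bad, collapse = ",K"), " in key '", key,
         "' are not lysines of ", histone)
  list(histone = histone, positions = sort(pos))
}

.siteKey <- function(histone, positions) {
  paste0(histone, " ", paste0("K", sort(positions), "ac", collapse = "+"))
}

#' Map modified-peptide records to acetyl-site combinations
#'
#' Aggregates peptide-level intensities to acetyl-site-combination keys such
#' as \code{"H3 K18ac"} or \code{"H3 K18ac+K23ac"}.  A multiply-acetylated
#' peptide contributes to its combination key only (never double-counted
#' into the single sites), and records sharing a key (charge states,
#' duplicates) are summed, so total intensity is conserved.  Records whose
#' peptide sequence does not match the reference at the stated position are
#' rejected and reported.
#'
#' @param records data frame with columns \code{protein}, \code{sequence},
#'   \code{start} (1-based position in the mature histone),
#'   \code{modifications} (semicolon-joined \code{"offset:type"} with
#'   1-based offsets within the peptide and types \code{acetyl} /
#'   \code{propionyl}) and one \code{"Intensity <sample>"} column per
#'   sample.
#' @param references named character vector of mature histone sequences
#'   (default \code{\link{histoneReferences}()}).
#' @return A \code{SummarizedExperiment} with assay \code{intensity}
#'   (site-combinations x samples), rowData \code{histone}, \code{sites},
#'   \code{nSites}, and the rejected records (with reasons) in
#'   \code{metadata()$rejected}.
#' @export
mapPeptidesToSites <- function(records, references = histoneReferences()) {
  stopifnot(is.data.frame(records),
            all(c("protein", "sequence", "start", "modifications") %in%
                  names(records)))
  intCols <- grep("^Intensity ", names(records), value = TRUE)
  if (!length(intCols)) stop("no 'Intensity <sample>' columns in records")
  samples <- substring(intCols, nchar("Intensity ") + 1L)

  keys <- character(nrow(records))
  reject <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    prot <- as.character(records$protein[i])
    pep <- toupper(as.character(records$sequence[i]))
    start <- as.integer(records$start[i])
    if (!prot %in% names(references)) {
      reject[i] <- "unknown protein"; next
    }
    ref <- references[[prot]]
    refSub <- substring(ref, start, start + nchar(pep) - 1L)
    if (!identical(refSub, pep)) {
      reject[i] <- "sequence/position mismatch"; next
    }
    mods <- trimws(strsplit(as.character(records$modifications[i]), ";")[[1]])
    mods <- mods[nzchar(mods)]
    off <- as.integer(sub(":.*$", "", mods))
    type <- sub("^[0-9]+:", "", mods)
    if (length(mods) && (anyNA(off) || any(off < 1 | off > nchar(pep)))) {
      reject[i] <- "modification offset outside peptide"; next
    }
    if (any(duplicated(off[type %in% c("acetyl", "propionyl")]))) {
      reject[i] <- "conflicting modifications at one residue"; next
    }
    acOff <- off[type == "acetyl"]
    if (length(acOff) &&
        any(substring(pep, acOff, acOff) != "K")) {
      reject[i] <- "acetyl on a non-lysine residue"; next
    }
    keys[i] <- if (length(acOff))
      .siteKey(prot, start + acOff - 1L) else
        paste0(prot, " unmodified ", start, "-", start + nchar(pep) - 1L)
  }
  ok <- reject == ""
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reject[!ok]
    message(nrow(rejected), " record(s) rejected during site mapping")
  }
  recs <- records[ok, , drop = FALSE]
  keysOk <- keys[ok]
  ukeys <- unique(keysOk)
  mat <- matrix(0, length(ukeys), length(samples),
                dimnames = list(ukeys, samples))
  for (j in seq_along(intCols)) {
    v <- as.numeric(recs[[intCols[j]]])
    mat[, j] <- vapply(ukeys, function(k) sum(v[keysOk == k]), numeric(1))
  }
  isAc <- grepl(" K[0-9]+ac", ukeys)
  rd <- DataFrame(
    histone = sub(" .*$", "", ukeys),
    sites = sub("^[^ ]+ ", "", ukeys),
    nSites = ifelse(isAc, lengths(regmatches(ukeys,
                                             gregexpr("K[0-9]+ac", ukeys))), 0L))
  SummarizedExperiment(assays = list(intensity = mat), rowData = rd,
                       metadata = list(rejected = rejected))
}

#' Acetylation change of each site combination between groups
#'
#' Applies the label-free statistics to a site-combination table: log2
#' transform (zero intensity = missing), per-sample normalization, the
#' minimum-valid-values filter, downshifted Gaussian imputation, and
#' two-sided pooled-variance t-tests with permutation-based FDR.  Returns
#' the per-site log2 change (mutant minus reference) and significance.
#'
#' @param sites the \code{SummarizedExperiment} from
#'   \code{\link{mapPeptidesToSites}} (acetylated keys only are tested;
#'   unmodified-peptide rows are dropped).
#' @param design data frame (\code{sample}, \code{group}) or named vector.
#' @param contrast \code{c(mutant, reference)} group names.
#' @param normalization \code{"median"} (default), \code{"total"}
#'   (subtract each sample's log2 total signal) or \code{"none"}.
#' @param minValid valid-value filter threshold (default 3, as in the
#'   pulldown path).
#' @param width,downshift,fdrLevel,nPermutations,s0,seed as in
#'   \code{\link{enrichmentAnalysis}}.
#' @return A data frame with columns \code{site}, \code{difference},
#'   \code{t}, \code{p}, \code{d}, \code{q}, \code{significant}.
#' @export
relativeAcetylationChange <- function(sites, design, contrast,
                                      normalization = c("median", "total",
                                                        "none"),
                                      minValid = 3L, width = 0.3,
                                      downshift = 1.8, fdrLevel = 0.05,
                                      nPermutations = 250L, s0 = 0,
                                      seed = 1L) {
  normalization <- match.arg(normalization)
  mat <- assay(sites, "intensity")
  mat <- mat[grepl(" K[0-9]+ac", rownames(mat)), , drop = FALSE]
  if (!nrow(mat)) stop("no acetylated site combinations to test")
  grp <- .designGroups(design, colnames(mat))
  v <- ifelse(mat > 0, log2(mat), NA_real_)
  dimnames(v) <- dimnames(mat)
  m <- methods::new("LogIntensityMatrix", values = v, groups = grp)
  if (normalization == "median") {
    m <- medianNormalize(m)
  } else if (normalization == "total") {
    tot <- log2(colSums(mat))
    m <- methods::initialize(m, values = sweep(m@values, 2L, tot, "-"))
  }
  m <- filterMinValid(m, minValid = minValid)
  if (!nrow(m)[1]) stop("no site combination passes the valid-value filter")
  m <- imputeGaussianDownshift(m, width = width, downshift = downshift,
                               seed = seed)
  res <- permutationFDR(m, contrast, fdrLevel = fdrLevel,
                        nPermutations = nPermutations, s0 = s0, seed = seed)
  names(res)[names(res) == "protein"] <- "site"
  res
}

#' Simulate a derivatized-histone modified-peptide table
#'
#' Generates peptide-level records for the propionylation workflow: each
#' requested acetyl-site combination is placed on the (unique) Arg-C-like
#' peptide of the reference tail containing those lysines, with the
#' remaining lysines of the peptide propionylated; an all-propionylated
#' (unmodified) form carries the residual occupancy of each peptide.  The
#' linear intensity of a form in a sample is \code{histoneAmount *
#' occupancy} under multiplicative log-normal noise, so a between-group
#' occupancy ratio propagates exactly to the intensity ratio when noise is
#' off.
#'
#' @param siteOccupanciesByGroup named list: group -> named numeric vector of
#'   occupancies between 0 and 1, keyed like \code{"H3 K18ac"} or
#'   \code{"H3 K18ac+K23ac"}.  All groups must share the same keys.
#' @param nReplicates replicates per group (default 4).
#' @param noiseSdLog2 log-normal noise sd in log2 units (default 0.2; 0
#'   disables noise).
#' @param histoneAmount linear intensity of a fully occupied form (default
#'   1e8).
#' @param references named mature histone sequences (default
#'   \code{\link{histoneReferences}()}).
#' @param seed integer seed; seeded runs are reproducible.
#' @return A list with \code{records} (the modified-peptide data frame
#'   accepted by \code{\link{mapPeptidesToSites}}) and \code{design}.
#' @export
simulateHistonePeptides <- function(siteOccupanciesByGroup,
                                    nReplicates = 4L, noiseSdLog2 = 0.2,
                                    histoneAmount = 1e8,
                                    references = histoneReferences(),
                                    seed = 1L) {
  stopifnot(is.list(siteOccupanciesByGroup),
            length(siteOccupanciesByGroup) >= 1L,
            !is.null(names(siteOccupanciesByGroup)))
  groups <- names(siteOccupanciesByGroup)
  keys <- names(siteOccupanciesByGroup[[1]])
  for (g in groups) {
    occ <- siteOccupanciesByGroup[[g]]
    if (!identical(sort(names(occ)), sort(keys)))
      stop("all groups must define the same site-combination keys")
    if (any(occ < 0 | occ > 1))
      stop("occupancies must lie in [0, 1]")
  }
  parsed <- lapply(keys, .parseSiteKey, refs = references)

  # place each combination on the fully-cleaved Arg-C-like peptide
  peptideOf <- lapply(parsed, function(p) {
    dig <- digestProtein(references[[p$histone]], "argc_propionyl", 0L)
    hit <- dig[dig$start <= min(p$positions) & dig$end >= max(p$positions), ,
               drop = FALSE]
    if (!nrow(hit))
      stop("sites ", paste(p$positions, collapse = ","),
           " of ", p$histone, " span a cleavage boundary")
    c(list(histone = p$histone, positions = p$positions),
      as.list(hit[1, c("peptide", "start", "end")]))
  })

  modString <- function(pep, start, acPositions) {
    chars <- strsplit(pep, "")[[1]]
    kOff <- which(chars == "K")
    acOff <- acPositions - start + 1L
    propOff <- setdiff(kOff, acOff)
    paste(c(sprintf("%d:acetyl", acOff), sprintf("%d:propionyl", propOff)),
          collapse = ";")
  }

  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_%d", g, seq_len(nReplicates))))
  sampleGroup <- rep(groups, each = nReplicates)

  rows <- list()
  for (i in seq_along(keys)) {
    p <- peptideOf[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      protein = p$histone, sequence = p$peptide, start = p$start,
      modifications = modString(p$peptide, p$start, p$positions),
      key = keys[i], stringsAsFactors = FALSE)
  }
  # residual, fully propionylated form per distinct peptide
  pepIds <- vapply(peptideOf, function(p)
    paste(p$histone, p$start, p$end), character(1))
  for (pid in unique(pepIds)) {
    p <- peptideOf[[match(pid, pepIds)]]
    rows[[length(rows) + 1L]] <- data.frame(
      protein = p$histone, sequence = p$peptide, start = p$start,
      modifications = modString(p$peptide, p$start, integer(0)),
      key = paste0("resid:", pid), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)

  occupancyOf <- function(g, key) {
    if (startsWith(key, "resid:")) {
      pid <- sub("^resid:", "", key)
      onPep <- keys[pepIds == pid]
      max(0, 1 - sum(siteOccupanciesByGroup[[g]][onPep]))
    } else {
      siteOccupanciesByGroup[[g]][[key]]
    }
  }

  .withSubstream(seed, "histone", {
    for (j in seq_along(samples)) {
      g <- sampleGroup[j]
      expected <- vapply(records$key, function(k)
        histoneAmount * occupancyOf(g, k), numeric(1))
      noise <- if (noiseSdLog2 > 0)
        2^stats::rnorm(length(expected), 0, noiseSdLog2) else 1
      records[[paste0("Intensity ", samples[j])]] <- expected * noise
    }
    records$key <- NULL
    list(records = records,
         design = data.frame(sample = samples, group = sampleGroup,
                             stringsAsFactors = FALSE))
  })
}

#' Read / write modified-peptide tables
#'
#' Tab-separated tables with columns \code{protein}, \code{sequence},
#' \code{start}, \code{modifications} and per-sample
#' \code{"Intensity <sample>"} columns.
#'
#' @param path file path.
#' @return \code{readModifiedPeptides}: the records data frame.
#' @export
readModifiedPeptides <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein", "sequence", "start", "modifications")
  if (!all(need %in% names(df)))
    stop("modified-peptide table needs columns: ",
         paste(need, collapse = ", "))
  df
}

#' @rdname readModifiedPeptides
#' @param records the records data frame.
#' @return \code{writeModifiedPeptides}: \code{path}, invisibly.
#' @export
writeModifiedPeptides <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
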