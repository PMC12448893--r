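# Cleavage chemistry: trypsin_p cuts C-terminal of K and R regardless of the
# following residue (the "/P" convention); argc_propionyl models tryptic
# digestion of propionylated histones, where derivatized Lys blocks cleavage
# so only Arg sites remain (Arg-C-like specificity).
.cleavageResidues <- function(rule) {
  switch(rule,
         trypsin_p = c("K", "R"),
         argc_propionyl = "R",
         stop("unknown cleavage rule: ", rule))
}

#' In-silico proteolytic digestion
#'
#' Cleaves a protein sequence according to the chosen rule and returns every
#' peptide obtainable with up to \code{missedCleavages} missed cleavage
#' sites.  \code{"trypsin_p"} cuts after Lys and Arg irrespective of a
#' following Pro; \code{"argc_propionyl"} cuts after Arg only, modelling
#' propionylated (derivatization-blocked) lysines in histone workflows.  A
#' peptide with \code{m} missed cleavages is a run of \code{m + 1} adjacent
#' fully-cleaved fragments; each reported span is unique.
#'
#' @param sequence a single amino-acid string (standard 20-letter alphabet).
#' @param rule \code{"trypsin_p"} or \code{"argc_propionyl"}.
#' @param missedCleavages maximum number of internal missed cleavage sites
#'   (nonnegative integer).
#' @return A data frame with columns \code{peptide}, \code{start}, \code{end}
#'   (1-based, inclusive) and \code{missed} (internal sites joined).
#' @examples
#' digestProtein("AAAKAAAR", "trypsin_p")$peptide        # "AAAK" "AAAR"
#' digestProtein("AAAKAAAR", "argc_propionyl")$peptide   # "AAAKAAAR"
#' @export
digestProtein <- function(sequence, rule = c("trypsin_p", "argc_propionyl"),
                          missedCleavages = 0L) {
  rule <- match.arg(rule)
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L,
            missedCleavages >= 0L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad))
    stop("illegal residue(s) in sequence: ", paste(bad, collapse = ", "))
  n <- length(chars)
  # cleavage after position i; a site at the C-terminus is a no-op boundary
  sites <- which(chars %in% .cleavageResidues(rule))
  bounds <- c(0L, sites[sites < n], n)      # fragment boundaries
  nf <- length(bounds) - 1L                 # number of fully-cleaved fragments
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  m <- as.integer(missedCleavages)
  res <- vector("list", m + 1L)
  for (k in 0:m) {                          # join runs of k+1 fragments
    if (k + 1L > nf) break
    i <- seq_len(nf - k)
    res[[k + 1L]] <- data.frame(start = starts[i], end = ends[i + k],
                                missed = k)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end), , drop = FALSE]
  data.frame(peptide = substring(sequence, out$start, out$end),
             start = out$start, end = out$end, missed = out$missed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count theoretically observable peptides
#'
#' Number of distinct peptide sequences produced by digestion whose length
#' falls inside \code{lengthWindow}.  With the defaults (fully-cleaved
#' peptides of 6-30 residues) this is the denominator of the iBAQ
#' calculation.
#'
#' @inheritParams digestProtein
#' @param lengthWindow inclusive \code{c(min, max)} peptide-length window.
#' @return A nonnegative integer count (possibly zero).
#' @examples
#' countObservablePeptides("AAAAAAKAAAAAAR")  # 2
#' @export
countObservablePeptides <- function(sequence,
                                    rule = c("trypsin_p", "argc_propionyl"),
                                    missedCleavages = 0L,
                                    lengthWindow = c(6L, 30L)) {
  rule <- match.arg(rule)
  stopifnot(length(lengthWindow) == 2L, lengthWindow[1] >= 1L,
            lengthWindow[1] <= lengthWindow[2])
  pep <- digestProtein(sequence, rule, missedCleavages)
  len <- pep$end - pep$start + 1L
  keep <- len >= lengthWindow[1] & len <= lengthWindow[2]
  length(unique(pep$peptide[keep]))
}

#' Compute an iBAQ table from a protein-groups table
#'
#' For each protein, iBAQ in a sample is the raw intensity divided by the
#' protein's count of theoretically observable peptides; it is proportional
#' to the molar amount of the protein in the pulldown.  \code{ibaqMean} is
#' the mean iBAQ over the treatment-group samples, with zero (missing)
#' measurements excluded; proteins undetected in every treatment sample get
#' \code{ibaqMean} 0.  Proteins with no sequence are skipped with a warning;
#' proteins whose digestion yields no observable peptide are flagged and
#' carry \code{NA} iBAQ rather than a division by zero.
#'
#' @param pg a \code{\link{ProteinGroups}} object.
#' @param fasta named character vector or AAStringSet of protein sequences.
#' @param design data frame (\code{sample}, \code{group}) or named group
#'   vector.
#' @param treatmentGroup group label whose samples define \code{ibaqMean};
#'   defaults to the first group in the design.
#' @param which assay to quantify from: \code{"intensity"} (raw, the
#'   conventional iBAQ input, default) or \code{"lfq"}.
#' @param rule,missedCleavages,lengthWindow digestion settings for the
#'   observable-peptide count (defaults: fully-cleaved tryptic peptides of
#'   6-30 residues).
#' @param aggregate how \code{ibaqMean} combines detected replicates:
#'   \code{"mean"} (default) or \code{"sum"}.
#' @return An \code{\link{IbaqTable}}.
#' @export
computeIbaq <- function(pg, fasta, design = NULL, treatmentGroup = NULL,
                        which = c("intensity", "lfq"),
                        rule = c("trypsin_p", "argc_propionyl"),
                        missedCleavages = 0L, lengthWindow = c(6L, 30L),
                        aggregate = c("mean", "sum")) {
  which <- match.arg(which)
  rule <- match.arg(rule)
  aggregate <- match.arg(aggregate)
  stopifnot(methods::is(pg, "ProteinGroups"))
  seqs <- .asSequenceVector(fasta)
  ids <- rownames(pg)
  haveSeq <- ids %in% names(seqs)
  if (!all(haveSeq)) {
    warning(sum(!haveSeq), " protein(s) without a sequence skipped: ",
            paste(utils::head(ids[!haveSeq], 5), collapse = ", "),
            if (sum(!haveSeq) > 5) ", ..." else "")
    pg <- pg[haveSeq, ]
    ids <- rownames(pg)
  }
  counts <- vapply(seqs[ids], countObservablePeptides, integer(1),
                   rule = rule, missedCleavages = missedCleavages,
                   lengthWindow = lengthWindow)
  intensity <- assay(pg, which)
  ibaq <- sweep(intensity, 1L, counts, "/")
  zeroCount <- counts == 0L
  if (any(zeroCount)) {
    warning(sum(zeroCount), " protein(s) with zero observable peptides; ",
            "their iBAQ is undefined (NA)")
    ibaq[zeroCount, ] <- NA_real_
  }

  if (is.null(design)) {
    grp <- sampleGroups(pg)
    if (is.null(grp)) grp <- stats::setNames(rep("all", ncol(pg)),
                                             colnames(pg))
  } else {
    grp <- .designGroups(design, colnames(pg))
  }
  if (is.null(treatmentGroup)) treatmentGroup <- grp[[1L]]
  trt <- names(grp)[grp == treatmentGroup]
  if (!length(trt)) stop("no samples in treatment group '", treatmentGroup, "'")
  sub <- ibaq[, trt, drop = FALSE]
  ibaqMean <- apply(sub, 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) 0 else if (aggregate == "mean") mean(v) else sum(v)
  })
  ibaqMean[zeroCount] <- NA_real_

  rd <- rowData(pg)
  rd$observablePeptides <- counts
  rd$ibaqMean <- ibaqMean
  rd$noObservablePeptides <- zeroCount
  cd <- DataFrame(group = unname(grp), row.names = names(grp))
  out <- SummarizedExperiment(
    assays = list(intensity = intensity, ibaq = ibaq),
    rowData = rd, colData = cd,
    metadata = list(treatmentGroup = treatmentGroup, which = which,
                    rule = rule, missedCleavages = missedCleavages,
                    lengthWindow = lengthWindow, aggregate = aggregate))
  new("IbaqTable", out)
}

#' Write an iBAQ table to TSV
#'
#' @param ibaq an \code{\link{IbaqTable}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIbaqTable <- function(ibaq, path) {
  stopifnot(methods::is(ibaq, "IbaqTable"))
  rd <- rowData(ibaq)
  df <- data.frame(protein = rownames(ibaq),
                   observablePeptides = rd$observablePeptides,
                   ibaqMean = rd$ibaqMean, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ib <- assay(ibaq, "ibaq")
  for (s in colnames(ib)) df[[paste0("iBAQ ", s)]] <- ib[, s]
  writeResultsTable(df, path,
                    params = S4Vectors::metadata(ibaq)[c("which", "rule")])
}
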