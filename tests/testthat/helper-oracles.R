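# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately take a different computational route from the
# package (per-pair enumeration, stats::t.test, explicit loops) so that
# agreement is evidence, not tautology.

# --- digestion oracle -------------------------------------------------------
# A substring (i, j) is a peptide with <= m missed cleavages iff it starts at
# the N-terminus or right after a cleavage residue, ends at the C-terminus or
# on a cleavage residue, and contains at most m internal cleavage residues
# (positions i..j-1).
oracleDigest <- function(sequence, rule, m) {
  chars <- strsplit(sequence, "")[[1]]
  cleav <- if (rule == "trypsin_p") c("K", "R") else "R"
  isC <- chars %in% cleav
  n <- length(chars)
  out <- list()
  for (i in seq_len(n)) {
    if (i > 1 && !isC[i - 1]) next
    for (j in i:n) {
      if (j < n && !isC[j]) next
      internal <- if (j > i) sum(isC[i:(j - 1)]) else 0L
      if (internal > m) next
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end")
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# enumerate all sequences of a given length over an alphabet
allSequences <- function(alphabet, len) {
  grids <- rep(list(alphabet), len)
  apply(do.call(expand.grid, c(grids, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

expectDigestMatchesOracle <- function(sequences, rules = c("trypsin_p",
                                                           "argc_propionyl"),
                                      ms = 0:2) {
  for (rule in rules) {
    for (m in ms) {
      for (s in sequences) {
        got <- digestProtein(s, rule, m)[, c("start", "end")]
        rownames(got) <- NULL
        want <- oracleDigest(s, rule, m)
        if (!isTRUE(all.equal(got, want))) {
          testthat::fail(sprintf("digest mismatch: seq=%s rule=%s m=%d",
                                 s, rule, m))
          return(invisible(FALSE))
        }
      }
    }
  }
  testthat::succeed()
  invisible(TRUE)
}

# --- permutation-FDR oracle -------------------------------------------------
# Brute force: stats::t.test for each protein and relabeling, explicit
# counting loops, explicit monotonization.
oraclePermutationFDR <- function(values, groups, contrast, s0 = 0) {
  trt <- which(groups == contrast[1])
  ctl <- which(groups == contrast[2])
  n <- length(trt) + length(ctl)
  cols <- c(trt, ctl)
  v <- values[, cols, drop = FALSE]
  n1 <- length(trt)
  dOf <- function(tIdx) {
    apply(v, 1L, function(row) {
      x <- row[tIdx]; y <- row[-tIdx]
      tt <- stats::t.test(x, y, var.equal = TRUE)
      se <- unname((mean(x) - mean(y)) / tt$statistic)
      if (!is.finite(se) || se == 0) se <- 0
      diff <- mean(x) - mean(y)
      if (se + s0 > 0) diff / (se + s0) else
        if (diff == 0) 0 else sign(diff) * Inf
    })
  }
  dObs <- dOf(seq_len(n1))
  combos <- utils::combn(n, n1, simplify = FALSE)
  combos <- Filter(function(ix) !identical(ix, seq_len(n1)), combos)
  dPerm <- vapply(combos, dOf, numeric(nrow(v)))
  absObs <- abs(dObs)
  fdr <- numeric(length(absObs))
  for (i in seq_along(absObs)) {
    obsCount <- sum(absObs >= absObs[i])
    permCount <- sum(abs(dPerm) >= absObs[i]) / length(combos)
    fdr[i] <- min(permCount / obsCount, 1)
  }
  ord <- order(absObs, decreasing = TRUE)
  q <- fdr
  for (k in rev(seq_along(ord))[-1]) {
    q[ord[k]] <- min(fdr[ord[k]], q[ord[k + 1]])
  }
  q
}

# --- fixture builders -------------------------------------------------------
tinyProteinGroups <- function(intensity, lfq = intensity, ids = NULL, ...) {
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(intensity)))
  if (is.null(colnames(intensity)))
    colnames(intensity) <- paste0("S", seq_len(ncol(intensity)))
  colnames(lfq) <- colnames(intensity)
  ProteinGroups(intensity, lfq, proteinIds = ids, ...)
}

sixComplexProportions <- c(0.49, 0.28, 0.15, 0.04, 0.03, 0.01)

# an IbaqTable with prescribed ibaqMean values, one protein per name
ibaqTableFromMeans <- function(means) {
  mat <- matrix(means, ncol = 1, dimnames = list(names(means), "bait_1"))
  counts <- rep(1L, length(means))
  rd <- S4Vectors::DataFrame(
    proteinIds = names(means), geneNames = NA_character_,
    reverse = FALSE, potentialContaminant = FALSE,
    onlyIdentifiedBySite = FALSE,
    observablePeptides = counts, ibaqMean = unname(means),
    noObservablePeptides = FALSE, row.names = names(means))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat, ibaq = mat), rowData = rd,
    colData = S4Vectors::DataFrame(group = "bait", row.names = "bait_1"))
  methods::new("IbaqTable", se)
}

noiseFreeDataset <- function(proportions = sixComplexProportions,
                             occupancy = 0.91, nBackground = 20, seed = 11) {
  truth <- generateGroundTruth(proportions = proportions,
                               occupancy = occupancy,
                               nBackground = nBackground, seed = seed)
  fasta <- generateSequences(truth, seed = seed)
  cfg <- simulationConfig(noiseSdLog2 = 0, dropoutMidpointLog2 = -Inf,
                          seed = seed)
  simulatePulldown(truth, fasta, cfg)
}
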