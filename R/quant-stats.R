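# ---------------------------------------------------------------------------
# Label-free differential statistics: log2 transform, median normalization,
# valid-value filtering, downshifted Gaussian imputation of MNAR missing
# values, pooled-variance two-sample t-tests, and permutation-based FDR.
# These are implemented here rather than delegated, as they are the
# quantities under test; stats::pt supplies the t tail probability.
# ---------------------------------------------------------------------------

#' Construct a log-intensity matrix directly
#'
#' @param values numeric matrix of log2 intensities with \code{NA} marking
#'   missing cells; column names are sample names.
#' @param groups character vector of group labels, one per column (recycled
#'   names are taken from the matrix).
#' @return A \code{LogIntensityMatrix}.
#' @export
logIntensityMatrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  methods::new("LogIntensityMatrix", values = values,
               groups = stats::setNames(as.character(groups),
                                        colnames(values)))
}

#' Log2-transform a protein-groups table
#'
#' Zero intensities (the table's missing-value convention) become \code{NA};
#' positive intensities become their log2.
#'
#' @param pg a \code{\link{ProteinGroups}} object.
#' @param which which assay to transform: \code{"lfq"} (the enrichment-path
#'   default) or \code{"intensity"}.
#' @param design optional design (data frame or named vector) supplying group
#'   labels; defaults to the table's own \code{group} column.
#' @return A \code{LogIntensityMatrix}.
#' @export
log2Transform <- function(pg, which = c("lfq", "intensity"), design = NULL) {
  which <- match.arg(which)
  stopifnot(methods::is(pg, "ProteinGroups"))
  m <- assay(pg, which)
  v <- ifelse(m > 0, log2(m), NA_real_)
  dimnames(v) <- dimnames(m)
  grp <- if (is.null(design)) sampleGroups(pg) else
    .designGroups(design, colnames(m))
  if (is.null(grp))
    stop("no group labels: supply 'design' or a table with a group column")
  methods::new("LogIntensityMatrix", values = v, groups = grp)
}

#' Median-normalize a log-intensity matrix
#'
#' Subtracts each column's median over present values, so every sample's
#' median log2 intensity becomes 0.  The missing mask is unchanged, and the
#' operation is idempotent.
#'
#' @param m a \code{LogIntensityMatrix}.
#' @return The normalized \code{LogIntensityMatrix}.
#' @export
medianNormalize <- function(m) {
  stopifnot(methods::is(m, "LogIntensityMatrix"))
  v <- m@values
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med))
    stop("column(s) with no present values: ",
         paste(colnames(v)[is.na(med)], collapse = ", "))
  methods::initialize(m, values = sweep(v, 2L, med, "-"))
}

#' Filter rows by minimum valid values per group
#'
#' Keeps a protein iff at least one group contains \code{minValid} or more
#' present (non-missing) measurements for it — the "minimum of three valid
#' values in at least one group" rule by default.
#'
#' @param m a \code{LogIntensityMatrix}.
#' @param minValid required number of present values (default 3).
#' @return The filtered \code{LogIntensityMatrix}.
#' @export
filterMinValid <- function(m, minValid = 3L) {
  stopifnot(methods::is(m, "LogIntensityMatrix"), minValid >= 1L)
  v <- m@values
  grp <- m@groups
  sizes <- table(grp)
  if (any(sizes < minValid))
    warning("minValid exceeds the size of group(s): ",
            paste(names(sizes)[sizes < minValid], collapse = ", "))
  keep <- rep(FALSE, nrow(v))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    keep <- keep | rowSums(!is.na(v[, cols, drop = FALSE])) >= minValid
  }
  methods::initialize(m, values = v[keep, , drop = FALSE])
}

#' Impute missing values from a downshifted Gaussian
#'
#' Models missing-not-at-random dropout: each missing cell in a column with
#' present-value mean \eqn{\mu} and standard deviation \eqn{\sigma} is drawn
#' independently from \eqn{N(\mu - downshift \cdot \sigma, (width \cdot
#' \sigma)^2)} — by default 1.8 standard deviations below the mean with width
#' 0.3, placing imputed values in the low-intensity tail where censored
#' measurements are expected to lie.  With \code{perColumn = FALSE} the
#' whole-matrix mean and standard deviation are used instead.  Columns (or
#' matrices) containing missing values must have positive standard deviation.
#'
#' @param m a \code{LogIntensityMatrix}.
#' @param width width of the imputation distribution, in units of
#'   \eqn{\sigma} (default 0.3).
#' @param downshift downshift of its mean, in units of \eqn{\sigma}
#'   (default 1.8).
#' @param perColumn impute from each sample's own distribution (default
#'   \code{TRUE}).
#' @param seed integer seed; identical seeds give identical imputations.
#' @return A fully present \code{LogIntensityMatrix}.
#' @export
imputeGaussianDownshift <- function(m, width = 0.3, downshift = 1.8,
                                    perColumn = TRUE, seed = 1L) {
  stopifnot(methods::is(m, "LogIntensityMatrix"), width > 0)
  v <- m@values
  if (!anyNA(v)) return(m)
  .withSubstream(seed, "impute", {
    if (perColumn) {
      for (j in seq_len(ncol(v))) {
        miss <- which(is.na(v[, j]))
        if (!length(miss)) next
        pres <- v[-miss, j]
        if (length(pres) < 2L)
          stop("column '", colnames(v)[j],
               "' needs >= 2 present values for per-column imputation")
        sdj <- stats::sd(pres)
        if (sdj == 0)
          stop("degenerate column '", colnames(v)[j],
               "': zero standard deviation")
        # draws keyed to row names so that reordering rows permutes the
        # imputed cells identically
        if (!is.null(rownames(v))) miss <- miss[order(rownames(v)[miss])]
        v[miss, j] <- stats::rnorm(length(miss), mean(pres) - downshift * sdj,
                                   width * sdj)
      }
    } else {
      pres <- v[!is.na(v)]
      sdg <- stats::sd(pres)
      if (is.na(sdg) || sdg == 0) stop("degenerate matrix: zero standard deviation")
      miss <- is.na(v)
      v[miss] <- stats::rnorm(sum(miss), mean(pres) - downshift * sdg,
                              width * sdg)
    }
    methods::initialize(m, values = v)
  })
}

# Pooled-variance two-sample statistics for a fully present matrix.
# Returns difference (trt - ctl), pooled standard error, t, and two-sided p.
.pooledTStats <- function(v, trtCols, ctlCols, s0 = 0) {
  x <- v[, trtCols, drop = FALSE]
  y <- v[, ctlCols, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  ss1 <- rowSums((x - m1)^2)
  ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se,
              ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[t == 0 & se == 0] <- 1
  d <- ifelse(se + s0 > 0, diff / (se + s0),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  list(difference = diff, se = se, t = t, p = p, d = d, df = df)
}

#' Two-sample Student's t-test per protein
#'
#' Two-sided pooled-variance (Student's) t-tests of treatment versus control
#' for every row of a fully imputed matrix.  With zero pooled variance the
#' statistic is \code{+/-Inf} by convention (p = 0), or 0 (p = 1) when the
#' difference is also zero.
#'
#' @param m a fully present \code{LogIntensityMatrix}.
#' @param contrast character vector \code{c(treatment, control)} naming the
#'   two groups.
#' @return A data frame with columns \code{protein}, \code{difference}
#'   (mean treatment - mean control), \code{t}, \code{p}.
#' @export
twoSampleTTest <- function(m, contrast) {
  stopifnot(methods::is(m, "LogIntensityMatrix"), length(contrast) == 2L)
  v <- m@values
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  grp <- m@groups
  trt <- which(grp == contrast[1]); ctl <- which(grp == contrast[2])
  if (length(trt) < 2L || length(ctl) < 2L)
    stop("both groups need at least 2 samples")
  st <- .pooledTStats(v, trt, ctl)
  data.frame(protein = rownames(v), difference = st$difference, t = st$t,
             p = st$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation-based FDR for two-sample tests
#'
#' Computes the moderated statistic \eqn{d_i = difference_i / (s_i + s_0)}
#' (with \eqn{s_i} the pooled-variance standard error and \eqn{s_0 = 0} by
#' default), re-computes it under permuted group labels, and converts the
#' exceedance counts into q-values: for a threshold at each observed
#' \eqn{|d|}, \code{FDR = mean permuted count of |d*| >= threshold / observed
#' count >= threshold}, monotonized by a running minimum from the least
#' significant statistic upward and capped at 1.  All distinct label
#' assignments are enumerated when there are at most \code{nPermutations} of
#' them (excluding the identity); otherwise that many distinct random
#' non-identity assignments are drawn.
#'
#' @inheritParams twoSampleTTest
#' @param fdrLevel significance threshold on q (default 0.05).
#' @param nPermutations maximum number of permutations (default 250).
#' @param s0 variance fudge factor added to the standard error (default 0).
#' @param seed integer seed for the sampled permutations.
#' @return A data frame with columns \code{protein}, \code{difference},
#'   \code{t}, \code{p}, \code{d}, \code{q}, \code{significant}.
#' @export
permutationFDR <- function(m, contrast, fdrLevel = 0.05,
                           nPermutations = 250L, s0 = 0, seed = 1L) {
  stopifnot(methods::is(m, "LogIntensityMatrix"), length(contrast) == 2L,
            fdrLevel > 0, fdrLevel < 1, s0 >= 0)
  v <- m@values
  if (anyNA(v)) stop("matrix contains missing values; impute first")
  grp <- m@groups
  use <- which(grp %in% contrast)
  v <- v[, use, drop = FALSE]
  grp <- grp[use]
  trt <- which(grp == contrast[1]); ctl <- which(grp == contrast[2])
  if (length(trt) < 2L || length(ctl) < 2L)
    stop("both groups need at least 2 samples")
  n <- length(grp); n1 <- length(trt)
  obs <- .pooledTStats(v, trt, ctl, s0 = s0)

  nDistinct <- choose(n, n1) - 1   # non-identity label assignments
  if (nDistinct < 2) stop("fewer than 2 distinct permutations available")
  identityKey <- paste(sort(trt), collapse = ",")
  if (nDistinct <= nPermutations) {
    all <- utils::combn(n, n1, simplify = FALSE)
    keys <- vapply(all, paste, character(1), collapse = ",")
    perms <- all[keys != identityKey]
  } else {
    perms <- .withSubstream(seed, "permute", {
      seen <- character(0)
      out <- vector("list", nPermutations)
      k <- 0L
      while (k < nPermutations) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        if (key == identityKey || key %in% seen) next
        k <- k + 1L
        seen <- c(seen, key)
        out[[k]] <- cand
      }
      out
    })
  }
  nPerm <- length(perms)
  permAbs <- numeric(nPerm * nrow(v))
  for (i in seq_len(nPerm)) {
    tIdx <- perms[[i]]
    cIdx <- setdiff(seq_len(n), tIdx)
    permAbs[((i - 1) * nrow(v) + 1):(i * nrow(v))] <-
      abs(.pooledTStats(v, tIdx, cIdx, s0 = s0)$d)
  }

  absd <- abs(obs$d)
  sortedObs <- sort(absd)
  sortedPerm <- sort(permAbs)
  # counts >= threshold via #{values < t}; left.open counts strictly-less
  obsGe <- length(sortedObs) -
    findInterval(absd, sortedObs, left.open = TRUE)
  permGe <- (length(sortedPerm) -
               findInterval(absd, sortedPerm, left.open = TRUE)) / nPerm
  fdr <- pmin(permGe / obsGe, 1)
  # monotonize: q at a larger |d| never exceeds q at a smaller |d|
  ord <- order(absd, decreasing = TRUE)
  qSorted <- rev(cummin(rev(fdr[ord])))
  q <- numeric(length(fdr))
  q[ord] <- qSorted
  data.frame(protein = rownames(v), difference = obs$difference, t = obs$t,
             p = obs$p, d = obs$d, q = q, significant = q <= fdrLevel,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' End-to-end enrichment analysis of a pulldown table
#'
#' Runs the full label-free workflow: remove flagged rows, log2-transform,
#' median-normalize, keep proteins with at least \code{minValid} present
#' values in some group, impute missing values from a downshifted Gaussian,
#' and test treatment versus control with pooled-variance t-tests under
#' permutation-based FDR control.  Row counts after each stage are returned
#' as a stage log.
#'
#' @param pg a \code{\link{ProteinGroups}} object.
#' @param design data frame (\code{sample}, \code{group}) or named vector.
#' @param contrast \code{c(treatment, control)} group names.
#' @param which assay feeding the statistics (default \code{"lfq"}).
#' @param minValid valid-value filter threshold (default 3).
#' @param width,downshift imputation parameters (defaults 0.3 and 1.8).
#' @param fdrLevel,nPermutations,s0 testing parameters (defaults 0.05, 250,
#'   0).
#' @param seed master seed for imputation and permutation draws.
#' @return A list with elements \code{result} (the per-protein test table)
#'   and \code{stageLog} (data frame of row counts after each stage).
#' @export
enrichmentAnalysis <- function(pg, design = NULL, contrast,
                               which = c("lfq", "intensity"),
                               minValid = 3L, width = 0.3, downshift = 1.8,
                               fdrLevel = 0.05, nPermutations = 250L,
                               s0 = 0, seed = 1L) {
  which <- match.arg(which)
  log <- data.frame(stage = "input", rows = nrow(pg),
                    stringsAsFactors = FALSE)
  pg2 <- filterFlagged(pg)
  log <- rbind(log, data.frame(stage = "filterFlagged", rows = nrow(pg2)))
  m <- log2Transform(pg2, which = which, design = design)
  m <- medianNormalize(m)
  m <- filterMinValid(m, minValid = minValid)
  log <- rbind(log, data.frame(stage = "filterMinValid", rows = nrow(m)[1]))
  if (nrow(m)[1] == 0L)
    stop("no proteins left after filtering; nothing to test")
  m <- imputeGaussianDownshift(m, width = width, downshift = downshift,
                               seed = seed)
  res <- permutationFDR(m, contrast, fdrLevel = fdrLevel,
                        nPermutations = nPermutations, s0 = s0, seed = seed)
  log <- rbind(log, data.frame(stage = "tested", rows = nrow(res)))
  list(result = res, stageLog = log)
}

#' Overlap statistics for two identifier sets
#'
#' @param setA,setB character vectors of identifiers (duplicates ignored).
#' @return A list with the set sizes, intersection size, the percentage of
#'   each set contained in the other, and the percentage unique to each set;
#'   percentages are given at full precision (\code{pctAInB}, ...) and
#'   rounded to integers (\code{pctAInBRounded}, ...).  Percentages for an
#'   empty set are \code{NA} and flagged via \code{emptySide}.
#' @examples
#' # two sets sharing 938 of 1227 / 3151 members
#' a <- as.character(seq_len(1227))
#' b <- as.character(c(seq_len(938), 10000 + seq_len(3151 - 938)))
#' setOverlap(a, b)$pctAInBRounded  # 76
#' @export
setOverlap <- function(setA, setB) {
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  nA <- length(a); nB <- length(b)
  nI <- length(intersect(a, b))
  pctA <- if (nA) 100 * nI / nA else NA_real_
  pctB <- if (nB) 100 * nI / nB else NA_real_
  uniqA <- if (nA) 100 * (nA - nI) / nA else NA_real_
  uniqB <- if (nB) 100 * (nB - nI) / nB else NA_real_
  list(nA = nA, nB = nB, nIntersection = nI,
       pctAInB = pctA, pctBInA = pctB,
       pctAUnique = uniqA, pctBUnique = uniqB,
       pctAInBRounded = if (is.na(pctA)) NA_integer_ else round(pctA),
       pctBInARounded = if (is.na(pctB)) NA_integer_ else round(pctB),
       pctAUniqueRounded = if (is.na(uniqA)) NA_integer_ else round(uniqA),
       pctBUniqueRounded = if (is.na(uniqB)) NA_integer_ else round(uniqB),
       emptySide = c("A", "B")[c(nA == 0, nB == 0)])
}
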