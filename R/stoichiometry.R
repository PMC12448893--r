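# ---------------------------------------------------------------------------
# Partitioning bait-bound material among complexes via direct-binder iBAQ
# sums; subunit stoichiometry ratios; bait mass balance; and the
# mutant-vs-reference differential-binding matrix.
# ---------------------------------------------------------------------------

#' Partition the bait among complexes
#'
#' For each catalog complex, sums the mean iBAQ of its direct binders (a
#' complex with several interchangeable direct binders has them summed);
#' the complex proportion is its sum divided by the total over all catalog
#' complexes.  Undetected direct binders contribute 0 and are listed in the
#' returned table.  Proportions are invariant to rescaling all iBAQ values,
#' and proteins outside the catalog have no effect.  If \code{baitId} is
#' supplied the bait mass balance (see \code{\link{baitMassBalance}}) is
#' attached.
#'
#' @param ibaq an \code{\link{IbaqTable}}.
#' @param catalog a \code{\link{ComplexCatalog}}.
#' @param baitId optional bait protein ID.
#' @return A \code{ComplexAbundance}; see \code{\link{baitProportions}},
#'   \code{\link{abundanceTable}}, \code{\link{massBalance}}.
#' @export
complexProportions <- function(ibaq, catalog, baitId = NULL) {
  stopifnot(methods::is(ibaq, "IbaqTable"), methods::is(catalog, "ComplexCatalog"))
  mu <- ibaqMean(ibaq)
  getIbaq <- function(id) if (id %in% names(mu) && !is.na(mu[[id]]))
    mu[[id]] else 0
  rows <- lapply(catalog@complexes, function(cx) {
    dbVals <- vapply(cx$directBinders, getIbaq, numeric(1))
    detected <- vapply(cx$members, function(id) getIbaq(id) > 0, logical(1))
    data.frame(complex = cx$name,
               directBinderIbaq = sum(dbVals),
               directBindersDetected = sum(dbVals > 0),
               directBindersTotal = length(dbVals),
               membersDetected = sum(detected),
               membersTotal = length(cx$members),
               undetectedDirectBinders = paste(
                 cx$directBinders[dbVals == 0], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  total <- sum(tb$directBinderIbaq)
  if (total <= 0)
    stop("no direct binders detected in any complex")
  tb$proportion <- tb$directBinderIbaq / total
  tb$percent <- round(100 * tb$proportion)
  tb <- tb[, c("complex", "directBinderIbaq", "proportion", "percent",
               "directBindersDetected", "directBindersTotal",
               "membersDetected", "membersTotal", "undetectedDirectBinders")]
  baitIbaq <- NA_real_; mb <- NA_real_
  if (!is.null(baitId)) {
    mb <- baitMassBalance(ibaq, baitId, catalog)
    baitIbaq <- mu[[baitId]]
  }
  methods::new("ComplexAbundance", table = tb,
               baitId = if (is.null(baitId)) NA_character_ else baitId,
               baitIbaq = baitIbaq, massBalance = mb)
}

#' Bait mass balance
#'
#' Fraction of the recovered bait accounted for by its direct binders under
#' a 1:1 binding model: the sum of mean iBAQ over every catalog complex's
#' direct binders, divided by the bait's mean iBAQ.  Values above 1 indicate
#' over-assignment and are flagged with a warning.
#'
#' @param ibaq an \code{\link{IbaqTable}}.
#' @param baitId the bait protein ID; must be detected.
#' @param catalog a \code{\link{ComplexCatalog}}.
#' @return The mass-balance fraction (nonnegative numeric).
#' @export
baitMassBalance <- function(ibaq, baitId, catalog) {
  stopifnot(methods::is(ibaq, "IbaqTable"), methods::is(catalog, "ComplexCatalog"))
  mu <- ibaqMean(ibaq)
  if (!baitId %in% names(mu) || is.na(mu[[baitId]]) || mu[[baitId]] <= 0)
    stop("bait '", baitId, "' not detected in the iBAQ table")
  binders <- unique(unlist(directBinders(catalog)))
  binderSum <- sum(vapply(binders, function(id)
    if (id %in% names(mu) && !is.na(mu[[id]])) mu[[id]] else 0, numeric(1)))
  mb <- binderSum / mu[[baitId]]
  if (mb > 1)
    warning(sprintf("mass balance %.3f > 1: direct binders over-assigned", mb))
  mb
}

#' Subunit stoichiometry ratio
#'
#' Mean-iBAQ ratio of two subunits, formatted in the conventional
#' \code{"R:1"} style (numerator normalized to one copy of the denominator).
#' An undetected denominator yields \code{NA} with a flag rather than an
#' infinite ratio.
#'
#' @param ibaq an \code{\link{IbaqTable}}.
#' @param numeratorId,denominatorId protein IDs; both must be rows of the
#'   table.
#' @return A list with \code{ratio} (numeric or \code{NA}),
#'   \code{formatted} (e.g. \code{"10.0:1"}) and \code{undefined} (logical).
#' @export
subunitRatio <- function(ibaq, numeratorId, denominatorId) {
  stopifnot(methods::is(ibaq, "IbaqTable"))
  mu <- ibaqMean(ibaq)
  for (id in c(numeratorId, denominatorId))
    if (!id %in% names(mu)) stop("protein '", id, "' not in the iBAQ table")
  num <- mu[[numeratorId]]; den <- mu[[denominatorId]]
  if (is.na(den) || den <= 0 || is.na(num))
    return(list(ratio = NA_real_, formatted = NA_character_,
                undefined = TRUE))
  r <- num / den
  list(ratio = r, formatted = sprintf("%.1f:1", r), undefined = FALSE)
}

#' Differential-binding matrix across mutants
#'
#' Assembles per-mutant enrichment results (each computed against the same
#' reference by \code{\link{enrichmentAnalysis}} or
#' \code{\link{permutationFDR}}) into a components x mutants matrix
#' restricted to catalog members, ordered by complex and member.  Components
#' absent from a mutant's results are \code{NA} (flagged
#' \code{"missing"}), never zero.  A per-complex summary counts components
#' significantly increased or decreased at \code{q <= fdrLevel}.
#'
#' @param resultsByMutant named list: mutant name -> test-result data frame
#'   with columns \code{protein}, \code{difference}, \code{q}.
#' @param catalog a \code{\link{ComplexCatalog}}.
#' @param fdrLevel significance threshold on q (default 0.05).
#' @return A \code{BindingChangeMatrix}; see \code{\link{bindingLogDiff}},
#'   \code{\link{bindingQValue}}, \code{\link{bindingSummary}}.
#' @export
differentialBindingMatrix <- function(resultsByMutant, catalog,
                                      fdrLevel = 0.05) {
  stopifnot(is.list(resultsByMutant), length(resultsByMutant) >= 1L,
            !is.null(names(resultsByMutant)),
            methods::is(catalog, "ComplexCatalog"))
  memberList <- complexMembers(catalog)
  comps <- unlist(memberList, use.names = FALSE)
  complexOf <- rep(names(memberList), lengths(memberList))
  # a shared subunit appears once per complex row-block; row names disambiguate
  rowIds <- paste(complexOf, comps, sep = ":")
  mutants <- names(resultsByMutant)
  logDiff <- qMat <- matrix(NA_real_, length(comps), length(mutants),
                            dimnames = list(rowIds, mutants))
  dirMat <- matrix("missing", length(comps), length(mutants),
                   dimnames = list(rowIds, mutants))
  for (mut in mutants) {
    res <- resultsByMutant[[mut]]
    if (is.list(res) && !is.data.frame(res) && "result" %in% names(res))
      res <- res$result
    idx <- match(comps, res$protein)
    if (all(is.na(idx)))
      stop("mutant '", mut, "' shares no proteins with the catalog")
    logDiff[, mut] <- res$difference[idx]
    qMat[, mut] <- res$q[idx]
    sig <- !is.na(idx) & res$q[idx] <= fdrLevel
    dirMat[!is.na(idx), mut] <- "ns"
    dirMat[sig & logDiff[, mut] > 0, mut] <- "increased"
    dirMat[sig & logDiff[, mut] < 0, mut] <- "decreased"
  }
  summ <- do.call(rbind, lapply(names(memberList), function(cxName) {
    rows <- complexOf == cxName
    do.call(rbind, lapply(mutants, function(mut) data.frame(
      complex = cxName, mutant = mut,
      increased = sum(dirMat[rows, mut] == "increased"),
      decreased = sum(dirMat[rows, mut] == "decreased"),
      total = sum(rows), stringsAsFactors = FALSE)))
  }))
  methods::new("BindingChangeMatrix", logDiff = logDiff, qValue = qMat,
               direction = dirMat,
               complexOf = stats::setNames(complexOf, rowIds),
               summary = summ, fdrLevel = fdrLevel)
}

#' Write a complex-abundance report to TSV
#'
#' @param abundance a \code{ComplexAbundance}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeComplexAbundance <- function(abundance, path) {
  stopifnot(methods::is(abundance, "ComplexAbundance"))
  writeResultsTable(abundance@table, path,
                    params = list(bait = abundance@baitId,
                                  massBalance = abundance@massBalance))
}
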