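#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

# ---------------------------------------------------------------------------
# ProteinGroups: a MaxQuant-dialect protein-group table.
#
# Assays "intensity" (raw) and "lfq" hold linear, nonnegative intensities with
# zero meaning "not detected".  rowData carries the full semicolon-joined
# accession string, optional gene names and the three quality flags; rownames
# are the primary (first) accession.  colData may carry a 'group' label.
# ---------------------------------------------------------------------------

#' @rdname ProteinGroups
#' @export
setClass("ProteinGroups", contains = "SummarizedExperiment")

setValidity("ProteinGroups", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("intensity", "lfq") %in% an))
    msg <- c(msg, "assays 'intensity' and 'lfq' are required")
  for (a in intersect(c("intensity", "lfq"), an)) {
    m <- assay(object, a)
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, sprintf("assay '%s' must be finite and nonnegative", a))
  }
  rd <- rowData(object)
  need <- c("proteinIds", "reverse", "potentialContaminant",
            "onlyIdentifiedBySite")
  if (!all(need %in% names(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (primary protein IDs) must be unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "colnames (sample names) must be unique")
  if (length(msg)) msg else TRUE
})

#' Protein-group intensity table
#'
#' Container for a label-free protein-group quantification table in the
#' MaxQuant dialect: one row per protein group, one column per sample, with a
#' raw \code{intensity} assay and an \code{lfq} (label-free quantification)
#' assay.  Zero intensity encodes a missing measurement.  Row metadata holds
#' the full accession list, optional gene names, and the reverse-hit,
#' potential-contaminant and only-identified-by-site quality flags.
#'
#' @param intensity numeric matrix of raw intensities (proteins x samples).
#' @param lfq numeric matrix of LFQ intensities, same dimensions; defaults to
#'   \code{intensity}.
#' @param proteinIds character vector of semicolon-joined accession lists; the
#'   first accession is used as the row name (primary ID).
#' @param geneNames optional character vector of gene names.
#' @param reverse,potentialContaminant,onlyIdentifiedBySite logical flag
#'   vectors (default all \code{FALSE}).
#' @param group optional character vector of per-sample group labels.
#'
#' @return A \code{ProteinGroups} object.
#' @examples
#' m <- matrix(c(4, 0, 8, 2), 2, 2,
#'             dimnames = list(NULL, c("bait_1", "ctrl_1")))
#' pg <- ProteinGroups(m, proteinIds = c("P1;P1b", "P2"))
#' primaryIds(pg)
#' @export
ProteinGroups <- function(intensity, lfq = intensity, proteinIds,
                          geneNames = NULL,
                          reverse = logical(nrow(intensity)),
                          potentialContaminant = logical(nrow(intensity)),
                          onlyIdentifiedBySite = logical(nrow(intensity)),
                          group = NULL) {
  intensity <- as.matrix(intensity)
  lfq <- as.matrix(lfq)
  primary <- vapply(strsplit(as.character(proteinIds), ";", fixed = TRUE),
                    `[`, character(1), 1L)
  if (anyDuplicated(primary))
    stop("duplicated primary protein IDs: ",
         paste(unique(primary[duplicated(primary)]), collapse = ", "))
  rownames(intensity) <- rownames(lfq) <- primary
  rd <- DataFrame(
    proteinIds = as.character(proteinIds),
    geneNames = if (is.null(geneNames)) NA_character_ else
      as.character(geneNames),
    reverse = as.logical(reverse),
    potentialContaminant = as.logical(potentialContaminant),
    onlyIdentifiedBySite = as.logical(onlyIdentifiedBySite)
  )
  cd <- DataFrame(row.names = colnames(intensity))
  if (!is.null(group)) cd$group <- as.character(group)
  new("ProteinGroups",
      SummarizedExperiment(assays = list(intensity = intensity, lfq = lfq),
                           rowData = rd, colData = cd))
}

#' @describeIn ProteinGroups primary (first) accession per row.
#' @param x a \code{ProteinGroups} object.
#' @export
primaryIds <- function(x) rownames(x)

#' @describeIn ProteinGroups sample names.
#' @export
sampleNames <- function(x) colnames(x)

#' @describeIn ProteinGroups per-sample group labels (or NULL).
#' @export
sampleGroups <- function(x) {
  cd <- colData(x)
  if ("group" %in% names(cd)) stats::setNames(cd$group, rownames(cd)) else NULL
}

# ---------------------------------------------------------------------------
# IbaqTable: per-protein iBAQ values.
# ---------------------------------------------------------------------------

#' @rdname IbaqTable-class
#' @export
setClass("IbaqTable", contains = "SummarizedExperiment")

setValidity("IbaqTable", function(object) {
  msg <- character()
  if (!all(c("intensity", "ibaq") %in% assayNames(object)))
    msg <- c(msg, "assays 'intensity' and 'ibaq' are required")
  rd <- rowData(object)
  if (!all(c("observablePeptides", "ibaqMean") %in% names(rd)))
    msg <- c(msg, "rowData must contain observablePeptides and ibaqMean")
  ib <- assay(object, "ibaq")
  ok <- !is.na(ib)
  if (any(ib[ok] < 0)) msg <- c(msg, "iBAQ values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' iBAQ quantification table
#'
#' Per-protein iBAQ values: raw intensity divided by the number of
#' theoretically observable peptides.  Rows whose protein has zero observable
#' peptides carry \code{NA} iBAQ and are flagged.  Built by
#' \code{\link{computeIbaq}}.
#'
#' @param x an \code{IbaqTable}.
#' @name IbaqTable-class
#' @aliases IbaqTable
NULL

#' @describeIn IbaqTable-class named vector of mean iBAQ over detected
#'   treatment-group replicates (zeros excluded).
#' @export
ibaqMean <- function(x) {
  stats::setNames(rowData(x)$ibaqMean, rownames(x))
}

#' @describeIn IbaqTable-class named integer vector of observable-peptide
#'   counts.
#' @export
observablePeptides <- function(x) {
  stats::setNames(rowData(x)$observablePeptides, rownames(x))
}

# ---------------------------------------------------------------------------
# ComplexCatalog
# ---------------------------------------------------------------------------

#' @rdname ComplexCatalog
#' @export
setClass("ComplexCatalog", representation(complexes = "list"))

setValidity("ComplexCatalog", function(object) {
  msg <- character()
  for (cx in object@complexes) {
    if (!all(c("name", "members", "directBinders") %in% names(cx))) {
      msg <- c(msg, "each complex needs name, members, directBinders")
      next
    }
    if (!length(cx$directBinders))
      msg <- c(msg, sprintf("complex '%s' has no direct binders", cx$name))
    if (!all(cx$directBinders %in% cx$members))
      msg <- c(msg, sprintf(
        "complex '%s': direct binders not among members: %s", cx$name,
        paste(setdiff(cx$directBinders, cx$members), collapse = ", ")))
    if (!is.null(cx$stoichiometry) &&
        !all(names(cx$stoichiometry) %in% cx$members))
      msg <- c(msg, sprintf(
        "complex '%s': stoichiometry entries for non-members", cx$name))
  }
  nm <- vapply(object@complexes, function(cx) cx$name %||% NA_character_,
               character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "duplicated complex names")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Catalog of protein complexes
#'
#' A curated catalog mapping each complex to its member subunits and the
#' subset that binds the bait directly (used to partition bait-bound material
#' among complexes).  A protein may belong to several complexes (shared
#' subunits such as the histone chaperones of the RBBP4/RBBP7 type).
#' Optional per-subunit stoichiometry multipliers record expected copy numbers
#' per complex (e.g. 2 for a twice-present subunit); they default to 1 and are
#' reporting metadata only.
#'
#' @param complexes a list; each element a list with elements \code{name},
#'   \code{members} (character), \code{directBinders} (character, subset of
#'   members) and optionally \code{stoichiometry} (named numeric).
#' @return A \code{ComplexCatalog}.
#' @examples
#' cat <- ComplexCatalog(list(
#'   list(name = "NuRD", members = c("MTA1", "MBD3", "CHD4"),
#'        directBinders = "MTA1")))
#' complexNames(cat)
#' @export
ComplexCatalog <- function(complexes) {
  complexes <- lapply(complexes, function(cx) {
    cx$members <- as.character(cx$members)
    cx$directBinders <- as.character(cx$directBinders)
    cx
  })
  new("ComplexCatalog", complexes = complexes)
}

#' @describeIn ComplexCatalog complex names, in catalog order.
#' @param x a \code{ComplexCatalog}.
#' @export
complexNames <- function(x) {
  vapply(x@complexes, function(cx) cx$name, character(1))
}

#' @describeIn ComplexCatalog named list of member IDs per complex.
#' @export
complexMembers <- function(x) {
  stats::setNames(lapply(x@complexes, function(cx) cx$members),
                  complexNames(x))
}

#' @describeIn ComplexCatalog named list of direct-binder IDs per complex.
#' @export
directBinders <- function(x) {
  stats::setNames(lapply(x@complexes, function(cx) cx$directBinders),
                  complexNames(x))
}

setMethod("show", "ComplexCatalog", function(object) {
  cat("ComplexCatalog with", length(object@complexes), "complexes\n")
  for (cx in object@complexes)
    cat(sprintf("  %s: %d members, %d direct binders\n", cx$name,
                length(cx$members), length(cx$directBinders)))
})

setMethod("length", "ComplexCatalog", function(x) length(x@complexes))

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' @rdname generateGroundTruth
#' @export
setClass("GroundTruth", representation(
  complexes = "list",        # list(name, members, directBinders)
  copyNumber = "numeric",    # named: all proteins incl. bait & background
  baitId = "character",
  trueProportions = "numeric",
  backgroundIds = "character",
  occupancy = "numeric",
  baitAmount = "numeric"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  for (cx in object@complexes) {
    if (!length(cx$directBinders))
      msg <- c(msg, sprintf("complex '%s' has no direct binder", cx$name))
    if (!all(cx$directBinders %in% cx$members))
      msg <- c(msg, sprintf("complex '%s': direct binders must be members",
                            cx$name))
  }
  if (abs(sum(object@trueProportions) - 1) > 1e-9)
    msg <- c(msg, "trueProportions must sum to 1")
  if (any(object@trueProportions < 0))
    msg <- c(msg, "trueProportions must be nonnegative")
  boundSum <- sum(unlist(lapply(object@complexes, function(cx)
    object@copyNumber[cx$directBinders])))
  if (boundSum > object@copyNumber[[object@baitId]] + 1e-9)
    msg <- c(msg, "direct-binder copies exceed bait copies (1:1 binding)")
  allIds <- unique(c(unlist(lapply(object@complexes, `[[`, "members")),
                     object@baitId, object@backgroundIds))
  if (!all(allIds %in% names(object@copyNumber)))
    msg <- c(msg, "every protein needs a copy number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@complexes), "complexes,",
      length(object@backgroundIds), "background proteins\n")
  cat("  bait:", object@baitId, " occupancy:", object@occupancy, "\n")
  cat("  true proportions:",
      paste(sprintf("%s=%.3f", names(object@trueProportions),
                    object@trueProportions), collapse = " "), "\n")
})

#' @describeIn generateGroundTruth named vector of true per-complex bait
#'   fractions.
#' @param truth a \code{GroundTruth}.
#' @export
trueProportions <- function(truth) truth@trueProportions

#' @describeIn generateGroundTruth named vector of expected molecule counts
#'   per protein.
#' @export
copyNumbers <- function(truth) truth@copyNumber

#' @describeIn generateGroundTruth bait protein ID.
#' @export
baitId <- function(truth) truth@baitId

#' Convert a ground truth to the catalog its analysis would use
#'
#' @param truth a \code{GroundTruth}.
#' @return A \code{ComplexCatalog} with the same complexes, members and
#'   direct binders.
#' @export
asComplexCatalog <- function(truth) {
  stopifnot(methods::is(truth, "GroundTruth"))
  ComplexCatalog(lapply(truth@complexes, function(cx)
    list(name = cx$name, members = cx$members,
         directBinders = cx$directBinders)))
}

# ---------------------------------------------------------------------------
# LogIntensityMatrix
# ---------------------------------------------------------------------------

#' @rdname log2Transform
#' @export
setClass("LogIntensityMatrix", representation(
  values = "matrix",   # log2 intensities; NA = missing
  groups = "character" # named by sample
))

setValidity("LogIntensityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (any(is.infinite(v) | is.nan(v), na.rm = TRUE))
    msg <- c(msg, "present values must be finite")
  if (is.null(colnames(v)) || !identical(colnames(v), names(object@groups)))
    msg <- c(msg, "groups must be named by the matrix column names")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LogIntensityMatrix", function(object) {
  v <- object@values
  cat(sprintf("LogIntensityMatrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  cat("  groups:", paste(sprintf("%s(n=%d)", names(table(object@groups)),
                                 table(object@groups)), collapse = " "), "\n")
})

setMethod("dim", "LogIntensityMatrix", function(x) dim(x@values))

#' @describeIn log2Transform extract the log2 matrix (\code{NA} = missing).
#' @export
logValues <- function(m) m@values

#' @describeIn log2Transform extract the named group labels.
#' @export
groupLabels <- function(m) m@groups

# ---------------------------------------------------------------------------
# ComplexAbundance
# ---------------------------------------------------------------------------

#' @rdname complexProportions
#' @export
setClass("ComplexAbundance", representation(
  table = "data.frame", baitId = "character", baitIbaq = "numeric",
  massBalance = "numeric"
))

setValidity("ComplexAbundance", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(c("complex", "directBinderIbaq", "proportion", "percent",
             "membersDetected") %in% names(tb)))
    msg <- c(msg, "abundance table missing required columns")
  if (nrow(tb) && abs(sum(tb$proportion) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1")
  if (nrow(tb) && any(tb$proportion < 0))
    msg <- c(msg, "proportions must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ComplexAbundance", function(object) {
  cat("ComplexAbundance over", nrow(object@table), "complexes\n")
  tb <- object@table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s %5.1f%%  (iBAQ sum %.4g, %d/%d members detected)\n",
                tb$complex[i], 100 * tb$proportion[i], tb$directBinderIbaq[i],
                tb$membersDetected[i], tb$membersTotal[i]))
  if (!is.na(object@massBalance))
    cat(sprintf("  bait %s mass balance: %.3f\n", object@baitId,
                object@massBalance))
})

#' @describeIn complexProportions named vector of per-complex proportions.
#' @export
baitProportions <- function(x) {
  stats::setNames(x@table$proportion, x@table$complex)
}

#' @describeIn complexProportions the full per-complex table.
#' @export
abundanceTable <- function(x) x@table

#' @describeIn complexProportions bait mass-balance fraction (NA when no bait
#'   was supplied).
#' @export
massBalance <- function(x) x@massBalance

# ---------------------------------------------------------------------------
# BindingChangeMatrix
# ---------------------------------------------------------------------------

#' @rdname differentialBindingMatrix
#' @export
setClass("BindingChangeMatrix", representation(
  logDiff = "matrix", qValue = "matrix", direction = "matrix",
  complexOf = "character", summary = "data.frame", fdrLevel = "numeric"
))

setMethod("show", "BindingChangeMatrix", function(object) {
  cat(sprintf("BindingChangeMatrix: %d components x %d mutants (q <= %g)\n",
              nrow(object@logDiff), ncol(object@logDiff), object@fdrLevel))
  print(object@summary)
})

#' @describeIn differentialBindingMatrix components x mutants matrix of log2
#'   differences versus the reference.
#' @export
bindingLogDiff <- function(x) x@logDiff

#' @describeIn differentialBindingMatrix matching matrix of permutation-FDR
#'   q-values.
#' @export
bindingQValue <- function(x) x@qValue

#' @describeIn differentialBindingMatrix per-complex counts of significantly
#'   increased/decreased components per mutant.
#' @export
bindingSummary <- function(x) x@summary

# ---------------------------------------------------------------------------
# SyntheticDataset
# ---------------------------------------------------------------------------

#' @rdname simulatePulldown
#' @export
setClass("SyntheticDataset", representation(
  proteinGroups = "ProteinGroups", fasta = "character",
  truth = "GroundTruth", design = "data.frame"
))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  ids <- rownames(object@proteinGroups)
  if (!all(ids %in% names(object@fasta)))
    msg <- c(msg, "every protein in the table needs a sequence")
  if (!setequal(object@design$sample, colnames(object@proteinGroups)))
    msg <- c(msg, "design samples must match table samples")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@proteinGroups), "proteins,",
      ncol(object@proteinGroups), "samples\n")
  print(object@truth)
})

#' @describeIn simulatePulldown the simulated \code{ProteinGroups} table.
#' @export
proteinGroups <- function(x) x@proteinGroups

#' @describeIn simulatePulldown the simulated sequences (named character).
#' @export
fastaSequences <- function(x) x@fasta

#' @describeIn simulatePulldown the generating \code{GroundTruth}.
#' @export
groundTruth <- function(x) x@truth

#' @describeIn simulatePulldown the sample-to-group design table.
#' @export
sampleDesign <- function(x) x@design
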