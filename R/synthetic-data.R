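# ---------------------------------------------------------------------------
# Synthetic AP-MS scenarios: ground truth -> sequences -> pulldown tables.
# The simulator encodes the assumptions the analysis relies on: expected
# linear intensity proportional to copy number x observable peptides, 1:1
# bait:binder occupancy, log-normal measurement noise, and intensity-
# dependent (missing-not-at-random) dropout.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Bundles the stochastic parameters of \code{\link{simulatePulldown}}.  All
#' draws derive from named substreams of \code{seed}, so identical
#' configurations reproduce bit-identical tables and adding one stage never
#' perturbs another's draws.
#'
#' @param nReplicates bait-group replicates (default 4, a typical
#'   biological-replicate design).
#' @param nControlReplicates control-group replicates (default: same as
#'   \code{nReplicates}).
#' @param noiseSdLog2 standard deviation of multiplicative log-normal
#'   measurement noise, in log2 units (default 0.2).
#' @param dropoutMidpointLog2 log2 intensity at which the dropout probability
#'   is 1/2 (default 20; set to \code{-Inf} to disable dropout).
#' @param dropoutSteepness logistic slope of the dropout curve (default 1).
#' @param responseFactor global linear response factor converting
#'   copies x peptides to intensity units (default 1e6).
#' @param seed master seed (integer).
#' @return A named list of validated settings.
#' @export
simulationConfig <- function(nReplicates = 4L,
                             nControlReplicates = nReplicates,
                             noiseSdLog2 = 0.2,
                             dropoutMidpointLog2 = 20,
                             dropoutSteepness = 1,
                             responseFactor = 1e6,
                             seed = 1L) {
  stopifnot(nReplicates >= 1L, nControlReplicates >= 1L, noiseSdLog2 >= 0,
            dropoutSteepness > 0, responseFactor > 0)
  list(nReplicates = as.integer(nReplicates),
       nControlReplicates = as.integer(nControlReplicates),
       noiseSdLog2 = noiseSdLog2,
       dropoutMidpointLog2 = dropoutMidpointLog2,
       dropoutSteepness = dropoutSteepness,
       responseFactor = responseFactor,
       seed = as.integer(seed))
}

#' Generate a ground-truth complex scenario
#'
#' Builds a bait protein partitioned among \code{nComplexes} multiprotein
#' complexes under a 1:1 bait:direct-binder binding model.  Within complex
#' \code{c}, the direct-binder copy numbers sum to
#' \code{proportions[c] * baitAmount * occupancy}; the slack
#' \code{1 - occupancy} models free (unassigned) bait.  Non-direct members
#' receive the complex amount scaled by a per-subunit stoichiometry
#' multiplier drawn log-uniformly from \code{stoichRange} (so sub- and
#' super-stoichiometric subunits both occur).  Background contaminants get
#' log-normal copy numbers spanning the dropout regime.
#'
#' @param nComplexes number of complexes; must equal
#'   \code{length(proportions)}.
#' @param proportions per-complex fractions of bound bait; must be
#'   nonnegative and sum to 1.
#' @param membersPerComplex inclusive integer range for members per complex.
#' @param nDirectBinders inclusive integer range for direct binders per
#'   complex (capped at the member count).
#' @param nBackground number of background contaminant proteins.
#' @param baitAmount bait copy number (arbitrary linear units).
#' @param occupancy fraction of bait bound across all complexes, in (0, 1];
#'   default 0.91.
#' @param stoichRange range of non-direct-member stoichiometry multipliers.
#' @param backgroundMeanLog,backgroundSdLog log-normal parameters (natural
#'   log) of background copy numbers.
#' @param seed integer seed; identical seeds give identical objects.
#' @return A \code{GroundTruth} object.
#' @examples
#' truth <- generateGroundTruth(
#'   proportions = c(0.49, 0.28, 0.15, 0.04, 0.03, 0.01), seed = 1)
#' trueProportions(truth)
#' @export
generateGroundTruth <- function(nComplexes = length(proportions),
                                proportions,
                                membersPerComplex = c(4L, 8L),
                                nDirectBinders = c(1L, 3L),
                                nBackground = 50L,
                                baitAmount = 100,
                                occupancy = 0.91,
                                stoichRange = c(0.25, 2),
                                backgroundMeanLog = log(0.5),
                                backgroundSdLog = 2,
                                seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", sum(proportions), ")")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (nComplexes != length(proportions))
    stop("nComplexes must equal length(proportions)")
  stopifnot(occupancy > 0, occupancy <= 1, baitAmount > 0)
  .withSubstream(seed, "truth", {
    baitId <- "BAIT"
    cxNames <- paste0("CPLX", seq_len(nComplexes))
    complexes <- vector("list", nComplexes)
    copy <- c(stats::setNames(baitAmount, baitId))
    for (i in seq_len(nComplexes)) {
      nm <- sample(membersPerComplex[1]:membersPerComplex[2], 1L)
      nd <- min(sample(nDirectBinders[1]:nDirectBinders[2], 1L), nm)
      members <- sprintf("%s_P%02d", cxNames[i], seq_len(nm))
      direct <- members[seq_len(nd)]
      amount <- proportions[i] * baitAmount * occupancy
      w <- stats::runif(nd, 0.5, 1.5)
      copy[direct] <- amount * w / sum(w)
      rest <- setdiff(members, direct)
      if (length(rest)) {
        mult <- exp(stats::runif(length(rest), log(stoichRange[1]),
                                 log(stoichRange[2])))
        copy[rest] <- amount * mult
      }
      complexes[[i]] <- list(name = cxNames[i], members = members,
                             directBinders = direct)
    }
    backgroundIds <- character(0)
    if (nBackground > 0) {
      backgroundIds <- sprintf("BG_%04d", seq_len(nBackground))
      copy[backgroundIds] <- exp(stats::rnorm(nBackground, backgroundMeanLog,
                                              backgroundSdLog))
    }
    methods::new("GroundTruth", complexes = complexes, copyNumber = copy,
                 baitId = baitId,
                 trueProportions = stats::setNames(proportions, cxNames),
                 backgroundIds = backgroundIds, occupancy = occupancy,
                 baitAmount = baitAmount)
  })
}

#' Generate random protein sequences for a ground truth
#'
#' Random sequences over the 20-letter amino-acid alphabet with a stated
#' combined Lys+Arg frequency (default 0.11, a typical proteome value) and
#' uniform lengths in \code{lengthRange}.  All residue frequencies other than
#' K, R and P are uniform over the remaining letters.
#'
#' @param truth a \code{GroundTruth} (one sequence per protein) or a
#'   character vector of protein IDs.
#' @param lengthRange inclusive integer range of sequence lengths (default
#'   200-1500).
#' @param krFrequency combined frequency of K and R (split equally).
#' @param pFrequency frequency of P.
#' @param seed integer seed.
#' @return Named character vector of sequences.
#' @export
generateSequences <- function(truth, lengthRange = c(200L, 1500L),
                              krFrequency = 0.11, pFrequency = 0.05,
                              seed = 1L) {
  ids <- if (methods::is(truth, "GroundTruth")) names(truth@copyNumber)
         else as.character(truth)
  if (lengthRange[1] > lengthRange[2] || lengthRange[1] < 1)
    stop("empty sequence length range")
  if (krFrequency + pFrequency > 1)
    stop("residue frequencies exceed 1")
  other <- setdiff(.AA20, c("K", "R", "P"))
  probs <- c(stats::setNames(rep(krFrequency / 2, 2), c("K", "R")),
             P = pFrequency,
             stats::setNames(rep((1 - krFrequency - pFrequency) /
                                   length(other), length(other)), other))
  .withSubstream(seed, "sequences", {
    lens <- sample(lengthRange[1]:lengthRange[2], length(ids), replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    stats::setNames(seqs, ids)
  })
}

#' Simulate a bait-pulldown protein-groups table
#'
#' The expected linear intensity of protein \code{p} in a bait-group sample
#' is \code{copyNumber(p) * observablePeptides(p) * responseFactor}; each
#' replicate measurement is multiplied by independent log-normal noise of
#' standard deviation \code{noiseSdLog2} (log2 units) and then set to missing
#' (zero, the table convention) with probability
#' \code{plogis(-steepness * (log2(intensity) - midpoint))}, so low-intensity
#' measurements drop out preferentially.  Control samples contain background
#' contaminants only, at the same expected intensity as in the bait group;
#' bait and true interactors are absent from them.  LFQ columns mirror the
#' raw columns (the simulator does not model cross-sample normalization).
#'
#' @param truth a \code{GroundTruth}.
#' @param fasta named sequences covering every protein in \code{truth}.
#' @param config a \code{\link{simulationConfig}} list.
#' @return A \code{SyntheticDataset} holding the \code{ProteinGroups} table,
#'   the sequences, the generating truth, and the sample design (groups
#'   \code{"bait"} and \code{"control"}).
#' @export
simulatePulldown <- function(truth, fasta, config = simulationConfig()) {
  stopifnot(methods::is(truth, "GroundTruth"))
  seqs <- .asSequenceVector(fasta)
  ids <- names(truth@copyNumber)
  missingSeq <- setdiff(ids, names(seqs))
  if (length(missingSeq))
    stop("no sequence for: ", paste(missingSeq, collapse = ", "))
  counts <- vapply(seqs[ids], countObservablePeptides, integer(1))
  if (any(counts == 0L))
    warning("protein(s) with zero observable peptides get intensity 0: ",
            paste(ids[counts == 0L], collapse = ", "))

  nb <- config$nReplicates
  nc <- config$nControlReplicates
  samples <- c(sprintf("bait_%d", seq_len(nb)), sprintf("ctrl_%d", seq_len(nc)))
  groups <- c(rep("bait", nb), rep("control", nc))
  inControl <- ids %in% truth@backgroundIds
  expected <- truth@copyNumber[ids] * counts * config$responseFactor
  baseline <- outer(expected, rep(1, nb + nc))
  baseline[!inControl, groups == "control"] <- 0
  colnames(baseline) <- samples

  noisy <- .withSubstream(config$seed, "noise", {
    noise <- matrix(stats::rnorm(length(baseline), 0, config$noiseSdLog2),
                    nrow(baseline))
    baseline * 2^noise
  })
  noisy[baseline == 0] <- 0

  final <- .withSubstream(config$seed, "dropout", {
    pos <- noisy > 0
    pmiss <- matrix(0, nrow(noisy), ncol(noisy))
    pmiss[pos] <- stats::plogis(-config$dropoutSteepness *
                                  (log2(noisy[pos]) -
                                     config$dropoutMidpointLog2))
    drop <- matrix(stats::runif(length(noisy)), nrow(noisy)) < pmiss
    out <- noisy
    out[drop] <- 0
    out
  })

  pg <- ProteinGroups(intensity = final, proteinIds = ids, group = groups)
  design <- data.frame(sample = samples, group = groups,
                       stringsAsFactors = FALSE)
  methods::new("SyntheticDataset", proteinGroups = pg, fasta = seqs[ids],
               truth = truth, design = design)
}
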