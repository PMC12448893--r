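#' @importFrom methods new validObject is slot
#' @importFrom stats median pt rnorm runif sd setNames
#' @importFrom utils combn read.delim write.table packageVersion head
NULL

# Named substreams derived from one master seed, so that adding a stochastic
# stage never perturbs another stage's draws.  Offsets are fixed per stream.
.SUBSTREAMS <- c(
  truth = 101L, sequences = 211L, noise = 307L, dropout = 401L,
  impute = 503L, permute = 601L, histone = 701L, misc = 811L
)

.substreamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- .SUBSTREAMS[[match.arg(stream, names(.SUBSTREAMS))]]
  # keep within 32-bit integer range
  as.integer((abs(as.numeric(seed)) * 1009 + off) %% 2147483647)
}

.withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(.substreamSeed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

# Accept an AAStringSet or a named character vector of sequences.
.asSequenceVector <- function(fasta) {
  if (methods::is(fasta, "XStringSet")) {
    out <- as.character(fasta)
  } else if (is.character(fasta)) {
    out <- fasta
  } else {
    stop("'fasta' must be an AAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == ""))
    stop("all sequences must be named by protein ID")
  toupper(out)
}

# design: data.frame(sample, group) or a named character vector.
.designGroups <- function(design, samples) {
  if (is.data.frame(design)) {
    if (!all(c("sample", "group") %in% names(design)))
      stop("design must have columns 'sample' and 'group'")
    grp <- stats::setNames(as.character(design$group), design$sample)
  } else if (!is.null(names(design))) {
    grp <- stats::setNames(as.character(design), names(design))
  } else {
    stop("design must be a data.frame(sample, group) or a named vector")
  }
  if (anyDuplicated(names(grp)))
    stop("duplicated sample names in design")
  missing <- setdiff(samples, names(grp))
  if (length(missing))
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  grp[samples]
}
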