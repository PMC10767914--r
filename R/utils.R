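#' @import methods
#' @importFrom stats cor fisher.test pbinom rbinom rgamma rnorm runif setNames
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
## All stochastic operations in the package funnel through this so that an
## explicit seed fully determines their output.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

## DNA string -> integer codes A=1 C=2 G=3 T=4 N=5; anything else is an error.
encodeDNA <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
                 c(DNA_BASES, "N"))
  if (anyNA(codes)) {
    stop("sequence contains characters outside ACGTN")
  }
  codes
}

decodeDNA <- function(codes) {
  paste(c(DNA_BASES, "N")[codes], collapse = "")
}

revcompDNA <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(seq, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), ""))
}

## character vector in, character vector out; keeps names
asSequenceCharacters <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) {
    x
  } else {
    stop("expected a character vector or a DNAStringSet")
  }
}
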