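#' @importFrom BiocGenerics counts score
NULL

#' Generic accessors
#'
#' `name()` returns a motif's identifier; `sequences()` the DNAStringSet
#' underlying a [SequenceSet-class]. `counts()`, `weights()` and `score()`
#' reuse the BiocGenerics / stats generics.
#'
#' @param object a pwmbench object
#' @return the accessed component
#' @export
setGeneric("name", function(object) standardGeneric("name"))

#' @rdname name
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname name
#' @export
setGeneric("weights")
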