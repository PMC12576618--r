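#' @rdname dictionary
#' @export
setGeneric("dictionary", function(x) standardGeneric("dictionary"))

#' @rdname parseIds
#' @export
setGeneric("parseIds", function(x) standardGeneric("parseIds"))

#' @rdname parseParams
#' @export
setGeneric("parseParams", function(x) standardGeneric("parseParams"))

#' @rdname textLength
#' @export
setGeneric("textLength", function(x) standardGeneric("textLength"))

#' Count occurrences of a pattern
#'
#' Generic for counting the (possibly overlapping) occurrences of a query
#' pattern in an indexed text.  See the \linkS4class{PFPFMIndex} method in
#' \code{\link{countOccurrences,PFPFMIndex-method}}.
#'
#' @param x an index object.
#' @param pattern character(1) query.
#' @param ... passed to methods.
#' @return A non-negative integer count (see methods).
#' @export
setGeneric("countOccurrences",
           function(x, pattern, ...) standardGeneric("countOccurrences"))
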