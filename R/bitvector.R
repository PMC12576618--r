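#' Construct a marking bitvector
#'
#' @param bits logical vector.
#' @return A \linkS4class{MarkBitvector} with precomputed rank/select
#'   support.
#' @export
MarkBitvector <- function(bits) {
    bits <- as.logical(bits)
    new("MarkBitvector", bits = bits,
        rcum = c(0L, cumsum(bits)),
        ones = which(bits) - 1L)
}

#' Rank and select on a marking bitvector
#'
#' \code{bvRank1(bv, i)} counts the ones in \code{bits[0..i-1]} (0-based,
#' so \code{bvRank1(bv, 0) == 0}); \code{bvSelect1(bv, k)} returns the
#' 0-based position of the k-th one (k is 1-based).
#'
#' @param bv a \linkS4class{MarkBitvector}.
#' @param i integer, 0 <= i <= length(bits).
#' @param k integer, 1 <= k <= number of ones.
#' @return integer.
#' @examples
#' bv <- MarkBitvector(c(TRUE, FALSE, TRUE))
#' bvRank1(bv, 3)    # 2
#' bvSelect1(bv, 2)  # 2
#' @export
bvRank1 <- function(bv, i) {
    stopifnot(i >= 0L, i <= length(bv@bits))
    bv@rcum[i + 1L]
}

#' @rdname bvRank1
#' @export
bvSelect1 <- function(bv, k) {
    if (any(k < 1L) || any(k > length(bv@ones)))
        stop("select1 index out of range")
    bv@ones[k]
}

## Number of maximal runs of ones (bounded by the distinct-trigger count;
## checked in tests).
bvRuns1 <- function(bv) {
    r <- rle(bv@bits)
    sum(r$values)
}

setMethod("show", "MarkBitvector", function(object) {
    cat("MarkBitvector: length", length(object@bits), "with",
        length(object@ones), "ones in", bvRuns1(object), "runs\n")
})
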