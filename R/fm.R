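# FM-index core: suffix array, BWT, rank, backward search, all over dense
# 0-based integer codes.  The terminal invariant (unique smallest symbol,
# final position) makes cyclic-shift order equal suffix order, which the
# two-level construction relies on.

OCC_TABLE_MAX_SIGMA <- 64L  # cumulative table below, position lists above

checkIntText <- function(x) {
    if (!length(x)) stop("empty text")
    mn <- min(x)
    if (mn < 0L) stop("symbols must be non-negative")
    if (x[length(x)] != mn || sum(x == mn) != 1L)
        stop("the smallest symbol must be unique and at the final position")
    invisible(x)
}

#' Suffix array of an integer text
#'
#' 0-based suffix array: \code{sa[i+1]} is the start of the i-th smallest
#' suffix.  The smallest symbol must be unique and final (the terminal), so
#' suffix order coincides with cyclic-rotation order.  Construction is
#' prefix-doubling with counting sort (O(n log n), compiled).
#'
#' @param x integer vector of 0-based symbol codes, or a character(1)
#'   (encoded over its own alphabet, sentinel smallest).
#' @return integer vector, a permutation of 0..n-1.
#' @examples
#' buildSuffixArray(c(1L, 2L, 0L))  # "AB$" -> 2 0 1
#' @export
buildSuffixArray <- function(x) {
    if (is.character(x)) x <- encodeText(x, makeAlphabet(x))
    x <- as.integer(x)
    checkIntText(x)
    sa_int_cpp(x)
}

#' FM-index from a text and its suffix array
#'
#' Builds the Burrows-Wheeler transform \code{bwt[i] = x[(sa[i]-1) mod n]},
#' the cumulative count array C and the rank structure.
#'
#' @param x integer vector of 0-based symbol codes (terminal invariant as
#'   in \code{\link{buildSuffixArray}}).
#' @param sa its 0-based suffix array.
#' @return An \linkS4class{FMIndex}.
#' @examples
#' x <- c(1L, 2L, 0L)            # "AB$"
#' fm <- bwtFromSA(x, buildSuffixArray(x))
#' fm@bwt                        # 2 0 1 == "B$A"
#' @export
bwtFromSA <- function(x, sa) {
    x <- as.integer(x)
    n <- length(x)
    stopifnot(length(sa) == n)
    bwt <- x[(sa - 1L) %% n + 1L]
    sigma <- max(x) + 1L
    counts <- tabulate(bwt + 1L, nbins = sigma)
    C <- c(0L, cumsum(counts))
    if (sigma <= OCC_TABLE_MAX_SIGMA) {
        occTab <- vapply(seq_len(sigma) - 1L,
                         function(s) c(0L, cumsum(bwt == s)),
                         integer(n + 1L))
        occPos <- list()
    } else {
        occTab <- matrix(integer(0), 0L, 0L)
        occPos <- unname(split(seq_len(n) - 1L,
                               factor(bwt, levels = seq_len(sigma) - 1L)))
    }
    new(Class = "FMIndex", bwt = bwt, C = C, n = n, sigma = sigma,
        occTab = occTab, occPos = occPos)
}

#' Build an FM-index in one step
#'
#' @param x integer codes or character(1), as \code{\link{buildSuffixArray}}.
#' @return An \linkS4class{FMIndex}.
#' @export
buildFMIndex <- function(x) {
    if (is.character(x)) x <- encodeText(x, makeAlphabet(x))
    x <- as.integer(x)
    checkIntText(x)
    bwtFromSA(x, sa_int_cpp(x))
}

#' Rank query on the BWT
#'
#' Number of occurrences of \code{symbol} in \code{bwt[0..i-1]} (0-based);
#' \code{bwtRank(fm, s, 0) == 0}.  Unknown symbols have rank 0.
#'
#' @param fm an \linkS4class{FMIndex}.
#' @param symbol integer 0-based code.
#' @param i integer position, 0 <= i <= n.
#' @return integer count.
#' @export
bwtRank <- function(fm, symbol, i) {
    stopifnot(i >= 0L, i <= fm@n)
    if (is.na(symbol) || symbol < 0L || symbol >= fm@sigma) return(0L)
    if (ncol(fm@occTab) > 0L)
        fm@occTab[i + 1L, symbol + 1L]
    else
        findInterval(i - 0.5, fm@occPos[[symbol + 1L]])
}

emptyInterval <- function() c(0L, -1L)

intervalEmpty <- function(iv) iv[1L] > iv[2L]

intervalSize <- function(iv) max(0L, iv[2L] - iv[1L] + 1L)

fullInterval <- function(fm) c(0L, fm@n - 1L)

#' One backward-search step
#'
#' Refines a BWT-row interval by prepending one symbol via the LF-mapping:
#' \code{[C[c] + rank(c, lo), C[c] + rank(c, hi + 1) - 1]}.  Empty in,
#' empty out; a symbol absent from the text yields the empty interval.
#'
#' @param fm an \linkS4class{FMIndex}.
#' @param iv integer(2), 0-based inclusive \code{c(lo, hi)}; empty when
#'   \code{lo > hi}.
#' @param symbol integer 0-based code (NA allowed, yields empty).
#' @return integer(2) interval.
#' @export
backwardStep <- function(fm, iv, symbol) {
    if (intervalEmpty(iv)) return(emptyInterval())
    if (is.na(symbol) || symbol < 0L || symbol >= fm@sigma)
        return(emptyInterval())
    c0 <- fm@C[symbol + 1L]
    lo <- c0 + bwtRank(fm, symbol, iv[1L])
    hi <- c0 + bwtRank(fm, symbol, iv[2L] + 1L) - 1L
    if (lo > hi) emptyInterval() else c(lo, hi)
}

#' Backward search of a symbol sequence
#'
#' Runs \code{\link{backwardStep}} right-to-left over \code{pattern},
#' starting from \code{start} (default: the full range).  The result is
#' the interval of BWT rows prefixed by the pattern (restricted to rows
#' reachable from \code{start}); its size is the match count.  The empty
#' pattern returns \code{start} unchanged.
#'
#' @param fm an \linkS4class{FMIndex}.
#' @param pattern integer vector of 0-based codes (NAs allowed: no match).
#' @param start integer(2) starting interval.
#' @return integer(2) interval; empty (\code{lo > hi}) when unmatched.
#' @export
backwardSearch <- function(fm, pattern, start = fullInterval(fm)) {
    iv <- start
    for (s in rev(pattern)) {
        iv <- backwardStep(fm, iv, s)
        if (intervalEmpty(iv)) return(emptyInterval())
    }
    iv
}

#' Invert a BWT
#'
#' Reconstructs the text (as 0-based codes) from its FM-index by iterating
#' the LF-mapping from the terminal row.
#'
#' @param fm an \linkS4class{FMIndex}.
#' @return integer vector of length n ending in the terminal symbol.
#' @export
reconstructText <- function(fm) {
    n <- fm@n
    out <- integer(n)
    out[n] <- 0L  # terminal = smallest code, by the terminal invariant
    s <- 0L
    for (i in seq(n - 1L, by = -1L, length.out = n - 1L)) {
        sym <- fm@bwt[s + 1L]
        out[i] <- sym
        s <- fm@C[sym + 1L] + bwtRank(fm, sym, s)
    }
    out
}

setMethod("show", "FMIndex", function(object) {
    cat("FMIndex: n =", object@n, ", alphabet size", object@sigma,
        if (ncol(object@occTab) > 0L) "(occurrence table)"
        else "(position lists)", "\n")
})
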