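#' Construct parsing parameters
#'
#' @param w integer window length (>= 2).
#' @param p integer hash modulus (>= 1); a window triggers when its
#'   fingerprint is divisible by \code{p}.  Defaults to the
#'   \code{(w, p) = (6, 50)} setting that works well on repetitive
#'   pangenome collections.
#' @param mode \code{"hash"} (Karp-Rabin selection) or \code{"explicit"}
#'   (trigger set given verbatim).
#' @param triggers character vector of length-\code{w} windows, explicit
#'   mode only.
#' @param hashBase,hashMod Karp-Rabin constants; the defaults (base 256,
#'   prime modulus 1999999973) are recorded in every index so queries are
#'   parsed with the identical fingerprint.
#' @return A \linkS4class{ParseParams} object.
#' @examples
#' ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' @export
ParseParams <- function(w = 6L, p = 50L, mode = c("hash", "explicit"),
                        triggers = character(),
                        hashBase = 256, hashMod = 1999999973) {
    mode <- match.arg(mode)
    if (mode == "explicit") triggers <- toupper(triggers)
    new("ParseParams", w = as.integer(w), p = as.integer(p), mode = mode,
        triggers = triggers, hashBase = as.numeric(hashBase),
        hashMod = as.numeric(hashMod))
}

#' Karp-Rabin fingerprint of a window
#'
#' Polynomial rolling hash f(r) = sum r[i] * base^(w-1-i) mod m over the
#' byte values of the window.  Deterministic given the hash constants in
#' \code{params}; the rolling update (shift one character out, one in) is
#' exercised by \code{\link{krWindowFingerprints}}.
#'
#' @param window character(1) of length exactly \code{params@w}.
#' @param params a \linkS4class{ParseParams}.
#' @return integer fingerprint in [0, hashMod).
#' @examples
#' p <- ParseParams(w = 2L)
#' krFingerprint("AA", p)
#' @export
krFingerprint <- function(window, params) {
    if (nchar(window) != params@w)
        stop("window must have length w = ", params@w)
    krWindowFingerprints(window, params)[1L]
}

#' Fingerprints of every window of a string
#'
#' All length-\code{w} window fingerprints of \code{s}, computed with one
#' from-scratch evaluation followed by O(1) rolling updates.
#'
#' @param s character(1).
#' @param params a \linkS4class{ParseParams}.
#' @return integer vector of length \code{nchar(s) - w + 1} (empty when the
#'   string is shorter than \code{w}).
#' @export
krWindowFingerprints <- function(s, params) {
    kr_windows_cpp(textBytes(s), params@w, params@hashBase, params@hashMod)
}

## Fingerprint of a whole (variable-length) string, for the phrase map.
krStringFingerprint <- function(s, params) {
    kr_windows_cpp(textBytes(s), nchar(s), params@hashBase, params@hashMod)[1L]
}

#' Is a window a trigger string?
#'
#' Hash mode: true iff the window's fingerprint is divisible by \code{p}
#' or the window is the designated sentinel window.  Explicit mode: true
#' iff the window is in the explicit trigger set or is the sentinel window.
#'
#' @param window character(1) of length \code{params@w}.
#' @param params a \linkS4class{ParseParams}.
#' @param sentinelWindow logical(1): is this the window that begins with
#'   the sentinel (always a trigger)?
#' @return logical(1).
#' @examples
#' p <- ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' isTrigger("TA", p)   # TRUE
#' isTrigger("AG", p)   # FALSE
#' @export
isTrigger <- function(window, params, sentinelWindow = FALSE) {
    if (nchar(window) != params@w)
        stop("window must have length w = ", params@w)
    if (sentinelWindow || startsWith(window, SENTINEL)) return(TRUE)
    if (params@mode == "explicit")
        window %in% params@triggers
    else
        krFingerprint(window, params) %% params@p == 0
}

## 0-based trigger-window start positions in a pattern (no sentinel window,
## no cyclicity).  Used both for pattern parsing and, through buildPFP, for
## the explicit-mode scan of S'.
patternTriggerStarts <- function(pattern, params) {
    m <- nchar(pattern)
    w <- params@w
    if (m < w) return(integer(0))
    if (params@mode == "hash") {
        fp <- krWindowFingerprints(pattern, params)
        which(fp %% params@p == 0L) - 1L
    } else {
        if (!length(params@triggers)) return(integer(0))
        idx <- seq_len(m - w + 1L)
        wins <- substring(pattern, idx, idx + w - 1L)
        which(wins %in% params@triggers) - 1L
    }
}
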