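# Character-level encoding: the sentinel orders below every other symbol,
# the record separator between the sentinel and the rest, remaining
# characters by byte value.  All internal machinery works on dense 0-based
# integer codes; strings exist only at the API boundary.

SENTINEL  <- "$"
SEPARATOR <- "#"

## Byte values of a string, as integers.
textBytes <- function(s) as.integer(charToRaw(s))

## Ordered alphabet (character vector) of a text: sentinel first, then the
## separator if present, then everything else by byte value.
makeAlphabet <- function(text) {
    chars <- rawToChar(as.raw(sort(unique(textBytes(text)))), multiple = TRUE)
    special <- c(SENTINEL, SEPARATOR)
    c(special[special %in% chars], setdiff(chars, special))
}

## Encode a string to 0-based codes under `alphabet`; characters outside the
## alphabet become NA (queries containing them simply cannot match).
encodeText <- function(s, alphabet) {
    lut <- rep(NA_integer_, 256L)
    lut[vapply(alphabet, function(ch) as.integer(charToRaw(ch)), 0L) + 1L] <-
        seq_along(alphabet) - 1L
    lut[textBytes(s) + 1L]
}

decodeText <- function(codes, alphabet) {
    paste(alphabet[codes + 1L], collapse = "")
}

## Sort strings lexicographically under the package's symbol order
## (sentinel < separator < rest by byte).  Locale-proof: characters are
## remapped to rank bytes, then radix-sorted in the C locale.
sortStrings <- function(x, alphabet) {
    if (length(x) <= 1L) return(x)
    target <- rawToChar(as.raw(seq_along(alphabet)))
    x[order(chartr(paste(alphabet, collapse = ""), target, x),
            method = "radix")]
}

## Uppercase, append the sentinel when absent, reject internal sentinels.
prepareText <- function(text) {
    stopifnot(is.character(text), length(text) == 1L, !is.na(text))
    text <- toupper(text)
    n <- nchar(text)
    if (n == 0L) stop("text must be non-empty")
    hits <- gregexpr(SENTINEL, text, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
        text <- paste0(text, SENTINEL)
    } else if (length(hits) > 1L || hits[1L] != n) {
        stop("the sentinel '", SENTINEL,
             "' may only occur as the final character")
    }
    text
}
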