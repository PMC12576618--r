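# Independent oracles and small fixture builders.  The oracles never go
# through the package's suffix-array / backward-search code paths: the
# suffix array oracle sorts explicit rotation strings, the counting oracle
# is Biostrings::countPattern (and a from-scratch R scan for tiny cases).

# The running worked example: a 41-character text whose explicit-trigger
# parse is small enough to verify by hand.
EX_TEXT <- "TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT"
EX_PARAMS <- ParseParams(w = 2L, mode = "explicit",
                         triggers = c("AA", "CG", "TA"))
EX_QUERY <- "CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT"

# remap 0-based codes to a string whose C-locale order equals code order:
# single bytes for small alphabets, fixed-width decimal for large ones
codesToSortable <- function(codes, big = FALSE) {
    if (big) paste(sprintf("%06d", codes), collapse = "")
    else rawToChar(as.raw(codes + 1L))
}

oracleSuffixArray <- function(codes) {
    n <- length(codes)
    big <- max(codes) > 254L
    rot <- vapply(seq_len(n) - 1L, function(i) {
        codesToSortable(codes[((i + 0:(n - 1L)) %% n) + 1L], big)
    }, "")
    order(rot, method = "radix") - 1L
}

# 0-based inclusive interval of sorted-rotation rows prefixed by pattern
oracleInterval <- function(codes, patCodes) {
    n <- length(codes)
    big <- max(codes, patCodes) > 254L
    sa <- oracleSuffixArray(codes)
    pref <- codesToSortable(patCodes, big)
    rows <- which(vapply(sa, function(i) {
        startsWith(codesToSortable(codes[((i + 0:(n - 1L)) %% n) + 1L], big),
                   pref)
    }, NA))
    if (!length(rows)) c(0L, -1L) else c(min(rows) - 1L, max(rows) - 1L)
}

bioCount <- function(text, pattern) {
    Biostrings::countPattern(pattern, Biostrings::BString(text))
}

# from-scratch overlapping scan in plain R, for tiny cases
rScanCount <- function(text, pattern) {
    n <- nchar(text); m <- nchar(pattern)
    if (m == 0L || m > n) return(0L)
    sum(vapply(seq_len(n - m + 1L),
               function(i) substr(text, i, i + m - 1L) == pattern, NA))
}

randomText <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutatePattern <- function(pattern, k = 2L) {
    bases <- c("A", "C", "G", "T")
    ch <- strsplit(pattern, "")[[1]]
    pos <- sample.int(length(ch), min(k, length(ch)))
    ch[pos] <- sample(bases, length(pos), replace = TRUE)
    paste(ch, collapse = "")
}

encodeFor <- function(idx, s) pfpfm:::encodeText(s, idx@alphabet)

# expansion of the parse rotation starting at 0-based parse position j
# (each phrase contributes all but its trailing w characters)
expandRotation <- function(dict, prot, j, w) {
    len <- length(prot)
    ids <- prot[((j + 0:(len - 1L)) %% len) + 1L]
    ph <- dict[ids + 1L]
    paste(substr(ph, 1L, nchar(ph) - w), collapse = "")
}

# brute-force pairwise prefix-freeness: no phrase is a proper prefix of
# another (vectorized over all ordered pairs)
isPrefixFree <- function(d) {
    n <- length(d)
    if (n < 2L) return(TRUE)
    hits <- startsWith(rep(d, times = n), rep(d, each = n))
    sum(hits) == n  # only the diagonal (every string prefixes itself)
}

# single-level FM count, character-by-character only (comparison route)
plainFMCount <- function(fm, alphabet, pattern) {
    iv <- backwardSearch(fm, pfpfm:::encodeText(pattern, alphabet))
    max(0L, iv[2L] - iv[1L] + 1L)
}
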