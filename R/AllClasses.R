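#' @import methods
NULL

#' Parsing parameters for the prefix-free parse
#'
#' Bundles the window length \code{w}, the hash modulus \code{p}, the
#' trigger-selection mode and the Karp-Rabin hash constants.  In
#' \code{"hash"} mode a length-\code{w} window is a trigger string when its
#' Karp-Rabin fingerprint is congruent to 0 modulo \code{p}; in
#' \code{"explicit"} mode the trigger set is given verbatim (useful for
#' reproducing small worked examples).  The window that begins with the
#' sentinel is always a trigger, in either mode.
#'
#' The hash constants are stored with the parameters (and serialized into
#' index files) because query patterns must be parsed with the identical
#' fingerprint function that parsed the text.
#'
#' @slot w integer(1), window length in characters (>= 2).
#' @slot p integer(1), hash modulus (>= 1); \code{p = 1} makes every window
#'   a trigger.
#' @slot mode character(1), \code{"hash"} or \code{"explicit"}.
#' @slot triggers character vector of length-\code{w} trigger strings
#'   (explicit mode only).
#' @slot hashBase numeric(1), base of the polynomial fingerprint.
#' @slot hashMod numeric(1), modulus of the polynomial fingerprint
#'   (a prime below 2^31).
#'
#' @examples
#' ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' ParseParams(w = 6L, p = 50L)
#' @export
setClass("ParseParams",
    representation(w = "integer", p = "integer", mode = "character",
                   triggers = "character", hashBase = "numeric",
                   hashMod = "numeric"))

setValidity("ParseParams", function(object) {
    msg <- character()
    if (length(object@w) != 1L || is.na(object@w) || object@w < 2L)
        msg <- c(msg, "'w' must be a single integer >= 2")
    if (length(object@p) != 1L || is.na(object@p) || object@p < 1L)
        msg <- c(msg, "'p' must be a single integer >= 1")
    if (!object@mode %in% c("hash", "explicit"))
        msg <- c(msg, "'mode' must be \"hash\" or \"explicit\"")
    if (object@mode == "explicit" && length(object@triggers) &&
        any(nchar(object@triggers) != object@w))
        msg <- c(msg, "explicit triggers must all have length w")
    if (object@hashMod < 2 || object@hashMod >= 2^31)
        msg <- c(msg, "'hashMod' must lie in [2, 2^31)")
    if (length(msg)) msg else TRUE
})

#' Prefix-free parse of a text
#'
#' The result of parsing a sentinel-terminated text into phrases bounded by
#' trigger strings: the lexicographically sorted phrase dictionary, the
#' parse (the text rewritten as 0-based phrase IDs, i.e. ranks in the
#' dictionary), and the 0-based start offset of each phrase occurrence in
#' the scanned string S' (the cyclic text anchored at the sentinel).
#' Consecutive phrases overlap by exactly \code{w} characters.
#'
#' @slot dictionary character vector, strictly sorted, prefix-free.
#' @slot parse integer vector of 0-based phrase IDs.
#' @slot occStarts integer vector, 0-based phrase start offsets in S'.
#' @slot params the \linkS4class{ParseParams} used.
#' @slot n integer(1), length of the text including the sentinel.
#' @export
setClass("PFPParse",
    representation(dictionary = "character", parse = "integer",
                   occStarts = "integer", params = "ParseParams",
                   n = "integer"))

setValidity("PFPParse", function(object) {
    msg <- character()
    nd <- length(object@dictionary)
    if (nd == 0L) msg <- c(msg, "dictionary is empty")
    if (anyDuplicated(object@dictionary))
        msg <- c(msg, "dictionary phrases must be distinct")
    if (length(object@parse) &&
        (min(object@parse) < 0L || max(object@parse) >= nd))
        msg <- c(msg, "parse contains IDs outside the dictionary")
    if (length(object@parse) != length(object@occStarts))
        msg <- c(msg, "parse and occStarts lengths differ")
    if (length(msg)) msg else TRUE
})

#' Partial encoding of a query pattern
#'
#' Decomposition of a pattern into a prefix \code{alpha} ending at the
#' right end of its first trigger string, the 0-based IDs of the complete
#' phrases it contains, and a suffix \code{beta} starting at the left end
#' of its last trigger string.  Reassembling
#' \code{alpha + phrases(ids) + beta} while collapsing the \code{w}-character
#' overlap at every junction reproduces the pattern.  A trigger-free
#' pattern is encoded as \code{alpha} alone.
#'
#' @slot alpha character(1), possibly "".
#' @slot ids integer vector of phrase IDs, possibly empty.
#' @slot beta character(1), possibly "".
#' @export
setClass("PartialEncoding",
    representation(alpha = "character", ids = "integer", beta = "character"))

#' FM-index over an integer alphabet
#'
#' Burrows-Wheeler transform, cumulative count array C and a rank structure,
#' supporting backward search.  Used both for the character-level text and
#' for the phrase-ID parse.  Symbols are dense 0-based integer codes; the
#' terminal (code 0 at the final text position) must be unique and smallest.
#'
#' The rank structure is chosen by alphabet size: a full cumulative
#' occurrence table (O(1) rank) for small alphabets, per-symbol sorted
#' position lists with binary search for large ones (the phrase level,
#' where the alphabet is the dictionary).
#'
#' @slot bwt integer vector, the last BWT-matrix column as 0-based codes.
#' @slot C integer vector of length sigma + 1; \code{C[c+1]} = number of
#'   text symbols smaller than code c.
#' @slot n integer(1), text length.
#' @slot sigma integer(1), alphabet size.
#' @slot occTab integer matrix ((n+1) x sigma) of cumulative symbol counts,
#'   or a 0 x 0 matrix when position lists are used instead.
#' @slot occPos list of sorted 0-based position vectors, one per symbol,
#'   or an empty list when the table is used.
#' @export
setClass("FMIndex",
    representation(bwt = "integer", C = "integer", n = "integer",
                   sigma = "integer", occTab = "matrix", occPos = "list"))

setValidity("FMIndex", function(object) {
    msg <- character()
    if (length(object@bwt) != object@n)
        msg <- c(msg, "bwt length differs from n")
    if (length(object@C) != object@sigma + 1L)
        msg <- c(msg, "C must have length sigma + 1")
    if (is.unsorted(object@C))
        msg <- c(msg, "C must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' Marking bitvector over the rows of the text BWT matrix
#'
#' One bit per BWT-matrix row of the text, set when the row's rotation
#' starts at a trigger-string occurrence (the sentinel-anchored one
#' included).  \code{rank1}/\code{select1} on this vector translate
#' intervals between the character-level and the phrase-level BWT: the
#' number of ones equals the parse length, and the ones fall into at most
#' as many runs as there are distinct trigger strings in the text.
#'
#' @slot bits logical vector of length n.
#' @slot rcum integer vector of length n + 1, \code{rcum[i+1]} = ones in
#'   \code{bits[0..i-1]} (0-based).
#' @slot ones integer vector, 0-based positions of the set bits.
#' @export
setClass("MarkBitvector",
    representation(bits = "logical", rcum = "integer", ones = "integer"))

setValidity("MarkBitvector", function(object) {
    msg <- character()
    if (length(object@rcum) != length(object@bits) + 1L)
        msg <- c(msg, "rcum must have length n + 1")
    if (length(object@ones) != sum(object@bits))
        msg <- c(msg, "ones inconsistent with bits")
    if (length(msg)) msg else TRUE
})

#' Two-level FM-index built on a prefix-free parse
#'
#' The assembled index: an FM-index of the character-level text, an
#' FM-index of the (suitably rotated) phrase-ID parse, the marking
#' bitvector tying the two BWTs together, the phrase dictionary with an
#' exact fingerprint-verified phrase map, and the parsing parameters.
#' \code{\link{countOccurrences}} answers count queries by backward
#' searching character-by-character at the pattern's ends and
#' phrase-by-phrase in its middle.
#'
#' @slot fmText \linkS4class{FMIndex} over the text.
#' @slot fmParse \linkS4class{FMIndex} over the rotated parse.
#' @slot marks \linkS4class{MarkBitvector}.
#' @slot dictionary character vector of sorted phrases.
#' @slot phraseMap environment mapping phrase fingerprints to candidate
#'   (id, phrase) pairs; lookups verify characters, so they are exact.
#' @slot params \linkS4class{ParseParams}.
#' @slot alphabet character vector: the code table, \code{alphabet[k]} is
#'   the character with 0-based code k - 1 (sentinel first).
#' @slot n integer(1), text length including the sentinel.
#' @slot parseLen integer(1), number of phrase occurrences.
#' @export
setClass("PFPFMIndex",
    representation(fmText = "FMIndex", fmParse = "FMIndex",
                   marks = "MarkBitvector", dictionary = "character",
                   phraseMap = "environment", params = "ParseParams",
                   alphabet = "character", n = "integer",
                   parseLen = "integer"))

setValidity("PFPFMIndex", function(object) {
    msg <- character()
    if (length(object@marks@bits) != object@n)
        msg <- c(msg, "mark bitvector length differs from text length")
    if (length(object@marks@ones) != object@parseLen)
        msg <- c(msg, "number of marked rows must equal the parse length")
    if (object@fmParse@n != object@parseLen)
        msg <- c(msg, "parse FM-index length differs from parse length")
    if (length(msg)) msg else TRUE
})

#' A corpus of concatenated sequence records
#'
#' One or more records (FASTA entries or generated sequences) concatenated
#' into a single indexable text: records are joined by a reserved separator
#' character (ordered between the sentinel and the sequence alphabet) and
#' the text ends with the unique sentinel.
#'
#' @slot name character(1).
#' @slot text character(1), the concatenated text including the terminal
#'   sentinel.
#' @slot recordNames character vector.
#' @slot recordStarts integer vector, 0-based record start offsets in text.
#' @slot recordLengths integer vector.
#' @slot separator character(1), the separator character ("" if unused).
#' @export
setClass("Corpus",
    representation(name = "character", text = "character",
                   recordNames = "character", recordStarts = "integer",
                   recordLengths = "integer", separator = "character"))

setValidity("Corpus", function(object) {
    msg <- character()
    txt <- object@text
    n <- nchar(txt)
    if (n == 0L || substr(txt, n, n) != SENTINEL)
        msg <- c(msg, "corpus text must end with the sentinel")
    if (length(gregexpr(SENTINEL, txt, fixed = TRUE)[[1L]]) != 1L)
        msg <- c(msg, "sentinel must occur exactly once")
    if (length(object@recordStarts) != length(object@recordLengths))
        msg <- c(msg, "recordStarts and recordLengths lengths differ")
    if (length(msg)) msg else TRUE
})

#' A set of query patterns sampled from a corpus
#'
#' @slot patterns character vector.
#' @slot starts integer vector, 0-based sampled start offsets (NA for
#'   patterns not drawn from the corpus).
#' @slot lengths integer vector.
#' @slot seed integer(1), the seed the sampler was run with.
#' @export
setClass("QuerySet",
    representation(patterns = "character", starts = "integer",
                   lengths = "integer", seed = "integer"))
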