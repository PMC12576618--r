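# Assembly of the two-level index and the count query.

## Exact phrase map: Karp-Rabin fingerprint hash with stored-phrase
## verification, so a lookup never reports a false positive.
makePhraseMap <- function(dict, params) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(dict)) {
        key <- as.character(krStringFingerprint(dict[i], params))
        env[[key]] <- c(env[[key]], list(list(id = i - 1L, phrase = dict[i])))
    }
    env
}

#' Exact phrase lookup
#'
#' Returns a function mapping a phrase string to its 0-based ID in the
#' index's dictionary, or NA when absent.  Candidates are found by
#' Karp-Rabin fingerprint and verified character by character, so the
#' lookup is exact (never a false positive).
#'
#' @param idx a \linkS4class{PFPFMIndex}.
#' @return function(phrase) -> integer ID or NA.
#' @export
phraseLookup <- function(idx) {
    env <- idx@phraseMap
    params <- idx@params
    function(phrase) {
        key <- as.character(krStringFingerprint(phrase, params))
        for (cand in env[[key]])
            if (identical(cand$phrase, phrase)) return(cand$id)
        NA_integer_
    }
}

#' Build the two-level index
#'
#' Runs the prefix-free parse, builds the character-level FM-index of the
#' text and the phrase-level FM-index of the parse (rotated so the
#' sentinel-anchored phrase ID 0 is the terminal symbol), marks the BWT
#' rows of the text whose rotations start at trigger-string occurrences,
#' and stores the exact phrase map.  The i-th marked row corresponds to
#' the i-th row of the parse's BWT matrix, which is what lets count
#' queries hop between the two levels.
#'
#' @param text character(1); sentinel appended when absent.
#' @param params a \linkS4class{ParseParams}.
#' @return A \linkS4class{PFPFMIndex}.
#' @examples
#' pp <- ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' idx <- buildIndex("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", pp)
#' countOccurrences(idx, "CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT")
#' @export
buildIndex <- function(text, params = ParseParams()) {
    text <- prepareText(text)
    pfp <- buildPFP(text, params)
    n <- pfp@n
    alphabet <- makeAlphabet(text)
    codes <- encodeText(text, alphabet)
    checkIntText(codes)
    saS <- sa_int_cpp(codes)
    fmText <- bwtFromSA(codes, saS)

    P <- pfp@parse
    z <- which(P == 0L)
    stopifnot(length(z) == 1L)  # sentinel phrase occurs exactly once
    Prot <- if (z < length(P)) c(P[-seq_len(z)], P[seq_len(z)]) else P
    fmParse <- bwtFromSA(Prot, sa_int_cpp(Prot))

    # trigger occurrence positions in the cyclic text (S' offset - 1 mod n)
    tpos <- (pfp@occStarts - 1L) %% n
    marks <- MarkBitvector(saS %in% tpos)

    new("PFPFMIndex", fmText = fmText, fmParse = fmParse, marks = marks,
        dictionary = pfp@dictionary,
        phraseMap = makePhraseMap(pfp@dictionary, params),
        params = params, alphabet = alphabet, n = n,
        parseLen = length(P))
}

#' Map a text-level interval to the parse level
#'
#' Given an interval of text-BWT rows that are all marked (i.e. whose
#' rotations start at trigger occurrences), returns the corresponding
#' interval of parse-BWT rows via rank on the marking bitvector.
#'
#' @param idx a \linkS4class{PFPFMIndex}.
#' @param iv integer(2), non-empty 0-based inclusive interval over the
#'   text BWT; every row must be marked (else an error: the interval is
#'   not trigger-aligned).
#' @return integer(2) interval over the parse BWT.
#' @export
mapToParse <- function(idx, iv) {
    stopifnot(!intervalEmpty(iv))
    if (!triggerAligned(idx, iv))
        stop("interval contains unmarked rows; not trigger-aligned")
    c(bvRank1(idx@marks, iv[1L]), bvRank1(idx@marks, iv[2L]))
}

#' Map a parse-level interval back to the text level
#'
#' Inverse of \code{\link{mapToParse}}: select on the marking bitvector
#' takes an interval of parse-BWT rows to the spanned interval of text-BWT
#' rows.
#'
#' @param idx a \linkS4class{PFPFMIndex}.
#' @param iv integer(2), non-empty 0-based interval within
#'   \code{[0, parseLen - 1]}.
#' @return integer(2) interval over the text BWT.
#' @export
mapToText <- function(idx, iv) {
    stopifnot(!intervalEmpty(iv))
    if (iv[1L] < 0L || iv[2L] >= idx@parseLen)
        stop("parse-level interval out of range")
    c(bvSelect1(idx@marks, iv[1L] + 1L), bvSelect1(idx@marks, iv[2L] + 1L))
}

#' Is every row of a text-level interval marked?
#'
#' True iff all rows in \code{iv} are marked, i.e. the interval lies
#' inside the interval of some trigger string.
#'
#' @param idx a \linkS4class{PFPFMIndex}.
#' @param iv integer(2), non-empty interval over the text BWT.
#' @return logical(1).
#' @export
triggerAligned <- function(idx, iv) {
    stopifnot(!intervalEmpty(iv))
    bvRank1(idx@marks, iv[2L] + 1L) - bvRank1(idx@marks, iv[1L]) ==
        iv[2L] - iv[1L] + 1L
}

encodePattern <- function(idx, pattern) {
    if (nchar(pattern) == 0L) return(integer(0))
    encodeText(pattern, idx@alphabet)
}

#' Count pattern occurrences with the two-level index
#'
#' Returns the number of (possibly overlapping) occurrences of
#' \code{pattern} in the indexed text.  The pattern is first partially
#' encoded (\code{\link{parsePattern}}); when it spans no complete phrase
#' it is backward searched character by character; otherwise the suffix
#' \code{beta} is searched in the text FM-index, the interval is mapped to
#' the parse BWT, the complete phrase IDs are searched phrase by phrase,
#' the result is mapped back, and the remainder of \code{alpha} (its
#' trailing \code{w} characters are already covered by the first complete
#' phrase) finishes the search character by character.  Any failing step
#' yields 0.  The empty pattern returns n, the size of the full interval.
#'
#' @param x a \linkS4class{PFPFMIndex}.
#' @param pattern character(1), free of the sentinel character.
#' @param details logical(1); when TRUE, also return the partial encoding
#'   and the interval chain.
#' @return integer count, or when \code{details = TRUE} a list with
#'   elements \code{count}, \code{encoding} and \code{trace} (the named
#'   intervals visited: \code{betaText}, \code{betaParse},
#'   \code{parseFinal}, \code{textMapped}, \code{final}).
#' @examples
#' pp <- ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' idx <- buildIndex("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", pp)
#' countOccurrences(idx, "CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT")  # 1
#' countOccurrences(idx, "GGGG")                                 # 0
#' @aliases countOccurrences,PFPFMIndex-method
#' @export
setMethod("countOccurrences", "PFPFMIndex",
          function(x, pattern, details = FALSE) {
    idx <- x
    w <- idx@params@w
    done <- function(count, trace, enc = NULL) {
        if (details) list(count = as.integer(count), encoding = enc,
                          trace = trace)
        else as.integer(count)
    }
    pattern <- toupper(pattern)
    enc <- parsePattern(pattern, idx@params, phraseLookup(idx))
    if (is.null(enc)) return(done(0L, list()))
    if (length(enc@ids) == 0L) {
        iv <- backwardSearch(idx@fmText, encodePattern(idx, pattern))
        return(done(intervalSize(iv), list(final = iv), enc))
    }
    trace <- list()
    if (nzchar(enc@beta)) {
        ivS <- backwardSearch(idx@fmText, encodePattern(idx, enc@beta))
        trace$betaText <- ivS
        if (intervalEmpty(ivS)) return(done(0L, trace, enc))
        ivP <- mapToParse(idx, ivS)  # errors if not trigger-aligned
    } else {
        ivP <- c(0L, idx@parseLen - 1L)
    }
    trace$betaParse <- ivP
    ivP <- backwardSearch(idx@fmParse, enc@ids, start = ivP)
    trace$parseFinal <- ivP
    if (intervalEmpty(ivP)) return(done(0L, trace, enc))
    ivS <- mapToText(idx, ivP)
    trace$textMapped <- ivS
    if (nzchar(enc@alpha)) {
        rem <- substr(enc@alpha, 1L, nchar(enc@alpha) - w)
        if (nzchar(rem)) {
            ivS <- backwardSearch(idx@fmText, encodePattern(idx, rem),
                                  start = ivS)
            if (intervalEmpty(ivS)) {
                trace$final <- ivS
                return(done(0L, trace, enc))
            }
        }
    }
    trace$final <- ivS
    done(intervalSize(ivS), trace, enc)
})

INDEX_FORMAT  <- "pfpfm-index"
INDEX_VERSION <- 1L

#' Save / load an index
#'
#' \code{saveIndex} writes a versioned, self-describing archive (an RDS
#' file holding a plain list: format tag, version, parsing parameters with
#' hash constants, alphabet, dictionary, both BWTs, C arrays and the mark
#' bitvector).  \code{loadIndex} validates the header and rebuilds the
#' rank structures and phrase map; a truncated or foreign file raises a
#' load error.  Saving is deterministic: the same index yields
#' byte-identical files.
#'
#' @param idx a \linkS4class{PFPFMIndex}.
#' @param path file path.
#' @return \code{saveIndex}: invisibly, \code{path}; \code{loadIndex}: the
#'   restored \linkS4class{PFPFMIndex}, answering identical counts.
#' @export
saveIndex <- function(idx, path) {
    obj <- list(format = INDEX_FORMAT, version = INDEX_VERSION,
                w = idx@params@w, p = idx@params@p, mode = idx@params@mode,
                triggers = idx@params@triggers,
                hashBase = idx@params@hashBase, hashMod = idx@params@hashMod,
                alphabet = idx@alphabet, dictionary = idx@dictionary,
                bwtText = idx@fmText@bwt, CText = idx@fmText@C,
                bwtParse = idx@fmParse@bwt, CParse = idx@fmParse@C,
                marks = idx@marks@bits, n = idx@n, parseLen = idx@parseLen)
    saveRDS(obj, path)
    invisible(path)
}

rebuildFM <- function(bwt, C) {
    n <- length(bwt)
    # bwt holds the text's symbols as a multiset; any suffix array of a
    # text with this BWT yields the same rank structures, so rebuild
    # occ/ C directly from the stored columns
    sigma <- length(C) - 1L
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

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
    obj <- tryCatch(readRDS(path), error = function(e)
        stop("cannot load index from '", path, "': ", conditionMessage(e)))
    if (!is.list(obj) || !identical(obj$format, INDEX_FORMAT))
        stop("'", path, "' is not a ", INDEX_FORMAT, " file")
    if (!identical(obj$version, INDEX_VERSION))
        stop("unsupported index version: ", obj$version)
    params <- ParseParams(w = obj$w, p = obj$p, mode = obj$mode,
                          triggers = obj$triggers, hashBase = obj$hashBase,
                          hashMod = obj$hashMod)
    new("PFPFMIndex",
        fmText = rebuildFM(obj$bwtText, obj$CText),
        fmParse = rebuildFM(obj$bwtParse, obj$CParse),
        marks = MarkBitvector(obj$marks),
        dictionary = obj$dictionary,
        phraseMap = makePhraseMap(obj$dictionary, params),
        params = params, alphabet = obj$alphabet,
        n = obj$n, parseLen = obj$parseLen)
}

#' @describeIn dictionary phrases of a two-level index
#' @export
setMethod("dictionary", "PFPFMIndex", function(x) x@dictionary)

#' @describeIn parseParams parameters of a two-level index
#' @export
setMethod("parseParams", "PFPFMIndex", function(x) x@params)

#' @describeIn textLength indexed text length (sentinel included)
#' @export
setMethod("textLength", "PFPFMIndex", function(x) x@n)

setMethod("show", "PFPFMIndex", function(object) {
    cat("PFPFMIndex: text length", object@n, "| dictionary",
        length(object@dictionary), "phrases | parse length",
        object@parseLen, "\n  ")
    show(object@params)
})
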