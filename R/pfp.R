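#' Prefix-free parse of a text
#'
#' Scans S' = $ S[0..n-2] $ S[0..w-2] (the cyclic text anchored at its
#' sentinel, extended by one window) for trigger-string occurrences and
#' cuts it into phrases that start and end at triggers with no trigger
#' inside.  The distinct phrases, sorted lexicographically (sentinel <
#' separator < rest), form the dictionary; the parse lists each phrase
#' occurrence as its 0-based rank.  Consecutive phrases overlap by exactly
#' \code{w} characters, so collapsing those overlaps reconstructs S'.
#'
#' @param text character(1); uppercased, and the sentinel is appended when
#'   absent.  The sentinel must not occur internally.  The text (with
#'   sentinel) must be at least \code{w} characters long.
#' @param params a \linkS4class{ParseParams}.
#' @return A \linkS4class{PFPParse}.
#' @examples
#' pp <- ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' pf <- buildPFP("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", pp)
#' dictionary(pf)
#' parseIds(pf)   # 0 2 4 3 1 5
#' @export
buildPFP <- function(text, params) {
    text <- prepareText(text)
    n <- nchar(text)
    w <- params@w
    if (n < w) stop("text (with sentinel) shorter than the window length w")
    body <- substr(text, 1L, n - 1L)
    sprime <- paste0(SENTINEL, body, SENTINEL, substr(text, 1L, w - 1L))
    # windows at 0-based positions 0..n; 0 and n are the forced sentinel
    # windows, the rest trigger by hash / explicit membership
    starts <- sort(unique(c(0L, patternTriggerStarts(sprime, params), n)))
    k <- length(starts)
    phrases <- substring(sprime, starts[-k] + 1L, starts[-1L] + w)
    dict <- sortStrings(unique(phrases), makeAlphabet(sprime))
    new("PFPParse", dictionary = dict,
        parse = match(phrases, dict) - 1L,
        occStarts = starts[-k], params = params, n = n)
}

## Expansion of a parse: concatenate phrases collapsing the w-overlap at
## each junction; equals S' (round-trip invariant, exercised in tests).
expandParse <- function(pfp) {
    ph <- pfp@dictionary[pfp@parse + 1L]
    w <- pfp@params@w
    if (length(ph) == 1L) return(ph)
    paste0(ph[1L], paste(substring(ph[-1L], w + 1L), collapse = ""))
}

#' Partial encoding of a query pattern
#'
#' Splits a pattern at its trigger-string occurrences into a prefix
#' \code{alpha} (ending at the right end of the first trigger), the IDs of
#' the complete phrases between consecutive triggers, and a suffix
#' \code{beta} (from the left end of the last trigger).  The pattern is not
#' treated as cyclic and has no sentinel window.  A trigger-free pattern
#' (including any pattern shorter than \code{w}) is returned unchanged as
#' an alpha-only encoding.  When the pattern ends at a trigger, the trigger
#' folds into the last complete phrase and \code{beta} is empty; when it
#' starts with a trigger, \code{alpha} is empty.
#'
#' @param pattern character(1), free of the sentinel character.
#' @param params the \linkS4class{ParseParams} the text was parsed with.
#' @param phraseLookup a function(phrase) returning the 0-based phrase ID
#'   or NA when the phrase is not in the dictionary (see
#'   \code{\link{phraseLookup}}).
#' @return A \linkS4class{PartialEncoding}, or NULL when some complete
#'   phrase is absent from the dictionary (the pattern cannot occur in the
#'   text).
#' @examples
#' pp <- ParseParams(w = 2L, mode = "explicit", triggers = c("AA", "CG", "TA"))
#' idx <- buildIndex("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", pp)
#' parsePattern("CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT", pp, phraseLookup(idx))
#' @export
parsePattern <- function(pattern, params, phraseLookup) {
    if (grepl(SENTINEL, pattern, fixed = TRUE))
        stop("patterns must not contain the sentinel character")
    pattern <- toupper(pattern)
    m <- nchar(pattern)
    w <- params@w
    trig <- patternTriggerStarts(pattern, params)
    len <- length(trig)
    if (len == 0L)
        return(new("PartialEncoding", alpha = pattern, ids = integer(0),
                   beta = ""))
    t0 <- trig[1L]
    tl <- trig[len]
    endsAtTrigger <- tl + w == m
    alpha <- if (t0 == 0L) "" else substr(pattern, 1L, t0 + w)
    beta <- if (endsAtTrigger) "" else substr(pattern, tl + 1L, m)
    if (len == 1L) {
        # single trigger: no complete phrase; degenerate Q == trigger is
        # carried in beta so the encoding still reassembles to Q
        if (t0 == 0L && endsAtTrigger) beta <- pattern
        return(new("PartialEncoding", alpha = alpha, ids = integer(0),
                   beta = beta))
    }
    from <- trig[-len]
    phr <- substring(pattern, from + 1L, trig[-1L] + w)
    ids <- vapply(phr, phraseLookup, 0L, USE.NAMES = FALSE)
    if (anyNA(ids)) return(NULL)
    new("PartialEncoding", alpha = alpha, ids = ids, beta = beta)
}

#' @describeIn dictionary phrases of a prefix-free parse
#' @export
setMethod("dictionary", "PFPParse", function(x) x@dictionary)

#' @describeIn parseIds phrase IDs of a prefix-free parse
#' @export
setMethod("parseIds", "PFPParse", function(x) x@parse)

#' @describeIn parseParams parameters of a prefix-free parse
#' @export
setMethod("parseParams", "PFPParse", function(x) x@params)

#' Accessors
#'
#' \code{dictionary} returns the sorted phrase dictionary; \code{parseIds}
#' the 0-based phrase-ID sequence; \code{parseParams} the
#' \linkS4class{ParseParams}; \code{textLength} the indexed text length
#' (sentinel included).
#'
#' @param x a \linkS4class{PFPParse} or \linkS4class{PFPFMIndex}.
#' @return See each accessor's description.
#' @name dictionary
#' @aliases parseIds parseParams textLength
NULL

setMethod("show", "ParseParams", function(object) {
    cat("ParseParams: w =", object@w,
        if (object@mode == "hash")
            paste0("| hash mode, p = ", object@p)
        else
            paste0("| explicit triggers {",
                   paste(object@triggers, collapse = ", "), "}"),
        "\n")
})

setMethod("show", "PFPParse", function(object) {
    cat("PFPParse:", length(object@dictionary), "phrases,",
        length(object@parse), "parse symbols, text length", object@n, "\n")
})

setMethod("show", "PartialEncoding", function(object) {
    cat("PartialEncoding: alpha=\"", object@alpha, "\" ids=(",
        paste(object@ids, collapse = ","), ") beta=\"", object@beta,
        "\"\n", sep = "")
})

#' Write a parse to flat files
#'
#' Writes the dictionary (phrases one per line, lexicographic order) and
#' the parse (whitespace-separated 0-based phrase IDs on one line) for
#' inspection and cross-tool comparison.
#'
#' @param pfp a \linkS4class{PFPParse}.
#' @param dictFile,parseFile output paths.
#' @return invisibly, \code{pfp}.
#' @export
writeParse <- function(pfp, dictFile, parseFile) {
    writeLines(pfp@dictionary, dictFile)
    writeLines(paste(pfp@parse, collapse = " "), parseFile)
    invisible(pfp)
}
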