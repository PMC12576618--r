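# Corpus I/O, synthetic data and the naive counting oracle.

makeCorpus <- function(records, name = "corpus", separator = SEPARATOR) {
    records <- toupper(records)
    if (!length(records) || any(!nzchar(records)))
        stop("corpus records must be non-empty")
    bad <- c(SENTINEL, if (length(records) > 1L) separator)
    for (b in bad)
        if (any(grepl(b, records, fixed = TRUE)))
            stop("records must not contain '", b, "'")
    sep <- if (length(records) > 1L) separator else ""
    text <- paste0(paste(records, collapse = sep), SENTINEL)
    lens <- nchar(records)
    starts <- cumsum(c(0L, (lens + nchar(sep))[-length(lens)]))
    nm <- names(records)
    if (is.null(nm)) nm <- paste0("record", seq_along(records))
    new("Corpus", name = name, text = text, recordNames = nm,
        recordStarts = as.integer(starts), recordLengths = as.integer(lens),
        separator = sep)
}

#' Read a corpus from FASTA or plain text
#'
#' FASTA records (detected by a leading '>') are read with
#' \code{Biostrings::readBStringSet}, uppercased and concatenated with the
#' separator character between records; a plain-text file is concatenated
#' across lines into a single record.  The sentinel is appended.
#'
#' @param path input file.
#' @param separator character(1) placed between records (ordered between
#'   the sentinel and the sequence alphabet).
#' @param name corpus name (defaults to the file name).
#' @return A \linkS4class{Corpus}.
#' @export
readCorpus <- function(path, separator = SEPARATOR, name = basename(path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty input file: ", path)
    if (startsWith(trimws(first), ">")) {
        set <- Biostrings::readBStringSet(path)
        if (length(set) == 0L) stop("no FASTA records in ", path)
        records <- stats::setNames(as.character(set), names(set))
    } else {
        txt <- paste(trimws(readLines(path)), collapse = "")
        if (!nzchar(txt)) stop("empty input file: ", path)
        records <- c(text = txt)
    }
    makeCorpus(records, name = name, separator = separator)
}

#' Generate a synthetic pangenome collection
#'
#' One random DNA sequence plus \code{nCopies - 1} point-mutated copies
#' (each site redrawn independently with probability \code{mutationRate},
#' uniformly over the four bases, so the expected per-site difference from
#' the base sequence is \code{3/4 * mutationRate}), concatenated into a
#' \linkS4class{Corpus}.  Emulates, at desk scale, the
#' highly repetitive genome collections that word-based indexing targets.
#' Deterministic under \code{seed}.
#'
#' @param baseLength length of the base sequence (>= 1).
#' @param nCopies total number of records (>= 1).
#' @param mutationRate per-site substitution probability in [0, 1].
#' @param seed integer RNG seed.
#' @return A \linkS4class{Corpus}.
#' @export
generatePangenome <- function(baseLength, nCopies = 1L, mutationRate = 0.01,
                              seed = 1L) {
    stopifnot(baseLength >= 1L, nCopies >= 1L,
              mutationRate >= 0, mutationRate <= 1)
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    base <- sample(bases, baseLength, replace = TRUE)
    records <- character(nCopies)
    records[1L] <- paste(base, collapse = "")
    for (i in seq_len(nCopies - 1L)) {
        copy <- base
        hit <- which(stats::runif(baseLength) < mutationRate)
        if (length(hit))
            copy[hit] <- sample(bases, length(hit), replace = TRUE)
        records[i + 1L] <- paste(copy, collapse = "")
    }
    names(records) <- paste0("copy", seq_len(nCopies))
    makeCorpus(records, name = sprintf("pangenome_%dx%d", nCopies, baseLength))
}

#' Sample query patterns from a corpus
#'
#' Draws \code{n} substrings of the requested length uniformly from within
#' the corpus records (never crossing a separator or the sentinel), with
#' replacement.  Deterministic under \code{seed}.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param n number of patterns.
#' @param length pattern length (must fit inside at least one record).
#' @param seed integer RNG seed.
#' @return A \linkS4class{QuerySet}.
#' @export
samplePatterns <- function(corpus, n, length, seed = 1L) {
    ok <- corpus@recordLengths >= length
    if (!any(ok)) stop("no record is long enough for patterns of length ",
                       length)
    set.seed(seed)
    nwin <- corpus@recordLengths[ok] - length + 1L
    offs <- corpus@recordStarts[ok]
    # choose a record weighted by its window count, then a window in it
    rec <- sample.int(length(nwin), n, replace = TRUE, prob = nwin)
    win <- floor(stats::runif(n) * nwin[rec])
    starts <- as.integer(offs[rec] + win)
    pats <- substring(corpus@text, starts + 1L, starts + length)
    new("QuerySet", patterns = pats, starts = starts,
        lengths = rep(as.integer(length), n), seed = as.integer(seed))
}

#' Naive overlapping-occurrence count
#'
#' Direct scan of the text: the oracle every index query is tested
#' against.  Counts possibly overlapping matches; the empty pattern
#' counts 0.
#'
#' @param text character(1) or a \linkS4class{Corpus}.
#' @param pattern character(1).
#' @return integer count.
#' @examples
#' naiveCount("AAAA", "AA")  # 3
#' @export
naiveCount <- function(text, pattern) {
    if (is(text, "Corpus")) text <- text@text
    naive_count_cpp(textBytes(toupper(text)), textBytes(toupper(pattern)))
}

#' @describeIn textLength corpus text length (sentinel included)
#' @export
setMethod("textLength", "Corpus", function(x) nchar(x@text))

setMethod("show", "Corpus", function(object) {
    cat("Corpus '", object@name, "': ", length(object@recordNames),
        " record(s), ", nchar(object@text), " characters total\n", sep = "")
})

setMethod("show", "QuerySet", function(object) {
    cat("QuerySet:", length(object@patterns), "patterns of length",
        paste(unique(object@lengths), collapse = "/"),
        "(seed", paste0(object@seed, ")"), "\n")
})
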