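exIdx <- buildIndex(EX_TEXT, EX_PARAMS)

test_that("rank and select on the marking bitvector are mutual inverses", {
    bv <- MarkBitvector(c(TRUE, FALSE, TRUE, TRUE, FALSE))
    expect_identical(bvRank1(bv, 0L), 0L)
    expect_identical(bvRank1(bv, 5L), 3L)
    expect_identical(bvSelect1(bv, 1:3), c(0L, 2L, 3L))
    for (i in which(bv@bits) - 1L)
        expect_identical(bvSelect1(bv, bvRank1(bv, i) + 1L), i)
    expect_error(bvSelect1(bv, 4L), "range")
})

test_that("the worked-example index assembles with the expected shape", {
    expect_identical(length(dictionary(exIdx)), 6L)
    expect_identical(exIdx@parseLen, 6L)
    expect_identical(length(exIdx@marks@ones), 6L)
    expect_identical(textLength(exIdx), 41L)
    # marked rows are exactly the rows whose rotations start at trigger
    # occurrences: $T at 40, AA at 5 and 28, CG at 18, TA at 10 and 34
    text <- pfpfm:::prepareText(EX_TEXT)
    codes <- pfpfm:::encodeText(text, exIdx@alphabet)
    sa <- buildSuffixArray(codes)
    expect_identical(which(sa %in% c(40L, 5L, 28L, 18L, 10L, 34L)) - 1L,
                     exIdx@marks@ones)
})

test_that("interval mapping between the two BWTs matches the worked example", {
    expect_true(triggerAligned(exIdx, c(31L, 32L)))
    expect_identical(mapToParse(exIdx, c(31L, 32L)), c(4L, 5L))
    expect_identical(mapToText(exIdx, c(2L, 2L)), c(2L, 2L))
    # full range cannot be trigger-aligned when |P| < n
    expect_false(triggerAligned(exIdx, c(0L, 40L)))
    expect_error(mapToParse(exIdx, c(0L, 40L)), "trigger-aligned")
    expect_error(mapToText(exIdx, c(0L, 10L)), "range")
    # round trips on marked intervals
    for (k in seq_len(5L)) {
        ivP <- sort(sample(0:5, 2L, replace = TRUE))
        ivS <- mapToText(exIdx, ivP)
        if (triggerAligned(exIdx, ivS))
            expect_identical(mapToParse(exIdx, ivS), ivP)
    }
    expect_identical(mapToText(exIdx, c(0L, 5L)),
                     c(exIdx@marks@ones[1L], exIdx@marks@ones[6L]))
    # trigger alignment agrees with a per-row scan of the bits
    set.seed(3)
    for (k in 1:20) {
        iv <- sort(sample(0:40, 2L, replace = TRUE))
        expect_identical(triggerAligned(exIdx, iv),
                         all(exIdx@marks@bits[(iv[1L]:iv[2L]) + 1L]))
    }
})

test_that("counting the worked-example query walks the published intervals", {
    res <- countOccurrences(exIdx, EX_QUERY, details = TRUE)
    expect_identical(res$trace$betaText, c(31L, 32L))
    expect_identical(res$trace$betaParse, c(4L, 5L))
    expect_identical(res$trace$parseFinal, c(2L, 2L))
    expect_identical(res$trace$textMapped, c(2L, 2L))
    expect_identical(res$trace$final, c(14L, 14L))
    expect_identical(res$count, 1L)
    expect_identical(rScanCount(EX_TEXT, EX_QUERY), 1L)
})

test_that("count conventions at the boundaries are honoured", {
    expect_identical(countOccurrences(exIdx, ""), 41L)     # full interval
    expect_identical(countOccurrences(exIdx, "GGGG"), 0L)  # absent
    expect_identical(countOccurrences(exIdx, "ZZ"), 0L)    # foreign symbol
    # patterns at or below the window length use plain character search
    for (q in c("A", "TA", "AA", "GAT")) {
        expect_identical(countOccurrences(exIdx, q),
                         rScanCount(EX_TEXT, q))
    }
    # query ending at a trigger folds it into the last complete phrase
    qEnd <- "CAGAAGAGTA"
    res <- countOccurrences(exIdx, qEnd, details = TRUE)
    expect_identical(res$encoding@beta, "")
    expect_identical(res$encoding@ids, 2L)
    expect_identical(res$count, rScanCount(EX_TEXT, qEnd))
    # query starting with a trigger skips the alpha stage
    qStart <- "TATCTCCTCGACATGTTGAA"
    res <- countOccurrences(exIdx, qStart, details = TRUE)
    expect_identical(res$encoding@alpha, "")
    expect_identical(res$count, rScanCount(EX_TEXT, qStart))
})

test_that("phrase lookups are exact: no false positives, no misses", {
    look <- phraseLookup(exIdx)
    d <- dictionary(exIdx)
    for (i in seq_along(d)) expect_identical(look(d[i]), i - 1L)
    set.seed(41)
    # phrase-shaped strings (trigger-bounded) that are not in the dictionary
    tries <- 0L
    while (tries < 500L) {
        mid <- randomText(sample(3:9, 1L))
        cand <- paste0("AA", mid, "TA")
        if (!cand %in% d) {
            expect_true(is.na(look(cand)))
            tries <- tries + 1L
        }
    }
})

test_that("counts equal the naive oracle and the single-level FM-index", {
    set.seed(43)
    cases <- list(
        list(text = randomText(500), params = ParseParams(w = 2L, p = 3L)),
        list(text = randomText(1500), params = ParseParams(w = 4L, p = 11L)),
        list(text = randomText(900), params = ParseParams(w = 3L, p = 1L)),
        list(text = generatePangenome(400L, 4L, 0.02, seed = 9L)@text,
             params = ParseParams(w = 6L, p = 13L)))
    for (cs in cases) {
        text <- pfpfm:::prepareText(cs$text)
        idx <- buildIndex(text, cs$params)
        body <- substr(text, 1L, nchar(text) - 1L)
        alpha <- idx@alphabet
        fmPlain <- buildFMIndex(pfpfm:::encodeText(text, alpha))
        for (rep in 1:25) {
            len <- sample(c(3:10, 20L, 50L), 1L)
            if (stats::runif(1) < 0.6 && len < nchar(body)) {
                st <- sample(nchar(body) - len + 1L, 1L)
                q <- substr(body, st, st + len - 1L)
                if (stats::runif(1) < 0.4) q <- mutatePattern(q)
            } else {
                q <- randomText(len)
            }
            expected <- bioCount(text, q)
            expect_identical(countOccurrences(idx, q), expected)
            expect_identical(naiveCount(text, q), expected)
            expect_identical(plainFMCount(fmPlain, alpha, q), expected)
        }
    }
})

test_that("counts are invariant to the parsing parameters", {
    set.seed(47)
    corpus <- generatePangenome(600L, 3L, 0.03, seed = 19L)
    qs <- samplePatterns(corpus, 6L, 40L, seed = 20L)
    settings <- list(c(2L, 3L), c(4L, 7L), c(6L, 13L), c(8L, 1L))
    counts <- lapply(settings, function(wp) {
        idx <- buildIndex(corpus@text, ParseParams(w = wp[1L], p = wp[2L]))
        vapply(qs@patterns, function(q) countOccurrences(idx, q), 0L,
               USE.NAMES = FALSE)
    })
    for (k in 2:length(counts)) expect_identical(counts[[k]], counts[[1L]])
    expect_identical(counts[[1L]],
                     vapply(qs@patterns, function(q) naiveCount(corpus, q),
                            0L, USE.NAMES = FALSE))
})

test_that("every constructed index satisfies the two-level correspondences", {
    set.seed(53)
    cases <- list(
        list(text = EX_TEXT, params = EX_PARAMS),
        list(text = randomText(300), params = ParseParams(w = 2L, p = 4L)),
        list(text = randomText(700), params = ParseParams(w = 5L, p = 9L)),
        list(text = generatePangenome(250L, 3L, 0.05, seed = 2L)@text,
             params = ParseParams(w = 4L, p = 5L)))
    for (cs in cases) {
        text <- pfpfm:::prepareText(cs$text)
        n <- nchar(text)
        params <- cs$params
        w <- params@w
        idx <- buildIndex(text, params)
        pfp <- buildPFP(text, params)

        # ones count equals the parse length
        expect_identical(length(idx@marks@ones), length(parseIds(pfp)))

        # runs of ones bounded by the number of distinct triggers in S
        sprime <- paste0("$", substr(text, 1L, n - 1L), "$",
                         substr(text, 1L, w - 1L))
        trigWins <- unique(substring(sprime, pfp@occStarts + 1L,
                                     pfp@occStarts + w))
        expect_lte(pfpfm:::bvRuns1(idx@marks), length(trigWins))

        # row-by-row correspondence: the rotation of S at the i-th marked
        # row equals the expansion of the i-th row of the parse BWT matrix
        P <- parseIds(pfp)
        z <- which(P == 0L)
        prot <- if (z < length(P)) c(P[-seq_len(z)], P[seq_len(z)]) else P
        saP <- buildSuffixArray(prot)
        codes <- pfpfm:::encodeText(text, idx@alphabet)
        saS <- buildSuffixArray(codes)
        rows <- idx@marks@ones
        starts <- saS[rows + 1L]
        rots <- paste0(substring(text, starts + 1L),
                       substring(text, 1L, starts))
        expans <- vapply(saP, function(j)
            expandRotation(dictionary(pfp), prot, j, w), "")
        expect_identical(expans, rots)
    }
})

test_that("indexes survive a save/load round trip; corrupt files error", {
    path <- tempfile(fileext = ".pfpfm")
    saveIndex(exIdx, path)
    idx2 <- loadIndex(path)
    res <- countOccurrences(idx2, EX_QUERY, details = TRUE)
    expect_identical(res$count, 1L)
    expect_identical(res$trace$betaText, c(31L, 32L))
    set.seed(59)
    corpus <- generatePangenome(300L, 3L, 0.02, seed = 5L)
    idx <- buildIndex(corpus@text, ParseParams(w = 4L, p = 7L))
    saveIndex(idx, path)
    idx2 <- loadIndex(path)
    for (rep in 1:100) {
        len <- sample(3:40, 1L)
        st <- sample(nchar(corpus@text) - len, 1L)
        q <- substr(corpus@text, st, st + len - 1L)
        if (grepl("[$#]", q)) next
        expect_identical(countOccurrences(idx2, q), countOccurrences(idx, q))
    }
    # corrupted header: explicit load error, not a crash
    bad <- tempfile()
    writeLines("this is not an index", bad)
    expect_error(loadIndex(bad), "load")
    ok <- tempfile()
    saveRDS(list(format = "something-else"), ok)
    expect_error(loadIndex(ok), "not a")
    unlink(c(path, bad, ok))
})
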