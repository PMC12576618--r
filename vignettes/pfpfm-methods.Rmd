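---
title: "Counting with a two-level FM-index built on prefix-free parsing"
author: "pfpfm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting with a two-level FM-index built on prefix-free parsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfpfm)
```

## The problem

The FM-index answers *count* queries — how many times does a pattern `Q`
occur in a text `S` — by backward search over the Burrows–Wheeler transform
(BWT): one rank query, and in practice at least one cache-unfriendly random
access, per pattern character.  On highly repetitive collections such as
pangenomes, most of a long query consists of whole repeated "words", and a
word-based index can traverse them in far fewer steps.  DNA has no natural
word boundaries, so this package first imposes them with *prefix-free
parsing* and then runs backward search at two levels: character by
character at the pattern's two ends, phrase by phrase in its middle.

## Prefix-free parsing

Given a window length `w ≥ 2` and a modulus `p ≥ 1`, a length-`w` window is
a **trigger string** when its Karp–Rabin fingerprint is divisible by `p`
(the expected distance between triggers, and hence the average phrase
length, is about `p`).  The text `S[0..n-1]` carries a unique terminal
sentinel `$`, smaller than every other symbol, and is treated as cyclic;
the window beginning at the `$` is always a trigger.  Scanning
`S' = $ S[0..n-2] $ S[0..w-2]` and cutting at every trigger occurrence
yields phrases that begin and end with a trigger and contain no other
trigger occurrence; consecutive phrases overlap by exactly `w` characters.
The distinct phrases, sorted (sentinel < separator < alphabet), form the
dictionary `D`; the **parse** `P` rewrites the text as 0-based phrase IDs
(lexicographic ranks).  Because every phrase continues past its final
trigger into the next phrase's leading trigger, no phrase is a proper
prefix of another — the phrase set is prefix-free, which is what makes
phrase-level suffix sorting consistent with character-level sorting.

```{r}
params <- ParseParams(w = 2L, mode = "explicit",
                      triggers = c("AA", "CG", "TA"))
pf <- buildPFP("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", params)
dictionary(pf)
parseIds(pf)
```

The explicit-trigger mode exists so that small worked examples (and unit
tests) can pin the trigger set by name; production parsing uses the hash
mode, whose constants (base 256, prime modulus 1999999973) are stored in
the index so that queries are parsed with the identical fingerprint.

## The two-level index

`buildIndex()` assembles four components:

* the FM-index of the character-level text `S`;
* the FM-index of the parse `P`, rotated so that the sentinel-anchored
  phrase (always ID 0, since its phrase starts with `$`) sits at the end
  and serves as the parse's terminal symbol;
* a **marking bitvector** `B` over the rows of the BWT matrix of `S`, with
  a 1 exactly where the row's rotation starts at a trigger occurrence.
  The number of ones equals `|P|`, and the i-th one corresponds to the
  i-th row of the BWT matrix of `P`: prefix-freeness makes the
  lexicographic order of parse rotations agree with the order of their
  character-level expansions.  `rank1`/`select1` on `B` therefore convert
  intervals between the two BWTs in either direction;
* an exact phrase map from Karp–Rabin fingerprints to phrase IDs.  The
  probabilistic variant (fingerprints without verification) is correct
  only with high probability; this implementation always stores the
  phrase characters and verifies lookups, so counts are deterministic and
  exact, and no behaviour depends on a hash seed.

## Counting a query

A query is first cut at its trigger occurrences into a **partial
encoding**: a prefix `alpha` ending at the right end of the first trigger,
the IDs of the complete phrases between consecutive triggers, and a suffix
`beta` from the left end of the last trigger.  The pattern is not cyclic
and has no sentinel, so `alpha`/`beta` may be empty; a query that ends at
a trigger folds that trigger into its last complete phrase, and a query
with fewer than two trigger occurrences has no complete phrase at all and
is searched purely at character level (this includes every pattern shorter
than `w`).  If any complete phrase is absent from the dictionary the count
is 0 without touching the index.

Otherwise the search proceeds: backward search `beta` in the text
FM-index (its occurrences all start with a trigger, so the resulting rows
are all marked); map the interval to the parse BWT with `rank1`; backward
search the complete-phrase IDs right-to-left; map back with `select1`;
and finish with the remainder of `alpha` — its trailing `w` characters are
already covered by the first complete phrase and are skipped.  Any empty
interval along the way means count 0; otherwise the final interval size
is the count.

```{r}
idx <- buildIndex("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", params)
res <- countOccurrences(idx, "CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT",
                        details = TRUE)
res$trace
res$count
```

## Parameters and conventions

* `w` (window length, characters) and `p` (hash modulus) tune the average
  phrase length (~`p`) and thus how much of a query is traversed phrase by
  phrase.  The package default `(w, p) = (6, 50)` sits at the setting that
  profits most on repetitive pangenome-style collections; counts
  themselves are invariant to `(w, p)`, which the test suite checks
  explicitly.
* Coordinates are 0-based; BWT intervals are inclusive `[lo..hi]` and
  empty when `lo > hi`.
* The sentinel `$` is appended when missing and must not occur internally.
  Multi-record inputs are joined with a separator `#` ordered between `$`
  and the alphabet; patterns may not contain either.
* Input is uppercased; any other character (including `N`) is an ordinary
  alphabet symbol — the method is alphabet-agnostic.
* The empty pattern returns `n` (the size of the full BWT interval); the
  naive scanning oracle returns 0 for it, so the equivalence suites use
  non-empty patterns.
* Trigger occurrences may overlap (e.g. `AA` in `AAA`); every matching
  window position is a phrase boundary, giving phrases of length `w + 1`.
  The literal window scan of `S'` also hashes the few windows that
  straddle the appended sentinel copy; with `p = 1` these fire too, and
  the parse round-trip invariant still holds.

## Numerical and structural choices

* **Suffix arrays** are built by prefix-doubling over cyclic shifts with
  counting sort (compiled, O(n log n)); the unique smallest terminal makes
  cyclic order equal suffix order.  Correctness is contracted against a
  brute-force rotation-sort oracle, not a particular algorithm.
* **Rank structures**: the character-level BWT (alphabet of a handful of
  symbols) uses a full cumulative occurrence table with O(1) rank; the
  phrase-level BWT, whose alphabet is the dictionary and can be large,
  uses per-symbol sorted position lists with binary search.  At the
  problem sizes this package targets the asymptotic difference is
  irrelevant; the structures were chosen for memory shape.
* The parse FM-index is over the rotation of `P` that ends in phrase
  ID 0; since `$` is unique, ID 0 occurs exactly once and acts as the
  parse's end-of-string symbol.
* Serialization stores parameters (including hash constants), dictionary,
  both BWTs, C arrays and the bitvector in a versioned archive; rank
  structures and the phrase map are rebuilt deterministically on load.

## What the synthetic data does and does not emulate

`generatePangenome()` produces one random base sequence and point-mutated
copies (each site redrawn uniformly over the four bases with the given
probability, so rate 1 gives an expected per-site difference of 3/4).
This reproduces the repetitiveness that makes word-based indexing
attractive, and `samplePatterns()` draws in-record substrings the way
query workloads are drawn from input files.  It does not emulate
insertions/deletions, rearrangements, assembly gaps, or realistic base
composition; passing tests therefore demonstrate exact counting on
repetitive collections, not biological realism of the corpora.  Counting
itself is exact for any text, which the random-text suites cover
independently of the pangenome generator.

The test and acceptance suites run corpora of 1k–200k characters (plus
one 1 MB smoke comparison of the two-level index against a plain
single-level FM-index), pattern lengths 5–1000, `w ∈ {2,...,10}` and
`p ∈ {1, 11, 31, 50, 101}`; these sizes exercise every code path —
including degenerate parses under `p = 1` — while keeping the default
check quick on a laptop.

## Limitations

* Only *count* is supported; *locate* would need suffix-array samples,
  which the index deliberately drops after construction.
* The whole index lives in memory, uncompressed: no run-length BWT, no
  succinct bitvectors, no streaming construction for multi-gigabyte
  inputs.
* Query-time advantage over a plain FM-index materialises only when
  patterns span several phrases; the package chooses correctness-first
  structures and makes no wall-clock promises.
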