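# pfpfm — a two-level FM-index built on prefix-free parsing

`pfpfm` counts (possibly overlapping) occurrences of query patterns in a
text — typically a repetitive DNA collection such as a set of closely
related genomes.  A plain FM-index answers a `count` query by backward
search, spending one rank query (and in practice one random access) per
pattern character.  On repetitive collections most of a long query is made
of whole repeated "words", and `pfpfm` exploits that: it imposes word
boundaries on the sequence with **prefix-free parsing** and then backward
searches character by character only at the pattern's two ends, and phrase
by phrase in its middle.

## The method

Given a window length `w` and modulus `p`, a length-`w` window of the
sentinel-terminated text `S[0..n-1]` is a *trigger string* when its
Karp–Rabin fingerprint `f` satisfies `f ≡ 0 (mod p)` (the window starting
at the sentinel `$` is always a trigger).  Cutting the cyclic text at every
trigger occurrence yields phrases that begin and end with a trigger,
contain no other trigger, and overlap their neighbours by exactly `w`
characters; the distinct phrases form a prefix-free, lexicographically
sorted dictionary `D`, and the parse `P` rewrites `S` as the sequence of
phrase IDs (ranks in `D`).

The index stores the FM-index of `S` (`BWT`, `C`, rank), the FM-index of a
rotation of `P` whose terminal symbol is the sentinel-anchored phrase
ID 0, an exact map from phrase fingerprints to phrase IDs, and a bitvector
`B[0..n-1]` marking the BWT-matrix rows of `S` whose rotations start at a
trigger occurrence.  Prefix-freeness makes the lexicographic order of the
rotations of `P` agree with that of their character-level expansions, so
`B.rank1` / `B.select1` convert a BWT interval of `S` into the matching BWT
interval of `P` and back.

A query `Q` is decomposed into `alpha` (up to the right end of its first
trigger), complete-phrase IDs, and `beta` (from the left end of its last
trigger).  `count(Q)` backward searches `beta` in `BWT_S`, maps the
interval into `BWT_P` with `rank1`, backward searches the phrase IDs,
maps back with `select1`, and finishes with `alpha` minus its trailing
`w` characters; the final interval size is the count.  Patterns without
two trigger occurrences fall back to plain character-level search, so
counts are always exact and identical to a single-level FM-index.

## Worked example

```r
library(pfpfm)
params <- ParseParams(w = 2L, mode = "explicit",
                      triggers = c("AA", "CG", "TA"))
idx <- buildIndex("TCCAGAAGAGTATCTCCTCGACATGTTGAAGACATATGAT", params)
dictionary(idx)
#> [1] "$TCCAGAA"     "AAGACATA"     "AAGAGTA"      "CGACATGTTGAA"
#> [5] "TATCTCCTCG"   "TATGAT$T"
res <- countOccurrences(idx, "CAGAAGAGTATCTCCTCGACATGTTGAAGACATAT",
                        details = TRUE)
res$count
#> [1] 1
res$trace
#> $betaText   31 32     # BWT_S rows prefixed by beta = "TAT"
#> $betaParse   4  5     # their image in BWT_P via B.rank1
#> $parseFinal  2  2     # after phrase-level search of IDs 2 4 3 1
#> $textMapped  2  2     # back in BWT_S via B.select1
#> $final      14 14     # after searching "CAG" (alpha minus w chars)
```

The 41-character text parses into six phrases with parse
`(0, 2, 4, 3, 1, 5)`; the query spans four complete phrases, so after the
three character-level steps for `TAT` the middle 30 characters cost only
four phrase-level steps.  The final interval `[14..14]` has size 1: the
query occurs once.  `selftest()` prints this chain, and the command-line
tool (`inst/scripts/pfpfm.R`) exposes `build`, `count` and `selftest`
subcommands for shell use.

Synthetic data for experiments comes from `generatePangenome()` (mutated
copies of a base sequence, FASTA-free) and `samplePatterns()`;
`naiveCount()` is the brute-force scan every index count is tested
against.

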