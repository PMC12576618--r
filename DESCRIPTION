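Package: pfpfm
Title: Two-Level FM-Index Built on Prefix-Free Parsing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Word-based FM-indexing for counting pattern occurrences in
    repetitive sequence collections such as pangenomes.  A Karp-Rabin
    rolling hash selects trigger strings that cut the text into a
    prefix-free parse (a sorted phrase dictionary plus the text rewritten
    as phrase IDs); FM-indexes over both the character-level text and the
    phrase-level parse are tied together by a marking bitvector with
    rank/select, so a count query backward-searches character by character
    only at the pattern's ends and phrase by phrase in its middle.
    Includes corpus I/O (FASTA or plain text), synthetic pangenome
    generation, pattern samplers, a naive-scan oracle and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
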