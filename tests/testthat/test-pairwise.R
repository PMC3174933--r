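test_that("the move set is the 4x4 square minus the origin", {
    mv <- enumerateMoves()
    expect_equal(nrow(mv), 15L)
    expect_false(any(mv$da == 0 & mv$db == 0))
    expect_equal(sum(mv$nFs == 0), 3L)   # codon substitution / insertion / deletion
    expect_equal(sum(mv$nFs > 0), 12L)
    expect_setequal(paste(mv$da, mv$db),
                    setdiff(paste(rep(0:3, each = 4), rep(0:3, 4)), "0 0"))
    ## a move consuming 1 or 2 nt frameshifts that row
    expect_true(all((mv$da %in% 1:2) == (mv$fsA == 1)))
})

test_that("clean identical ORFs align gap-free with diagonal scores", {
    aln <- alignPair("ATGGCCTTT", "ATGGCCTTT")
    expect_equal(alignmentScore(aln), 15)   # M/M + A/A + F/F = 5 + 4 + 6
    expect_identical(unname(ntRows(aln)), rep("ATGGCCTTT", 2))
    expectAlignmentInvariants(aln)
})

test_that("the printed worked example reproduces its oracle-fixed optimum", {
    ## brute-force enumeration fixed the optimal score of this pair at 3
    aln <- alignPair("ATTTCGAAATG", "ATCGAGATG")
    expect_equal(alignmentScore(aln), 3)
    expect_true(any(grepl("!", codonSites(aln), fixed = TRUE)))
    expect_equal(oracleAlign("ATTTCGAAATG", "ATCGAGATG")$score, 3)
    expectAlignmentInvariants(aln, c(seqA = "ATTTCGAAATG", seqB = "ATCGAGATG"))
})

test_that("one extra nucleotide surfaces as exactly one frameshifted site", {
    aln <- alignPair("ATGTTT", "ATGATTT")
    nFs <- sum(grepl("!", codonSites(aln), fixed = TRUE))
    expect_equal(nFs, 1L)
    expect_equal(alignmentScore(aln), oracleAlign("ATGTTT", "ATGATTT")$score)
})

test_that("the oracle handles degenerate and terminal cases", {
    expect_equal(oracleAlign("ATG", "ATG")$score, 5)          # M vs M
    expect_equal(oracleAlign("ATG", "")$score, 0)             # free end gaps
    expect_equal(oracleAlign("ATGTGA", "ATG")$score, 5)       # terminal stop free
    expect_error(oracleAlign(randomNtString(20), randomNtString(20)),
                 "24 nt")
})

test_that("alignPair rejects empty or illegal input", {
    expect_error(alignPair("", "ATG"), "empty")
    expect_error(alignPair("ATG", "AXG"), "illegal")
})

test_that("DP score equals exhaustive enumeration on random small pairs", {
    set.seed(2024)
    for (rep in 1:80) {
        a <- randomNtString(sample(1:8, 1))
        b <- randomNtString(sample(1:8, 1))
        sc <- codonScoringScheme(gapOpen = -sample(1:12, 1),
                                 gapExt = -sample(0:4, 1),
                                 fs = -sample(5:50, 1),
                                 stop = -sample(5:120, 1))
        expect_equal(alignmentScore(alignPair(a, b, sc)),
                     oracleAlign(a, b, sc)$score,
                     info = paste(a, b))
    }
})

test_that("with frameshifts priced out the DP reduces to protein Needleman-Wunsch", {
    data(BLOSUM62, package = "Biostrings", envir = environment())
    set.seed(31)
    sc <- codonScoringScheme(fs = -1e6)
    for (rep in 1:25) {
        a <- randomOrf(sample(4:12, 1))
        b <- randomOrf(sample(4:12, 1))
        ref <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(translateRaw(a)),
            Biostrings::AAString(translateRaw(b)),
            substitutionMatrix = BLOSUM62,
            gapOpening = 7, gapExtension = 1, type = "overlap")
        expect_equal(alignmentScore(alignPair(a, b, sc)),
                     Biostrings::score(ref), info = paste(a, b))
    }
})

test_that("reported scores survive independent rescoring and rows ungap to inputs", {
    set.seed(77)
    for (rep in 1:30) {
        a <- randomNtString(sample(3:40, 1))
        b <- randomNtString(sample(3:40, 1))
        aln <- alignPair(a, b, idA = "a", idB = "b")
        s <- codonSites(aln)
        expect_equal(frameAlign:::scoreInducedPair(s[1, ], s[2, ]),
                     alignmentScore(aln), info = paste(a, b))
        expectAlignmentInvariants(aln, c(a = a, b = b))
    }
})

test_that("per-row penalty sets change only the owning row's events", {
    ## b carries the deletion; pricing b's frameshifts leniently must not
    ## score worse than the uniform scheme
    a <- randomOrf(12); set.seed(5)
    b <- injectFrameshift(a, 6, 1)
    sHard <- alignmentScore(alignPair(a, b))
    sSoft <- alignmentScore(alignPair(a, b, codonScoringScheme(fsLowpen = -10),
                                      setB = "lowpen"))
    expect_gte(sSoft, sHard)
})
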