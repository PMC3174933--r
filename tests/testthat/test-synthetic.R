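test_that("zero rates give identical copies of a stop-free ATG ancestor", {
    f <- evolveOrf(nCodons = 20, nSeqs = 4, seed = 1)
    expect_length(f$seqs, 4L)
    expect_true(all(f$seqs == f$ancestor))
    expect_identical(substr(f$ancestor, 1, 3), "ATG")
    expect_false(grepl("\\*", substr(translateRaw(f$ancestor), 1,
                                     nchar(f$ancestor) / 3)))
    expect_equal(nrow(f$truth), 0L)
})

test_that("fixtures are reproducible from their seed", {
    a <- evolveOrf(nCodons = 30, nSeqs = 5, subProb = 0.1, indelProb = 0.02,
                   seed = 77)
    b <- evolveOrf(nCodons = 30, nSeqs = 5, subProb = 0.1, indelProb = 0.02,
                   seed = 77)
    expect_identical(a$seqs, b$seqs)
    expect_identical(a$truth, b$truth)
    c2 <- evolveOrf(nCodons = 30, nSeqs = 5, subProb = 0.1, seed = 78)
    expect_false(identical(a$seqs, c2$seqs))
})

test_that("frameshift injection shortens by the stated length and is recorded", {
    f <- evolveOrf(nCodons = 40, nSeqs = 3,
                   fsInjections = data.frame(seq = 2, codon = 5, len = 1),
                   seed = 5)
    expect_equal(nchar(f$seqs[[2]]), 3 * 40 - 1)
    expect_equal(nchar(f$seqs[[1]]), 3 * 40)
    expect_identical(f$truth$type, "frameshift")
    expect_equal(f$truth$codon, 5)
    expect_equal(f$truth$ntPosition, 13)
    ## direct injection arithmetic
    expect_equal(injectFrameshift("ATGGCC", 2, 1), "ATGCC")
    expect_equal(nchar(injectFrameshift(strrep("ATG", 5), 5, 2)), 13)
    expect_error(injectFrameshift("ATGGCC", 2, 3), "delLen")
    expect_error(injectFrameshift("ATGGCC", 4, 1), "outside")
})

test_that("stop injection writes a stop triplet at an internal codon", {
    s <- strrep("ATG", 10)
    m <- injectStop(s, 3)
    expect_identical(substr(translateRaw(m), 3, 3), "*")
    expect_equal(nchar(m), nchar(s))
    expect_error(injectStop(s, 10), "internal")
    m2 <- injectStop(injectStop(s, 3), 6)
    expect_equal(lengths(regmatches(translateRaw(m2),
                                    gregexpr("*", translateRaw(m2),
                                             fixed = TRUE))), 2L)
})

test_that("a zero-mutation family aligns gap-free and event-free", {
    f <- evolveOrf(nCodons = 15, nSeqs = 5, seed = 2)
    res <- alignCodingSequences(f$seqs, trace = FALSE)
    expect_false(any(grepl("[-!]", codonSites(res$alignment))))
    expect_equal(nrow(reportEvents(res$alignment)), 0L)
})

test_that("injected stops surface at the right codon in the AA view", {
    f <- evolveOrf(nCodons = 18, nSeqs = 3, subProb = 0.05,
                   stopInjections = data.frame(seq = c(2, 2), codon = c(6, 11)),
                   seed = 19)
    ## lenient stop penalty keeps the stops in frame (pseudogene setting)
    res <- alignCodingSequences(f$seqs, codonScoringScheme(stop = -10),
                                trace = FALSE)
    aa <- aaRows(res$alignment)[["seq2"]]
    ## gap-free row: alignment columns are sequence codons
    stars <- which(strsplit(aa, "")[[1]] == "*")
    expect_equal(stars, c(6L, 11L))
})
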