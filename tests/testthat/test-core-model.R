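test_that("genetic code tables load with the expected stop behaviour", {
    std <- loadGeneticCode(1)
    expect_length(std, 64L)
    expect_identical(std[["TGA"]], "*")
    expect_identical(loadGeneticCode(2)[["TGA"]], "W")
    expect_true(all(c("*") %in% loadGeneticCode(5)))
    expect_true(all(nchar(names(std)) == 3L))
    expect_error(loadGeneticCode(99), "unsupported genetic code")
})

test_that("raw translation never interrupts and marks partial codons", {
    expect_identical(translateRaw("ATGTGAAAA"), "M*K")
    expect_identical(translateRaw("ATGA"), "M!")
    expect_identical(translateRaw("ATGAANTTT"), "MXF")
    ## length is always ceiling(n/3)
    for (len in c(1:7, 30, 31, 32)) {
        s <- randomNtString(len)
        expect_identical(nchar(translateRaw(s)), as.integer(ceiling(len / 3)))
    }
    ## mitochondrial code reads TGA through as tryptophan
    expect_identical(translateRaw("ATGTGAAAA", loadGeneticCode(2)), "MWK")
})

test_that("input normalisation uppercases, maps U to T and rejects junk", {
    expect_identical(normalizeNucleotides("augc"), "ATGC")
    expect_identical(normalizeNucleotides("ATUN"), "ATTN")
    expect_error(normalizeNucleotides(""), "empty")
    expect_error(normalizeNucleotides("ATB"), "illegal character")
})

test_that("codon sites classify totally and exclusively", {
    expect_identical(classifySite("---"), "gap")
    expect_identical(classifySite("ATG"), "full")
    expect_identical(classifySite("A!G"), "frameshift")
    expect_identical(classifySite("!!T"), "frameshift")
    expect_error(classifySite("A-G"), "invalid")
    expect_error(classifySite("-!A"), "invalid")
    expect_error(classifySite("!!!"), "invalid")
})

test_that("site scores decompose additively over events", {
    sc <- codonScoringScheme()
    expect_equal(siteScore("TGG", "TGG", scheme = sc), 11)
    expect_equal(siteScore("A!G", "ATG", scheme = sc), -30)
    expect_equal(siteScore("TGA", "A!G", scheme = sc), -130)
    ## stop vs stop, fs vs fs stack per side
    expect_equal(siteScore("TGA", "TAA", scheme = sc), -200)
    expect_equal(siteScore("A!G", "!!C", scheme = sc), -60)
    ## gap side contributes one extension
    expect_equal(siteScore("TGG", "---", scheme = sc), sc@gapExt)
    expect_error(siteScore("---", "---", scheme = sc), "both")
    ## per-set overrides apply to the owning row only
    sc2 <- codonScoringScheme(fsLowpen = -20, stopLowpen = -10)
    expect_equal(siteScore("A!G", "ATG", setA = "lowpen", scheme = sc2), -20)
    expect_equal(siteScore("A!G", "ATG", setA = "reliable", setB = "lowpen",
                           scheme = sc2), -30)
    expect_equal(siteScore("TGA", "A!G", setA = "lowpen", setB = "lowpen",
                           scheme = sc2), -30)
})

test_that("site score is symmetric and reduces to the matrix on clean codons", {
    sc <- codonScoringScheme(fsLowpen = -20, stopLowpen = -10)
    code <- loadGeneticCode(1)
    pool <- orfCodonPool()
    set.seed(101)
    sites <- c(sample(pool, 12), "A!G", "!!T", "TGA", "TAA", "---", "ANT")
    sets <- c("reliable", "lowpen")
    for (rep in 1:100) {
        x <- sample(sites, 1); y <- sample(sites, 1)
        if (x == "---" && y == "---") next
        sx <- sample(sets, 1); sy <- sample(sets, 1)
        expect_equal(siteScore(x, y, sx, sy, sc, code),
                     siteScore(y, x, sy, sx, sc, code))
        if (classifySite(x) == "full" && classifySite(y) == "full") {
            ax <- translateRaw(x); ay <- translateRaw(y)
            if (ax != "*" && ay != "*")
                expect_equal(siteScore(x, y, sx, sy, sc, code),
                             unname(sc@matrix[ax, ay]))
        }
    }
})

test_that("the scoring scheme validates its invariants", {
    expect_error(codonScoringScheme(gapOpen = 3), "<= 0")
    sc <- codonScoringScheme()
    expect_true(isTRUE(all.equal(substitutionMatrix(sc),
                                 t(substitutionMatrix(sc)))))
    expect_equal(unname(gapScores(sc)), c(-7, -1))
})
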