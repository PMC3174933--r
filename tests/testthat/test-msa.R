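test_that("k-mer distances follow the shared-type formula", {
    expect_equal(unname(kmerDistanceMatrix(c(a = "ATGATG", b = "ATGATG"), 3)["a", "b"]), 0)
    expect_equal(unname(kmerDistanceMatrix(c(a = "AAAAAA", b = "CCCCCC"), 3)["a", "b"]), 1)
    ## hand enumeration: ATGATG -> {ATG,TGA,GAT}; ATGCCC -> {ATG,TGC,GCC,CCC}
    ## shared {ATG}; similarity 1/3; distance 2/3
    d <- kmerDistanceMatrix(c(a = "ATGATG", b = "ATGCCC"), 3)
    expect_equal(unname(d["a", "b"]), 2 / 3)
    expect_equal(diag(d), c(a = 0, b = 0))
    expect_warning(kmerDistanceMatrix(c(a = "AT", b = "ATGATG"), 3), "shorter")
})

test_that("UPGMA trees are binary, complete and match average-linkage clustering", {
    d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- buildGuideTree(d)
    expect_s3_class(tr, "phylo")
    expect_setequal(tr$tip.label, c("A", "B", "C"))
    ## A and B must form the cherry
    mrca <- ape::getMRCA(tr, c("A", "B"))
    expect_equal(length(ape::extract.clade(tr, mrca)$tip.label), 2L)
    expect_error(buildGuideTree(d[1, 1, drop = FALSE]), "at least 2")
    ## independent check against hclust average linkage on tie-free tables
    set.seed(99)
    for (rep in 1:10) {
        n <- sample(4:7, 1)
        ids <- paste0("t", seq_len(n))
        m <- matrix(0, n, n, dimnames = list(ids, ids))
        v <- runif(n * (n - 1) / 2, 0.05, 1)
        m[lower.tri(m)] <- v
        m <- m + t(m)
        t1 <- buildGuideTree(m)
        t2 <- ape::as.phylo(stats::hclust(stats::as.dist(m), method = "average"))
        expect_true(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))) == 0)
    }
})

test_that("aligning alignments preserves blocks and reproduces pairwise scores", {
    one <- frameAlign:::singleRowAlignment
    ## identical single-row ORFs merge gap-free; SP equals the pairwise score
    m <- alignAlignments(one("ATGGCCTTT", "a"), one("ATGGCCTTT", "b"))
    expect_equal(alignmentScore(m), 15)
    expect_false(any(codonSites(m) == "---"))
    ## three tryptophan rows: every pair scores 11
    m2 <- alignSequenceToAlignment("TGG", m3 <- alignAlignments(one("TGG", "a"), one("TGG", "b")),
                                   id = "c")
    expect_equal(spScore(m2), 3 * 11)
    ## 1-row blocks vs alignPair on frameshift-free ORF pairs
    set.seed(12)
    for (rep in 1:10) {
        a <- randomOrf(sample(4:9, 1)); b <- randomOrf(sample(4:9, 1))
        mm <- alignAlignments(one(a, "a"), one(b, "b"))
        pp <- alignPair(a, b, idA = "a", idB = "b")
        expect_equal(alignmentScore(mm), alignmentScore(pp), info = paste(a, b))
    }
    expect_error(alignAlignments(one("ATG", "x"), one("TGG", "x")), "overlap")
})

test_that("the DP merge estimate is pessimistic about gap openings", {
    ## quasi-natural opening counts never overestimate the exact SP score
    one <- frameAlign:::singleRowAlignment
    set.seed(40)
    for (rep in 1:10) {
        a <- randomNtString(sample(6:20, 1))
        b <- randomNtString(sample(6:20, 1))
        cc <- randomNtString(sample(6:20, 1))
        ab <- alignPair(a, b, idA = "a", idB = "b")
        m <- alignSequenceToAlignment(cc, ab, id = "c")
        est <- attr(m, "dpEstimate")
        cross <- sum(vapply(c("a", "b"), function(r)
            frameAlign:::scoreInducedPair(codonSites(m)[r, ], codonSites(m)["c", ]), 0))
        expect_lte(est, cross + 1e-9)
    }
    ## and is exact when no gaps exist at all
    m <- alignAlignments(one("ATGGCCTTT", "a"), one("ATGGCATTT", "b"))
    expect_equal(attr(m, "dpEstimate"), alignmentScore(m))
})

test_that("sequence-to-alignment merges preserve the block and can frameshift", {
    one <- frameAlign:::singleRowAlignment
    blk <- one("ATGGCCTTT", "a")
    m <- alignSequenceToAlignment("ATGGCCTTT", blk, id = "b")
    expect_false(any(grepl("[-!]", codonSites(m))))
    ## one extra nucleotide in the query: exactly one frameshift event
    m2 <- alignSequenceToAlignment("ATGGCACTTT", blk, id = "b")
    expect_equal(sum(grepl("!", codonSites(m2)["b", ], fixed = TRUE)), 1L)
    induced <- codonSites(m2)["a", ]
    expect_identical(unname(induced[induced != "---"]),
                     frameAlign:::seqToSites("ATGGCCTTT"))
    ## dissimilar sequences still produce a structurally valid merge
    m3 <- alignSequenceToAlignment("CCCCCCCCC", one("ATGATGATG", "a"), id = "b")
    expectAlignmentInvariants(m3, c(a = "ATGATGATG", b = "CCCCCCCCC"))
    expect_error(alignSequenceToAlignment("ATG", blk, id = "a"), "already")
})

test_that("sum-of-pairs equals the pairwise score on 2-row alignments", {
    set.seed(55)
    for (rep in 1:10) {
        aln <- alignPair(randomNtString(sample(5:25, 1)),
                         randomNtString(sample(5:25, 1)))
        expect_equal(spScore(aln), alignmentScore(aln))
    }
    ## k identical single-codon rows: C(k,2) * 11
    one <- frameAlign:::singleRowAlignment
    m <- alignAlignments(one("TGG", "a"), one("TGG", "b"))
    for (id in c("c", "d", "e"))
        m <- alignSequenceToAlignment("TGG", m, id = id)
    expect_equal(spScore(m), choose(5, 2) * 11)
})

test_that("progressive alignment follows the guide tree bottom-up", {
    ## two sequences: identical to alignPair
    seqs <- c(x = "ATGGCCTTTAAA", y = "ATGGCATTTAAA")
    tr <- buildGuideTree(kmerDistanceMatrix(seqs, 3))
    A <- progressiveAlign(seqs, tr)
    expect_equal(spScore(A), alignmentScore(alignPair(seqs[["x"]], seqs[["y"]])))
    ## n identical ORFs: gap-free, event-free for n up to 20
    for (n in c(3, 8, 20)) {
        seqs <- stats::setNames(rep("ATGGCCTTTAAACCC", n), paste0("s", seq_len(n)))
        A <- progressiveAlign(seqs, buildGuideTree(kmerDistanceMatrix(seqs, 6)))
        expect_false(any(grepl("[-!]", codonSites(A))))
        expect_equal(ncol(codonSites(A)), 5L)
    }
    expect_error(progressiveAlign(c(a = "ATG", b = "TGG"),
                                  buildGuideTree(kmerDistanceMatrix(
                                      c(x = "ATG", y = "TGG"), 2))),
                 "tips")
})

test_that("a synthetic frameshift is recovered by the full progressive pass", {
    f <- evolveOrf(nCodons = 25, nSeqs = 4, subProb = 0.05,
                   fsInjections = data.frame(seq = 2, codon = 9, len = 1),
                   seed = 17)
    res <- alignCodingSequences(f$seqs, trace = FALSE)
    sites <- codonSites(res$alignment)
    expect_true(any(grepl("!", sites["seq2", ], fixed = TRUE)))
    expect_false(any(grepl("!", sites[c("seq1", "seq3", "seq4"), ], fixed = TRUE)))
    expectAlignmentInvariants(res$alignment, f$seqs)
})

test_that("2-cut refinement never worsens the sum-of-pairs score", {
    set.seed(202)
    f <- evolveOrf(nCodons = 20, nSeqs = 5, subProb = 0.15, seed = 23)
    d <- kmerDistanceMatrix(f$seqs, 6)
    tr <- buildGuideTree(d)
    draft <- progressiveAlign(f$seqs, tr)
    ref <- refineTwoCut(draft, tr, trace = TRUE)
    traj <- attr(ref, "spTrajectory")
    expect_gte(alignmentScore(ref), spScore(draft))
    expect_true(all(diff(traj) > 0))
    expectAlignmentInvariants(ref, f$seqs)
    ## an already-optimal 2-row alignment is left unchanged
    p <- alignPair("ATGGCCTTT", "ATGGCATTT", idA = "u", idB = "v")
    tr2 <- buildGuideTree(kmerDistanceMatrix(
        c(u = "ATGGCCTTT", v = "ATGGCATTT"), 3))
    expect_identical(codonSites(refineTwoCut(p, tr2)), codonSites(p))
    expect_error(refineTwoCut(p, tr2, maxIter = -1), "maxIter")
})

test_that("refinement repairs a deliberately corrupted alignment", {
    f <- evolveOrf(nCodons = 15, nSeqs = 4, subProb = 0.1, seed = 31)
    res <- alignCodingSequences(f$seqs, trace = FALSE)
    good <- res$alignment
    ## corrupt: slide one row's site into a private extra column
    s <- codonSites(good)
    cc <- which(s[2, ] != "---")[2]
    extra <- matrix("---", nrow(s), 1)
    extra[2, 1] <- s[2, cc]
    bad <- cbind(s[, seq_len(cc), drop = FALSE], extra,
                 s[, -seq_len(cc), drop = FALSE])
    bad[2, cc] <- "---"
    corrupted <- frameAlign:::newCodonAlignment(bad, setLabels(good), codeIds(good))
    corrupted@score <- spScore(corrupted)
    tr <- retreeFromSP(corrupted)
    fixedUp <- refineTwoCut(corrupted, tr)
    expect_gte(alignmentScore(fixedUp), alignmentScore(corrupted))
})

test_that("SP-based retree groups identical rows first", {
    one <- frameAlign:::singleRowAlignment
    m <- alignAlignments(one("ATGGCCTTT", "a"), one("ATGGCCTTT", "b"))
    m <- alignSequenceToAlignment("TGGTGGTGGTGG", m, id = "c")
    tr <- retreeFromSP(m)
    mrca <- ape::getMRCA(tr, c("a", "b"))
    expect_equal(length(ape::extract.clade(tr, mrca)$tip.label), 2L)
})
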