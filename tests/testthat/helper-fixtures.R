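## shared fixtures: random coding sequences built in code

NTS <- c("A", "C", "G", "T")

## stop-free codons of the standard code
orfCodonPool <- function() {
    code <- loadGeneticCode(1L)
    names(code)[code != "*"]
}

randomNtString <- function(len) {
    paste0(sample(NTS, len, replace = TRUE), collapse = "")
}

## random stop-free in-frame ORF of nCodons codons
randomOrf <- function(nCodons, pool = orfCodonPool()) {
    paste0(sample(pool, nCodons, replace = TRUE), collapse = "")
}

## structural invariants every alignment must satisfy
expectAlignmentInvariants <- function(A, inputs = NULL) {
    s <- codonSites(A)
    expect_true(all(grepl(frameAlign:::SITE_REGEX, s)))
    if (ncol(s) > 0)
        expect_true(all(colSums(s != "---") > 0L))   # no all-gap column
    nt <- ntRows(A)
    aa <- aaRows(A)
    expect_equal(unname(nchar(nt)), unname(3L * nchar(aa)))
    if (!is.null(inputs))
        expect_identical(ungappedSequences(A)[names(inputs)], inputs)
}
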