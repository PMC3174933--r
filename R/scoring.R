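## Exact scoring of an induced pairwise alignment. This is the reference
## scorer: the pairwise DP must reproduce it on its own output, and the
## sum-of-pairs score is defined through it.

## sa, sb: character vectors of codon sites (one row each, equal length).
## Applies the full convention: columns that are gaps in both rows are
## dropped; gap runs cost gapOpen + len*gapExt unless they touch either end
## of the pair (terminal gaps free); a frameshifted site at a row's last
## non-gap position (trailing partial codon) is free; a stop codon at a
## row's last non-gap position is free.
scoreInducedPair <- function(sa, sb, setA = "reliable", setB = "reliable",
                             codeA = NULL, codeB = NULL,
                             scheme = codonScoringScheme()) {
    if (is.null(codeA)) codeA <- loadGeneticCode(1L)
    if (is.null(codeB)) codeB <- loadGeneticCode(1L)
    keep <- !(sa == "---" & sb == "---")
    sa <- sa[keep]; sb <- sb[keep]
    L <- length(sa)
    if (L == 0L) return(0)
    clsA <- vapply(sa, classifySite, "")
    clsB <- vapply(sb, classifySite, "")
    ## an all-gap row (empty sequence) has no events; its single gap run is
    ## terminal, hence free
    lastA <- if (any(clsA != "gap")) max(which(clsA != "gap")) else 0L
    lastB <- if (any(clsB != "gap")) max(which(clsB != "gap")) else 0L
    fsA <- fsFor(scheme, setA); fsB <- fsFor(scheme, setB)
    stopA <- stopFor(scheme, setA); stopB <- stopFor(scheme, setB)
    aaA <- ifelse(clsA == "full", vapply(sa, siteToAa, "", code = codeA), NA)
    aaB <- ifelse(clsB == "full", vapply(sb, siteToAa, "", code = codeB), NA)

    total <- 0
    ## per-side event costs with trailing exemptions
    fsCols <- which(clsA == "frameshift" & seq_len(L) != lastA)
    total <- total + length(fsCols) * fsA
    fsCols <- which(clsB == "frameshift" & seq_len(L) != lastB)
    total <- total + length(fsCols) * fsB
    total <- total + sum(aaA == "*" & seq_len(L) != lastA, na.rm = TRUE) * stopA
    total <- total + sum(aaB == "*" & seq_len(L) != lastB, na.rm = TRUE) * stopB
    ## substitutions where both sides are full non-stop codons
    subCols <- which(clsA == "full" & clsB == "full" & aaA != "*" & aaB != "*")
    if (length(subCols))
        total <- total + sum(scheme@matrix[cbind(aaA[subCols], aaB[subCols])])
    ## affine gap runs, terminal runs free
    total <- total + gapRunCost(clsA == "gap", scheme)
    total <- total + gapRunCost(clsB == "gap", scheme)
    as.numeric(unname(total))
}

gapRunCost <- function(isGap, scheme) {
    if (!any(isGap)) return(0)
    r <- rle(isGap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    L <- ends[length(ends)]
    total <- 0
    for (k in which(r$values)) {
        if (starts[k] == 1L || ends[k] == L) next   # terminal run: free
        total <- total + scheme@gapOpen + r$lengths[k] * scheme@gapExt
    }
    total
}

#' Sum-of-pairs score of a codon alignment
#'
#' Sum over all unordered row pairs of the induced pairwise alignment score:
#' columns that are gaps in both rows of a pair are dropped before scoring,
#' gap runs are charged affine costs (free at pair ends), and the trailing
#' frameshift / terminal stop exemptions of the pairwise aligner apply.
#'
#' @param A a \code{CodonAlignment}.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @return numeric sum-of-pairs score.
#' @export
spScore <- function(A, scheme = codonScoringScheme()) {
    s <- A@sites
    n <- nrow(s)
    if (n < 2L) return(0)
    codes <- lapply(A@codeIds, loadGeneticCode)
    total <- 0
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            total <- total + scoreInducedPair(
                s[i, ], s[j, ],
                setA = A@setLabels[i], setB = A@setLabels[j],
                codeA = codes[[i]], codeB = codes[[j]],
                scheme = scheme)
        }
    }
    as.numeric(total)
}

## Data the C++ block kernels need, precomputed per alignment:
## per-cell gap flag, substitutable amino-acid index (0-based, -1 when the
## cell carries no substitution term), the cell's own event cost with the
## trailing exemptions already applied, and whether a gap cell is row-
## terminal (leading/trailing run of its row).
blockData <- function(A, scheme) {
    s <- A@sites
    r <- nrow(s); cc <- ncol(s)
    isGap <- matrix(0L, r, cc)
    subAa <- matrix(-1L, r, cc)
    eventCost <- matrix(0, r, cc)
    gapTerm <- matrix(0L, r, cc)
    for (i in seq_len(r)) {
        code <- loadGeneticCode(A@codeIds[i])
        fsI <- fsFor(scheme, A@setLabels[i])
        stopI <- stopFor(scheme, A@setLabels[i])
        cls <- vapply(s[i, ], classifySite, "")
        nonGap <- which(cls != "gap")
        lastNG <- max(nonGap); firstNG <- min(nonGap)
        for (j in seq_len(cc)) {
            if (cls[j] == "gap") {
                isGap[i, j] <- 1L
                if (j < firstNG || j > lastNG) gapTerm[i, j] <- 1L
            } else if (cls[j] == "frameshift") {
                if (j != lastNG) eventCost[i, j] <- fsI
            } else {
                aa <- siteToAa(s[i, j], code)
                if (aa == "*") {
                    if (j != lastNG) eventCost[i, j] <- stopI
                } else {
                    subAa[i, j] <- match(aa, AA_ORDER) - 1L
                }
            }
        }
    }
    list(isGap = isGap, subAa = subAa, eventCost = eventCost,
         gapTerm = gapTerm)
}
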