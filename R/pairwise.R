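#' The 15 moves of the frameshift-aware recursion
#'
#' Each dynamic-programming cell looks back at the 4x4 square of cells
#' consuming 0-3 nucleotides from each sequence, excluding (0,0): 15 moves.
#' Three of them (codon substitution, codon insertion, codon deletion) are
#' the classical amino-acid moves; the other 12 induce one or two
#' frameshifts. Moves are listed in the deterministic tie-break priority
#' order used by \code{\link{alignPair}}: fewer frameshifts first, then
#' (3,3) > (3,0) > (0,3), then lexicographically larger (da, db).
#'
#' @return data.frame with columns \code{da}, \code{db} (nucleotides
#'   consumed from each sequence), \code{fsA}, \code{fsB} (frameshifts
#'   induced in each row), \code{nFs} and \code{state} (the Gotoh state the
#'   move enters: M, D or I).
#' @examples
#' nrow(enumerateMoves())                 # 15
#' sum(enumerateMoves()$nFs == 0)         # 3
#' @export
enumerateMoves <- function() {
    g <- expand.grid(da = 0:3, db = 0:3)
    g <- g[!(g$da == 0 & g$db == 0), ]
    g$fsA <- as.integer(g$da %in% 1:2)
    g$fsB <- as.integer(g$db %in% 1:2)
    g$nFs <- g$fsA + g$fsB
    g$state <- ifelse(g$db == 0, "D", ifelse(g$da == 0, "I", "M"))
    ## deterministic priority: fewer frameshifts, then the three classical
    ## moves in order (3,3) > (3,0) > (0,3), then descending (da, db)
    special <- match(paste(g$da, g$db), c("3 3", "3 0", "0 3"))
    special[is.na(special)] <- 4L
    o <- order(g$nFs, special, -g$da, -g$db)
    g <- g[o, , drop = FALSE]
    rownames(g) <- NULL
    g
}

## One site of a row for a move consuming k nucleotides ending at 1-based
## position `end` of sequence string s ("!" pads precede the nucleotides).
moveSite <- function(s, end, k) {
    if (k == 0L) return("---")
    nts <- substr(s, end - k + 1L, end)
    paste0(strrep("!", 3L - k), nts)
}

## Chunk an unaligned sequence into codon sites (trailing partial codon
## padded with "!").
seqToSites <- function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = 3L)
    vapply(starts, function(p) moveSite(s, min(p + 2L, n), min(3L, n - p + 1L)), "")
}

## Single-row CodonAlignment from an unaligned sequence.
singleRowAlignment <- function(seq, id, set = "reliable", codeId = 1L) {
    sites <- matrix(seqToSites(seq), nrow = 1L,
                    dimnames = list(id, NULL))
    newCodonAlignment(sites, set, codeId, score = NA_real_)
}

#' Optimal frameshift-aware pairwise alignment
#'
#' Aligns two coding nucleotide sequences by the 15-move dynamic program:
#' three Gotoh state matrices (match/substitution, insertion, deletion)
#' over nucleotide prefix lengths, with affine gap costs in codon-site
#' units, free terminal gaps (semi-global), free trailing partial codons
#' and free terminal stop codons. Scoring is purely at the amino-acid
#' level: full codon pairs score through the substitution matrix, each
#' frameshifted codon costs the row's frameshift score and each internal
#' stop the row's stop score. Only cell (0,0) is initialised; all other
#' boundary accesses go through a -Inf sentinel.
#'
#' @param a,b nucleotide strings over \{A,C,G,T,N\} (lowercase and U
#'   accepted).
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param idA,idB row ids for the result.
#' @param setA,setB set labels (\code{"reliable"}/\code{"lowpen"}) choosing
#'   which frameshift/stop scores apply to each row.
#' @param codeA,codeB NCBI genetic code table ids for each row.
#' @return A \code{CodonAlignment} with two rows and the optimal score.
#' @examples
#' aln <- alignPair("ATGGCCTTT", "ATGGCCTTT")
#' alignmentScore(aln)  # 15
#' @export
alignPair <- function(a, b, scheme = codonScoringScheme(),
                      idA = "seqA", idB = "seqB",
                      setA = "reliable", setB = "reliable",
                      codeA = 1L, codeB = 1L) {
    a <- normalizeNucleotides(a, idA)
    b <- normalizeNucleotides(b, idB)
    ea <- encodeNt(a); eb <- encodeNt(b)
    aaMapA <- codeToAaIndex(loadGeneticCode(codeA))
    aaMapB <- codeToAaIndex(loadGeneticCode(codeB))
    res <- cpp_align_pair(ea, eb, aaMapA, aaMapB, scheme@matrix,
                          scheme@gapOpen, scheme@gapExt,
                          fsFor(scheme, setA), fsFor(scheme, setB),
                          stopFor(scheme, setA), stopFor(scheme, setB))
    path <- res$path   # matrix, columns da, db, rows in alignment order
    pa <- cumsum(path[, 1L]); pb <- cumsum(path[, 2L])
    rowA <- vapply(seq_len(nrow(path)),
                   function(k) moveSite(a, pa[k], path[k, 1L]), "")
    rowB <- vapply(seq_len(nrow(path)),
                   function(k) moveSite(b, pb[k], path[k, 2L]), "")
    sites <- rbind(rowA, rowB)
    rownames(sites) <- c(idA, idB)
    newCodonAlignment(sites, c(setA, setB), c(codeA, codeB),
                      score = res$score)
}

#' Brute-force alignment oracle
#'
#' Exhaustively explores every sequence of the 15 moves consuming both
#' inputs (depth-first), pruning only branches whose partial score plus an
#' admissible upper bound on the remainder (remaining codon pairs times the
#' largest substitution entry) cannot strictly beat the incumbent — the
#' returned maximum is exact. Intended for validating
#' \code{\link{alignPair}} on small inputs; refuses inputs longer than 24
#' nucleotides combined.
#'
#' @inheritParams alignPair
#' @return list with elements \code{score} and \code{alignment} (a
#'   \code{CodonAlignment}).
#' @export
oracleAlign <- function(a, b, scheme = codonScoringScheme(),
                        idA = "seqA", idB = "seqB",
                        setA = "reliable", setB = "reliable",
                        codeA = 1L, codeB = 1L) {
    if (nzchar(a)) a <- normalizeNucleotides(a, idA)
    if (nzchar(b)) b <- normalizeNucleotides(b, idB)
    n <- nchar(a); m <- nchar(b)
    if (n + m > 24L)
        stop("oracleAlign refuses inputs longer than 24 nt combined (exponential enumeration)")
    codeMapA <- loadGeneticCode(codeA)
    codeMapB <- loadGeneticCode(codeB)
    fsA <- fsFor(scheme, setA); fsB <- fsFor(scheme, setB)
    stopA <- stopFor(scheme, setA); stopB <- stopFor(scheme, setB)
    maxSub <- max(max(scheme@matrix), 0)

    ## event cost of consuming k nucleotides of s ending at position `end`
    sideCost <- function(s, len, code, end, k, fs, stopPen) {
        if (k == 3L) {
            cd <- substr(s, end - 2L, end)
            if (grepl("N", cd, fixed = TRUE)) return(0)
            if (code[[cd]] == "*" && end < len) return(stopPen)
            return(0)
        }
        if (end < len) fs else 0   # trailing partial codon is free
    }
    subTerm <- function(endA, endB) {
        ca <- substr(a, endA - 2L, endA); cb <- substr(b, endB - 2L, endB)
        aaA <- if (grepl("N", ca, fixed = TRUE)) "X" else codeMapA[[ca]]
        aaB <- if (grepl("N", cb, fixed = TRUE)) "X" else codeMapB[[cb]]
        if (aaA == "*" || aaB == "*") return(0)
        scheme@matrix[aaA, aaB]
    }

    mv <- enumerateMoves()
    env <- new.env()
    env$best <- -Inf
    env$bestPath <- NULL
    path <- matrix(0L, nrow = n + m, ncol = 2L)

    rec <- function(i, j, state, acc, depth) {
        if (i == n && j == m) {
            if (acc > env$best) {
                env$best <- acc
                env$bestPath <- path[seq_len(depth), , drop = FALSE]
            }
            return(invisible(NULL))
        }
        bound <- min(ceiling((n - i) / 3), ceiling((m - j) / 3)) * maxSub
        if (!is.null(env$bestPath) && acc + bound <= env$best)
            return(invisible(NULL))
        for (k in seq_len(nrow(mv))) {
            da <- mv$da[k]; db <- mv$db[k]
            i2 <- i + da; j2 <- j + db
            if (i2 > n || j2 > m) next
            d <- 0
            if (da > 0L) d <- d + sideCost(a, n, codeMapA, i2, da, fsA, stopA)
            if (db > 0L) d <- d + sideCost(b, m, codeMapB, j2, db, fsB, stopB)
            if (da == 3L && db == 3L) d <- d + subTerm(i2, j2)
            st <- mv$state[k]
            if (st == "D") {          # gap in b
                if (!(j == 0L || j == m))
                    d <- d + scheme@gapExt + if (state != "D") scheme@gapOpen else 0
            } else if (st == "I") {   # gap in a
                if (!(i == 0L || i == n))
                    d <- d + scheme@gapExt + if (state != "I") scheme@gapOpen else 0
            }
            path[depth + 1L, ] <<- c(da, db)
            rec(i2, j2, st, acc + d, depth + 1L)
        }
        invisible(NULL)
    }
    rec(0L, 0L, "M", 0, 0L)

    p <- env$bestPath
    pa <- cumsum(p[, 1L]); pb <- cumsum(p[, 2L])
    rowA <- vapply(seq_len(nrow(p)), function(k) moveSite(a, pa[k], p[k, 1L]), "")
    rowB <- vapply(seq_len(nrow(p)), function(k) moveSite(b, pb[k], p[k, 2L]), "")
    sites <- rbind(rowA, rowB)
    rownames(sites) <- c(idA, idB)
    list(score = env$best,
         alignment = newCodonAlignment(sites, c(setA, setB),
                                       c(codeA, codeB), score = env$best))
}
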