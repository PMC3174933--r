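## ---------------------------------------------------------------------------
## Guide-tree estimation and progressive multiple alignment
## ---------------------------------------------------------------------------

#' k-mer distance matrix
#'
#' Compositional distances from shared nucleotide k-mer sets:
#' \code{similarity(i,j)} is the number of k-mer types the two sequences
#' share divided by the smaller of their k-mer type counts, and
#' \code{distance = 1 - similarity}, clamped to \code{[0,1]}. Sequences
#' shorter than k have an empty k-mer set and get distance 1 to everything
#' (with a warning).
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param k k-mer length in nucleotides (default 6).
#' @return symmetric distance matrix with zero diagonal.
#' @export
kmerDistanceMatrix <- function(seqs, k = 6L) {
    stopifnot(k >= 1L, !is.null(names(seqs)))
    n <- length(seqs)
    if (any(nchar(seqs) < k))
        warning("sequence(s) shorter than k: assigned distance 1 to all others")
    sets <- lapply(seqs, function(s) {
        L <- nchar(s)
        if (L < k) return(character(0))
        unique(substring(s, 1:(L - k + 1L), k:L))
    })
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (j <= i) next
            lo <- min(length(sets[[i]]), length(sets[[j]]))
            sim <- if (lo == 0L) 0 else
                length(intersect(sets[[i]], sets[[j]])) / lo
            d[i, j] <- d[j, i] <- min(max(1 - sim, 0), 1)
        }
    }
    d
}

#' UPGMA guide tree
#'
#' Standard UPGMA agglomeration (arithmetic-average linkage) over a
#' distance matrix, returning a rooted strictly binary \code{ape::phylo}
#' tree. Ties are broken deterministically by merging the pair whose
#' cluster labels (the lexicographically smallest member id of each
#' cluster) come first.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return an \code{ape} \code{phylo} object with the input ids as tips.
#' @export
buildGuideTree <- function(d) {
    ids <- rownames(d)
    if (is.null(ids) || length(ids) < 2L)
        stop("need a distance matrix over at least 2 ids")
    n <- length(ids)
    members <- as.list(ids)
    label <- ids             # smallest member id per active cluster
    newick <- ids
    height <- rep(0, n)
    size <- rep(1L, n)
    active <- rep(TRUE, n)
    dd <- d
    for (step in seq_len(n - 1L)) {
        act <- which(active)
        ## smallest distance; ties -> lexicographically first (label_i, label_j)
        bi <- bj <- 0L; bv <- Inf; bl <- c("", "")
        for (ii in act) for (jj in act) {
            if (jj <= ii) next
            v <- dd[ii, jj]
            lab <- sort(c(label[ii], label[jj]))
            better <- v < bv ||
                (v == bv && (lab[1L] < bl[1L] ||
                             (lab[1L] == bl[1L] && lab[2L] < bl[2L])))
            if (better) { bv <- v; bi <- ii; bj <- jj; bl <- lab }
        }
        if (label[bj] < label[bi]) { tmp <- bi; bi <- bj; bj <- tmp }
        h <- bv / 2
        bli <- max(h - height[bi], 0)
        blj <- max(h - height[bj], 0)
        newClade <- sprintf("(%s:%g,%s:%g)", newick[bi], bli, newick[bj], blj)
        ## average linkage update into slot bi
        for (kk in act) {
            if (kk == bi || kk == bj) next
            v <- (size[bi] * dd[bi, kk] + size[bj] * dd[bj, kk]) /
                (size[bi] + size[bj])
            dd[bi, kk] <- dd[kk, bi] <- v
        }
        members[[bi]] <- c(members[[bi]], members[[bj]])
        size[bi] <- size[bi] + size[bj]
        height[bi] <- h
        newick[bi] <- newClade
        active[bj] <- FALSE
    }
    ape::read.tree(text = paste0(newick[which(active)], ";"))
}

## ---------------------------------------------------------------------------
## Merging alignments
## ---------------------------------------------------------------------------

#' Align two alignments (block vs block)
#'
#' Finds, among the alignments inducing both input blocks unchanged, one
#' maximising the sum-of-pairs objective: cross-pair substitution costs
#' come from \code{\link{siteScore}}'s decomposition, gap extensions from
#' per-column gap configurations, and gap openings from the quasi-natural
#' (pessimistic) count, with "!"-containing sites treated as residues.
#' Columns are atomic, so no new frameshift can be introduced here.
#'
#' @param A1,A2 \code{CodonAlignment} objects with disjoint row ids.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @return merged \code{CodonAlignment}; its \code{score} slot holds the
#'   exact recomputed sum-of-pairs score.
#' @export
alignAlignments <- function(A1, A2, scheme = codonScoringScheme()) {
    if (length(intersect(rownames(A1@sites), rownames(A2@sites))))
        stop("row ids of the two alignments overlap")
    b1 <- blockData(A1, scheme)
    b2 <- blockData(A2, scheme)
    ng1 <- blockExtents(b1$isGap)
    ng2 <- blockExtents(b2$isGap)
    res <- cpp_align_blocks(b1$isGap, b1$subAa, b1$eventCost,
                            ng1$first, ng1$last,
                            b2$isGap, b2$subAa, b2$eventCost,
                            ng2$first, ng2$last,
                            scheme@matrix, scheme@gapOpen, scheme@gapExt)
    mvs <- res$moves
    r1 <- nrow(A1@sites); r2 <- nrow(A2@sites)
    out <- matrix("---", r1 + r2, length(mvs))
    i <- 0L; j <- 0L
    for (q in seq_along(mvs)) {
        if (mvs[q] != 3L) { i <- i + 1L; out[seq_len(r1), q] <- A1@sites[, i] }
        if (mvs[q] != 2L) { j <- j + 1L; out[r1 + seq_len(r2), q] <- A2@sites[, j] }
    }
    rownames(out) <- c(rownames(A1@sites), rownames(A2@sites))
    merged <- newCodonAlignment(out,
                                c(A1@setLabels, A2@setLabels),
                                c(A1@codeIds, A2@codeIds))
    merged@score <- spScore(merged, scheme)
    ## the DP's internal cross-pair estimate (quasi-natural gap opens,
    ## within-block pair contributions excluded) for diagnostics/tests
    attr(merged, "dpEstimate") <- res$score
    merged
}

## first/last non-gap column per row (1-based), for terminal-gap handling
blockExtents <- function(isGap) {
    first <- apply(isGap == 0L, 1L, function(z) min(which(z)))
    last <- apply(isGap == 0L, 1L, function(z) max(which(z)))
    list(first = as.integer(first), last = as.integer(last))
}

#' Align a sequence to an existing alignment
#'
#' Hybrid dynamic program whose moves consume 0 or 1 column of the block
#' and 0-3 nucleotides of the sequence (7 moves), so new frameshifts can be
#' introduced in the sequence while the block's induced alignment is
#' preserved exactly.
#'
#' @param s nucleotide string.
#' @param A a \code{CodonAlignment} not containing \code{id}.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param id row id for the new sequence.
#' @param set set label for the new sequence.
#' @param codeId NCBI genetic code id for the new sequence.
#' @return merged \code{CodonAlignment} (new row last); \code{score} holds
#'   the exact recomputed sum-of-pairs score.
#' @export
alignSequenceToAlignment <- function(s, A, scheme = codonScoringScheme(),
                                     id = "query", set = "reliable",
                                     codeId = 1L) {
    if (id %in% rownames(A@sites))
        stop(sprintf("id '%s' already present in the alignment", id))
    s <- normalizeNucleotides(s, id)
    b <- blockData(A, scheme)
    ng <- blockExtents(b$isGap)
    res <- cpp_align_seq_block(b$isGap, b$subAa, b$eventCost,
                               ng$first, ng$last,
                               encodeNt(s), codeToAaIndex(loadGeneticCode(codeId)),
                               scheme@matrix, scheme@gapOpen, scheme@gapExt,
                               fsFor(scheme, set), stopFor(scheme, set))
    path <- res$path
    r <- nrow(A@sites)
    out <- matrix("---", r + 1L, nrow(path))
    i <- 0L; pos <- 0L
    for (q in seq_len(nrow(path))) {
        if (path[q, 1L] == 1L) { i <- i + 1L; out[seq_len(r), q] <- A@sites[, i] }
        k <- path[q, 2L]
        if (k > 0L) { pos <- pos + k; out[r + 1L, q] <- moveSite(s, pos, k) }
    }
    rownames(out) <- c(rownames(A@sites), id)
    merged <- newCodonAlignment(out,
                                c(A@setLabels, set),
                                c(A@codeIds, codeId))
    merged@score <- spScore(merged, scheme)
    attr(merged, "dpEstimate") <- res$score
    merged
}

## ---------------------------------------------------------------------------
## Progressive alignment and 2-cut refinement
## ---------------------------------------------------------------------------

#' Progressive multiple alignment along a guide tree
#'
#' Processes the internal nodes of the rooted binary guide tree bottom-up:
#' two leaves are merged with the 15-move pairwise aligner, a leaf joining
#' a block uses the 7-move hybrid aligner, and two blocks are merged
#' column-atomically under the sum-of-pairs objective.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param tree \code{phylo} guide tree whose tip labels equal
#'   \code{names(seqs)}.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param setLabels,codeIds per-sequence set labels / genetic code ids
#'   (recycled).
#' @return a \code{CodonAlignment}; \code{score} holds its sum-of-pairs
#'   score.
#' @export
progressiveAlign <- function(seqs, tree, scheme = codonScoringScheme(),
                             setLabels = "reliable", codeIds = 1L) {
    ids <- names(seqs)
    if (!setequal(tree$tip.label, ids))
        stop("guide tree tips do not match the sequence ids")
    n <- length(seqs)
    setLabels <- rep_len(setLabels, n); names(setLabels) <- ids
    codeIds <- rep_len(as.integer(codeIds), n); names(codeIds) <- ids
    mergeNode <- function(node) {
        if (node <= n) {   # tip
            id <- tree$tip.label[node]
            return(list(leaf = TRUE, id = id))
        }
        kids <- tree$edge[tree$edge[, 1L] == node, 2L]
        stopifnot(length(kids) == 2L)
        L <- mergeNode(kids[1L]); R <- mergeNode(kids[2L])
        mergeParts(L, R)
    }
    mergeParts <- function(L, R) {
        if (isTRUE(L$leaf) && isTRUE(R$leaf)) {
            aln <- alignPair(seqs[[L$id]], seqs[[R$id]], scheme,
                             idA = L$id, idB = R$id,
                             setA = setLabels[[L$id]], setB = setLabels[[R$id]],
                             codeA = codeIds[[L$id]], codeB = codeIds[[R$id]])
            return(list(leaf = FALSE, aln = aln))
        }
        if (isTRUE(L$leaf) || isTRUE(R$leaf)) {
            leaf <- if (isTRUE(L$leaf)) L else R
            block <- if (isTRUE(L$leaf)) R else L
            aln <- alignSequenceToAlignment(seqs[[leaf$id]], block$aln, scheme,
                                            id = leaf$id,
                                            set = setLabels[[leaf$id]],
                                            codeId = codeIds[[leaf$id]])
            return(list(leaf = FALSE, aln = aln))
        }
        list(leaf = FALSE, aln = alignAlignments(L$aln, R$aln, scheme))
    }
    root <- n + 1L
    res <- mergeNode(root)
    if (isTRUE(res$leaf)) {   # single-sequence "tree" cannot occur (>=2 tips)
        return(singleRowAlignment(seqs[[res$id]], res$id,
                                  setLabels[[res$id]], codeIds[[res$id]]))
    }
    res$aln
}

## subset rows of an alignment, dropping all-gap columns
subsetAlignment <- function(A, ids) {
    keepRows <- match(ids, rownames(A@sites))
    s <- A@sites[keepRows, , drop = FALSE]
    keepCols <- colSums(s != "---") > 0L
    newCodonAlignment(s[, keepCols, drop = FALSE],
                      A@setLabels[keepRows], A@codeIds[keepRows])
}

## clades (tip-label sets) of all internal nodes and single tips, root
## excluded; ordered tips-first then post-order internal nodes
treeClades <- function(tree) {
    n <- length(tree$tip.label)
    out <- as.list(tree$tip.label)
    parts <- ape::prop.part(tree)
    labs <- attr(parts, "labels")
    for (k in seq_along(parts)) {
        tipSet <- labs[parts[[k]]]
        if (length(tipSet) < n)    # skip the root clade
            out[[length(out) + 1L]] <- tipSet
    }
    out
}

#' Tree-driven 2-cut refinement
#'
#' Iteratively considers each clade of the guide tree, splits the current
#' alignment into the clade rows versus the rest (dropping all-gap columns
#' in each part), re-merges the two parts, and keeps the result only if the
#' sum-of-pairs score strictly improves. When a split leaves a single row
#' on one side, that row is ungapped and realigned with the 7-move hybrid
#' aligner, so frameshifts can be re-placed. After each full sweep the
#' guide tree is re-estimated from normalised sum-of-pairs contributions;
#' refinement stops when a sweep brings no improvement or after
#' \code{maxIter} sweeps.
#'
#' @param A a \code{CodonAlignment}.
#' @param tree guide tree over the rows of \code{A}.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param maxIter maximum number of sweeps (default 10).
#' @param trace logical; if TRUE, attach the accepted-score trajectory as
#'   attribute \code{"spTrajectory"}.
#' @return refined \code{CodonAlignment} with final score in \code{score};
#'   never worse than the input.
#' @export
refineTwoCut <- function(A, tree, scheme = codonScoringScheme(),
                         maxIter = 10L, trace = FALSE) {
    if (maxIter < 0L) stop("maxIter must be >= 0")
    cur <- A
    if (is.na(cur@score)) cur@score <- spScore(cur, scheme)
    trajectory <- cur@score
    allIds <- rownames(cur@sites)
    if (length(allIds) < 2L || maxIter == 0L) {
        if (trace) attr(cur, "spTrajectory") <- trajectory
        return(cur)
    }
    for (sweep in seq_len(maxIter)) {
        improved <- FALSE
        for (clade in treeClades(tree)) {
            rest <- setdiff(allIds, clade)
            if (length(rest) == 0L || length(clade) == 0L) next
            cand <- remergeParts(cur, clade, rest, scheme)
            if (!is.null(cand) && cand@score > cur@score) {
                cur <- cand
                improved <- TRUE
                trajectory <- c(trajectory, cur@score)
            }
        }
        if (!improved) break
        tree <- retreeFromSP(cur, scheme)
    }
    ## keep the original row order for reproducible output
    cur <- reorderRows(cur, allIds)
    if (trace) attr(cur, "spTrajectory") <- trajectory
    cur
}

remergeParts <- function(cur, clade, rest, scheme) {
    P1 <- subsetAlignment(cur, clade)
    P2 <- subsetAlignment(cur, rest)
    if (nrow(P1@sites) == 1L) {
        s <- ungappedSequences(P1)[[1L]]
        alignSequenceToAlignment(s, P2, scheme, id = rownames(P1@sites),
                                 set = P1@setLabels, codeId = P1@codeIds)
    } else if (nrow(P2@sites) == 1L) {
        s <- ungappedSequences(P2)[[1L]]
        alignSequenceToAlignment(s, P1, scheme, id = rownames(P2@sites),
                                 set = P2@setLabels, codeId = P2@codeIds)
    } else {
        alignAlignments(P1, P2, scheme)
    }
}

reorderRows <- function(A, ids) {
    o <- match(ids, rownames(A@sites))
    newCodonAlignment(A@sites[o, , drop = FALSE], A@setLabels[o],
                      A@codeIds[o], A@score)
}

#' Guide tree from sum-of-pairs contributions
#'
#' Re-estimates the guide tree from the current alignment: the similarity
#' of rows i and j is their induced pairwise score normalised by the larger
#' of the two self-scores, and distance is 1 - similarity clamped to
#' \code{[0,1]}; UPGMA as in \code{\link{buildGuideTree}}.
#'
#' @param A a \code{CodonAlignment} with at least 2 rows.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @return an \code{ape} \code{phylo} guide tree.
#' @export
retreeFromSP <- function(A, scheme = codonScoringScheme()) {
    s <- A@sites
    n <- nrow(s)
    if (n < 2L) stop("need at least 2 rows")
    codes <- lapply(A@codeIds, loadGeneticCode)
    self <- vapply(seq_len(n), function(i)
        scoreInducedPair(s[i, ], s[i, ], A@setLabels[i], A@setLabels[i],
                         codes[[i]], codes[[i]], scheme), 0)
    d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            pij <- scoreInducedPair(s[i, ], s[j, ], A@setLabels[i], A@setLabels[j],
                                    codes[[i]], codes[[j]], scheme)
            denom <- max(self[i], self[j])
            sim <- if (denom <= 0) 0 else pij / denom
            d[i, j] <- d[j, i] <- min(max(1 - sim, 0), 1)
        }
    }
    buildGuideTree(d)
}

#' Full alignment pipeline
#'
#' k-mer distances, UPGMA guide tree, progressive alignment and 2-cut
#' refinement in one call.
#'
#' @param seqs named character vector of coding nucleotide sequences.
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param setLabels,codeIds per-sequence set labels / genetic code ids
#'   (recycled).
#' @param k nucleotide k-mer length for the initial distances.
#' @param maxIter maximum refinement sweeps.
#' @param initAlignment optional \code{CodonAlignment} to use as the
#'   starting point instead of running the progressive stage.
#' @param trace logical, keep the accepted sum-of-pairs trajectory.
#' @return list with elements \code{alignment} (a \code{CodonAlignment}),
#'   \code{tree} (the final guide tree, NULL for a single sequence) and
#'   \code{spTrajectory} (numeric, accepted scores in order).
#' @export
alignCodingSequences <- function(seqs, scheme = codonScoringScheme(),
                                 setLabels = "reliable", codeIds = 1L,
                                 k = 6L, maxIter = 10L,
                                 initAlignment = NULL, trace = TRUE) {
    ids <- names(seqs)
    if (is.null(ids) || anyDuplicated(ids))
        stop("sequences must carry unique names")
    seqs <- vapply(ids, function(i) normalizeNucleotides(seqs[[i]], i), "")
    n <- length(seqs)
    setLabels <- rep_len(setLabels, n)
    codeIds <- rep_len(as.integer(codeIds), n)
    if (n == 1L) {
        aln <- singleRowAlignment(seqs[[1L]], ids[1L], setLabels[1L], codeIds[1L])
        return(list(alignment = aln, tree = NULL, spTrajectory = numeric(0)))
    }
    if (is.null(initAlignment)) {
        d <- kmerDistanceMatrix(seqs, k = k)
        tree <- buildGuideTree(d)
        draft <- progressiveAlign(seqs, tree, scheme, setLabels, codeIds)
    } else {
        stopifnot(is(initAlignment, "CodonAlignment"))
        if (!setequal(rownames(initAlignment@sites), ids))
            stop("initial alignment rows do not match the input ids")
        draft <- initAlignment
        if (is.na(draft@score)) draft@score <- spScore(draft, scheme)
        tree <- retreeFromSP(draft, scheme)
    }
    refined <- refineTwoCut(draft, tree, scheme, maxIter = maxIter,
                            trace = trace)
    trajectory <- attr(refined, "spTrajectory")
    attr(refined, "spTrajectory") <- NULL
    finalTree <- retreeFromSP(refined, scheme)
    list(alignment = refined, tree = finalTree,
         spTrajectory = if (is.null(trajectory)) refined@score else trajectory)
}
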