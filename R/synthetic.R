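## ---------------------------------------------------------------------------
## Synthetic coding-sequence families with known ground truth
## ---------------------------------------------------------------------------

## codons of a genetic code that are not stops (used to keep ancestors and
## substitutions stop-free)
nonStopCodons <- function(code = loadGeneticCode(1L)) {
    names(code)[code != "*"]
}

stopCodonOf <- function(code = loadGeneticCode(1L)) {
    stops <- names(code)[code == "*"]
    if ("TGA" %in% stops) "TGA" else stops[1L]
}

#' Inject a 1-2 nt deletion (frameshift) into a sequence
#'
#' Removes \code{delLen} nucleotides starting at the first position of the
#' stated codon, producing the "FS-" events the aligner is built to
#' recover.
#'
#' @param seq nucleotide string.
#' @param codonPos 1-based codon position at which the deletion starts.
#' @param delLen 1 or 2 nucleotides.
#' @return mutated sequence string.
#' @export
injectFrameshift <- function(seq, codonPos, delLen) {
    if (!delLen %in% 1:2) stop("delLen must be 1 or 2")
    start <- (codonPos - 1L) * 3L + 1L
    if (codonPos < 1L || start + delLen - 1L > nchar(seq))
        stop("deletion position outside the sequence")
    paste0(substr(seq, 1L, start - 1L),
           substr(seq, start + delLen, nchar(seq)))
}

#' Replace an internal codon with a stop codon
#'
#' @param seq nucleotide string (length a multiple of 3 for the replaced
#'   region to be a codon).
#' @param codonIndex 1-based codon index; must be internal (not the last
#'   codon, since terminal stops are unpenalised and useless as truth).
#' @param code genetic code providing the stop triplet (TGA preferred).
#' @return mutated sequence string.
#' @export
injectStop <- function(seq, codonIndex, code = loadGeneticCode(1L)) {
    nCod <- nchar(seq) %/% 3L
    if (codonIndex < 1L || codonIndex >= nCod)
        stop("codonIndex must be internal (not the last codon)")
    start <- (codonIndex - 1L) * 3L + 1L
    paste0(substr(seq, 1L, start - 1L), stopCodonOf(code),
           substr(seq, start + 3L, nchar(seq)))
}

#' Evolve a star-topology coding-sequence family with known ground truth
#'
#' Draws a random stop-free ancestor ORF starting with ATG, then evolves
#' each descendant independently (star topology, for truth simplicity):
#' per-codon substitutions drawn uniformly over non-stop codons, optional
#' per-codon whole-codon indels, then the requested frameshift (1-2 nt
#' deletion) and premature-stop injections. All randomness is governed by
#' one seed.
#'
#' @param nCodons ancestor length in codons.
#' @param nSeqs number of descendant sequences.
#' @param subProb per-codon substitution probability per lineage.
#' @param indelProb per-codon probability of a whole-codon indel
#'   (deletion or insertion, equally likely).
#' @param fsInjections data.frame with columns \code{seq} (index),
#'   \code{codon}, \code{len} (1 or 2), or NULL.
#' @param stopInjections data.frame with columns \code{seq}, \code{codon},
#'   or NULL.
#' @param seed integer seed.
#' @param codeId NCBI genetic code id.
#' @return list with \code{seqs} (named character vector, ids
#'   \code{"seq1"}...), \code{truth} (data.frame of injected events with
#'   1-based positions) and \code{ancestor}.
#' @export
evolveOrf <- function(nCodons, nSeqs, subProb = 0, indelProb = 0,
                      fsInjections = NULL, stopInjections = NULL,
                      seed = 1L, codeId = 1L) {
    stopifnot(nCodons >= 2L, nSeqs >= 1L,
              subProb >= 0, subProb <= 1, indelProb >= 0, indelProb <= 1)
    set.seed(as.integer(seed))
    code <- loadGeneticCode(codeId)
    pool <- nonStopCodons(code)
    anc <- c("ATG", sample(pool, nCodons - 1L, replace = TRUE))
    ancestor <- paste0(anc, collapse = "")
    seqs <- character(nSeqs)
    truth <- list()
    for (s in seq_len(nSeqs)) {
        cods <- anc
        if (subProb > 0) {
            hit <- which(stats::runif(nCodons) < subProb)
            hit <- hit[hit > 1L]   # keep the start codon
            if (length(hit))
                cods[hit] <- sample(pool, length(hit), replace = TRUE)
        }
        if (indelProb > 0) {
            out <- character(0)
            for (ci in seq_along(cods)) {
                if (stats::runif(1) < indelProb && ci > 1L) {
                    if (stats::runif(1) < 0.5) {
                        truth[[length(truth) + 1L]] <- data.frame(
                            seq = s, type = "codon_deletion", codon = ci, len = 3L)
                        next                       # codon deleted
                    }
                    out <- c(out, cods[ci], sample(pool, 1L))
                    truth[[length(truth) + 1L]] <- data.frame(
                        seq = s, type = "codon_insertion", codon = ci, len = 3L)
                    next
                }
                out <- c(out, cods[ci])
            }
            cods <- out
        }
        seqs[s] <- paste0(cods, collapse = "")
    }
    names(seqs) <- paste0("seq", seq_len(nSeqs))
    if (!is.null(stopInjections)) {
        for (q in seq_len(nrow(stopInjections))) {
            s <- stopInjections$seq[q]; ci <- stopInjections$codon[q]
            seqs[s] <- injectStop(seqs[s], ci, code)
            truth[[length(truth) + 1L]] <- data.frame(
                seq = s, type = "internal_stop", codon = ci, len = 3L)
        }
    }
    if (!is.null(fsInjections)) {
        for (q in seq_len(nrow(fsInjections))) {
            s <- fsInjections$seq[q]
            ci <- fsInjections$codon[q]
            dl <- fsInjections$len[q]
            seqs[s] <- injectFrameshift(seqs[s], ci, dl)
            truth[[length(truth) + 1L]] <- data.frame(
                seq = s, type = "frameshift", codon = ci, len = dl)
        }
    }
    truthDf <- if (length(truth)) do.call(rbind, truth)
               else data.frame(seq = integer(0), type = character(0),
                               codon = integer(0), len = integer(0))
    truthDf$ntPosition <- (truthDf$codon - 1L) * 3L + 1L
    list(seqs = seqs, truth = truthDf, ancestor = ancestor)
}
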