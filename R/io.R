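#' Read coding nucleotide sequences from FASTA
#'
#' Ids are taken from the header up to the first whitespace; sequences are
#' uppercased with U converted to T, and characters outside \{A,C,G,T,N\}
#' are an error, as are duplicate ids or an empty file.
#'
#' @param path FASTA file.
#' @param setLabel set label given to every sequence in the file
#'   (\code{"reliable"} or \code{"lowpen"}).
#' @param codeId default NCBI genetic code id for the file.
#' @param codeFile optional two-column tab-separated file
#'   (\code{sequence_id <TAB> table_id}) assigning genetic codes per
#'   sequence; unlisted sequences keep \code{codeId}.
#' @return named character vector of sequences with attributes
#'   \code{setLabels} and \code{codeIds} (parallel named vectors).
#' @export
readCodingFasta <- function(path, setLabel = "reliable", codeId = 1L,
                            codeFile = NULL) {
    if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop(sprintf("'%s' contains no sequences", path))
    ids <- sub("\\s.*$", "", names(x))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(sprintf("duplicate sequence id '%s' in '%s'", dup[1L], path))
    seqs <- vapply(seq_along(x), function(i)
        normalizeNucleotides(as.character(x[[i]]), ids[i]), "")
    names(seqs) <- ids
    codes <- rep(as.integer(codeId), length(seqs))
    names(codes) <- ids
    if (!is.null(codeFile)) {
        tab <- utils::read.table(codeFile, sep = "\t", header = FALSE,
                                 col.names = c("id", "table"),
                                 colClasses = c("character", "integer"))
        hit <- tab$id %in% ids
        codes[tab$id[hit]] <- tab$table[hit]
    }
    structure(seqs,
              setLabels = stats::setNames(rep(setLabel, length(seqs)), ids),
              codeIds = codes)
}

#' Write the dual NT/AA FASTA views of an alignment
#'
#' \code{<prefix>_NT.fasta} holds each row as its concatenated codon sites
#' (nucleotides, \code{"!"}, \code{"-"}); \code{<prefix>_AA.fasta} holds
#' one symbol per codon site (residue, \code{"*"} for stops, \code{"!"}
#' for frameshifted sites, \code{"-"} for gaps). Every NT row is exactly 3
#' times the length of its AA row.
#'
#' @param A a \code{CodonAlignment}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeAlignment <- function(A, prefix) {
    nt <- Biostrings::BStringSet(ntRows(A))
    aa <- Biostrings::BStringSet(aaRows(A))
    ntPath <- paste0(prefix, "_NT.fasta")
    aaPath <- paste0(prefix, "_AA.fasta")
    Biostrings::writeXStringSet(nt, ntPath)
    Biostrings::writeXStringSet(aa, aaPath)
    invisible(c(NT = ntPath, AA = aaPath))
}

#' Read an aligned NT FASTA back into a CodonAlignment
#'
#' Inverse of the NT view written by \code{\link{writeAlignment}}: rows
#' must share one length divisible by 3 and decompose into valid codon
#' sites.
#'
#' @param path aligned nucleotide FASTA.
#' @param setLabels,codeIds per-row metadata (recycled; named vectors are
#'   matched by id).
#' @return a \code{CodonAlignment}.
#' @export
readAlignmentFasta <- function(path, setLabels = "reliable", codeIds = 1L) {
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop(sprintf("'%s' contains no sequences", path))
    ids <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(ids)) stop("duplicate ids in alignment file")
    rows <- toupper(vapply(seq_along(x), function(i) as.character(x[[i]]), ""))
    L <- unique(nchar(rows))
    if (length(L) != 1L || L %% 3L != 0L)
        stop("aligned rows must share one length divisible by 3")
    sites <- t(vapply(rows, function(r)
        substring(r, seq.int(1L, L, 3L), seq.int(3L, L, 3L)),
        character(L / 3L)))
    if (L / 3L == 1L) sites <- matrix(sites, ncol = 1L)
    rownames(sites) <- ids
    lab <- if (!is.null(names(setLabels))) setLabels[ids]
           else rep_len(setLabels, length(ids))
    cod <- if (!is.null(names(codeIds))) codeIds[ids]
           else rep_len(as.integer(codeIds), length(ids))
    newCodonAlignment(sites, unname(lab), unname(cod))
}

#' Frameshift and internal-stop event report
#'
#' One record per \code{"!"}-containing codon site and per internal stop
#' codon of every row; stops at a row's final codon position are exempt
#' and not reported. Positions are 1-based in the original ungapped
#' sequence, codon indices are 1-based alignment columns.
#'
#' @param A a \code{CodonAlignment}.
#' @param path optional TSV output path.
#' @return data.frame with columns \code{seqId}, \code{eventType}
#'   (\code{"frameshift"}/\code{"internal_stop"}), \code{ntPosition},
#'   \code{codonIndex}, sorted by id then position.
#' @export
reportEvents <- function(A, path = NULL) {
    recs <- list()
    for (r in seq_len(nrow(A@sites))) {
        id <- rownames(A@sites)[r]
        code <- loadGeneticCode(A@codeIds[r])
        sites <- A@sites[r, ]
        cls <- vapply(sites, classifySite, "")
        nonGap <- which(cls != "gap")
        lastNG <- max(nonGap)
        ## nucleotides consumed before each column
        ntBefore <- cumsum(c(0L, vapply(sites, function(x)
            sum(strsplit(x, "")[[1L]] %in% c("A", "C", "G", "T", "N")), 0L)))
        for (cc in seq_along(sites)) {
            if (cls[cc] == "frameshift") {
                recs[[length(recs) + 1L]] <- data.frame(
                    seqId = id, eventType = "frameshift",
                    ntPosition = ntBefore[cc] + 1L, codonIndex = cc)
            } else if (cls[cc] == "full" && cc != lastNG &&
                       !grepl("N", sites[cc], fixed = TRUE) &&
                       code[[sites[cc]]] == "*") {
                recs[[length(recs) + 1L]] <- data.frame(
                    seqId = id, eventType = "internal_stop",
                    ntPosition = ntBefore[cc] + 1L, codonIndex = cc)
            }
        }
    }
    out <- if (length(recs)) do.call(rbind, recs)
           else data.frame(seqId = character(0), eventType = character(0),
                           ntPosition = integer(0), codonIndex = integer(0))
    out <- out[order(out$seqId, out$ntPosition), , drop = FALSE]
    rownames(out) <- NULL
    if (!is.null(path))
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    out
}
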