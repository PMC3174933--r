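#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib frameAlign, .registration = TRUE
NULL

## Amino-acid alphabet used by all scoring tables: the 20 standard residues
## plus "X" for ambiguous (N-containing) codons. Stop ("*") is handled as an
## event, never through the substitution matrix.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X")

SET_LABELS <- c("reliable", "lowpen")

#' Scoring scheme for frameshift-aware codon alignment
#'
#' Bundles the amino-acid substitution matrix with the gap, frameshift and
#' internal-stop scores used by every aligner in the package. All penalties
#' are non-positive integers and the objective is maximised. Sequences in
#' the \code{"lowpen"} set (e.g. pseudogenes or raw reads) use the
#' \code{fsLowpen}/\code{stopLowpen} overrides for their frameshift and stop
#' contributions.
#'
#' @slot matrix symmetric integer substitution matrix over the 20 standard
#'   amino acids plus \code{"X"}.
#' @slot gapOpen gap opening score (added on top of the extension for the
#'   first site of an internal gap run), default -7.
#' @slot gapExt gap extension score per codon site, default -1.
#' @slot fs frameshift score per frameshifted codon site, default -30.
#' @slot stop internal stop codon score, default -100.
#' @slot fsLowpen frameshift score for rows in the \code{"lowpen"} set.
#' @slot stopLowpen internal stop score for rows in the \code{"lowpen"} set.
#'
#' @export
setClass("CodonScoringScheme",
    representation(
        matrix = "matrix",
        gapOpen = "numeric",
        gapExt = "numeric",
        fs = "numeric",
        stop = "numeric",
        fsLowpen = "numeric",
        stopLowpen = "numeric"
    )
)

setValidity("CodonScoringScheme", function(object) {
    m <- object@matrix
    if (!identical(rownames(m), AA_ORDER) || !identical(colnames(m), AA_ORDER))
        return("matrix must have rows/columns named by the 20 amino acids plus X")
    if (!isTRUE(all.equal(m, t(m))))
        return("substitution matrix must be symmetric")
    pens <- c(object@gapOpen, object@gapExt, object@fs, object@stop,
              object@fsLowpen, object@stopLowpen)
    if (any(!is.finite(pens)) || length(pens) != 6L)
        return("all penalties must be single finite numbers")
    if (any(pens > 0))
        return("gap, frameshift and stop scores must all be <= 0")
    TRUE
})

#' Construct a scoring scheme
#'
#' @param matrix substitution matrix; defaults to BLOSUM62 (from
#'   \pkg{Biostrings}) restricted to the 20 amino acids plus X.
#' @param gapOpen,gapExt,fs,stop non-positive scores for gap opening, gap
#'   extension (per codon site), frameshifted codon sites and internal stop
#'   codons. Defaults -7, -1, -30, -100.
#' @param fsLowpen,stopLowpen frameshift/stop scores applied to rows in the
#'   \code{"lowpen"} sequence set; default to \code{fs}/\code{stop}.
#'
#' @return A \code{CodonScoringScheme} object.
#' @examples
#' sc <- codonScoringScheme()
#' substitutionMatrix(sc)["W", "W"]  # 11
#' @export
codonScoringScheme <- function(matrix = NULL, gapOpen = -7, gapExt = -1,
                               fs = -30, stop = -100,
                               fsLowpen = fs, stopLowpen = stop) {
    if (is.null(matrix))
        matrix <- blosum62Matrix()
    new("CodonScoringScheme", matrix = matrix,
        gapOpen = as.numeric(gapOpen), gapExt = as.numeric(gapExt),
        fs = as.numeric(fs), stop = as.numeric(stop),
        fsLowpen = as.numeric(fsLowpen), stopLowpen = as.numeric(stopLowpen))
}

blosum62Matrix <- function() {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_ORDER, AA_ORDER]
    storage.mode(m) <- "double"
    m
}

#' @rdname CodonScoringScheme-class
#' @param object,x a \code{CodonScoringScheme}.
#' @export
setGeneric("substitutionMatrix", function(x) standardGeneric("substitutionMatrix"))

#' @rdname CodonScoringScheme-class
#' @export
setMethod("substitutionMatrix", "CodonScoringScheme", function(x) x@matrix)

#' @rdname CodonScoringScheme-class
#' @export
setGeneric("gapScores", function(x) standardGeneric("gapScores"))

#' @rdname CodonScoringScheme-class
#' @export
setMethod("gapScores", "CodonScoringScheme", function(x)
    c(open = x@gapOpen, ext = x@gapExt))

## frameshift / stop score for a given set label
fsFor <- function(scheme, set) ifelse(set == "lowpen", scheme@fsLowpen, scheme@fs)
stopFor <- function(scheme, set) ifelse(set == "lowpen", scheme@stopLowpen, scheme@stop)

setMethod("show", "CodonScoringScheme", function(object) {
    cat("CodonScoringScheme\n")
    cat(sprintf("  gap open %g, gap ext %g (per codon site)\n",
                object@gapOpen, object@gapExt))
    cat(sprintf("  frameshift %g (lowpen %g), internal stop %g (lowpen %g)\n",
                object@fs, object@fsLowpen, object@stop, object@stopLowpen))
    cat(sprintf("  %dx%d substitution matrix (%s...)\n",
                nrow(object@matrix), ncol(object@matrix),
                paste(AA_ORDER[1:5], collapse = "")))
})

#' Codon-structured alignment
#'
#' An alignment of coding nucleotide sequences whose atomic unit is the
#' codon site: a three-character cell over \{A,C,G,T,N,!,-\}. A cell is a
#' gap (\code{"---"}), a frameshifted codon (one or two \code{"!"} padding
#' the observed nucleotides), or a full codon. Removing all \code{"-"} and
#' \code{"!"} characters from a row reconstructs the input sequence exactly.
#'
#' @slot sites character matrix (rows = sequences, columns = codon sites) of
#'   3-character cells; rownames are the sequence ids.
#' @slot setLabels per-row set label, \code{"reliable"} or \code{"lowpen"}.
#' @slot codeIds per-row NCBI genetic code table id.
#' @slot score alignment score (pairwise score or sum-of-pairs), NA when not
#'   yet computed.
#'
#' @export
setClass("CodonAlignment",
    representation(
        sites = "matrix",
        setLabels = "character",
        codeIds = "integer",
        score = "numeric"
    )
)

## gap, full codon, or a frameshifted codon (one or two "!" anywhere)
SITE_REGEX <- paste0("^(---|[ACGTN]{3}",
                     "|![ACGTN]{2}|[ACGTN]![ACGTN]|[ACGTN]{2}!",
                     "|!![ACGTN]|![ACGTN]!|[ACGTN]!!)$")

setValidity("CodonAlignment", function(object) {
    s <- object@sites
    if (!is.character(s) || is.null(rownames(s)))
        return("sites must be a character matrix with rownames (sequence ids)")
    if (anyDuplicated(rownames(s)))
        return("duplicate sequence ids")
    if (length(object@setLabels) != nrow(s) || !all(object@setLabels %in% SET_LABELS))
        return("setLabels must be one of reliable/lowpen per row")
    if (length(object@codeIds) != nrow(s))
        return("codeIds must have one entry per row")
    if (ncol(s) > 0) {
        bad <- !grepl(SITE_REGEX, s)
        if (any(bad))
            return(sprintf("invalid codon site(s), e.g. '%s'", s[which(bad)[1L]]))
        allGap <- colSums(s != "---") == 0L
        if (any(allGap))
            return("alignment contains an all-gap column")
    }
    TRUE
})

newCodonAlignment <- function(sites, setLabels, codeIds, score = NA_real_) {
    new("CodonAlignment", sites = sites,
        setLabels = as.character(setLabels),
        codeIds = as.integer(codeIds), score = as.numeric(score))
}

#' @rdname CodonAlignment-class
#' @param x a \code{CodonAlignment}.
#' @export
setGeneric("codonSites", function(x) standardGeneric("codonSites"))

#' @rdname CodonAlignment-class
#' @export
setMethod("codonSites", "CodonAlignment", function(x) x@sites)

#' @rdname CodonAlignment-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname CodonAlignment-class
#' @export
setMethod("alignmentScore", "CodonAlignment", function(x) x@score)

#' @rdname CodonAlignment-class
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @rdname CodonAlignment-class
#' @export
setMethod("setLabels", "CodonAlignment", function(x) x@setLabels)

#' @rdname CodonAlignment-class
#' @export
setGeneric("codeIds", function(x) standardGeneric("codeIds"))

#' @rdname CodonAlignment-class
#' @export
setMethod("codeIds", "CodonAlignment", function(x) x@codeIds)

setMethod("length", "CodonAlignment", function(x) nrow(x@sites))

#' Nucleotide-level rows of an alignment
#'
#' @param x a \code{CodonAlignment}.
#' @return Named character vector: one string per row, codon sites
#'   concatenated (\code{ntRows}) or one symbol per site (\code{aaRows};
#'   \code{"!"} for frameshifted sites, \code{"*"} for stops, \code{"-"}
#'   for gaps).
#' @export
setGeneric("ntRows", function(x) standardGeneric("ntRows"))

#' @rdname ntRows
#' @export
setMethod("ntRows", "CodonAlignment", function(x)
    apply(x@sites, 1L, paste0, collapse = ""))

#' @rdname ntRows
#' @export
setGeneric("aaRows", function(x) standardGeneric("aaRows"))

#' @rdname ntRows
#' @export
setMethod("aaRows", "CodonAlignment", function(x) {
    out <- vapply(seq_len(nrow(x@sites)), function(r) {
        code <- loadGeneticCode(x@codeIds[r])
        paste0(vapply(x@sites[r, ], siteToAa, "", code = code), collapse = "")
    }, "")
    names(out) <- rownames(x@sites)
    out
})

#' Recover the unaligned input sequences
#'
#' Strips all \code{"-"} and \code{"!"} characters from each row.
#'
#' @param x a \code{CodonAlignment}.
#' @return Named character vector of the original sequences.
#' @export
setGeneric("ungappedSequences", function(x) standardGeneric("ungappedSequences"))

#' @rdname ungappedSequences
#' @export
setMethod("ungappedSequences", "CodonAlignment", function(x)
    gsub("[-!]", "", ntRows(x)))

setMethod("show", "CodonAlignment", function(object) {
    cat(sprintf("CodonAlignment: %d sequence(s), %d codon site(s)",
                nrow(object@sites), ncol(object@sites)))
    if (!is.na(object@score)) cat(sprintf(", score %g", object@score))
    cat("\n")
    nt <- ntRows(object)
    show_n <- min(length(nt), 8L)
    for (i in seq_len(show_n)) {
        s <- nt[i]
        if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
        cat(sprintf("  %-12s %s\n", names(nt)[i], s))
    }
    if (length(nt) > show_n) cat(sprintf("  ... %d more\n", length(nt) - show_n))
})
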