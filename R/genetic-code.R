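#' Load an NCBI genetic code table
#'
#' Returns the complete 64-entry codon-to-amino-acid map for an NCBI
#' translation table, with \code{"*"} for stop codons. Tables are taken from
#' \pkg{Biostrings}' copy of the NCBI genetic codes; the standard (1),
#' vertebrate mitochondrial (2), invertebrate mitochondrial (5) and
#' bacterial (11) codes are the common choices for coding-sequence work.
#'
#' @param tableId integer NCBI translation-table number.
#' @return Named character vector of length 64 mapping each DNA triplet to
#'   its amino acid (or \code{"*"}).
#' @examples
#' loadGeneticCode(1)[["TGA"]]  # "*"
#' loadGeneticCode(2)[["TGA"]]  # "W"
#' @export
loadGeneticCode <- function(tableId) {
    id <- as.character(as.integer(tableId))
    supported <- Biostrings::GENETIC_CODE_TABLE$id
    if (is.na(id) || !(id %in% supported))
        stop(sprintf("unsupported genetic code table '%s' (supported: %s)",
                     as.character(tableId), paste(supported, collapse = ", ")))
    code <- Biostrings::getGeneticCode(id)
    stopifnot(length(code) == 64L, any(code == "*"))
    code
}

CODON_BASES <- c("A", "C", "G", "T")

## All 64 codons in the base-4 order A<C<G<T used by the C++ kernels
## (index = 16*b1 + 4*b2 + b3, zero-based).
codonUniverse <- function() {
    g <- expand.grid(b3 = CODON_BASES, b2 = CODON_BASES, b1 = CODON_BASES,
                     stringsAsFactors = FALSE)
    paste0(g$b1, g$b2, g$b3)
}

## Map a genetic code onto amino-acid indices into AA_ORDER (1..21, X = 21);
## stop codons get index 22 (a sentinel the kernels treat as an event).
codeToAaIndex <- function(code) {
    aa <- code[codonUniverse()]
    idx <- match(aa, AA_ORDER)
    idx[aa == "*"] <- length(AA_ORDER) + 1L
    if (anyNA(idx))
        stop("genetic code maps a codon to an unsupported amino-acid symbol")
    as.integer(idx)
}

## Encode a DNA string over ACGTN as integers 0..4 for the C++ kernels.
encodeNt <- function(seq) {
    v <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T", "N")) - 1L
    if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N}")
    v
}

#' Normalise raw nucleotide input
#'
#' Uppercases, converts U to T, and rejects anything outside
#' \{A,C,G,T,N\}.
#'
#' @param seq character string.
#' @param id sequence id used in error messages.
#' @return normalised string.
#' @export
normalizeNucleotides <- function(seq, id = "sequence") {
    s <- chartr("u", "T", toupper(seq))
    s <- gsub("U", "T", s, fixed = TRUE)
    if (!nzchar(s)) stop(sprintf("%s: empty sequence", id))
    if (grepl("[^ACGTN]", s)) {
        bad <- regmatches(s, regexpr("[^ACGTN]", s))
        stop(sprintf("%s: illegal character '%s'", id, bad))
    }
    s
}

#' Raw frame-1 translation with frameshift and stop symbols
#'
#' Translates a nucleotide sequence codon by codon in reading frame 1
#' without ever interrupting: stop codons become \code{"*"} and translation
#' continues, a trailing incomplete codon becomes \code{"!"}, and any codon
#' containing \code{N} becomes \code{"X"}.
#'
#' @param seq nucleotide string over \{A,C,G,T,N\} (or anything
#'   \code{\link{normalizeNucleotides}} accepts).
#' @param code genetic code from \code{\link{loadGeneticCode}}.
#' @return Amino-acid string of length \code{ceiling(nchar(seq)/3)}.
#' @examples
#' translateRaw("ATGTGAAAA")  # "M*K"
#' translateRaw("ATGA")       # "M!"
#' @export
translateRaw <- function(seq, code = loadGeneticCode(1L)) {
    s <- normalizeNucleotides(seq)
    n <- nchar(s)
    starts <- seq.int(1L, n, by = 3L)
    chunks <- substring(s, starts, pmin(starts + 2L, n))
    aa <- vapply(chunks, function(cd) {
        if (nchar(cd) < 3L) return("!")
        if (grepl("N", cd, fixed = TRUE)) return("X")
        unname(code[[cd]])
    }, "")
    paste0(aa, collapse = "")
}

#' Classify a codon site
#'
#' @param site 3-character cell over \{A,C,G,T,N,!,-\}.
#' @return One of \code{"gap"}, \code{"frameshift"}, \code{"full"}.
#'   Mixed cells (gap characters together with nucleotides or \code{"!"})
#'   are invalid and raise an error.
#' @export
classifySite <- function(site) {
    if (identical(site, "---")) return("gap")
    if (grepl("^[ACGTN]{3}$", site)) return("full")
    nBang <- nchar(gsub("[^!]", "", site))
    if (nchar(site) == 3L && nBang %in% 1:2 && !grepl("[^ACGTN!]", site))
        return("frameshift")
    stop(sprintf("invalid codon site '%s'", site))
}

## Amino-acid symbol of a site for the AA view ("!" / "*" / "-" / residue).
siteToAa <- function(site, code) {
    cls <- classifySite(site)
    if (cls == "gap") return("-")
    if (cls == "frameshift") return("!")
    if (grepl("N", site, fixed = TRUE)) return("X")
    unname(code[[site]])
}

#' Score the pairing of two codon sites
#'
#' The additive amino-acid-level site cost: each frameshifted side
#' contributes that row's frameshift score, each stop-codon side contributes
#' that row's stop score, a gap side contributes one gap extension
#' (opening surcharges are bookkept by the aligners, and terminal
#' exemptions are applied by callers that know the site's position), and
#' only when both sides are full non-stop codons is the substitution matrix
#' entry of their translations added.
#'
#' @param a,b codon sites (3-character cells).
#' @param setA,setB set labels of the two rows (\code{"reliable"} or
#'   \code{"lowpen"}).
#' @param scheme a \code{\link{codonScoringScheme}}.
#' @param code genetic code used to translate both sites.
#' @return numeric score contribution.
#' @examples
#' sc <- codonScoringScheme()
#' siteScore("TGG", "TGG", scheme = sc)          # 11
#' siteScore("A!G", "ATG", scheme = sc)          # -30
#' siteScore("TGA", "A!G", scheme = sc)          # -130
#' @export
siteScore <- function(a, b, setA = "reliable", setB = "reliable",
                      scheme = codonScoringScheme(),
                      code = loadGeneticCode(1L)) {
    clsA <- classifySite(a)
    clsB <- classifySite(b)
    if (clsA == "gap" && clsB == "gap")
        stop("invalid column: both sites are gaps")
    total <- 0
    aaA <- if (clsA == "full") siteToAa(a, code) else NA_character_
    aaB <- if (clsB == "full") siteToAa(b, code) else NA_character_
    if (clsA == "frameshift") total <- total + fsFor(scheme, setA)
    if (clsB == "frameshift") total <- total + fsFor(scheme, setB)
    if (identical(aaA, "*")) total <- total + stopFor(scheme, setA)
    if (identical(aaB, "*")) total <- total + stopFor(scheme, setB)
    if (clsA == "gap") total <- total + scheme@gapExt
    if (clsB == "gap") total <- total + scheme@gapExt
    if (clsA == "full" && clsB == "full" && aaA != "*" && aaB != "*")
        total <- total + scheme@matrix[aaA, aaB]
    as.numeric(unname(total))
}
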