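## Shared sequence utilities.

#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement GENETIC_CODE readDNAStringSet readAAStringSet
#'   writeXStringSet subseq pairwiseAlignment
#' @importFrom stats setNames
NULL

## IUPAC nucleotide code -> set of concrete bases. Subject-side N is
## deliberately NOT matched by any code (including code N): masked regions
## must never produce hits.
IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper around Biostrings; accepts IUPAC
#' degeneracy codes.
#'
#' @param x a single nucleotide string.
#' @return the reverse-complemented string.
#' @export
revComp <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    ch <- rev(strsplit(x, "", fixed = TRUE)[[1L]])
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp))
        stop("cannot complement character(s): ",
             paste(unique(ch[is.na(comp)]), collapse = ", "))
    paste(comp, collapse = "")
}

## split a string into a character vector of single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## codon table as a named character vector (stop = "*")
CODON_TABLE <- Biostrings::GENETIC_CODE

STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]

## split a CDS string into codons
.codons <- function(cds) {
    n <- nchar(cds)
    stopifnot(n %% 3L == 0L)
    substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code. The trailing stop codon (if any) is not included
#' in the protein. An internal stop does not truncate silently: translation
#' runs over the full frame with internal stops rendered as \code{*} and the
#' result is flagged.
#'
#' @param cds a single nucleotide string, length divisible by 3.
#' @return a list with \code{protein} (string) and \code{internalStop}
#'   (logical).
#' @examples
#' translateCds("ATGAAATAA")  # "MK"
#' @export
translateCds <- function(cds) {
    stopifnot(is.character(cds), length(cds) == 1L)
    cds <- toupper(cds)
    if (nchar(cds) == 0L) stop("empty CDS")
    if (nchar(cds) %% 3L != 0L)
        stop("CDS length ", nchar(cds), " is not a multiple of 3")
    aa <- CODON_TABLE[.codons(cds)]
    if (anyNA(aa)) {
        ## codons containing N or other ambiguity translate to X
        aa[is.na(aa)] <- "X"
    }
    n <- length(aa)
    trailingStop <- aa[n] == "*"
    if (trailingStop) aa <- aa[-n]
    internal <- any(aa == "*")
    list(protein = paste(aa, collapse = ""), internalStop = internal)
}

## deterministic integer sub-seed derivation, kept below 2^31
.subseed <- function(seed, k) {
    (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 11L
}
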