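## 3-kb promoter extraction and IUPAC degenerate scanning for
## secondary-cell-wall cis-elements.

#' Built-in catalog of secondary-cell-wall cis-elements
#'
#' The ten IUPAC consensus elements implicated in secondary cell wall
#' formation and xylem programmed cell death: SNBE, TERE, M46RE, ACI,
#' ACII, ACIII and the SMRE variants.
#'
#' @return named character vector, element name -> IUPAC consensus.
#' @export
cisElementCatalog <- function() {
    c(SNBE  = "WNNYBTNNNNNNNAMGNHW",
      TERE  = "CTTNAAAGCNA",
      M46RE = "RKTWGGTR",
      ACI   = "ACCTACC",
      ACII  = "ACCAACC",
      ACIII = "ACCTAAC",
      SMRE1 = "ACCAAAT",
      SMRE2 = "ACCAACT",
      SMRE3 = "ACCAAAC",
      SMRE5 = "ACCTAAT")
}

#' Read a cis-element catalog from TSV
#'
#' Two columns (name, consensus), header optional. Consensus strings are
#' validated against the IUPAC alphabet.
#'
#' @param path TSV file.
#' @return named character vector.
#' @export
readCisCatalog <- function(path) {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (tolower(tab[1L, 1L]) %in% c("name", "element"))
        tab <- tab[-1L, , drop = FALSE]
    cat <- setNames(toupper(tab[[2L]]), tab[[1L]])
    if (anyDuplicated(names(cat))) stop("duplicate element names")
    for (nm in names(cat)) iupacMatcher(cat[[nm]])  # validates
    cat
}

#' Compile an IUPAC consensus into a matcher
#'
#' The matcher accepts exactly the strings in the consensus expansion. N
#' in the subject sequence never matches any code (including consensus N):
#' masked regions cannot produce hits.
#'
#' @param consensus IUPAC string.
#' @return list: \code{sets} (per-position allowed base sets),
#'   \code{length}, \code{match(subjectChars, offset)} predicate is
#'   provided via \code{\link{scanElements}}.
#' @export
iupacMatcher <- function(consensus) {
    ch <- .chars(toupper(consensus))
    bad <- !ch %in% names(IUPAC_SETS)
    if (any(bad))
        stop("invalid IUPAC code(s): ", paste(unique(ch[bad]), collapse = ", "))
    list(sets = IUPAC_SETS[ch], length = length(ch))
}

## all 1-based start positions where the consensus matches, given the
## subject as a character vector. Vectorized over offsets per pattern
## position.
.scanOne <- function(chars, matcher) {
    L <- matcher$length
    n <- length(chars)
    if (n < L) return(integer())
    ok <- rep(TRUE, n - L + 1L)
    starts <- seq_len(n - L + 1L)
    for (k in seq_len(L)) {
        ok <- ok & chars[starts + (k - 1L)] %in% matcher$sets[[k]]
        if (!any(ok)) return(integer())
    }
    starts[ok]
}

#' Scan a promoter for cis-elements
#'
#' Every occurrence at every offset is reported (overlaps allowed). With
#' \code{strands = "both"}, minus-strand hits are matches of the reverse
#' complement of the consensus, reported at the hit's 5'-most promoter
#' coordinate.
#'
#' @param promoter nucleotide string (promoter reported 5' to 3' on the
#'   gene's coding strand).
#' @param catalog named character vector of IUPAC consensi (default the
#'   built-in SCW catalog).
#' @param strands \code{"both"} (default) or \code{"plus"}.
#' @param geneId optional id copied into the result.
#' @return data.frame: gene_id, element, start (1-based), strand, matched.
#' @examples
#' scanElements("TTACCTACCTT", c(ACI = "ACCTACC"))
#' @export
scanElements <- function(promoter, catalog = cisElementCatalog(),
                         strands = c("both", "plus"), geneId = NA_character_) {
    strands <- match.arg(strands)
    chars <- .chars(toupper(promoter))
    rows <- list()
    for (nm in names(catalog)) {
        fwd <- iupacMatcher(catalog[[nm]])
        pos <- .scanOne(chars, fwd)
        if (length(pos))
            rows[[paste0(nm, "+")]] <- data.frame(
                gene_id = geneId, element = nm, start = pos, strand = "+",
                matched = vapply(pos, function(p) paste(
                    chars[p:(p + fwd$length - 1L)], collapse = ""),
                    character(1L)),
                stringsAsFactors = FALSE)
        if (strands == "both") {
            rev <- iupacMatcher(revComp(catalog[[nm]]))
            pos <- .scanOne(chars, rev)
            if (length(pos))
                rows[[paste0(nm, "-")]] <- data.frame(
                    gene_id = geneId, element = nm, start = pos,
                    strand = "-",
                    matched = vapply(pos, function(p) paste(
                        chars[p:(p + rev$length - 1L)], collapse = ""),
                        character(1L)),
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(gene_id = character(), element = character(),
                          start = integer(), strand = character(),
                          matched = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$element, out$start, out$strand), , drop = FALSE]
}

#' Extract the promoter of a gene
#'
#' The window of \code{lengthBp} bp upstream of the transcription start
#' (the 5'-most transcript coordinate on the plus strand; the 3'-most on
#' the minus strand), reported 5' to 3' on the gene's coding strand.
#' Genes lacking an annotated 5'-UTR are anchored at the CDS start and
#' flagged. The window is truncated at the chromosome edge with a flag.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param assembly a \link[Biostrings]{DNAStringSet}.
#' @param lengthBp promoter length, default 3000.
#' @return list: \code{sequence}, \code{truncated}, \code{anchor}
#'   (\code{"utr5"} or \code{"cds"}).
#' @export
extractPromoter <- function(gene, assembly, lengthBp = 3000L) {
    hasUtr5 <- nrow(utr5Segments(gene)) > 0L
    anchor <- if (hasUtr5) "utr5" else "cds"
    seg <- if (hasUtr5) exonSegments(gene) else cdsSegments(gene)
    if (nrow(seg) == 0L) stop("no anchor determinable for ", geneId(gene))
    chromSeq <- as.character(assembly[[geneChrom(gene)]])
    if (is.null(chromSeq))
        stop("chromosome ", geneChrom(gene), " not in assembly")
    clen <- nchar(chromSeq)
    if (geneStrand(gene) == "+") {
        tss <- min(seg[, 1L])            # 0-based start of transcript
        from <- max(0L, tss - lengthBp)
        truncated <- from > tss - lengthBp
        s <- substring(chromSeq, from + 1L, tss)
    } else {
        tss <- max(seg[, 2L])            # 0-based end (exclusive)
        to <- min(clen, tss + lengthBp)
        truncated <- to < tss + lengthBp
        s <- revComp(substring(chromSeq, tss + 1L, to))
    }
    list(sequence = s, truncated = truncated, anchor = anchor)
}

#' Gene-by-element presence/count matrix
#'
#' @param hits data.frame of rbound \code{\link{scanElements}} results.
#' @param genes character vector of all gene ids (all-zero rows are
#'   retained).
#' @param catalog element catalog (column universe).
#' @return integer matrix of hit counts, genes x elements; presence is
#'   count >= 1.
#' @export
presenceMatrix <- function(hits, genes, catalog = cisElementCatalog()) {
    m <- matrix(0L, length(genes), length(catalog),
                dimnames = list(genes, names(catalog)))
    if (nrow(hits)) {
        tab <- table(factor(hits$gene_id, levels = genes),
                     factor(hits$element, levels = names(catalog)))
        m[] <- as.integer(tab)
    }
    m
}
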