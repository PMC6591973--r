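#' @import methods
#' @importFrom IRanges IRanges start end width reduce findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Gene model for one annotated transcript
#'
#' Holds the selected (primary) transcript of one gene: its chromosome,
#' strand, exon chain, CDS segments and UTR segments. All coordinates are
#' stored 0-based half-open internally; GFF3 readers/writers convert at the
#' boundary. Exons must be sorted by genomic start and non-overlapping, and
#' every CDS segment must fall inside an exon.
#'
#' @slot geneId gene identifier.
#' @slot txId identifier of the selected transcript.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons,cds,utr5,utr3 \link[IRanges]{IRanges} of 0-based half-open
#'   segments (stored as start = 0-based start + 1 internally by IRanges
#'   convention; use the accessors, which hand back 0-based half-open
#'   matrices).
#' @slot primaryRule how the transcript was chosen: \code{"suffix.1"},
#'   \code{"longest-cds"} or \code{"only"}.
#' @export
setClass("GeneModel", representation(
    geneId = "character",
    txId = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges",
    utr5 = "IRanges",
    utr3 = "IRanges",
    primaryRule = "character"
))

setValidity("GeneModel", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "at least one exon required")
    if (length(ex) > 1L) {
        if (is.unsorted(start(ex)))
            msg <- c(msg, "exons must be sorted by genomic start")
        if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
    }
    if (length(object@cds) > 0L) {
        hit <- findOverlaps(object@cds, ex, type = "within")
        if (length(unique(queryHits(hit))) < length(object@cds))
            msg <- c(msg, "every CDS segment must lie within an exon")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneId,txId,chrom,strand identifiers and location.
#' @param exons,cds,utr5,utr3 two-column matrices (or 2-vectors) of 0-based
#'   half-open \code{[start, end)} segments.
#' @param primaryRule provenance of the transcript choice.
#' @return a \linkS4class{GeneModel}.
#' @examples
#' g <- GeneModel("g1", chrom = "chr1", strand = "+",
#'                exons = rbind(c(0, 100), c(200, 300)),
#'                cds = rbind(c(10, 100), c(200, 250)))
#' nExons(g)
#' @export
GeneModel <- function(geneId, txId = paste0(geneId, ".1"), chrom, strand,
                      exons, cds = NULL, utr5 = NULL, utr3 = NULL,
                      primaryRule = "only") {
    new("GeneModel", geneId = geneId, txId = txId, chrom = chrom,
        strand = strand,
        exons = .seg2ir(exons), cds = .seg2ir(cds),
        utr5 = .seg2ir(utr5), utr3 = .seg2ir(utr3),
        primaryRule = primaryRule)
}

## 0-based half-open [start,end) matrix -> IRanges (1-based closed inside)
.seg2ir <- function(m) {
    if (is.null(m) || (is.matrix(m) && nrow(m) == 0L)) return(IRanges())
    if (!is.matrix(m)) m <- matrix(m, ncol = 2L, byrow = TRUE)
    stopifnot(ncol(m) == 2L, all(m[, 1L] < m[, 2L]), all(m[, 1L] >= 0))
    m <- m[order(m[, 1L]), , drop = FALSE]
    IRanges(start = m[, 1L] + 1L, end = m[, 2L])
}

.ir2seg <- function(ir) {
    cbind(start = start(ir) - 1L, end = end(ir))
}

#' @describeIn GeneModel gene identifier
#' @param x a GeneModel
#' @export
geneId <- function(x) x@geneId

#' @describeIn GeneModel chromosome name
#' @export
geneChrom <- function(x) x@chrom

#' @describeIn GeneModel strand
#' @export
geneStrand <- function(x) x@strand

#' @describeIn GeneModel exon segments, 0-based half-open matrix
#' @export
exonSegments <- function(x) .ir2seg(x@exons)

#' @describeIn GeneModel CDS segments, 0-based half-open matrix
#' @export
cdsSegments <- function(x) .ir2seg(x@cds)

#' @describeIn GeneModel 5'-UTR segments, 0-based half-open matrix
#' @export
utr5Segments <- function(x) .ir2seg(x@utr5)

#' @describeIn GeneModel 3'-UTR segments, 0-based half-open matrix
#' @export
utr3Segments <- function(x) .ir2seg(x@utr3)

#' @describeIn GeneModel number of exons
#' @export
nExons <- function(x) length(x@exons)

#' @describeIn GeneModel gene span as c(start, end), 0-based half-open
#' @export
geneSpan <- function(x) {
    c(start = min(start(x@exons)) - 1L, end = max(end(x@exons)))
}

setMethod("show", "GeneModel", function(object) {
    sp <- geneSpan(object)
    cat("GeneModel", object@geneId, "(", object@txId, ")\n")
    cat("  ", object@chrom, ":", sp[1L], "-", sp[2L], " (", object@strand,
        "), ", length(object@exons), " exon(s), ",
        sum(width(object@cds)), " bp CDS\n", sep = "")
})

#' Nei-Gojobori (1986) Ka/Ks result
#'
#' Site counts, difference counts, proportions and Jukes-Cantor-corrected
#' rates for one pair of coding sequences. \code{S + N} always equals three
#' times the number of compared (ungapped, N-free) codons. The estimate is
#' flagged saturated when ps or pn reaches 3/4, where the Jukes-Cantor
#' correction diverges.
#'
#' @slot S,N synonymous / nonsynonymous sites (fractional, averaged over the
#'   two sequences).
#' @slot sd,nd synonymous / nonsynonymous differences (pathway-averaged).
#' @slot ps,pn proportions of differences per site.
#' @slot Ks,Ka Jukes-Cantor corrected rates (NA when undefined).
#' @slot ratio Ka/Ks (NA when Ks is 0 or the pair is saturated).
#' @slot saturated logical flag.
#' @slot codons number of codon pairs compared.
#' @export
setClass("KaKsResult", representation(
    S = "numeric", N = "numeric", sd = "numeric", nd = "numeric",
    ps = "numeric", pn = "numeric", Ks = "numeric", Ka = "numeric",
    ratio = "numeric", saturated = "logical", codons = "integer"
))

setValidity("KaKsResult", function(object) {
    if (object@ps < 0 || object@ps > 1 || object@pn < 0 || object@pn > 1)
        return("ps and pn must lie in [0, 1]")
    TRUE
})

setMethod("show", "KaKsResult", function(object) {
    cat("KaKsResult over", object@codons, "codon pairs\n")
    cat(sprintf("  S = %.4f  N = %.4f  sd = %.4f  nd = %.4f\n",
                object@S, object@N, object@sd, object@nd))
    cat(sprintf("  Ks = %s  Ka = %s  Ka/Ks = %s%s\n",
                format(object@Ks, digits = 4), format(object@Ka, digits = 4),
                format(object@ratio, digits = 4),
                if (object@saturated) "  [saturated]" else ""))
})
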