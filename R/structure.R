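## Exon/intron arrangement statistics and structural flags.

#' Per-gene exon/intron structure report
#'
#' Lengths are in bp on the selected primary transcript; intron i spans the
#' gap between consecutive exons in genomic order. A gene is intronless iff
#' it has a single exon. UTR presence is read from the annotation.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return one-row data.frame: gene_id, n_exons, n_introns, exon_lengths,
#'   intron_lengths (comma-joined bp), has_utr5, has_utr3, intronless.
#' @export
structureReport <- function(gene) {
    ex <- exonSegments(gene)
    exLen <- ex[, 2L] - ex[, 1L]
    inLen <- if (nrow(ex) > 1L)
        ex[-1L, 1L] - ex[-nrow(ex), 2L] else integer()
    if (any(inLen < 0)) stop("overlapping exons in ", geneId(gene))
    data.frame(gene_id = geneId(gene),
               n_exons = nrow(ex),
               n_introns = length(inLen),
               exon_lengths = paste(exLen, collapse = ","),
               intron_lengths = paste(inLen, collapse = ","),
               has_utr5 = nrow(utr5Segments(gene)) > 0L,
               has_utr3 = nrow(utr3Segments(gene)) > 0L,
               intronless = nrow(ex) == 1L,
               stringsAsFactors = FALSE)
}

#' Family-level structure summary
#'
#' @param reports data.frame of rbound \code{\link{structureReport}} rows.
#' @param categories optional named character vector gene_id -> category;
#'   when given, per-category exon-count ranges are included.
#' @return list: n_genes, n_intronless, n_lacking_utr5, exon_range, and
#'   (optionally) per_category exon ranges.
#' @export
familyStructureSummary <- function(reports, categories = NULL) {
    if (is.null(reports) || nrow(reports) == 0L)
        return(list(n_genes = 0L, n_intronless = 0L, n_lacking_utr5 = 0L,
                    exon_range = c(NA_integer_, NA_integer_)))
    out <- list(n_genes = nrow(reports),
                n_intronless = sum(reports$intronless),
                n_lacking_utr5 = sum(!reports$has_utr5),
                exon_range = range(reports$n_exons))
    if (!is.null(categories)) {
        cat <- categories[reports$gene_id]
        out$per_category <- lapply(split(reports$n_exons, cat), range)
    }
    out
}
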