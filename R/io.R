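## Readers/writers for FASTA and GFF3, and CDS extraction.

#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased on load and restricted to the A, C, G, T, N
#' alphabet. Record IDs are the first whitespace-delimited token of the
#' header and must be unique.
#'
#' @param path FASTA file (plain or gzip).
#' @param ambiguity what to do with IUPAC ambiguity characters other than N:
#'   \code{"error"} (default) or \code{"mask"} (map to N).
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
readGenome <- function(path, ambiguity = c("error", "mask")) {
    ambiguity <- match.arg(ambiguity)
    if (!file.exists(path)) stop("no such file: ", path)
    dss <- readDNAStringSet(path)
    if (length(dss) == 0L) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", names(dss))
    if (anyDuplicated(ids))
        stop("duplicate FASTA ID(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(dss) <- ids
    ## uppercase + alphabet normalization via character round-trip
    ch <- toupper(as.character(dss))
    bad <- grepl("[^ACGTN]", ch)
    if (any(bad)) {
        if (ambiguity == "error")
            stop("non-ACGTN characters in sequence(s): ",
                 paste(ids[bad], collapse = ", "),
                 " (use ambiguity = \"mask\" to map them to N)")
        ch <- gsub("[^ACGTN]", "N", ch)
    }
    if (any(nchar(ch) == 0L)) stop("empty sequence record in ", path)
    DNAStringSet(setNames(ch, ids))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return a named \link[Biostrings]{AAStringSet}, IDs = first header token.
#' @export
readProteins <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ass <- readAAStringSet(path)
    if (length(ass) == 0L) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", names(ass))
    if (anyDuplicated(ids))
        stop("duplicate FASTA ID(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(ass) <- ids
    ass
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features. GFF3
#' coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. One \linkS4class{GeneModel} is returned per gene,
#' for its primary transcript: the mRNA whose ID ends \code{".1"}, else the
#' mRNA with the longest total CDS. Models referencing chromosomes absent
#' from \code{assembly} are rejected.
#'
#' @param path GFF3 file.
#' @param assembly optional \link[Biostrings]{DNAStringSet}; when supplied,
#'   chromosome names and bounds are validated against it.
#' @return named list of \linkS4class{GeneModel} objects.
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges seqnames strand start end mcols
#' @export
readGeneModels <- function(path, assembly = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    typ <- as.character(md$type)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else
        rep(NA_character_, length(gr))
    parents <- if ("Parent" %in% names(md))
        vapply(md$Parent, function(p)
            if (length(p)) as.character(p)[1L] else NA_character_,
            character(1L))
    else rep(NA_character_, length(gr))

    genes <- which(typ == "gene")
    if (!length(genes)) stop("no gene features in ", path)
    out <- list()
    for (gi in genes) {
        gid <- ids[gi]
        mrnas <- which(typ == "mRNA" & parents == gid)
        if (!length(mrnas)) next
        cdsLenOf <- function(mi) {
            seg <- typ == "CDS" & parents == ids[mi]
            sum(end(gr)[seg] - start(gr)[seg] + 1L)
        }
        dotted <- which(endsWith(ids[mrnas], ".1"))
        if (length(dotted) == 1L) {
            mi <- mrnas[dotted]
            rule <- if (length(mrnas) == 1L) "only" else "suffix.1"
        } else {
            lens <- vapply(mrnas, cdsLenOf, numeric(1L))
            mi <- mrnas[which.max(lens)]
            rule <- if (length(mrnas) == 1L) "only" else "longest-cds"
        }
        tid <- ids[mi]
        pick <- function(what) {
            sel <- typ == what & parents == tid
            if (!any(sel)) return(NULL)
            cbind(start(gr)[sel] - 1L, end(gr)[sel])
        }
        chrom <- as.character(seqnames(gr))[gi]
        std <- as.character(strand(gr))[mi]
        if (!std %in% c("+", "-"))
            stop("gene ", gid, ": mRNA strand missing")
        gspan <- c(start(gr)[gi] - 1L, end(gr)[gi])
        cdsSeg <- pick("CDS")
        if (!is.null(cdsSeg) &&
            (min(cdsSeg[, 1L]) < gspan[1L] || max(cdsSeg[, 2L]) > gspan[2L]))
            stop("gene ", gid, ": CDS segment outside the declared gene span")
        if (!is.null(assembly)) {
            if (!chrom %in% names(assembly))
                stop("gene ", gid, ": unknown chromosome ", chrom)
            if (gspan[2L] > nchar(as.character(assembly[[chrom]])))
                stop("gene ", gid, ": span exceeds length of ", chrom)
        }
        exSeg <- pick("exon")
        if (is.null(exSeg)) exSeg <- if (is.null(cdsSeg)) gspan else cdsSeg
        out[[gid]] <- GeneModel(gid, txId = tid, chrom = chrom, strand = std,
                                exons = exSeg, cds = cdsSeg,
                                utr5 = pick("five_prime_UTR"),
                                utr3 = pick("three_prime_UTR"),
                                primaryRule = rule)
    }
    out
}

#' Write gene models to GFF3
#'
#' Inverse of \code{\link{readGeneModels}}: emits gene, mRNA, exon, CDS and
#' UTR features with 1-based inclusive coordinates.
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @param path output file.
#' @export
writeGeneModels <- function(genes, path) {
    lines <- "##gff-version 3"
    for (g in genes) {
        sp <- geneSpan(g)
        row <- function(type, s, e, attr)
            paste(geneChrom(g), "aspfam", type, s + 1L, e, ".",
                  geneStrand(g), ".", attr, sep = "\t")
        lines <- c(lines,
                   row("gene", sp[1L], sp[2L], paste0("ID=", geneId(g))),
                   row("mRNA", sp[1L], sp[2L],
                       paste0("ID=", g@txId, ";Parent=", geneId(g))))
        emit <- function(type, seg) {
            if (nrow(seg) == 0L) return(character())
            vapply(seq_len(nrow(seg)), function(i)
                row(type, seg[i, 1L], seg[i, 2L],
                    paste0("Parent=", g@txId)), character(1L))
        }
        lines <- c(lines,
                   emit("exon", exonSegments(g)),
                   emit("CDS", cdsSegments(g)),
                   emit("five_prime_UTR", utr5Segments(g)),
                   emit("three_prime_UTR", utr3Segments(g)))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Extract the coding sequence of a gene
#'
#' CDS segments are concatenated in transcription order; minus-strand genes
#' are reverse-complemented.
#'
#' @param gene a \linkS4class{GeneModel} with CDS segments.
#' @param assembly a \link[Biostrings]{DNAStringSet}.
#' @return the CDS as a single character string, 5' to 3' on the coding
#'   strand.
#' @export
extractCds <- function(gene, assembly) {
    seg <- cdsSegments(gene)
    if (nrow(seg) == 0L) stop("gene ", geneId(gene), " has no CDS segments")
    chromSeq <- as.character(assembly[[geneChrom(gene)]])
    if (is.null(chromSeq))
        stop("chromosome ", geneChrom(gene), " not in assembly")
    if (max(seg[, 2L]) > nchar(chromSeq))
        stop("CDS segment exceeds bounds of ", geneChrom(gene))
    pieces <- substring(chromSeq, seg[, 1L] + 1L, seg[, 2L])
    cds <- paste(pieces, collapse = "")
    if (geneStrand(gene) == "-") cds <- revComp(cds)
    cds
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param nuc nucleotide (TRUE) or protein (FALSE).
#' @export
writeFasta <- function(seqs, path, nuc = TRUE) {
    set <- if (nuc) DNAStringSet(seqs) else AAStringSet(seqs)
    writeXStringSet(set, path)
    invisible(path)
}
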