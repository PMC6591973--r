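## Pipeline orchestration: run every stage over one set of inputs and
## consolidate the results into machine-readable summaries.

#' Run the full family-characterization pipeline
#'
#' Reads a genome + annotation (or takes an in-memory simulation), derives
#' CDS and proteins where not supplied, then runs family identification,
#' gene-structure statistics, duplication/Ka-Ks/dating analysis, promoter
#' cis-element scanning, sequon analysis, expression filtering/clustering
#' and an NJ phylogeny. All stage tables are written under \code{outDir}
#' and summarized by \code{\link{consolidatedReport}}.
#'
#' @param genome path to a genome FASTA, or a DNAStringSet.
#' @param gff path to a GFF3 annotation, or a list of GeneModel.
#' @param cds,proteins optional named vectors (or FASTA paths); derived
#'   from the genome when absent.
#' @param blocks optional duplication-block table: path to TSV (1-based on
#'   disk) or a 0-based data.frame.
#' @param expression optional expression matrix: TSV path or matrix.
#' @param outDir output directory.
#' @param promoterLength,tandemWindow,lambda,efpThreshold,strands
#'   stage parameters (defaults: 3000 bp, 50 kb, 9.1e-9, 1000, both).
#' @param tissue tissue used for the high-expression selection.
#' @param nBootstrap bootstrap replicates for the NJ tree (the reference
#'   analysis scale is 1000; a smaller default keeps interactive runs
#'   quick).
#' @param seed RNG seed (bootstrap).
#' @return (invisibly) the consolidated report list.
#' @export
runPipeline <- function(genome, gff, cds = NULL, proteins = NULL,
                        blocks = NULL, expression = NULL,
                        outDir = ".", promoterLength = 3000L,
                        tandemWindow = 50000L,
                        lambda = POPULUS_CLOCK_RATE,
                        efpThreshold = 1000, strands = "both",
                        tissue = "XY", nBootstrap = 100L, seed = 1L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    isPath <- function(x) is.character(x) && length(x) == 1L &&
        is.null(names(x)) && file.exists(x)
    if (isPath(genome)) genome <- readGenome(genome)
    if (isPath(gff)) gff <- readGeneModels(gff, genome)
    if (isPath(cds)) cds <- as.character(readGenome(cds))
    if (isPath(proteins)) proteins <- as.character(readProteins(proteins))
    if (is.null(cds))
        cds <- vapply(gff, extractCds, character(1L), assembly = genome)
    if (is.null(proteins))
        proteins <- vapply(cds, function(x) translateCds(x)$protein,
                           character(1L))
    if (is.null(names(proteins))) names(proteins) <- names(cds)
    if (isPath(blocks)) blocks <- readBlockTable(blocks)
    if (isPath(expression)) expression <- readExpressionMatrix(expression)

    tsv <- function(x, f) {
        write.table(x, file.path(outDir, f), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        x
    }

    ## family identification
    members <- tsv(identifyFamily(proteins, cds = cds), "members.tsv")
    fam <- members$gene_id[members$domain_complete]

    ## gene structure
    structure <- tsv(do.call(rbind, lapply(gff[fam], structureReport)),
                     "structure.tsv")
    structSummary <- familyStructureSummary(
        structure, setNames(members$category, members$gene_id))

    ## duplication + Ka/Ks + dating
    spans <- do.call(rbind, lapply(gff[fam], function(g) {
        sp <- geneSpan(g)
        data.frame(gene_id = geneId(g), chrom = geneChrom(g),
                   start = sp[1L], end = sp[2L], stringsAsFactors = FALSE)
    }))
    dup <- duplicationAnalysis(spans, cds, blocks, windowBp = tandemWindow,
                               lambda = lambda)
    tsv(dup$pairs, "duplication_pairs.tsv")

    ## promoter cis-element scan
    hits <- do.call(rbind, lapply(gff[fam], function(g) {
        pr <- extractPromoter(g, genome, lengthBp = promoterLength)
        scanElements(pr$sequence, strands = strands, geneId = geneId(g))
    }))
    if (is.null(hits))
        hits <- scanElements("", geneId = NA_character_)
    tsv(hits, "cis_hits.tsv")
    pm <- presenceMatrix(hits, fam)
    tsv(data.frame(gene_id = rownames(pm), pm, check.names = FALSE),
        "cis_presence.tsv")

    ## glycosylation
    sequons <- do.call(rbind, lapply(fam, function(id) {
        s <- scanNSequons(proteins[[id]])
        if (nrow(s)) cbind(gene_id = id, s) else NULL
    }))
    if (is.null(sequons))
        sequons <- data.frame(gene_id = character(), position = integer(),
                              triplet = character(), context = character())
    tsv(sequons, "sequons.tsv")
    catOf <- setNames(members$category, members$gene_id)
    conserved <- vapply(fam, function(id)
        conservedSequonNearAnchor(proteins[[id]], catOf[[id]])$status,
        character(1L))

    ## expression
    exprOut <- NULL
    if (!is.null(expression)) {
        sel <- selectHighTissue(expression, tissue,
                                threshold = efpThreshold,
                                pairs = dup$pairs)
        cl <- log2HeatmapCluster(expression)
        exprOut <- list(selected = sel,
                        rowOrder = rownames(expression)[cl$order])
        tsv(data.frame(gene_id = sel), "selection.tsv")
    }

    ## phylogeny (family members only)
    tree <- NULL
    if (length(fam) >= 3L) {
        aln <- progressiveAlign(proteins[fam])
        tree <- bootstrapSupport(aln, nReps = nBootstrap, seed = seed)
        writeTree(tree, file.path(outDir, "family_nj.nwk"))
    }

    report <- consolidatedReport(
        members = members, structureSummary = structSummary,
        duplication = dup, presence = pm, sequons = sequons,
        conservedSequon = conserved, expression = exprOut)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}

#' Consolidate stage outputs into one machine-readable summary
#'
#' Every field is traceable to a stage table; nothing is recomputed.
#'
#' @param members family-member table.
#' @param structureSummary output of \code{\link{familyStructureSummary}}.
#' @param duplication output of \code{\link{duplicationAnalysis}}.
#' @param presence gene x element count matrix.
#' @param sequons sequon table.
#' @param conservedSequon named status vector.
#' @param expression list with \code{selected} ids, or NULL.
#' @return a nested list ready for JSON serialization.
#' @export
consolidatedReport <- function(members, structureSummary = NULL,
                               duplication = NULL, presence = NULL,
                               sequons = NULL, conservedSequon = NULL,
                               expression = NULL) {
    counts <- table(factor(members$category[members$domain_complete],
                           levels = c("A", "B", "C")))
    rep <- list(
        n_candidates = nrow(members),
        n_family = sum(members$domain_complete),
        category_counts = as.list(counts)
    )
    if (!is.null(structureSummary)) rep$structure <- structureSummary
    if (!is.null(duplication)) {
        rep$duplication <- list(
            n_tandem_clusters = length(duplication$tandemClusters),
            tandem_clusters = duplication$tandemClusters,
            n_pairs = nrow(duplication$pairs),
            pairs = duplication$pairs)
    }
    if (!is.null(presence))
        rep$cis_presence_per_element = as.list(colSums(presence >= 1))
    if (!is.null(sequons))
        rep$n_sequons = nrow(sequons)
    if (!is.null(conservedSequon))
        rep$conserved_sequon_status = as.list(table(conservedSequon))
    if (!is.null(expression))
        rep$expression = list(selected = expression$selected)
    rep
}
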