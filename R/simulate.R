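## Synthetic genome generator with planted ground truth. Emits the same
## FASTA/GFF3/TSV dialects the real-data path consumes, so every pipeline
## stage can be validated against known planted events.

AA20 <- names(RESIDUE_MASS)
## background residues exclude C and D so that catalytic D[TS]G motifs,
## PSI cysteine counts and nucellin motifs occur only where planted
BACKGROUND_AA <- setdiff(AA20, c("C", "D"))

## synonymous codon sets per amino acid
.codonsByAa <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) tab <<- split(names(CODON_TABLE), CODON_TABLE)
        tab
    }
})

.randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
.randAA <- function(n) paste(sample(BACKGROUND_AA, n, replace = TRUE),
                             collapse = "")

## back-translate a protein with uniformly chosen synonymous codons
.backTranslate <- function(protein) {
    tab <- .codonsByAa()
    cods <- vapply(.chars(protein), function(a) {
        opts <- tab[[a]]
        opts[sample.int(length(opts), 1L)]
    }, character(1L))
    paste(cods, collapse = "")
}

#' Default simulation configuration
#'
#' The default study conditions: a 2-chromosome assembly carrying 12
#' family genes in a 2/2/8 A/B/C category mix, one tandem cluster of 3
#' with 30-kb gaps, two segmentally duplicated pairs at controlled
#' synonymous/nonsynonymous divergence inside emitted duplication blocks,
#' two planted cis-elements per 3-kb promoter, and a 6-tissue expression
#' matrix in which xylem-specific genes sit at archetype 1500 against
#' sub-500 background with Gaussian noise (sd 50).
#'
#' @param seed RNG seed.
#' @param chromosomeLengthBp length of each chromosome.
#' @param categoryMix named counts for categories A, B, C.
#' @param tandemSize,tandemGapBp tandem cluster geometry.
#' @param segmentalSyn,segmentalNonsyn per-pair target substitution counts.
#' @param xylemArchetype,offArchetypeMax,noiseSd expression parameters.
#' @param tissues tissue labels (XY = developing xylem).
#' @param promoterLengthBp promoter window.
#' @return a SimulationConfig list.
#' @export
simulationConfig <- function(seed = 1L,
                             chromosomeLengthBp = 450000L,
                             categoryMix = c(A = 2L, B = 2L, C = 8L),
                             tandemSize = 3L, tandemGapBp = 30000L,
                             segmentalSyn = c(12L, 25L),
                             segmentalNonsyn = c(3L, 6L),
                             xylemArchetype = 1500,
                             offArchetypeMax = 500,
                             noiseSd = 50,
                             tissues = c("ML", "YL", "RT", "FC", "MC", "XY"),
                             promoterLengthBp = 3000L) {
    cfg <- list(seed = as.integer(seed), nChromosomes = 2L,
                chromosomeLengthBp = as.integer(chromosomeLengthBp),
                categoryMix = categoryMix, tandemSize = as.integer(tandemSize),
                tandemGapBp = as.integer(tandemGapBp),
                segmentalSyn = as.integer(segmentalSyn),
                segmentalNonsyn = as.integer(segmentalNonsyn),
                xylemArchetype = xylemArchetype,
                offArchetypeMax = offArchetypeMax, noiseSd = noiseSd,
                tissues = tissues,
                promoterLengthBp = as.integer(promoterLengthBp))
    nSeg <- length(cfg$segmentalSyn)
    if (cfg$categoryMix[["C"]] < 2L * nSeg + cfg$tandemSize - 1L)
        stop("category-C count too small for the requested segmental ",
             "pairs and tandem cluster")
    class(cfg) <- "SimulationConfig"
    cfg
}

## design one family protein of the requested category; returns the
## protein plus the regions that must be protected from mutation (codon
## indexes) and the planted anchor positions
.designProtein <- function(category) {
    nterm <- paste0("M", .randAA(39L))
    if (category == "A") {
        insert <- .chars(.randAA(100L))
        insert[sample.int(100L, 8L)] <- "C"
        body <- paste0("DTG", .randAA(60L), paste(insert, collapse = ""),
                       .randAA(40L), "DSG")
    } else if (category == "B") {
        body <- paste0("DTG", .randAA(30L), "QCDYE", .randAA(40L),
                       "NAS", .randAA(15L), "GCGYDQ", .randAA(50L), "DSG")
    } else {
        body <- paste0("DTG", .randAA(150L), "DSG")
    }
    protein <- paste0(nterm, body, .randAA(60L))
    ## protect everything from the first Asp through the second motif
    d1 <- 41L
    d2 <- d1 + nchar(body) - 3L
    list(protein = protein, protect = seq(d1, d2 + 2L))
}

#' Plant degenerate cis-element instances in a synthetic promoter
#'
#' Background is uniform A/C/G/T; each instance sequence is drawn
#' uniformly from the consensus expansion (and reverse-complemented for
#' minus-strand instances). Instances must not overlap.
#'
#' @param lengthBp promoter length.
#' @param instances data.frame with columns element, offset (0-based),
#'   strand.
#' @param catalog element catalog.
#' @return list: \code{sequence}, \code{truth} (data.frame element, start
#'   1-based, strand, matched).
#' @export
plantCisElements <- function(lengthBp, instances,
                             catalog = cisElementCatalog()) {
    seqc <- .chars(.randBases(lengthBp))
    truth <- list()
    if (!is.null(instances) && nrow(instances)) {
        iv <- cbind(instances$offset,
                    instances$offset + nchar(catalog[instances$element]))
        o <- order(iv[, 1L])
        if (any(iv[o, 1L][-1L] < iv[o, 2L][-nrow(iv)]))
            stop("planted instances overlap")
        if (any(iv[, 2L] > lengthBp))
            stop("planted instance extends beyond the promoter")
        for (i in seq_len(nrow(instances))) {
            el <- instances$element[i]
            cons <- catalog[[el]]
            draw <- paste(vapply(IUPAC_SETS[.chars(cons)], function(s)
                s[sample.int(length(s), 1L)], character(1L)), collapse = "")
            piece <- if (instances$strand[i] == "-") revComp(draw) else draw
            at <- instances$offset[i]
            seqc[(at + 1L):(at + nchar(piece))] <- .chars(piece)
            truth[[i]] <- data.frame(element = el, start = at + 1L,
                                     strand = instances$strand[i],
                                     matched = piece,
                                     stringsAsFactors = FALSE)
        }
    }
    list(sequence = paste(seqc, collapse = ""),
         truth = if (length(truth)) do.call(rbind, truth) else
             data.frame(element = character(), start = integer(),
                        strand = character(), matched = character(),
                        stringsAsFactors = FALSE))
}

#' Evolve a coding sequence by controlled substitution counts
#'
#' Applies exactly \code{nSyn} synonymous and \code{nNonsyn}
#' nonsynonymous single-nucleotide substitutions, each in a distinct
#' codon; a synonymous change preserves the amino acid, a nonsynonymous
#' one changes it, and neither may create a stop codon.
#'
#' @param cds coding sequence (no internal stops; trailing stop allowed).
#' @param nSyn,nNonsyn requested substitution counts.
#' @param protect codon indexes that must not be touched.
#' @param seed optional RNG seed for a reproducible mutation set.
#' @return list: \code{cds} (mutated), \code{synPositions},
#'   \code{nonsynPositions} (codon indexes).
#' @export
evolveCodonPair <- function(cds, nSyn, nNonsyn = 0L, protect = integer(),
                            seed = NULL) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    cods <- .codons(toupper(cds))
    hasStopTail <- cods[length(cods)] %in% STOP_CODONS
    body <- if (hasStopTail) cods[-length(cods)] else cods
    bases <- c("A", "C", "G", "T")
    altsOf <- function(cod, wantSyn) {
        ch <- .chars(cod); aa <- CODON_TABLE[[cod]]
        out <- character()
        for (k in 1:3) for (b in setdiff(bases, ch[k])) {
            mut <- ch; mut[k] <- b
            mc <- paste(mut, collapse = "")
            if (mc %in% STOP_CODONS) next
            if (wantSyn == (CODON_TABLE[[mc]] == aa)) out <- c(out, mc)
        }
        out
    }
    eligible <- function(wantSyn)
        setdiff(which(vapply(body, function(cod)
            length(altsOf(cod, wantSyn)) > 0L, logical(1L))), protect)
    synPool <- eligible(TRUE)
    if (length(synPool) < nSyn)
        stop("not enough codons for ", nSyn, " synonymous substitutions")
    synAt <- sort(sample(synPool, nSyn))
    nonPool <- setdiff(eligible(FALSE), synAt)
    if (length(nonPool) < nNonsyn)
        stop("not enough codons for ", nNonsyn,
             " nonsynonymous substitutions")
    nonAt <- if (nNonsyn > 0L) sort(sample(nonPool, nNonsyn)) else integer()
    for (i in synAt) {
        a <- altsOf(body[i], TRUE); body[i] <- a[sample.int(length(a), 1L)]
    }
    for (i in nonAt) {
        a <- altsOf(body[i], FALSE); body[i] <- a[sample.int(length(a), 1L)]
    }
    out <- paste(c(body, if (hasStopTail) cods[length(cods)]),
                 collapse = "")
    list(cds = out, synPositions = synAt, nonsynPositions = nonAt)
}

## transcript-space gene layout -> genomic region (plus orientation),
## then optional strand flip. Returns region sequence and 0-based segment
## matrices relative to the region start.
.buildGeneRegion <- function(cdsSeq, utr5Len, utr3Len, nEx, strand) {
    tx <- paste0(.randBases(utr5Len), cdsSeq, .randBases(utr3Len))
    txLen <- nchar(tx)
    cuts <- if (nEx > 1L)
        sort(sample(seq(30L, txLen - 30L), nEx - 1L)) else integer()
    exTx <- cbind(c(0L, cuts), c(cuts, txLen))   # tx-space exon intervals
    intronLens <- if (nEx > 1L)
        sample(150:400, nEx - 1L, replace = TRUE) else integer()
    gStarts <- integer(nEx)
    region <- character(0L)
    offset <- 0L
    exG <- matrix(0L, nEx, 2L)
    for (i in seq_len(nEx)) {
        piece <- substring(tx, exTx[i, 1L] + 1L, exTx[i, 2L])
        exG[i, ] <- c(offset, offset + nchar(piece))
        region <- c(region, piece)
        offset <- offset + nchar(piece)
        if (i < nEx) {
            region <- c(region, .randBases(intronLens[i]))
            offset <- offset + intronLens[i]
        }
    }
    regionSeq <- paste(region, collapse = "")
    R <- nchar(regionSeq)
    ## map a tx-space interval to genomic chunks through the exon layout
    mapTx <- function(s, e) {
        out <- NULL
        for (i in seq_len(nEx)) {
            os <- max(s, exTx[i, 1L]); oe <- min(e, exTx[i, 2L])
            if (os < oe)
                out <- rbind(out, c(exG[i, 1L] + (os - exTx[i, 1L]),
                                    exG[i, 1L] + (oe - exTx[i, 1L])))
        }
        out
    }
    segs <- list(exons = exG,
                 cds = mapTx(utr5Len, utr5Len + nchar(cdsSeq)),
                 utr5 = if (utr5Len > 0L) mapTx(0L, utr5Len) else NULL,
                 utr3 = if (utr3Len > 0L) mapTx(utr5Len + nchar(cdsSeq),
                                                txLen) else NULL)
    if (strand == "-") {
        regionSeq <- revComp(regionSeq)
        flip <- function(m) {
            if (is.null(m)) return(NULL)
            f <- cbind(R - m[, 2L], R - m[, 1L])
            f[order(f[, 1L]), , drop = FALSE]
        }
        segs <- lapply(segs, flip)
    }
    list(sequence = regionSeq, segments = segs, length = R)
}

#' Simulate a family genome with planted ground truth
#'
#' Generates a 2-chromosome assembly carrying the configured family:
#' every gene has two D[TS]G motifs at domain-complete spacing; category-A
#' genes carry a 100-residue cysteine-rich plant-specific-like insert;
#' category-B genes carry exact QCDYE and GCGYDQ motifs plus a sequon
#' just upstream of GCGYDQ; the tandem cluster sits at sub-50-kb gaps;
#' segmental copies diverge by the configured substitution counts and are
#' covered by emitted duplication blocks; promoters get planted
#' degenerate elements; the expression matrix carries a xylem-specific
#' planted set. Reproducible given the seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list: \code{assembly} (DNAStringSet), \code{genes} (GeneModel
#'   list), \code{cds}, \code{proteins} (named vectors), \code{blocks}
#'   (0-based data.frame), \code{expression} (matrix), \code{truth}
#'   (planted ground truth: categories, tandem clusters, segmental pairs
#'   with realized counts, promoter hits, xylem set).
#' @export
simulateFamilyGenome <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    mix <- config$categoryMix
    n <- sum(mix)
    ids <- sprintf("simAP%02d", seq_len(n))
    categories <- setNames(rep(names(mix), mix), ids)

    nSeg <- length(config$segmentalSyn)
    cIds <- ids[categories == "C"]
    segSources <- cIds[seq_len(nSeg)]
    segCopies <- cIds[nSeg + seq_len(nSeg)]
    tandemIds <- cIds[(length(cIds) - config$tandemSize + 1L):length(cIds)]

    ## chromosome assignment: copies and the tandem cluster on chr2
    chr2Set <- c(segCopies, setdiff(cIds, c(segSources, segCopies)))
    chrOf <- setNames(ifelse(ids %in% chr2Set, "chr2", "chr1"), ids)
    ## order within chromosomes: keep id order, tandem genes last on chr2
    ord2 <- c(setdiff(ids[chrOf == "chr2"], tandemIds), tandemIds)
    layout <- list(chr1 = ids[chrOf == "chr1"], chr2 = ord2)

    ## design proteins/CDS (copies are evolved from their sources)
    proteins <- cds <- setNames(character(n), ids)
    protect <- setNames(vector("list", n), ids)
    segTruth <- list()
    for (id in ids[!ids %in% segCopies]) {
        d <- .designProtein(categories[[id]])
        proteins[[id]] <- d$protein
        cds[[id]] <- paste0(.backTranslate(d$protein), "TAA")
        protect[[id]] <- d$protect
    }
    for (k in seq_len(nSeg)) {
        src <- segSources[k]; cp <- segCopies[k]
        ev <- evolveCodonPair(cds[[src]], config$segmentalSyn[k],
                              config$segmentalNonsyn[k],
                              protect = c(1L, protect[[src]]))
        cds[[cp]] <- ev$cds
        proteins[[cp]] <- translateCds(ev$cds)$protein
        segTruth[[k]] <- list(gene_a = src, gene_b = cp,
                              n_syn = length(ev$synPositions),
                              n_nonsyn = length(ev$nonsynPositions),
                              n_codons = nchar(cds[[src]]) / 3 - 1L)
    }

    ## placement and chromosome assembly
    catalog <- cisElementCatalog()
    plen <- config$promoterLengthBp
    genes <- list()
    promoterTruth <- list()
    chromSeqs <- list()
    for (chrom in names(layout)) {
        pieces <- character()
        cursor <- 0L
        pad <- function(k) { pieces <<- c(pieces, .randBases(k))
            cursor <<- cursor + k }
        pad(plen + 2000L)
        for (id in layout[[chrom]]) {
            idx <- match(id, ids)
            strand <- if (idx %% 2L == 1L) "+" else "-"
            utr5Len <- if (idx %% 4L == 0L) 0L else 150L
            nEx <- ((idx - 1L) %% 4L) + 1L
            cdsBody <- sub("TAA$", "", cds[[id]])
            region <- .buildGeneRegion(paste0(cdsBody, "TAA"), utr5Len,
                                       120L, nEx, strand)
            ## planted promoter: two instances per gene
            inst <- data.frame(
                element = names(catalog)[c((idx - 1L) %% 10L + 1L,
                                           idx %% 10L + 1L)],
                offset = c(300L, 1600L),
                strand = c("+", "-"), stringsAsFactors = FALSE)
            pp <- plantCisElements(plen, inst, catalog)
            pp$truth$gene_id <- id
            promoterTruth[[id]] <- pp$truth
            if (strand == "+") {
                ## promoter immediately upstream of the transcript start
                pieces <- c(pieces, pp$sequence, region$sequence)
                geneStart <- cursor + plen
            } else {
                pieces <- c(pieces, region$sequence,
                            revComp(pp$sequence))
                geneStart <- cursor
            }
            segAbs <- lapply(region$segments, function(m)
                if (is.null(m)) NULL else m + geneStart)
            genes[[id]] <- GeneModel(id, chrom = chrom, strand = strand,
                                     exons = segAbs$exons,
                                     cds = segAbs$cds,
                                     utr5 = segAbs$utr5,
                                     utr3 = segAbs$utr3)
            cursor <- cursor + plen + region$length
            pos <- match(id, layout[[chrom]])
            if (pos < length(layout[[chrom]])) {
                nxt <- layout[[chrom]][pos + 1L]
                gap <- if (nxt %in% tandemIds[-1L]) config$tandemGapBp else
                    60000L
                ## promoters flank the genes inside the gap; pad so the
                ## boundary-to-boundary distance equals `gap`
                adj <- (if (match(nxt, ids) %% 2L == 1L) plen else 0L) +
                    (if (strand == "-") plen else 0L)
                pad(gap - adj)
            }
        }
        pad(2000L)
        chromSeqs[[chrom]] <- paste(pieces, collapse = "")
    }
    assembly <- DNAStringSet(unlist(chromSeqs))

    ## duplication blocks covering source/copy spans (0-based half-open)
    blocks <- do.call(rbind, lapply(seq_len(nSeg), function(k) {
        ga <- genes[[segSources[k]]]; gb <- genes[[segCopies[k]]]
        sa <- geneSpan(ga); sb <- geneSpan(gb)
        data.frame(block_id = paste0("blk", k),
                   chromA = geneChrom(ga),
                   startA = max(0L, sa[1L] - 5000L), endA = sa[2L] + 5000L,
                   chromB = geneChrom(gb),
                   startB = max(0L, sb[1L] - 5000L), endB = sb[2L] + 5000L,
                   stringsAsFactors = FALSE)
    }))

    ## expression: xylem-specific planted set closed under segmental pairs
    xylemSet <- c(ids[1L], segSources[1L], segCopies[1L])
    tissues <- config$tissues
    arch <- matrix(0, n, length(tissues), dimnames = list(ids, tissues))
    for (id in ids) {
        arch[id, ] <- stats::runif(length(tissues), 20,
                                   config$offArchetypeMax)
        if (id %in% xylemSet) {
            arch[id, "XY"] <- config$xylemArchetype
            arch[id, setdiff(tissues, "XY")] <-
                stats::runif(length(tissues) - 1L, 20, 90)
        }
    }
    expr <- makeExpression(arch, noiseSd = config$noiseSd)

    truth <- list(categories = categories,
                  tandemClusters = list(tandemIds),
                  segmentalPairs = segTruth,
                  promoterHits = do.call(rbind, promoterTruth),
                  xylemSet = xylemSet,
                  archetypes = arch)
    list(assembly = assembly, genes = genes, cds = cds,
         proteins = proteins, blocks = blocks, expression = expr,
         truth = truth, config = config)
}

#' Expression matrix from tissue archetypes plus Gaussian noise
#'
#' value = max(0, archetype + N(0, noiseSd)).
#'
#' @param archetypes genes x tissues matrix of archetype values.
#' @param noiseSd Gaussian noise standard deviation.
#' @return expression matrix of the same shape.
#' @export
makeExpression <- function(archetypes, noiseSd = 50) {
    stopifnot(all(archetypes >= 0))
    noise <- matrix(stats::rnorm(length(archetypes), 0, noiseSd),
                    nrow(archetypes))
    pmax(archetypes + noise, 0)
}

#' Write a simulation to disk in the standard formats
#'
#' FASTA genome, GFF3 annotation, protein/CDS FASTA, blocks TSV (1-based
#' inclusive on disk), expression TSV and truth JSON.
#'
#' @param sim result of \code{\link{simulateFamilyGenome}}.
#' @param dir output directory (created).
#' @return named vector of file paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               gff = file.path(dir, "annotation.gff3"),
               cds = file.path(dir, "cds.fa"),
               proteins = file.path(dir, "proteins.fa"),
               blocks = file.path(dir, "blocks.tsv"),
               expression = file.path(dir, "expression.tsv"),
               truth = file.path(dir, "truth.json"))
    writeFasta(as.character(sim$assembly), paths[["genome"]])
    writeGeneModels(sim$genes, paths[["gff"]])
    writeFasta(sim$cds, paths[["cds"]])
    writeFasta(sim$proteins, paths[["proteins"]], nuc = FALSE)
    bl <- sim$blocks
    bl$startA <- bl$startA + 1L; bl$startB <- bl$startB + 1L
    write.table(bl, paths[["blocks"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    expr <- data.frame(gene_id = rownames(sim$expression),
                       sim$expression, check.names = FALSE)
    write.table(expr, paths[["expression"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    paths
}
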