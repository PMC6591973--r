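test_that("simulation is byte-identical under a fixed seed", {
    s1 <- simulateFamilyGenome(simulationConfig(seed = 5))
    s2 <- simulateFamilyGenome(simulationConfig(seed = 5))
    expect_identical(as.character(s1$assembly), as.character(s2$assembly))
    expect_identical(s1$cds, s2$cds)
    expect_identical(s1$truth$promoterHits, s2$truth$promoterHits)
    expect_identical(s1$expression, s2$expression)
    s3 <- simulateFamilyGenome(simulationConfig(seed = 6))
    expect_false(identical(as.character(s1$assembly),
                           as.character(s3$assembly)))
})

test_that("infeasible configurations are rejected", {
    expect_error(simulationConfig(categoryMix = c(A = 2, B = 2, C = 4),
                                  tandemSize = 3),
                 "too small")
})

test_that("planted genes satisfy the family rules by construction", {
    sim <- simulateFamilyGenome(simulationConfig(seed = 13))
    for (id in names(sim$proteins)) {
        hits <- findCatalyticMotifs(sim$proteins[[id]])
        dc <- domainComplete(hits)
        expect_true(dc$complete)
        gap <- dc$pair[2] - dc$pair[1]
        expect_gte(gap, 100L)
        expect_lte(gap, 350L)
        expect_true(checkOrf(sim$cds[[id]])$perfect)
    }
    ## category-B genes carry the planted conserved sequon
    bIds <- names(sim$truth$categories)[sim$truth$categories == "B"]
    for (id in bIds)
        expect_equal(conservedSequonNearAnchor(sim$proteins[[id]],
                                               "B")$status, "conserved")
})

test_that("planted promoter instances land where the truth says", {
    sim <- simulateFamilyGenome(simulationConfig(seed = 29))
    for (id in names(sim$genes)) {
        pr <- extractPromoter(sim$genes[[id]], sim$assembly)
        expect_false(pr$truncated)
        hits <- scanElements(pr$sequence, geneId = id)
        tr <- sim$truth$promoterHits[sim$truth$promoterHits$gene_id == id, ]
        for (i in seq_len(nrow(tr))) {
            expect_true(any(hits$element == tr$element[i] &
                            hits$start == tr$start[i] &
                            hits$strand == tr$strand[i]),
                        label = paste("planted", tr$element[i], "for", id))
        }
    }
})

test_that("cis-element planting validates geometry and draws from the consensus", {
    set.seed(3)
    inst <- data.frame(element = c("ACI", "SNBE"), offset = c(100L, 500L),
                       strand = c("+", "-"), stringsAsFactors = FALSE)
    pl <- plantCisElements(3000L, inst)
    expect_equal(nchar(pl$sequence), 3000L)
    got <- scanElements(pl$sequence)
    for (i in 1:2)
        expect_true(any(got$element == pl$truth$element[i] &
                        got$start == pl$truth$start[i] &
                        got$strand == pl$truth$strand[i]))
    ## overlap rejected
    bad <- data.frame(element = c("ACI", "ACII"), offset = c(100L, 103L),
                      strand = c("+", "+"))
    expect_error(plantCisElements(3000L, bad), "overlap")
    ## beyond-edge rejected
    expect_error(plantCisElements(100L, data.frame(
        element = "SNBE", offset = 95L, strand = "+")), "beyond")
    ## zero instances: hits equal the oracle on the pure background
    pl0 <- plantCisElements(1000L, NULL)
    expect_identical(hitKeys(scanElements(pl0$sequence)),
                     hitKeys(oracleIupacScan(pl0$sequence,
                                             cisElementCatalog())))
})

test_that("controlled codon evolution honors counts, types and seed", {
    set.seed(71)
    base <- paste(randomCodons(100), collapse = "")
    ev <- evolveCodonPair(base, nSyn = 5L, nNonsyn = 3L, seed = 99)
    expect_length(ev$synPositions, 5L)
    expect_length(ev$nonsynPositions, 3L)
    expect_length(intersect(ev$synPositions, ev$nonsynPositions), 0L)
    pa <- translateCds(base)$protein
    pb <- translateCds(ev$cds)$protein
    diffs <- which(strsplit(pa, "")[[1]] != strsplit(pb, "")[[1]])
    expect_identical(diffs, as.integer(ev$nonsynPositions))
    expect_false(translateCds(ev$cds)$internalStop)
    ## same seed -> same mutation set; no-op request -> identity
    ev2 <- evolveCodonPair(base, nSyn = 5L, nNonsyn = 3L, seed = 99)
    expect_identical(ev, ev2)
    expect_identical(evolveCodonPair(base, 0L, 0L)$cds, base)
    expect_error(evolveCodonPair("ATGATG", nSyn = 5L), "not enough")
})

test_that("expression generation respects archetypes and noise", {
    arch <- matrix(c(1500, 50, 40, 30), 1,
                   dimnames = list("g1", c("XY", "RT", "ML", "YL")))
    set.seed(1)
    e0 <- makeExpression(arch, noiseSd = 0)
    expect_equal(e0, arch)
    set.seed(1)
    e1 <- makeExpression(arch, noiseSd = 50)
    expect_true(all(e1 >= 0))
    expect_false(identical(e1, arch))
})

test_that("written simulations are re-readable and identical on disk", {
    sim <- simulateFamilyGenome(simulationConfig(seed = 37))
    d1 <- file.path(tempdir(), "sim-a"); d2 <- file.path(tempdir(), "sim-b")
    p1 <- writeSimulation(sim, d1)
    p2 <- writeSimulation(simulateFamilyGenome(simulationConfig(seed = 37)),
                          d2)
    for (k in names(p1))
        expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                         label = paste("file", k))
    asm <- readGenome(p1[["genome"]])
    expect_identical(as.character(asm), as.character(sim$assembly))
    expr <- readExpressionMatrix(p1[["expression"]])
    expect_equal(expr, sim$expression, tolerance = 1e-6)
    blocks <- readBlockTable(p1[["blocks"]])
    expect_equal(blocks$startA, sim$blocks$startA)
})
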