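test_that("ORF report flags start, stop, internal stop and frame", {
    expect_true(checkOrf("ATGAAATAA")$perfect)
    r <- checkOrf("ATGTAGAAATAA")
    expect_false(r$noInternalStop)
    expect_true(r$startsWithAtg && r$endsWithStop)
    expect_false(checkOrf("TTGAAATAA")$startsWithAtg)
    expect_false(checkOrf("ATGAAATA")$frameOk)
})

test_that("catalytic-motif scan finds all D[TS]G occurrences in order", {
    expect_equal(findCatalyticMotifs("AAADTGAAADSGAAA")$position, c(4L, 10L))
    expect_equal(nrow(findCatalyticMotifs("AAADAGAAA")), 0L)
    h <- findCatalyticMotifs("DTGDSG")
    expect_equal(h$position, c(1L, 4L))
    expect_equal(h$triplet, c("DTG", "DSG"))
    ## X never matches
    expect_equal(nrow(findCatalyticMotifs("DXG")), 0L)
})

test_that("motif positions agree with a brute-force substring scan", {
    set.seed(3)
    for (i in 1:50) {
        p <- randomProtein(200)
        hits <- findCatalyticMotifs(p)$position
        brute <- integer()
        for (j in seq_len(nchar(p) - 2L))
            if (grepl("^D[TS]G$", substr(p, j, j + 2L)))
                brute <- c(brute, j)
        expect_identical(hits, brute)
        expect_false(is.unsorted(hits, strictly = TRUE))
    }
})

test_that("domain completeness applies the spacing rule pairwise", {
    h <- function(pos) data.frame(position = pos,
                                  triplet = rep("DTG", length(pos)))
    expect_true(domainComplete(h(c(80L, 280L)))$complete)   # gap 200
    expect_false(domainComplete(h(c(10L, 40L)))$complete)   # gap 30
    r <- domainComplete(h(c(10L, 40L, 260L)))               # pair (10,260)
    expect_true(r$complete)
    expect_equal(r$pair, c(10L, 260L))
    expect_false(domainComplete(h(integer()))$complete)
})

test_that("category rules assign A, B, C with A-over-B precedence", {
    ## A: six cysteines inside a 100-residue insert between the motifs
    set.seed(5)
    insert <- strsplit(paste(sample(c("A", "G", "L", "S", "V"), 100,
                                    replace = TRUE), collapse = ""), "")[[1]]
    insert[seq(10, 60, by = 10)] <- "C"
    protA <- paste0(strrep("M", 1), strrep("A", 39), "DTG", strrep("L", 30),
                    paste(insert, collapse = ""), strrep("K", 30), "DSG",
                    strrep("A", 40))
    pairA <- domainComplete(findCatalyticMotifs(protA))$pair
    expect_equal(classifyCategory(protA, pairA)$category, "A")

    ## B: exact nucellin motifs, no Cys-rich insert
    protB <- paste0("M", strrep("A", 39), "DTG", strrep("L", 40), "QCDYE",
                    strrep("K", 50), "GCGYDQ", strrep("A", 40), "DSG",
                    strrep("G", 40))
    pairB <- domainComplete(findCatalyticMotifs(protB))$pair
    expect_equal(classifyCategory(protB, pairB)$category, "B")
    ## one substitution in each motif still matches by default
    protB1 <- sub("QCDYE", "QCDYD", sub("GCGYDQ", "GCGYDA", protB))
    pairB1 <- domainComplete(findCatalyticMotifs(protB1))$pair
    expect_equal(classifyCategory(protB1, pairB1)$category, "B")
    ## two substitutions break it -> C
    protB2 <- sub("QCDYE", "QADYD", protB)
    pairB2 <- domainComplete(findCatalyticMotifs(protB2))$pair
    expect_equal(classifyCategory(protB2, pairB2)$category, "C")

    ## C: neither feature
    protC <- paste0("M", strrep("A", 39), "DTG", strrep("L", 150), "DSG",
                    strrep("G", 40))
    pairC <- domainComplete(findCatalyticMotifs(protC))$pair
    expect_equal(classifyCategory(protC, pairC)$category, "C")

    ## not domain-complete -> unassigned
    expect_equal(classifyCategory(protC, NULL)$category, "unassigned")
})

test_that("molecular weight sums average masses plus one water", {
    expect_equal(round(computeMw("GG"), 2), 132.12)
    expect_equal(round(computeMw("G"), 2), 75.07)
    expect_error(computeMw(""), "empty")
    expect_error(computeMw("GZ"), "unknown")
    ## additivity: mw(a+b) = mw(a) + mw(b) - water
    set.seed(8)
    for (i in 1:10) {
        a <- randomProtein(sample(5:30, 1)); b <- randomProtein(sample(5:30, 1))
        expect_equal(computeMw(paste0(a, b)),
                     computeMw(a) + computeMw(b) - 18.0153)
    }
})

test_that("localization majority vote requires a strict majority", {
    expect_equal(majorityVoteLocalization(
        c("vacuole", "vacuole", "wall", "vacuole", "wall")), "vacuole")
    expect_equal(majorityVoteLocalization(c("wall", "vacuole")), "ambiguous")
    expect_equal(majorityVoteLocalization("wall"), "wall")
    expect_equal(majorityVoteLocalization(c("a", "a", "b", "b", "c")),
                 "ambiguous")
})

test_that("family identification recovers planted categories exactly", {
    sim <- simulateFamilyGenome(simulationConfig(seed = 23))
    mem <- identifyFamily(sim$proteins, cds = sim$cds)
    expect_true(all(mem$domain_complete))
    expect_true(all(mem$orf_perfect))
    got <- setNames(mem$category, mem$gene_id)
    expect_identical(got[names(sim$truth$categories)],
                     sim$truth$categories)
})
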