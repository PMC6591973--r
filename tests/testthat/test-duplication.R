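test_that("tandem clustering applies the 50-kb single-linkage rule", {
    mk <- function(...) {
        m <- rbind(...)
        data.frame(gene_id = m[, 1], chrom = m[, 2],
                   start = as.integer(m[, 3]), end = as.integer(m[, 4]),
                   stringsAsFactors = FALSE)
    }
    ## gap 28 kb -> one cluster
    m <- mk(c("g1", "chr1", 100000, 102000), c("g2", "chr1", 130000, 133000))
    expect_equal(findTandem(m), list(c("g1", "g2")))
    ## gap 60 kb -> no cluster
    m2 <- mk(c("g1", "chr1", 100000, 102000), c("g2", "chr1", 162001, 165000))
    expect_equal(findTandem(m2), list())
    ## chain 40 kb + 45 kb -> transitive cluster of 3
    m3 <- mk(c("g1", "chr1", 0, 2000), c("g2", "chr1", 42000, 44000),
             c("g3", "chr1", 89000, 91000))
    expect_equal(findTandem(m3), list(c("g1", "g2", "g3")))
    ## different chromosomes never cluster
    m4 <- mk(c("g1", "chr1", 0, 2000), c("g2", "chr2", 1000, 3000))
    expect_equal(findTandem(m4), list())
})

test_that("tandem clustering equals the O(n^2) closure oracle", {
    set.seed(31)
    for (i in 1:30) {
        n <- sample(3:12, 1)
        start <- sort(sample.int(500000L, n))
        members <- data.frame(
            gene_id = sprintf("g%02d", seq_len(n)),
            chrom = sample(c("c1", "c2"), n, replace = TRUE),
            start = start, end = start + sample(500:3000, n, replace = TRUE),
            stringsAsFactors = FALSE)
        got <- findTandem(members, windowBp = 30000L)
        want <- oracleTandem(members, windowBp = 30000L)
        key <- function(cl) sort(vapply(cl, paste, "", collapse = ","))
        expect_identical(key(got), key(want))
    }
})

test_that("segmental assignment pairs genes across block sides", {
    members <- data.frame(gene_id = c("g1", "g2", "g3"),
                          chrom = c("chr1", "chr2", "chr1"),
                          start = c(1000L, 5000L, 9000L),
                          end = c(2000L, 6000L, 10000L),
                          stringsAsFactors = FALSE)
    blocks <- data.frame(block_id = "b1", chromA = "chr1", startA = 500L,
                         endA = 3000L, chromB = "chr2", startB = 4000L,
                         endB = 7000L, stringsAsFactors = FALSE)
    got <- assignSegmental(members, blocks)
    expect_equal(got$gene_a, "g1")
    expect_equal(got$gene_b, "g2")
    ## no family partner inside B -> no pair
    blocks2 <- transform(blocks, startB = 100000L, endB = 101000L)
    expect_equal(nrow(assignSegmental(members, blocks2)), 0L)
    ## 1-bp overlap at a block edge still pairs
    blocks3 <- transform(blocks, startA = 1999L, endA = 2500L)
    expect_equal(nrow(assignSegmental(members, blocks3)), 1L)
    blocks4 <- transform(blocks, startA = 2000L, endA = 2500L)
    expect_equal(nrow(assignSegmental(members, blocks4)), 0L)
})

test_that("codon alignment maps residue pairs and strips stops", {
    r <- codonAlign("ATGAAACCCGGGTAA", "ATGAAACCCGGGTAA")
    expect_equal(length(r$codonsA), 4L)
    expect_equal(r$codonsA, r$codonsB)
    ## a gap column drops one pair
    aln <- list(alignedA = "MKPG", alignedB = "MK-G")
    r2 <- codonAlign("ATGAAACCCGGG", "ATGAAAGGG", proteinAln = aln)
    expect_equal(length(r2$codonsA), 3L)
    expect_equal(r2$codonsA, c("ATG", "AAA", "GGG"))
    expect_error(codonAlign("ATGAAAC", "ATGAAA"), "multiple of 3")
})

test_that("NG86 reproduces the hand-worked single-substitution case", {
    a <- rep("GGG", 9)
    b <- c(rep("GGG", 8), "GGA")
    k <- ng86(a, b)
    expect_equal(k@S, 9)
    expect_equal(k@N, 18)
    expect_equal(k@sd, 1)
    expect_equal(k@nd, 0)
    expect_equal(k@Ks, 0.1203, tolerance = 1e-4 / 0.1203)
    expect_equal(k@Ka, 0)
    ## identical input -> zero rates, ratio undefined by zero Ks
    k0 <- ng86(a, a)
    expect_equal(k0@Ks, 0)
    expect_equal(k0@Ka, 0)
    expect_true(is.na(k0@ratio))
})

test_that("NG86 is symmetric and conserves sites", {
    set.seed(41)
    for (i in 1:20) {
        a <- randomCodons(25)
        b <- randomCodons(25)
        kab <- ng86(a, b); kba <- ng86(b, a)
        expect_equal(kab@S, kba@S)
        expect_equal(kab@sd, kba@sd)
        expect_equal(kab@nd, kba@nd)
        expect_equal(kab@S + kab@N, 3 * kab@codons)
    }
})

test_that("NG86 matches the brute-force pathway oracle", {
    set.seed(43)
    for (i in 1:25) {
        a <- randomCodons(30)
        ## mutate a copy at a few sites to keep divergence moderate
        b <- a
        idx <- sample(30, 8)
        b[idx] <- randomCodons(8)
        k <- ng86(a, b)
        o <- oracleNg86(a, b)
        expect_lt(abs(k@S - o$S), 1e-12)
        expect_lt(abs(k@sd - o$sd), 1e-12)
        expect_lt(abs(k@nd - o$nd), 1e-12)
        if (!is.na(o$Ks) && !k@saturated)
            expect_lt(abs(k@Ks - o$Ks), 1e-12)
    }
})

test_that("molecular-clock dating is exact and linear", {
    expect_equal(dateDuplication(0)$years, 0)
    expect_equal(dateDuplication(0.182)$mya, 10)
    expect_equal(dateDuplication(0.182)$years, 1e7)
    set.seed(2)
    k <- runif(1, 0.01, 2)
    expect_equal(dateDuplication(2 * k)$years, 2 * dateDuplication(k)$years)
    expect_error(dateDuplication(-0.1), "non-negative")
})

test_that("selection classes follow the Ka/Ks thresholds", {
    expect_equal(selectionClass(0.3), "purifying")
    expect_equal(selectionClass(1.0), "neutral")
    expect_equal(selectionClass(2.5), "positive")
    expect_equal(selectionClass(NA_real_), "undefined")
    sat <- ng86(rep("TTT", 4), rep("AAG", 4))  # heavily diverged
    if (sat@saturated) expect_equal(selectionClass(sat), "undefined")
})

test_that("controlled synonymous evolution is recovered as sd = m", {
    set.seed(47)
    base <- paste(randomCodons(120), collapse = "")
    for (m in c(3L, 10L, 20L)) {
        ev <- evolveCodonPair(base, nSyn = m, nNonsyn = 0L)
        k <- ng86(splitCodons(base), splitCodons(ev$cds))
        expect_equal(k@sd, m)
        expect_equal(k@nd, 0)
    }
})
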