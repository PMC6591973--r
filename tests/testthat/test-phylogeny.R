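test_that("global pairwise alignment and percent identity", {
    r <- pairwiseAlignProteins("HEAGAWGHEE", "HEAGAWGHEE")
    expect_equal(r$identity, 100L)
    ## unit scores: match +1, mismatch -1, gap -1 per column
    unit <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
    diag(unit) <- 1
    r2 <- pairwiseAlignProteins("HEAG", "HEG", substitutionMatrix = unit,
                                gapOpening = 0, gapExtension = 1)
    expect_equal(r2$score, 2)
    ## empty vs "AA": two forced gap columns
    r3 <- pairwiseAlignProteins("", "AA", substitutionMatrix = unit,
                                gapOpening = 0, gapExtension = 1)
    expect_equal(r3$score, -2)
    expect_equal(r3$identity, 0L)
})

test_that("pairwise-deletion distances under p and poisson models", {
    aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAACC")
    expect_equal(proteinDistance(aln, model = "p")["a", "b"], 0.2)
    expect_equal(proteinDistance(aln, model = "poisson")["a", "b"],
                 -log(0.8), tolerance = 1e-12)
    expect_equal(round(proteinDistance(aln)["a", "b"], 5), 0.22314)
    same <- c(a = "AC-DE", b = "AC-DE")
    expect_equal(proteinDistance(same)["a", "b"], 0)
    ## gap columns excluded pairwise
    gapped <- c(a = "AC-AA", b = "ACCAC")
    expect_equal(proteinDistance(gapped, model = "p")["a", "b"], 0.25)
    ## saturation handling
    sat <- c(a = "AAAA", b = "CCCC", c = "AAAC")
    expect_error(proteinDistance(sat), "undefined")
    expect_true(all(is.finite(proteinDistance(sat, onSaturate = "cap"))))
})

test_that("NJ reproduces the three-taxon closed form exactly", {
    d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- njTree(d)
    pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
    expect_equal(pend[["A"]], 0.5)
    expect_equal(pend[["B"]], 1.5)
    expect_equal(pend[["C"]], 2.5)
    expect_error(njTree(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the generating topology of an additive matrix", {
    ## 4-taxon tree ((A,B),(C,D)) with internal edge 1
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- 2
    d["C", "D"] <- d["D", "C"] <- 2
    for (x in c("A", "B")) for (y in c("C", "D"))
        d[x, y] <- d[y, x] <- 3
    tr <- njTree(d)
    ## the AB|CD split must be present: drop each tip, check sibling
    expect_equal(sort(ape::prop.part(tr)[[2]]), c(1, 2))
    expect_equal(max(abs(as.matrix(ape::cophenetic.phylo(tr))[
        rownames(d), colnames(d)] - d)), 0, tolerance = 1e-12)
})

test_that("NJ path metric reproduces random additive matrices", {
    set.seed(17)
    for (i in 1:25) {
        d <- randomAdditiveMatrix(sample(4:12, 1))
        tr <- njTree(d)
        pd <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
        expect_lt(max(abs(pd - d)), 1e-9)
    }
})

test_that("NJ topology is invariant under taxon permutation", {
    set.seed(19)
    d <- randomAdditiveMatrix(8)
    tr1 <- njTree(d)
    perm <- sample(nrow(d))
    tr2 <- njTree(d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(tr1), ape::unroot(tr2))[1], 0)
})

test_that("bootstrap supports are reproducible and bounded", {
    ## two clean pairs: every column supports AB|CD
    aln <- c(A = strrep("A", 30), B = strrep("A", 30),
             C = strrep("W", 30), D = strrep("W", 30))
    ## add light distinguishing signal within pairs
    substr(aln[["B"]], 1, 3) <- "LLL"
    substr(aln[["D"]], 1, 3) <- "FFF"
    tr <- bootstrapSupport(aln, nReps = 50, seed = 9)
    supports <- suppressWarnings(as.numeric(tr$node.label))
    supports <- supports[!is.na(supports)]
    expect_true(all(supports >= 0 & supports <= 100))
    expect_true(100 %in% supports)  # the AB|CD edge is in every replicate
    tr2 <- bootstrapSupport(aln, nReps = 50, seed = 9)
    expect_identical(tr$node.label, tr2$node.label)
    ## single replicate: supports are 0 or 100
    tr3 <- bootstrapSupport(aln, nReps = 1, seed = 2)
    s3 <- suppressWarnings(as.numeric(tr3$node.label))
    expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
})

test_that("progressive alignment handles identical and divergent inputs", {
    seqs <- c(s1 = "MKVLHEAGAWGHEE", s2 = "MKVLHEAGAWGHEE",
              s3 = "MKVLHEAGAWGHEE")
    aln <- progressiveAlign(seqs)
    expect_identical(unname(aln), unname(seqs))  # no gaps needed
    seqs2 <- c(a = "MKVAAAGGWWLL", b = "MKVAAAGGWWLL", c = "MKVGGWWLL")
    aln2 <- progressiveAlign(seqs2)
    expect_equal(length(unique(nchar(aln2))), 1L)
    expect_identical(gsub("-", "", aln2[["c"]]), seqs2[["c"]])
    expect_identical(names(aln2), names(seqs2))
})
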