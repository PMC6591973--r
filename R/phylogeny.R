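## Distance-based NJ phylogeny with bootstrap support, plus pairwise and
## progressive protein alignment.

#' @importFrom ape nj prop.clades write.tree read.tree
NULL

#' Global pairwise protein alignment with percent identity
#'
#' Needleman-Wunsch global alignment (end gaps penalized) through
#' Biostrings. Percent identity is defined as identical aligned pairs over
#' all alignment columns, reported to the nearest integer.
#'
#' @param a,b protein strings.
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   BLOSUM62).
#' @param gapOpening,gapExtension gap penalties (positive costs, Biostrings
#'   convention).
#' @return list: \code{alignedA}, \code{alignedB} (gapped strings),
#'   \code{score}, \code{identity} (integer percent).
#' @export
pairwiseAlignProteins <- function(a, b, substitutionMatrix = "BLOSUM62",
                                  gapOpening = 10, gapExtension = 0.5) {
    if (nchar(a) == 0L || nchar(b) == 0L) {
        ## degenerate: one sequence forces end gaps across the other
        long <- if (nchar(a) >= nchar(b)) a else b
        n <- nchar(long)
        gaps <- strrep("-", n)
        return(list(alignedA = if (nchar(a)) a else gaps,
                    alignedB = if (nchar(b)) b else gaps,
                    score = -(if (n) gapOpening + gapExtension * n else 0),
                    identity = 0L))
    }
    pa <- pairwiseAlignment(AAString(a), AAString(b),
                            substitutionMatrix = substitutionMatrix,
                            gapOpening = gapOpening,
                            gapExtension = gapExtension, type = "global")
    sa <- as.character(Biostrings::alignedPattern(pa))
    sb <- as.character(Biostrings::alignedSubject(pa))
    ca <- .chars(sa); cb <- .chars(sb)
    ident <- round(100 * sum(ca == cb & ca != "-") / length(ca))
    list(alignedA = sa, alignedB = sb, score = Biostrings::score(pa),
         identity = as.integer(ident))
}

## gapped-string alignment -> character matrix (rows = sequences)
.alnMatrix <- function(aln) {
    stopifnot(length(unique(nchar(aln))) == 1L)
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- names(aln)
    m
}

#' Pairwise-deletion protein distance matrix
#'
#' For every pair, alignment columns where either row has a gap are
#' dropped; p = differing / compared columns. The poisson model applies
#' the correction d = -ln(1 - p).
#'
#' @param aln named character vector of equal-length gapped protein
#'   strings.
#' @param model \code{"poisson"} (default) or \code{"p"}.
#' @param onSaturate for poisson with p >= 1: \code{"error"} or
#'   \code{"cap"} (replace by the largest finite distance in the matrix,
#'   or 5 if none).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
proteinDistance <- function(aln, model = c("poisson", "p"),
                            onSaturate = c("error", "cap")) {
    model <- match.arg(model)
    onSaturate <- match.arg(onSaturate)
    m <- .alnMatrix(aln)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    sat <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- m[i, ] != "-" & m[j, ] != "-"
        if (!any(ok)) stop("no comparable columns for pair ",
                           rownames(m)[i], " / ", rownames(m)[j])
        p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
        if (model == "p") {
            d[i, j] <- d[j, i] <- p
        } else if (p < 1) {
            d[i, j] <- d[j, i] <- -log(1 - p)
        } else {
            if (onSaturate == "error")
                stop("poisson distance undefined (p >= 1) for pair ",
                     rownames(m)[i], " / ", rownames(m)[j])
            d[i, j] <- d[j, i] <- NA_real_
            sat <- TRUE
        }
    }
    if (sat) {
        cap <- max(d[is.finite(d)], 0)
        d[is.na(d)] <- max(cap * 1.1, 5)
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch-length estimates
#' are clamped to zero; the tree carries attribute \code{clamped} saying
#' whether that happened. For an additive input matrix the tree's
#' path-length metric reproduces the matrix exactly.
#'
#' @param d symmetric distance matrix with row/column names (or a dist).
#' @return an unrooted \link[ape]{phylo} tree.
#' @export
njTree <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    if (nrow(d) < 3L) stop("NJ requires at least 3 taxa")
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
    tr <- ape::nj(stats::as.dist(d))
    clamped <- any(tr$edge.length < 0)
    if (clamped) {
        warning("negative NJ branch length(s) clamped to 0")
        tr$edge.length[tr$edge.length < 0] <- 0
    }
    attr(tr, "clamped") <- clamped
    tr
}

#' NJ tree with bootstrap support
#'
#' Resamples alignment columns with replacement \code{nReps} times,
#' rebuilds the NJ tree for each replicate, and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition. Saturated poisson pairs in replicates are capped
#' rather than erroring, so every replicate yields a tree.
#'
#' @param aln named character vector of equal-length gapped proteins.
#' @param nReps number of bootstrap replicates (the reference analysis
#'   scale is 1000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param model distance model, see \code{\link{proteinDistance}}.
#' @return a \link[ape]{phylo} tree with \code{node.label} holding percent
#'   support on internal nodes.
#' @export
bootstrapSupport <- function(aln, nReps = 1000L, seed = 1L,
                             model = "poisson") {
    stopifnot(nReps >= 1L, length(aln) >= 3L)
    full <- njTree(proteinDistance(aln, model = model, onSaturate = "cap"))
    m <- .alnMatrix(aln)
    set.seed(as.integer(seed))
    reps <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        sub <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
        reps[[r]] <- suppressWarnings(
            njTree(proteinDistance(sub, model = model, onSaturate = "cap")))
    }
    counts <- ape::prop.clades(full, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    full$node.label <- round(100 * counts / nReps)
    full
}

## --- progressive aligner (approximate; external MSA preferred for real
## --- data) -------------------------------------------------------------

## k-mer distance between ungapped proteins: 1 - shared/min
.kmerDistance <- function(seqs, k = 3L) {
    km <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < k) return(character())
        unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
    })
    n <- length(seqs)
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        shared <- length(intersect(km[[i]], km[[j]]))
        lo <- min(length(km[[i]]), length(km[[j]]))
        d[i, j] <- d[j, i] <- if (lo == 0L) 1 else 1 - shared / lo
    }
    d
}

## profile-profile global alignment with linear gap cost; profiles are
## character matrices. Column scores computed as FA' M FB in one product.
.alignProfiles <- function(A, B, gapCost = -4) {
    syms <- c(names(RESIDUE_MASS), "-")
    M <- matrix(0, 21L, 21L, dimnames = list(syms, syms))
    data("BLOSUM62", package = "Biostrings", envir = environment())
    B62 <- get("BLOSUM62", envir = environment())
    M[1:20, 1:20] <- B62[names(RESIDUE_MASS), names(RESIDUE_MASS)]
    M["-", ] <- gapCost; M[, "-"] <- gapCost; M["-", "-"] <- 0
    freq <- function(P) {
        f <- vapply(seq_len(ncol(P)), function(j) {
            tabulate(match(P[, j], syms), 21L)
        }, numeric(21L))
        f / nrow(P)
    }
    FA <- freq(A); FB <- freq(B)
    S <- t(FA) %*% M %*% FB
    nA <- ncol(A); nB <- ncol(B)
    score <- matrix(0, nA + 1L, nB + 1L)
    ptr <- matrix(0L, nA + 1L, nB + 1L)
    score[, 1L] <- (0:nA) * gapCost
    score[1L, ] <- (0:nB) * gapCost
    ptr[, 1L] <- 1L; ptr[1L, ] <- 2L; ptr[1L, 1L] <- 0L
    for (i in seq_len(nA)) {
        diagv <- score[i, seq_len(nB)] + S[i, ]
        for (j in seq_len(nB)) {
            up <- score[i, j + 1L] + gapCost
            left <- score[i + 1L, j] + gapCost
            best <- diagv[j]; p <- 3L
            if (up > best) { best <- up; p <- 1L }
            if (left > best) { best <- left; p <- 2L }
            score[i + 1L, j + 1L] <- best
            ptr[i + 1L, j + 1L] <- p
        }
    }
    i <- nA; j <- nB
    pathA <- integer(); pathB <- integer()
    while (i > 0L || j > 0L) {
        p <- ptr[i + 1L, j + 1L]
        if (p == 3L) { pathA <- c(i, pathA); pathB <- c(j, pathB)
            i <- i - 1L; j <- j - 1L }
        else if (p == 1L) { pathA <- c(i, pathA); pathB <- c(0L, pathB)
            i <- i - 1L }
        else { pathA <- c(0L, pathA); pathB <- c(j, pathB); j <- j - 1L }
    }
    expand <- function(P, path) {
        out <- matrix("-", nrow(P), length(path),
                      dimnames = list(rownames(P), NULL))
        out[, path > 0L] <- P[, path[path > 0L], drop = FALSE]
        out
    }
    rbind(expand(A, pathA), expand(B, pathB))
}

#' Progressive multiple protein alignment
#'
#' A deliberately simple progressive aligner: k-mer guide distances, a
#' UPGMA-style guide order, and profile-profile global alignment with
#' BLOSUM62 column scores and a linear gap cost. It is approximate; for
#' real-data phylogenies an externally computed alignment is the
#' recommended input to \code{\link{proteinDistance}}.
#'
#' @param seqs named character vector of (ungapped) protein strings.
#' @param gapCost linear gap score per column (negative).
#' @return named character vector of equal-length gapped strings, original
#'   order.
#' @export
progressiveAlign <- function(seqs, gapCost = -4) {
    stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
    if (length(seqs) == 2L) {
        pa <- pairwiseAlignProteins(seqs[[1L]], seqs[[2L]])
        out <- c(pa$alignedA, pa$alignedB)
        names(out) <- names(seqs)
        return(out)
    }
    d <- .kmerDistance(seqs)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- lapply(seq_along(seqs), function(i)
        matrix(.chars(seqs[[i]]), nrow = 1L,
               dimnames = list(names(seqs)[i], NULL)))
    for (s in seq_len(nrow(hc$merge))) {
        pick <- function(k) if (k < 0L) groups[[-k]] else merged[[k]]
        if (s == 1L) merged <- list()
        merged[[s]] <- .alignProfiles(pick(hc$merge[s, 1L]),
                                      pick(hc$merge[s, 2L]),
                                      gapCost = gapCost)
    }
    final <- merged[[nrow(hc$merge)]]
    out <- apply(final, 1L, paste, collapse = "")
    out[names(seqs)]
}

#' Write a tree with bootstrap labels to Newick
#'
#' @param tree a \link[ape]{phylo} object.
#' @param path output file.
#' @export
writeTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}
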