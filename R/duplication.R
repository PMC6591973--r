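## Tandem/segmental duplication classification, Nei-Gojobori (1986) Ka/Ks
## with Jukes-Cantor correction, and molecular-clock dating.

POPULUS_CLOCK_RATE <- 9.1e-9  # synonymous substitutions / site / year

## ---- NG86 machinery ---------------------------------------------------

## Per-codon synonymous-site fractions, one row per sense codon, columns =
## codon positions. Fraction at a position = synonymous single-nucleotide
## changes / non-stop single-nucleotide changes at that position, so each
## position contributes exactly one site split between S and N.
.siteFractionTable <- local({
    tab <- NULL
    function() {
        if (!is.null(tab)) return(tab)
        bases <- c("A", "C", "G", "T")
        sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
        m <- matrix(0, length(sense), 3L, dimnames = list(sense, NULL))
        for (cod in sense) {
            aa <- CODON_TABLE[[cod]]
            ch <- .chars(cod)
            for (k in 1:3) {
                syn <- 0L; valid <- 0L
                for (b in setdiff(bases, ch[k])) {
                    mut <- ch; mut[k] <- b
                    mutc <- paste(mut, collapse = "")
                    if (mutc %in% STOP_CODONS) next
                    valid <- valid + 1L
                    if (CODON_TABLE[[mutc]] == aa) syn <- syn + 1L
                }
                m[cod, k] <- if (valid == 0L) 0 else syn / valid
            }
        }
        tab <<- m
        tab
    }
})

## syn/nonsyn step counts for one codon pair, averaged over all minimal
## mutational pathways that avoid stop codons; if every pathway passes
## through a stop, fall back to averaging over all pathways.
.pairPathCounts <- function(codA, codB) {
    chA <- .chars(codA); chB <- .chars(codB)
    diffPos <- which(chA != chB)
    nd <- length(diffPos)
    if (nd == 0L) return(c(sd = 0, nd = 0))
    if (nd == 1L) {
        syn <- CODON_TABLE[[codA]] == CODON_TABLE[[codB]]
        return(c(sd = as.numeric(syn), nd = as.numeric(!syn)))
    }
    perms <- if (nd == 2L) list(diffPos, rev(diffPos)) else {
        idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1))
        lapply(idx, function(o) diffPos[o])
    }
    evalPath <- function(order) {
        cur <- chA
        sd <- 0; ndc <- 0; valid <- TRUE
        for (p in order) {
            prev <- paste(cur, collapse = "")
            cur[p] <- chB[p]
            nxt <- paste(cur, collapse = "")
            if (nxt %in% STOP_CODONS && nxt != codB) valid <- FALSE
            if (CODON_TABLE[[prev]] == "*" || CODON_TABLE[[nxt]] == "*") {
                ## steps touching a stop contribute nothing interpretable;
                ## path will normally be discarded as invalid
                next
            }
            if (CODON_TABLE[[prev]] == CODON_TABLE[[nxt]]) sd <- sd + 1
            else ndc <- ndc + 1
        }
        list(sd = sd, nd = ndc, valid = valid)
    }
    res <- lapply(perms, evalPath)
    ok <- vapply(res, `[[`, logical(1L), "valid")
    use <- if (any(ok)) res[ok] else res
    c(sd = mean(vapply(use, `[[`, numeric(1L), "sd")),
      nd = mean(vapply(use, `[[`, numeric(1L), "nd")))
}

#' Map a protein alignment back to aligned codon pairs
#'
#' Trailing stop codons are stripped from the CDSs; gap columns of the
#' protein alignment are dropped; codon pairs containing N are dropped
#' with a count.
#'
#' @param cdsA,cdsB coding sequences (3x protein length, optional trailing
#'   stop).
#' @param proteinAln optional result of \code{\link{pairwiseAlignProteins}}
#'   on the two translations; computed if missing.
#' @return list: \code{codonsA}, \code{codonsB} (equal-length codon
#'   vectors), \code{nDroppedN}.
#' @export
codonAlign <- function(cdsA, cdsB, proteinAln = NULL) {
    strip <- function(cds) {
        cds <- toupper(cds)
        if (nchar(cds) %% 3L != 0L)
            stop("CDS length not a multiple of 3")
        cod <- .codons(cds)
        if (cod[length(cod)] %in% STOP_CODONS) cod <- cod[-length(cod)]
        cod
    }
    codA <- strip(cdsA); codB <- strip(cdsB)
    pa <- translateCds(paste(codA, collapse = ""))$protein
    pb <- translateCds(paste(codB, collapse = ""))$protein
    if (nchar(pa) != length(codA) || nchar(pb) != length(codB))
        stop("CDS/protein length mismatch")
    if (is.null(proteinAln)) proteinAln <- pairwiseAlignProteins(pa, pb)
    ca <- .chars(proteinAln$alignedA); cb <- .chars(proteinAln$alignedB)
    ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
    keep <- ca != "-" & cb != "-"
    pairsA <- codA[ia[keep]]; pairsB <- codB[ib[keep]]
    hasN <- grepl("N", pairsA, fixed = TRUE) |
        grepl("N", pairsB, fixed = TRUE)
    list(codonsA = pairsA[!hasN], codonsB = pairsB[!hasN],
         nDroppedN = sum(hasN))
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Synonymous-site fractions are computed per codon over its non-stop
#' single-nucleotide neighbors and averaged over the two sequences, so
#' S + N = 3 x compared codons exactly. Multi-nucleotide codon
#' differences are resolved by averaging synonymous/nonsynonymous step
#' counts over all minimal mutational pathways that avoid stop codons.
#' Ks = -(3/4) ln(1 - (4/3) ps), likewise Ka. The result is flagged
#' saturated when ps or pn reaches 3/4; Ka/Ks is NA when Ks is 0 or
#' saturated. Codon pairs where either codon is a stop are dropped.
#'
#' @param codonsA,codonsB equal-length codon vectors (e.g. from
#'   \code{\link{codonAlign}}).
#' @return a \linkS4class{KaKsResult}.
#' @examples
#' a <- rep("GGG", 9); b <- c(rep("GGG", 8), "GGA")
#' ng86(a, b)  # S = 9, N = 18, sd = 1, Ks ~ 0.1203
#' @export
ng86 <- function(codonsA, codonsB) {
    stopifnot(length(codonsA) == length(codonsB), length(codonsA) >= 1L)
    codonsA <- toupper(codonsA); codonsB <- toupper(codonsB)
    keep <- !(codonsA %in% STOP_CODONS) & !(codonsB %in% STOP_CODONS)
    codonsA <- codonsA[keep]; codonsB <- codonsB[keep]
    if (!length(codonsA)) stop("no comparable (non-stop) codon pairs")
    ft <- .siteFractionTable()
    sA <- sum(ft[codonsA, , drop = FALSE])
    sB <- sum(ft[codonsB, , drop = FALSE])
    S <- (sA + sB) / 2
    N <- 3 * length(codonsA) - S
    steps <- vapply(seq_along(codonsA), function(i)
        .pairPathCounts(codonsA[i], codonsB[i]), numeric(2L))
    sd <- sum(steps["sd", ]); nd <- sum(steps["nd", ])
    ps <- if (S > 0) sd / S else 0
    pn <- if (N > 0) nd / N else 0
    saturated <- ps >= 0.75 || pn >= 0.75
    jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
    Ks <- jc(ps); Ka <- jc(pn)
    ratio <- if (saturated || is.na(Ks) || is.na(Ka) || Ks == 0)
        NA_real_ else Ka / Ks
    new("KaKsResult", S = S, N = N, sd = sd, nd = nd,
        ps = min(ps, 1), pn = min(pn, 1),
        Ks = Ks, Ka = Ka, ratio = ratio, saturated = saturated,
        codons = length(codonsA))
}

#' Date a duplication event from Ks
#'
#' T = Ks / (2 lambda), with the Populus clock-like rate
#' lambda = 9.1e-9 synonymous substitutions per site per year by default.
#'
#' @param Ks synonymous substitutions per synonymous site (>= 0).
#' @param lambda clock rate in substitutions/site/year.
#' @return list: \code{years} and \code{mya}.
#' @examples
#' dateDuplication(0.182)$mya  # 10
#' @export
dateDuplication <- function(Ks, lambda = POPULUS_CLOCK_RATE) {
    if (any(is.na(Ks))) return(list(years = NA_real_, mya = NA_real_))
    if (any(Ks < 0)) stop("Ks must be non-negative")
    years <- Ks / (2 * lambda)
    list(years = years, mya = years / 1e6)
}

#' Selection class from a Ka/Ks ratio
#'
#' @param x a \linkS4class{KaKsResult} or a numeric ratio.
#' @return "purifying" (< 1), "neutral" (= 1), "positive" (> 1) or
#'   "undefined" (NA / saturated).
#' @export
selectionClass <- function(x) {
    r <- if (methods::is(x, "KaKsResult")) x@ratio else x
    if (is.na(r)) return("undefined")
    if (r < 1) "purifying" else if (r > 1) "positive" else "neutral"
}

## ---- duplication geography -------------------------------------------

#' Tandem duplication clusters
#'
#' Family genes on the same chromosome whose nearest gene boundaries lie
#' within \code{windowBp} (default 50 kb) are chained by single linkage;
#' clusters of size >= 2 are reported.
#'
#' @param members data.frame with columns gene_id, chrom, start, end
#'   (0-based half-open).
#' @param windowBp maximum boundary-to-boundary gap in bp.
#' @return list of character vectors of gene ids (each a cluster, ordered
#'   by genomic start).
#' @export
findTandem <- function(members, windowBp = 50000L) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                  colnames(members)))
    out <- list()
    for (chr in unique(members$chrom)) {
        m <- members[members$chrom == chr, , drop = FALSE]
        m <- m[order(m$start), , drop = FALSE]
        if (nrow(m) == 0L) next
        cluster <- m$gene_id[1L]
        maxEnd <- m$end[1L]
        flush <- function(cl) if (length(cl) >= 2L) out[[length(out) + 1L]] <<- cl
        for (i in seq_len(nrow(m))[-1L]) {
            gap <- m$start[i] - maxEnd
            if (gap <= windowBp) {
                cluster <- c(cluster, m$gene_id[i])
            } else {
                flush(cluster)
                cluster <- m$gene_id[i]
            }
            maxEnd <- max(maxEnd, m$end[i])
        }
        flush(cluster)
    }
    out
}

#' Read a segmental-duplication block table
#'
#' TSV with header block_id, chromA, startA, endA, chromB, startB, endB;
#' coordinates 1-based inclusive on disk, converted to 0-based half-open.
#'
#' @param path TSV file.
#' @return data.frame with 0-based half-open coordinates.
#' @importFrom utils read.delim write.table
#' @export
readBlockTable <- function(path) {
    b <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("block_id", "chromA", "startA", "endA", "chromB", "startB",
              "endB")
    stopifnot(all(need %in% colnames(b)))
    b$startA <- b$startA - 1L
    b$startB <- b$startB - 1L
    b
}

#' Segmentally duplicated gene pairs
#'
#' A pair (g1, g2) is emitted iff g1 overlaps interval A and g2 overlaps
#' interval B of the same block (or vice versa). Overlap is >= 1 bp.
#'
#' @param members data.frame with gene_id, chrom, start, end (0-based
#'   half-open).
#' @param blocks data.frame as returned by \code{\link{readBlockTable}}
#'   (0-based half-open).
#' @return data.frame gene_a, gene_b, block_id (gene_a < gene_b
#'   lexicographically; unique pairs, first supporting block kept).
#' @export
assignSegmental <- function(members, blocks) {
    ov <- function(chrom, s, e)
        members$gene_id[members$chrom == chrom &
                        members$start < e & members$end > s]
    rows <- list()
    for (i in seq_len(nrow(blocks))) {
        inA <- ov(blocks$chromA[i], blocks$startA[i], blocks$endA[i])
        inB <- ov(blocks$chromB[i], blocks$startB[i], blocks$endB[i])
        for (a in inA) for (b in inB) {
            if (a == b) next
            p <- sort(c(a, b))
            rows[[paste(p, collapse = "\r")]] <-
                data.frame(gene_a = p[1L], gene_b = p[2L],
                           block_id = blocks$block_id[i],
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(gene_a = character(), gene_b = character(),
                          block_id = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows[!duplicated(names(rows))])
    rownames(out) <- NULL
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Full duplication analysis for a family
#'
#' Classifies tandem clusters and segmental pairs, computes NG86 Ka/Ks for
#' every duplicate pair (within-cluster tandem pairs plus block-supported
#' pairs) and dates each event with T = Ks/2 lambda.
#'
#' @param members data.frame with gene_id, chrom, start, end.
#' @param cds named character vector of CDSs for the members.
#' @param blocks optional block table (0-based half-open).
#' @param windowBp tandem window, default 50 kb.
#' @param lambda clock rate.
#' @return list: \code{tandemClusters} and \code{pairs} (data.frame with
#'   gene_a, gene_b, dtype, Ka, Ks, ratio, T_mya, selection, saturated).
#' @export
duplicationAnalysis <- function(members, cds, blocks = NULL,
                                windowBp = 50000L,
                                lambda = POPULUS_CLOCK_RATE) {
    clusters <- findTandem(members, windowBp)
    pairRows <- list()
    addPair <- function(a, b, dtype) {
        p <- sort(c(a, b))
        key <- paste(p, collapse = "\r")
        if (!is.null(pairRows[[key]])) return()
        pairRows[[key]] <<- data.frame(gene_a = p[1L], gene_b = p[2L],
                                       dtype = dtype,
                                       stringsAsFactors = FALSE)
    }
    for (cl in clusters)
        for (i in seq_len(length(cl) - 1L))
            for (j in (i + 1L):length(cl)) addPair(cl[i], cl[j], "tandem")
    if (!is.null(blocks) && nrow(blocks)) {
        seg <- assignSegmental(members, blocks)
        for (i in seq_len(nrow(seg)))
            addPair(seg$gene_a[i], seg$gene_b[i], "segmental")
    }
    pairs <- if (length(pairRows)) do.call(rbind, pairRows) else
        data.frame(gene_a = character(), gene_b = character(),
                   dtype = character(), stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    if (nrow(pairs)) {
        res <- lapply(seq_len(nrow(pairs)), function(i) {
            ca <- cds[[pairs$gene_a[i]]]; cb <- cds[[pairs$gene_b[i]]]
            if (is.null(ca) || is.null(cb))
                return(data.frame(Ka = NA_real_, Ks = NA_real_,
                                  ratio = NA_real_, T_mya = NA_real_,
                                  selection = "undefined",
                                  saturated = NA))
            k <- ng86(codonAlign(ca, cb)$codonsA,
                      codonAlign(ca, cb)$codonsB)
            data.frame(Ka = k@Ka, Ks = k@Ks, ratio = k@ratio,
                       T_mya = dateDuplication(k@Ks, lambda)$mya,
                       selection = selectionClass(k),
                       saturated = k@saturated)
        })
        pairs <- cbind(pairs, do.call(rbind, res))
    }
    list(tandemClusters = clusters, pairs = pairs)
}
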