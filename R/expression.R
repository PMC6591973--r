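## Expression-matrix handling: tissue filtering, log2 heat-map clustering,
## relative qPCR expression and the two-sample significance test.

#' Read a genes x tissues expression matrix from TSV
#'
#' Genes in rows (first column = gene id), tissues in the header. Values
#' must be non-negative; missing values stay NA and are excluded from
#' statistics.
#'
#' @param path TSV file.
#' @return numeric matrix, rownames = gene ids.
#' @export
readExpressionMatrix <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
    m
}

#' Select genes highly expressed in one tissue, closed under duplication
#'
#' Genes whose value in \code{tissue} is strictly greater than
#' \code{threshold} are selected, then the set is closed under
#' duplication-pair partnership (a gene below threshold whose duplicate
#' partner passes is added). The closure is idempotent.
#'
#' @param matrix expression matrix (genes x tissues).
#' @param tissue tissue column name (e.g. \code{"XY"} for developing
#'   xylem).
#' @param threshold selection threshold, default 1000 (strict >).
#' @param pairs optional data.frame with gene_a, gene_b duplicate pairs.
#' @return character vector of selected gene ids (matrix row order).
#' @export
selectHighTissue <- function(matrix, tissue, threshold = 1000,
                             pairs = NULL) {
    if (!tissue %in% colnames(matrix)) stop("unknown tissue: ", tissue)
    v <- matrix[, tissue]
    sel <- rownames(matrix)[!is.na(v) & v > threshold]
    if (!is.null(pairs) && nrow(pairs)) {
        repeat {
            add <- unique(c(pairs$gene_b[pairs$gene_a %in% sel],
                            pairs$gene_a[pairs$gene_b %in% sel]))
            add <- setdiff(intersect(add, rownames(matrix)), sel)
            if (!length(add)) break
            sel <- c(sel, add)
        }
    }
    rownames(matrix)[rownames(matrix) %in% sel]
}

#' Log2 heat-map clustering of expression rows
#'
#' Values are transformed log2(x + 1); rows are clustered by hierarchical
#' agglomeration (average linkage, Euclidean metric by default), as in
#' standard heat-map tools. Leaf order is deterministic for a given input
#' order.
#'
#' @param matrix expression matrix.
#' @param linkage,metric clustering parameters.
#' @return list: \code{order} (row indexes, dendrogram order),
#'   \code{hclust} (the tree), \code{logValues} (transformed matrix).
#' @export
log2HeatmapCluster <- function(matrix, linkage = "average",
                               metric = "euclidean") {
    stopifnot(nrow(matrix) >= 2L)
    lv <- log2(matrix + 1)
    hc <- stats::hclust(stats::dist(lv, method = metric), method = linkage)
    list(order = hc$order, hclust = hc, logValues = lv)
}

#' Relative expression by the comparative Ct method
#'
#' 2^-(Ct_target - Ct_reference).
#'
#' @param ctTarget,ctRef cycle-threshold values (finite; vectorized).
#' @return relative expression.
#' @examples
#' ddctExpression(25, 20)  # 0.03125
#' @export
ddctExpression <- function(ctTarget, ctRef) {
    stopifnot(all(is.finite(ctTarget)), all(is.finite(ctRef)))
    2^(-(ctTarget - ctRef))
}

#' Two-sample t-test with significance stars
#'
#' Two-sided Student's t-test (pooled variance). Stars follow the usual
#' convention: p < 0.01 is \code{"**"}, p < 0.05 is \code{"*"}.
#' Degenerate input (zero variance in both groups, equal means) yields
#' p = 1.
#'
#' @param groupA,groupB numeric replicate vectors (>= 2 each).
#' @return list: \code{p}, \code{t}, \code{stars}.
#' @importFrom stats t.test
#' @export
twoSampleTest <- function(groupA, groupB) {
    stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
    if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
        if (mean(groupA) == mean(groupB))
            return(list(p = 1, t = 0, stars = ""))
        return(list(p = 0, t = Inf * sign(mean(groupA) - mean(groupB)),
                    stars = "**"))
    }
    tt <- stats::t.test(groupA, groupB, var.equal = TRUE)
    p <- tt$p.value
    stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    list(p = p, t = unname(tt$statistic), stars = stars)
}
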