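## Independent oracles used to cross-check the package implementations.
## They are deliberately written with different mechanisms (regex
## expansion, recursive pathway enumeration with seqinr's code table,
## union-find closure) than the code they validate.

## --- IUPAC scanner oracle: expand the consensus into a regex character
## --- class per position and scan with zero-width lookahead so that
## --- overlapping occurrences are all found. Subject N never matches
## --- because no class contains N.
IUPAC_ORACLE_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracleRegex <- function(consensus) {
    cls <- vapply(strsplit(consensus, "")[[1L]], function(ch) {
        s <- IUPAC_ORACLE_SETS[[ch]]
        if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
    }, character(1L))
    paste0("(?=", paste(cls, collapse = ""), ")")
}

oracleRevCompSeq <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", V = "B", D = "H", H = "D")
    paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
}

## hits as data.frame(element, start, strand) for one sequence
oracleIupacScan <- function(sequence, catalog, strands = "both") {
    rows <- list()
    for (nm in names(catalog)) {
        pats <- list("+" = oracleRegex(catalog[[nm]]))
        if (strands == "both")
            pats[["-"]] <- oracleRegex(oracleRevCompSeq(catalog[[nm]]))
        for (std in names(pats)) {
            m <- gregexpr(pats[[std]], sequence, perl = TRUE)[[1L]]
            pos <- as.integer(m[m > 0L])
            if (length(pos))
                rows[[paste0(nm, std)]] <- data.frame(
                    element = nm, start = pos, strand = std,
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(element = character(), start = integer(),
                          strand = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$element, out$start, out$strand), , drop = FALSE]
}

## canonical sortable key set for hit comparison
hitKeys <- function(df) sort(paste(df$element, df$start, df$strand))

## --- NG86 brute-force oracle: explicit neighbor enumeration and
## --- recursive pathway walking, amino acids via seqinr's translator.
oracleTranslateCodon <- function(codon) {
    seqinr::translate(strsplit(codon, "")[[1L]])
}

oracleIsStop <- function(codon) oracleTranslateCodon(codon) == "*"

oracleSiteCounts <- function(codon) {
    ch <- strsplit(codon, "")[[1L]]
    aa <- oracleTranslateCodon(codon)
    syn <- 0
    for (k in 1:3) {
        nb <- character(); sk <- 0
        for (b in c("A", "C", "G", "T")) {
            if (b == ch[k]) next
            mut <- ch; mut[k] <- b
            mc <- paste(mut, collapse = "")
            if (oracleIsStop(mc)) next
            nb <- c(nb, mc)
            if (oracleTranslateCodon(mc) == aa) sk <- sk + 1
        }
        syn <- syn + if (length(nb)) sk / length(nb) else 0
    }
    c(S = syn, N = 3 - syn)
}

## recursive enumeration of all orderings of the differing positions
oraclePathways <- function(a, b) {
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    dpos <- which(ca != cb)
    if (!length(dpos)) return(list())
    walk <- function(cur, remaining, steps) {
        if (!length(remaining)) return(list(steps))
        out <- list()
        for (p in remaining) {
            nxt <- cur; nxt[p] <- cb[p]
            out <- c(out, walk(nxt, setdiff(remaining, p),
                               c(steps, list(c(paste(cur, collapse = ""),
                                               paste(nxt, collapse = ""))))))
        }
        out
    }
    walk(ca, dpos, list())
}

oracleNg86 <- function(codonsA, codonsB) {
    keep <- !vapply(codonsA, oracleIsStop, logical(1L)) &
        !vapply(codonsB, oracleIsStop, logical(1L))
    codonsA <- codonsA[keep]; codonsB <- codonsB[keep]
    sA <- rowSums(vapply(codonsA, oracleSiteCounts, numeric(2L)))
    sB <- rowSums(vapply(codonsB, oracleSiteCounts, numeric(2L)))
    S <- (sA[["S"]] + sB[["S"]]) / 2
    N <- (sA[["N"]] + sB[["N"]]) / 2
    sd <- 0; nd <- 0
    for (i in seq_along(codonsA)) {
        paths <- oraclePathways(codonsA[i], codonsB[i])
        if (!length(paths)) next
        ok <- vapply(paths, function(p) !any(vapply(p, function(st)
            oracleIsStop(st[2L]) && st[2L] != codonsB[i], logical(1L))),
            logical(1L))
        use <- if (any(ok)) paths[ok] else paths
        contrib <- vapply(use, function(p) {
            s <- 0; n <- 0
            for (st in p) {
                if (oracleIsStop(st[1L]) || oracleIsStop(st[2L])) next
                if (oracleTranslateCodon(st[1L]) ==
                    oracleTranslateCodon(st[2L])) s <- s + 1 else n <- n + 1
            }
            c(s, n)
        }, numeric(2L))
        sd <- sd + mean(contrib[1L, ]); nd <- nd + mean(contrib[2L, ])
    }
    ps <- sd / S; pn <- nd / N
    jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
    list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
         Ks = jc(ps), Ka = jc(pn))
}

## random sense-codon CDS (no stops)
randomCodons <- function(nCodons) {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    sample(sense, nCodons, replace = TRUE)
}

## --- sequon oracle: per-position triple-window regex test
oracleSequons <- function(protein) {
    n <- nchar(protein)
    pos <- integer()
    for (i in seq_len(max(0L, n - 2L))) {
        if (grepl("^N[^P][ST]$", substr(protein, i, i + 2L))) pos <- c(pos, i)
    }
    pos
}

## --- tandem oracle: O(n^2) pairwise-gap closure with union-find
oracleTandem <- function(members, windowBp) {
    n <- nrow(members)
    parent <- seq_len(n)
    find2 <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i >= j || members$chrom[i] != members$chrom[j]) next
        gap <- max(members$start[i], members$start[j]) -
            min(members$end[i], members$end[j])
        if (gap <= windowBp) parent[find2(j)] <- find2(i)
    }
    roots <- vapply(seq_len(n), find2, integer(1L))
    cl <- split(members$gene_id, roots)
    cl <- Filter(function(x) length(x) >= 2L, cl)
    lapply(unname(cl), function(ids)
        ids[order(members$start[match(ids, members$gene_id)])])
}

## random ultrametric-free additive distance matrix from a random tree
randomAdditiveMatrix <- function(nTaxa) {
    tr <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.05, 1))
    as.matrix(ape::cophenetic.phylo(tr))
}

## random background DNA / protein
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
randomProtein <- function(n) paste(sample(names(aspfam:::RESIDUE_MASS), n,
                                          replace = TRUE), collapse = "")

## split a CDS string into codon vector
splitCodons <- function(cds) {
    n <- nchar(cds)
    substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
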