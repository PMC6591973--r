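## Family identification: perfect-ORF checks, D[TS]G catalytic motifs,
## domain-completeness spacing rule, A/B/C categorization, molecular
## weights, majority-vote localization.

## ExPASy average residue masses (Da), monoisotopic not used.
RESIDUE_MASS <- c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Open-reading-frame completeness report
#'
#' A "perfect ORF" starts with ATG, ends with a stop codon, has no internal
#' stop and a length divisible by 3.
#'
#' @param cds a nucleotide string.
#' @return list of flags: \code{startsWithAtg}, \code{endsWithStop},
#'   \code{noInternalStop}, \code{frameOk}, \code{perfect}.
#' @examples
#' checkOrf("ATGAAATAA")$perfect  # TRUE
#' @export
checkOrf <- function(cds) {
    stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) > 0L)
    cds <- toupper(cds)
    frameOk <- nchar(cds) %% 3L == 0L
    startsWithAtg <- substr(cds, 1L, 3L) == "ATG"
    endsWithStop <- FALSE
    noInternalStop <- TRUE
    if (frameOk) {
        cod <- .codons(cds)
        endsWithStop <- cod[length(cod)] %in% STOP_CODONS
        internal <- cod[-length(cod)] %in% STOP_CODONS
        noInternalStop <- !any(internal)
    }
    list(startsWithAtg = startsWithAtg, endsWithStop = endsWithStop,
         noInternalStop = noInternalStop, frameOk = frameOk,
         perfect = startsWithAtg && endsWithStop && noInternalStop && frameOk)
}

#' Find D[TS]G catalytic motifs in a protein
#'
#' Scans for the aspartic-protease catalytic triplet Asp-Thr/Ser-Gly. All
#' occurrences are reported in order of the 1-based position of the Asp.
#' \code{X} never matches.
#'
#' @param protein a protein string.
#' @return data.frame with columns \code{position} and \code{triplet}.
#' @examples
#' findCatalyticMotifs("AAADTGAAADSGAAA")$position  # 4 10
#' @export
findCatalyticMotifs <- function(protein) {
    stopifnot(is.character(protein), length(protein) == 1L)
    n <- nchar(protein)
    if (n < 3L)
        return(data.frame(position = integer(), triplet = character()))
    ch <- .chars(protein)
    i <- seq_len(n - 2L)
    hit <- ch[i] == "D" & (ch[i + 1L] == "T" | ch[i + 1L] == "S") &
        ch[i + 2L] == "G"
    pos <- i[hit]
    if (!length(pos))
        return(data.frame(position = integer(), triplet = character()))
    data.frame(position = pos,
               triplet = substring(protein, pos, pos + 2L),
               stringsAsFactors = FALSE)
}

#' Domain completeness from catalytic-motif spacing
#'
#' The catalytic domain is called complete when two D[TS]G hits are spaced
#' (Asp-to-Asp) within \code{[minGap, maxGap]} residues. The first such pair
#' (leftmost first Asp, then leftmost partner) is recorded. The generous
#' default window accommodates the ~100-residue plant-specific insert of
#' typical (category A) plant aspartic proteases.
#'
#' @param hits data.frame from \code{\link{findCatalyticMotifs}}.
#' @param minGap,maxGap allowed Asp-to-Asp spacing in residues.
#' @return list: \code{complete} flag and \code{pair} (positions of the two
#'   chosen Asp residues, or NULL).
#' @export
domainComplete <- function(hits, minGap = 100L, maxGap = 350L) {
    pos <- hits$position
    if (length(pos) >= 2L) {
        for (i in seq_len(length(pos) - 1L)) {
            for (j in seq((i + 1L), length(pos))) {
                gap <- pos[j] - pos[i]
                if (gap >= minGap && gap <= maxGap)
                    return(list(complete = TRUE, pair = c(pos[i], pos[j])))
            }
        }
    }
    list(complete = FALSE, pair = NULL)
}

## count of positions where two equal-length strings differ
.hamming <- function(a, b) sum(.chars(a) != .chars(b))

## best (position, mismatches) of a short motif against a protein;
## returns NULL when no window is within maxMismatch
.fuzzyFind <- function(protein, motif, maxMismatch = 1L) {
    n <- nchar(protein); m <- nchar(motif)
    if (n < m) return(NULL)
    mc <- .chars(motif)
    ch <- .chars(protein)
    best <- NULL
    for (i in seq_len(n - m + 1L)) {
        mm <- sum(ch[i:(i + m - 1L)] != mc)
        if (mm <= maxMismatch && (is.null(best) || mm < best$mismatches)) {
            best <- list(position = i, mismatches = mm)
            if (mm == 0L) break
        }
    }
    best
}

#' Detect a plant-specific-insert-like cysteine-rich region
#'
#' Heuristic for the saposin-like PSI: at least \code{minCys} cysteines in
#' some window of \code{window} residues lying strictly between the two
#' chosen catalytic Asp positions. When the inter-motif region is shorter
#' than \code{window}, the whole region is used as the window.
#'
#' @param protein protein string.
#' @param pair positions of the two chosen catalytic Asp residues.
#' @param minCys,window heuristic parameters.
#' @return logical.
#' @export
hasPsiInsert <- function(protein, pair, minCys = 6L, window = 120L) {
    lo <- pair[1L] + 1L; hi <- pair[2L] - 1L
    if (hi < lo) return(FALSE)
    region <- .chars(substring(protein, lo, hi))
    isC <- as.integer(region == "C")
    w <- min(window, length(isC))
    if (w == 0L) return(FALSE)
    run <- cumsum(isC)
    counts <- run[w:length(isC)] - c(0L, run)[seq_len(length(isC) - w + 1L)]
    max(counts) >= minCys
}

#' Assign an aspartic-protease category
#'
#' Sequence rules: a PSI-like cysteine-rich insert between the catalytic
#' motifs gives category A (typical AP); otherwise the presence of both
#' nucellin motifs QCDYE and GCGYDQ (each with up to
#' \code{maxMotifMismatch} substitutions) gives category B (nucellin-like);
#' everything else is category C (atypical). Precedence is A over B; a
#' protein matching both is assigned A and flagged.
#'
#' @param protein protein string.
#' @param pair chosen catalytic Asp pair from \code{\link{domainComplete}};
#'   NULL means not domain-complete and the category is "unassigned".
#' @param maxMotifMismatch substitutions tolerated in each nucellin motif.
#' @param minCys,psiWindow PSI heuristic parameters.
#' @return list: \code{category} in A/B/C/unassigned, \code{conflict} flag.
#' @export
classifyCategory <- function(protein, pair, maxMotifMismatch = 1L,
                             minCys = 6L, psiWindow = 120L) {
    if (is.null(pair))
        return(list(category = "unassigned", conflict = FALSE))
    psi <- hasPsiInsert(protein, pair, minCys = minCys, window = psiWindow)
    nuc <- !is.null(.fuzzyFind(protein, "QCDYE", maxMotifMismatch)) &&
        !is.null(.fuzzyFind(protein, "GCGYDQ", maxMotifMismatch))
    if (psi) return(list(category = "A", conflict = nuc))
    if (nuc) return(list(category = "B", conflict = FALSE))
    list(category = "C", conflict = FALSE)
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da), as computed by
#' standard pI/MW tools; reported to 2 decimals by the summary writers.
#'
#' @param protein protein string, 20-letter alphabet.
#' @return weight in daltons.
#' @examples
#' computeMw("GG")  # 132.1191
#' @export
computeMw <- function(protein) {
    stopifnot(is.character(protein), length(protein) == 1L)
    if (nchar(protein) == 0L) stop("empty protein")
    m <- RESIDUE_MASS[.chars(protein)]
    if (anyNA(m))
        stop("unknown residue(s): ",
             paste(unique(.chars(protein)[is.na(m)]), collapse = ", "))
    sum(m) + WATER_MASS
}

#' Majority vote over subcellular-localization predictions
#'
#' @param predictions character vector of labels from one or more
#'   predictors.
#' @return the strict-majority label, or \code{"ambiguous"} on a tie or
#'   when no label exceeds half the votes.
#' @examples
#' majorityVoteLocalization(c("vacuole", "vacuole", "wall"))  # "vacuole"
#' @export
majorityVoteLocalization <- function(predictions) {
    stopifnot(length(predictions) >= 1L)
    tab <- sort(table(predictions), decreasing = TRUE)
    if (tab[1L] * 2L > length(predictions)) names(tab)[1L] else "ambiguous"
}

#' Identify family members from candidate proteins and CDSs
#'
#' Runs the full rule chain per candidate: ORF completeness on the CDS,
#' catalytic-motif scan, domain-completeness spacing, category assignment
#' and molecular weight. Candidates whose catalytic domain is incomplete
#' are retained in the table with \code{domainComplete = FALSE} and
#' category "unassigned".
#'
#' @param proteins named character vector (or AAStringSet) of candidate
#'   proteins.
#' @param cds optional named character vector of the matching CDSs (for ORF
#'   flags); IDs must match.
#' @param localizations optional named list of per-gene prediction label
#'   vectors for the majority vote.
#' @param minGap,maxGap,maxMotifMismatch,minCys,psiWindow rule parameters,
#'   see the individual functions.
#' @return data.frame, one row per candidate: gene_id, orf_perfect,
#'   domain_complete, asp1, asp2, category, conflict, mw_da,
#'   localization_consensus.
#' @export
identifyFamily <- function(proteins, cds = NULL, localizations = NULL,
                           minGap = 100L, maxGap = 350L,
                           maxMotifMismatch = 1L, minCys = 6L,
                           psiWindow = 120L) {
    if (methods::is(proteins, "AAStringSet"))
        proteins <- setNames(as.character(proteins), names(proteins))
    ids <- names(proteins)
    stopifnot(!is.null(ids), !anyDuplicated(ids))
    rows <- lapply(ids, function(id) {
        p <- proteins[[id]]
        orf <- if (!is.null(cds) && id %in% names(cds))
            checkOrf(cds[[id]])$perfect else NA
        hits <- findCatalyticMotifs(p)
        dc <- domainComplete(hits, minGap, maxGap)
        cl <- classifyCategory(p, dc$pair, maxMotifMismatch, minCys,
                               psiWindow)
        loc <- if (!is.null(localizations) && id %in% names(localizations))
            majorityVoteLocalization(localizations[[id]]) else NA_character_
        data.frame(gene_id = id, orf_perfect = orf,
                   domain_complete = dc$complete,
                   asp1 = if (dc$complete) dc$pair[1L] else NA_integer_,
                   asp2 = if (dc$complete) dc$pair[2L] else NA_integer_,
                   category = cl$category, conflict = cl$conflict,
                   mw_da = round(computeMw(p), 2L),
                   localization_consensus = loc,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
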