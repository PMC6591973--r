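## N-glycosylation sequon detection and anchored-conservation calls.

#' Scan a protein for N-glycosylation sequons
#'
#' Canonical acceptor rule N-X-S/T with X != P. Overlapping sequons are
#' all reported.
#'
#' @param protein protein string.
#' @return data.frame: position (1-based index of the N), triplet,
#'   context (+/- 5 residues, clipped at the ends).
#' @examples
#' scanNSequons("MANQSV")$position  # 3
#' @export
scanNSequons <- function(protein) {
    stopifnot(is.character(protein), length(protein) == 1L)
    n <- nchar(protein)
    if (n < 3L)
        return(data.frame(position = integer(), triplet = character(),
                          context = character(), stringsAsFactors = FALSE))
    ch <- .chars(protein)
    i <- seq_len(n - 2L)
    hit <- ch[i] == "N" & ch[i + 1L] != "P" &
        (ch[i + 2L] == "S" | ch[i + 2L] == "T")
    pos <- i[hit]
    if (!length(pos))
        return(data.frame(position = integer(), triplet = character(),
                          context = character(), stringsAsFactors = FALSE))
    data.frame(position = pos,
               triplet = substring(protein, pos, pos + 2L),
               context = substring(protein, pmax(1L, pos - 5L),
                                   pmin(n, pos + 7L)),
               stringsAsFactors = FALSE)
}

#' Conserved sequon upstream of the nucellin GCGYDQ anchor
#'
#' For nucellin-like (category B) aspartic proteases, checks whether an
#' N-glycosylation sequon lies within \code{upstreamWindow} residues 5' of
#' the GCGYDQ match (located with at most one mismatch). This
#' operationalizes the conserved site reported between the invariant
#' pepsin-numbering Tyr75 and the GCGYDQ block.
#'
#' @param protein protein string.
#' @param category the protein's category; only "B" is evaluated.
#' @param upstreamWindow residues upstream of the anchor, default 60.
#' @param maxMismatch substitutions tolerated in the anchor motif.
#' @return list: \code{status} in \code{"conserved"}, \code{"absent"},
#'   \code{"anchor-missing"}, \code{"not-applicable"}; \code{position}
#'   (sequon position, or NA); \code{anchor} (anchor start, or NA).
#' @export
conservedSequonNearAnchor <- function(protein, category,
                                      upstreamWindow = 60L,
                                      maxMismatch = 1L) {
    if (!identical(category, "B"))
        return(list(status = "not-applicable", position = NA_integer_,
                    anchor = NA_integer_))
    anchor <- .fuzzyFind(protein, "GCGYDQ", maxMismatch)
    if (is.null(anchor))
        return(list(status = "anchor-missing", position = NA_integer_,
                    anchor = NA_integer_))
    seqons <- scanNSequons(protein)
    lo <- anchor$position - upstreamWindow
    inWin <- seqons$position >= lo & seqons$position < anchor$position
    if (any(inWin))
        list(status = "conserved",
             position = seqons$position[which(inWin)[1L]],
             anchor = anchor$position)
    else
        list(status = "absent", position = NA_integer_,
             anchor = anchor$position)
}
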