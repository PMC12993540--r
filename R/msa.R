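# Center-star progressive multiple alignment built from pairwise global
# alignments against a center sequence. Not guaranteed optimal; downstream
# scoring (full-length selection, conservation profiles) is always computed
# on the alignment actually built, so exactness is not required.

#' Center-star multiple sequence alignment
#'
#' Aligns every sequence globally (Needleman-Wunsch, BLOSUM62, gap open 11,
#' extend 1) against a center sequence (default: the longest, ties broken
#' lexically by id) and merges the pairwise alignments into a single
#' coordinate frame by taking, between consecutive center residues, the
#' maximum insertion length observed in any pair.
#'
#' @param seqs Named `AAStringSet` or named character vector (>= 1 sequence).
#' @param center Optional id of the center sequence.
#' @return Character matrix (rows = sequences, columns = alignment columns,
#'   gap = `"-"`), with attribute `"center"` = center id. Row order follows
#'   the input.
#' @export
center_star_msa <- function(seqs, center = NULL) {
  ss <- as_aa_set(seqs)
  if (length(ss) == 0L) stop("no sequences to align", call. = FALSE)
  if (is.null(names(ss))) names(ss) <- sprintf("seq%03d", seq_along(ss))
  if (anyDuplicated(names(ss))) stop("duplicate sequence ids", call. = FALSE)
  if (is.null(center)) {
    w <- Biostrings::width(ss)
    center <- names(ss)[order(-w, names(ss))[1L]]
  }
  stopifnot(center %in% names(ss))
  cen <- as.character(ss[[center]])
  L <- nchar(cen)
  others <- setdiff(names(ss), center)

  # Per pair: the aligned strings and the insertion count in each of the
  # L + 1 slots (before residue 1, between residues, after residue L).
  pair <- list()
  for (id in others) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = ss[[id]], subject = Biostrings::AAString(cen),
      type = "global", substitutionMatrix = scoring_matrix(),
      gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ins <- integer(L + 1L)
    slot <- 1L
    run <- 0L
    for (j in seq_along(s)) {
      if (is_gap(s[j])) {
        run <- run + 1L
      } else {
        ins[slot] <- run
        run <- 0L
        slot <- slot + 1L
      }
    }
    ins[slot] <- run
    pair[[id]] <- list(p = p, s = s, ins = ins)
  }
  max_ins <- integer(L + 1L)
  for (id in others) max_ins <- pmax(max_ins, pair[[id]]$ins)

  width <- L + sum(max_ins)
  # Column index of each center residue in the master frame.
  res_col <- cumsum(max_ins[seq_len(L)] + 1L)
  out <- matrix("-", nrow = length(ss), ncol = width,
                dimnames = list(names(ss), NULL))
  out[center, res_col] <- strsplit(cen, "")[[1]]

  for (id in others) {
    pr <- pair[[id]]
    row <- rep("-", width)
    slot <- 1L      # current inter-residue slot (1-based)
    used <- 0L      # insertions already emitted in this slot
    cres <- 0L      # center residues consumed
    for (j in seq_along(pr$s)) {
      if (is_gap(pr$s[j])) {
        # insertion: left-justified within the slot
        col <- (if (cres == 0L) 0L else res_col[cres]) + used + 1L
        row[col] <- pr$p[j]
        used <- used + 1L
      } else {
        cres <- cres + 1L
        row[res_col[cres]] <- pr$p[j]
        used <- 0L
      }
    }
    out[id, ] <- row
  }
  attr(out, "center") <- center
  out
}

# Collapse an alignment matrix back to ungapped sequences.
msa_to_seqs <- function(m) {
  apply(m, 1L, function(r) paste(r[!is_gap(r)], collapse = ""))
}
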