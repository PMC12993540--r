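# Targeted-sequencing read processing: pair joining, Phred filtering,
# barcode/primer validation and demultiplexing, and OTU clustering.

iupac_prefix_match <- function(pattern, text, offset = 0L) {
  # does IUPAC `pattern` match `text` starting at offset (0-based)?
  n <- nchar(pattern)
  if (offset + n > nchar(text)) return(FALSE)
  pt <- strsplit(pattern, "")[[1]]
  tx <- strsplit(substr(text, offset + 1L, offset + n), "")[[1]]
  sets <- iupac_sets()
  all(vapply(seq_len(n), function(i) tx[i] %in% sets[[pt[i]]], TRUE))
}

#' Join a read pair whose overlap spans the whole fragment
#'
#' The reverse read is reverse-complemented and compared base-by-base with
#' the forward read; the pair is accepted only when the full-length overlap
#' is mismatch-free. Joined quality per base is the maximum of the two
#' Phred scores.
#'
#' @param r1,r2 One-row data.frames (or lists) with `id`, `seq`, `qual`
#'   (Phred+33 string).
#' @return list: `status` (`"joined"` or `"rejected"`), `reason`, and on
#'   success `read` (one-row data.frame `id`, `seq`, `qual`).
#' @export
join_pairs <- function(r1, r2) {
  if (nchar(r1$seq) != nchar(r2$seq))
    return(list(status = "rejected", reason = "length_mismatch"))
  rc2 <- dna_revcomp(r2$seq)
  if (r1$seq != rc2) {
    c1 <- strsplit(r1$seq, "")[[1]]
    c2 <- strsplit(rc2, "")[[1]]
    return(list(status = "rejected", reason = "overlap_mismatch",
                n_mismatches = sum(c1 != c2)))
  }
  q <- pmax(phred_ints(r1$qual), rev(phred_ints(r2$qual)))
  list(status = "joined",
       read = data.frame(id = r1$id, seq = r1$seq, qual = phred_string(q),
                         stringsAsFactors = FALSE))
}

join_read_table <- function(r1, r2) {
  stopifnot(identical(r1$id, r2$id))
  joined <- list(); rejected <- list()
  for (i in seq_len(nrow(r1))) {
    res <- join_pairs(r1[i, ], r2[i, ])
    if (res$status == "joined") joined[[length(joined) + 1L]] <- res$read
    else rejected[[length(rejected) + 1L]] <- data.frame(
      id = r1$id[i], stage = "join", reason = res$reason,
      stringsAsFactors = FALSE)
  }
  list(reads = if (length(joined)) do.call(rbind, joined) else
         data.frame(id = character(0), seq = character(0), qual = character(0)),
       discards = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(id = character(0), stage = character(0),
                    reason = character(0)))
}

#' Phred quality filter
#'
#' A read is retained iff every base outside the first and last
#' `exempt_ends` positions has Phred quality at least `phred_min`
#' (read ends are exempt because they are systematically low-quality).
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param phred_min Minimum interior Phred score (default 30, i.e. scores
#'   of 29 or below are eliminated).
#' @param exempt_ends Number of exempt positions at each end.
#' @return list: `reads` (retained rows), `discards` (id/stage/reason).
#' @export
quality_filter <- function(reads, phred_min = 30L, exempt_ends = 2L) {
  keep <- vapply(seq_len(nrow(reads)), function(i) {
    q <- phred_ints(reads$qual[i])
    n <- length(q)
    interior <- q[seq_len(n) > exempt_ends & seq_len(n) <= n - exempt_ends]
    all(interior >= phred_min)
  }, TRUE)
  list(reads = reads[keep, , drop = FALSE],
       discards = if (any(!keep)) data.frame(
         id = reads$id[!keep], stage = "quality",
         reason = sprintf("interior base below Q%d", phred_min),
         stringsAsFactors = FALSE) else
         data.frame(id = character(0), stage = character(0),
                    reason = character(0)))
}

#' Demultiplex joined amplicon reads by barcode and primer
#'
#' Stage semantics: (i) reads are assigned to markers by their (degenerate)
#' forward primer, matched with zero mismatches after the barcode, and
#' their reverse primer at the 3' end; (ii) reads whose leading barcode is
#' not in the (error-detecting) barcode table are eliminated — barcodes are
#' matched exactly, so any single substitution is detected; (iii) barcode
#' and primers are stripped; (iv) reads whose stripped insert has an
#' unexpected length are eliminated. Every discard is logged with its
#' stage and reason.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (joined reads).
#' @param barcode_map data.frame `sample`, `barcode` (validated: unique,
#'   equal length, pairwise Hamming >= 2).
#' @param primer_map data.frame `marker`, `fwd_primer`, `rev_primer`
#'   (IUPAC).
#' @param expected_length Named integer vector marker -> insert length, or
#'   a named list of `c(min, max)` ranges.
#' @return list: `bins` (data.frame `id`, `sample`, `marker`, `insert`,
#'   `qual`), `discards` (data.frame `id`, `stage`, `reason`).
#' @export
demultiplex <- function(reads, barcode_map, primer_map, expected_length) {
  validate_barcodes(barcode_map$barcode)
  bl <- nchar(barcode_map$barcode[1L])
  primer_map <- primer_map[order(primer_map$marker), , drop = FALSE]
  bins <- list(); discards <- list()
  drop <- function(id, stage, reason)
    data.frame(id = id, stage = stage, reason = reason, stringsAsFactors = FALSE)
  exp_range <- function(marker) {
    v <- if (is.list(expected_length)) expected_length[[marker]] else
      expected_length[[marker]]
    if (length(v) == 1L) c(v, v) else v[1:2]
  }
  for (i in seq_len(nrow(reads))) {
    id <- reads$id[i]; s <- reads$seq[i]
    bc <- substr(s, 1L, bl)
    si <- match(bc, barcode_map$barcode)
    if (is.na(si)) {
      discards[[length(discards) + 1L]] <- drop(id, "barcode",
                                                "unknown or corrupted barcode")
      next
    }
    mk <- NA_character_; flen <- 0L; rlen <- 0L
    for (j in seq_len(nrow(primer_map))) {
      fp <- primer_map$fwd_primer[j]
      rp_rc <- dna_revcomp(primer_map$rev_primer[j])
      if (iupac_prefix_match(fp, s, offset = bl) &&
          nchar(s) >= bl + nchar(fp) + nchar(rp_rc) &&
          iupac_prefix_match(rp_rc, s, offset = nchar(s) - nchar(rp_rc))) {
        mk <- primer_map$marker[j]
        flen <- nchar(fp); rlen <- nchar(rp_rc)
        break
      }
    }
    if (is.na(mk)) {
      discards[[length(discards) + 1L]] <- drop(id, "primer",
                                                "no primer pair matches")
      next
    }
    ins <- substr(s, bl + flen + 1L, nchar(s) - rlen)
    qual <- substr(reads$qual[i], bl + flen + 1L, nchar(s) - rlen)
    rng <- exp_range(mk)
    if (nchar(ins) < rng[1L] || nchar(ins) > rng[2L]) {
      discards[[length(discards) + 1L]] <- drop(id, "length",
        sprintf("insert length %d outside [%d, %d]", nchar(ins), rng[1L], rng[2L]))
      next
    }
    bins[[length(bins) + 1L]] <- data.frame(
      id = id, sample = barcode_map$sample[si], marker = mk, insert = ins,
      qual = qual, stringsAsFactors = FALSE)
  }
  list(bins = if (length(bins)) do.call(rbind, bins) else
         data.frame(id = character(0), sample = character(0),
                    marker = character(0), insert = character(0),
                    qual = character(0)),
       discards = if (length(discards)) do.call(rbind, discards) else
         data.frame(id = character(0), stage = character(0),
                    reason = character(0)))
}

#' Greedy abundance-sorted OTU clustering
#'
#' Unique sequences are processed by descending abundance (ties: lexically
#' smaller sequence first); each is assigned to the first existing cluster
#' representative reaching at least `threshold` fraction identity in an
#' end-gap-free global alignment, else it opens a new cluster. The result
#' is independent of input order.
#'
#' @param sequences Named character vector (names = read/sequence ids;
#'   duplicated strings define abundance) or `DNAStringSet`.
#' @param threshold Fraction identity in `(0, 1]`.
#' @return list of class `"OTUSet"`: `threshold`, `representatives` (named
#'   character: rep id -> sequence), `clusters` (rep id -> member ids),
#'   `assignments` (data.frame `id`, `otu`).
#' @export
cluster_otus <- function(sequences, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("read%05d", seq_along(sequences))
  tab <- tapply(names(sequences), sequences, identity)
  uniq <- data.frame(seq = names(tab),
                     abundance = lengths(tab), stringsAsFactors = FALSE)
  uniq <- uniq[order(-uniq$abundance, uniq$seq), , drop = FALSE]
  reps <- character(0)   # representative sequences, in creation order
  rep_ids <- character(0)
  members <- list()
  for (i in seq_len(nrow(uniq))) {
    s <- uniq$seq[i]
    ids <- sort(tab[[s]])
    assigned <- FALSE
    for (r in seq_along(reps)) {
      if (otu_identity(s, reps[r]) >= threshold) {
        members[[r]] <- c(members[[r]], ids)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, ids[1L])
      members[[length(reps)]] <- ids
    }
  }
  names(members) <- rep_ids
  assignments <- data.frame(
    id = unlist(members, use.names = FALSE),
    otu = rep(rep_ids, lengths(members)), stringsAsFactors = FALSE)
  structure(list(threshold = threshold,
                 representatives = setNames(reps, rep_ids),
                 clusters = members, assignments = assignments),
            class = "OTUSet")
}

# Fraction identity of an end-gap-free ("overlap") global alignment.
otu_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 2, gapExtension = 1)
  if (nchar(pa) == 0L) return(0)
  Biostrings::nmatch(pa) / nchar(pa)
}

#' @export
print.OTUSet <- function(x, ...) {
  cat(sprintf("OTUSet: %d clusters at %.0f%% identity (%d sequences)\n",
              length(x$representatives), 100 * x$threshold,
              nrow(x$assignments)))
  invisible(x)
}
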