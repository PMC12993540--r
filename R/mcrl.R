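# Signature-based greedy clustering of a reference library against a
# metagenome: the discovery engine. A reference's "signature" is the set of
# metagenome contigs aligning to it with E below a cutoff; greedy clustering
# retains references whose signatures are minimally overlapping.

# Index the metagenome's amino-acid k-mers: kmer string -> contig indices.
kmer_index <- function(contigs, k) {
  seqs <- as.character(contigs)
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1), k:n))
  })
  idx <- rep(seq_along(seqs), lengths(km))
  split(idx, unlist(km))
}

kmer_candidates <- function(index, ref_seq, k) {
  n <- nchar(ref_seq)
  if (n < k) return(integer(0))
  kms <- unique(substring(ref_seq, 1:(n - k + 1), k:n))
  sort(unique(unlist(index[kms], use.names = FALSE)))
}

#' Compute reference signatures in a metagenome
#'
#' For every reference gene, the signature is the set of contigs whose
#' optimal local alignment against the reference reaches an E-value below
#' `e_max` (E computed against the whole metagenome as database).
#' References with empty signatures are dropped. By default a two-stage
#' search is used: only contigs sharing at least one exact amino-acid
#' `k`-mer with the reference are Smith-Waterman-aligned (a seeded search in
#' the BLAST mold; at the divergences this pipeline targets, a qualifying
#' homolog without an exact 5-mer match is vanishingly unlikely).
#'
#' @param library A `ReferenceLibrary` (or named `AAStringSet`).
#' @param metagenome A `Metagenome` (or named `AAStringSet` of contigs).
#' @param e_max Signature E-value cutoff (strict `<`).
#' @param prefilter Use the exact k-mer seed prefilter.
#' @param k Seed length (amino acids).
#' @return Named list of class `"SignatureMap"`; one element per reference
#'   with a non-empty signature: `ref_id`, `contig_ids`, `representative`
#'   (contig with the lowest E-value), `best_e`, and named `e_values`.
#' @export
compute_signatures <- function(library, metagenome, e_max = 0.001,
                               prefilter = TRUE, k = 5L) {
  refs <- if (is(library, "ReferenceLibrary")) library$seqs else as_aa_set(library)
  contigs <- if (is(metagenome, "Metagenome")) metagenome$contigs else
    as_aa_set(metagenome)
  if (length(refs) == 0L || length(contigs) == 0L)
    stop("library and metagenome must be non-empty", call. = FALSE)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("c%05d", seq_along(contigs))
  n_db <- sum(Biostrings::width(contigs))
  N <- length(contigs)
  index <- if (prefilter) kmer_index(contigs, k) else NULL

  out <- list()
  for (i in seq_along(refs)) {
    rid <- names(refs)[i]
    rseq <- as.character(refs[[i]])
    cand <- if (prefilter) kmer_candidates(index, rseq, k) else seq_len(N)
    if (!length(cand)) next
    scores <- local_scores(contigs[cand], rseq)
    ev <- karlin_evalue(scores, query_len = nchar(rseq), db_residues = n_db,
                        n_seqs = N)
    qual <- which(ev < e_max)
    if (!length(qual)) next
    ids <- names(contigs)[cand[qual]]
    evq <- setNames(ev[qual], ids)
    ord <- order(evq, names(evq))
    out[[rid]] <- list(ref_id = rid, contig_ids = ids,
                       representative = names(evq)[ord[1L]],
                       best_e = unname(evq[ord[1L]]),
                       e_values = evq)
  }
  structure(out, class = "SignatureMap")
}

#' Stringent overlap between two signatures
#'
#' Fraction of shared contigs measured against the smaller signature:
#' `|a %intersect% b| / min(|a|, |b|)`. Two references overlap "regardless
#' of the reference sequence" when this fraction exceeds the threshold,
#' i.e. when more than the threshold fraction of either signature is shared.
#'
#' @param a,b Signatures (elements of a `SignatureMap`) or character vectors
#'   of contig ids.
#' @return Overlap fraction in `[0, 1]`.
#' @export
#' @examples
#' stringent_overlap(c("c1", "c2", "c3", "c4"), c("c3", "c4", "c5"))
stringent_overlap <- function(a, b) {
  ca <- if (is.list(a)) a$contig_ids else a
  cb <- if (is.list(b)) b$contig_ids else b
  if (!length(ca) || !length(cb))
    stop("signatures must be non-empty", call. = FALSE)
  length(intersect(ca, cb)) / min(length(ca), length(cb))
}

#' Greedy clustering of references by signature overlap
#'
#' Repeatedly selects the unprocessed reference with the largest signature
#' (ties: lowest best E-value, then lexical ref id), retains it, and marks
#' as eclipsed every unprocessed reference whose stringent overlap with it
#' exceeds `overlap_threshold`. The retained set has pairwise stringent
#' overlap `<= overlap_threshold` and is independent of input order.
#'
#' @param signature_map A `SignatureMap` from [compute_signatures()].
#' @param overlap_threshold Overlap above which a reference is eclipsed.
#' @return list of class `"ClusterResult"`: `retained` (ordered ref ids),
#'   `signatures` (the input map), `provenance` (retained ref -> character
#'   vector of refs it eclipsed) and `eclipsed_by` (named vector).
#' @export
cluster_references <- function(signature_map, overlap_threshold = 0.5) {
  if (!length(signature_map)) stop("signature_map must be non-empty", call. = FALSE)
  sizes <- vapply(signature_map, function(s) length(s$contig_ids), 0L)
  best <- vapply(signature_map, function(s) s$best_e, 0)
  ids <- vapply(signature_map, function(s) s$ref_id, "")
  ord <- order(-sizes, best, ids)
  queue <- ids[ord]
  eclipsed_by <- setNames(rep(NA_character_, length(queue)), queue)
  retained <- character(0)
  provenance <- list()
  for (r in queue) {
    if (!is.na(eclipsed_by[[r]])) next
    retained <- c(retained, r)
    provenance[[r]] <- character(0)
    later <- queue[match(r, queue) < seq_along(queue)]
    for (s in later) {
      if (!is.na(eclipsed_by[[s]])) next
      ov <- stringent_overlap(signature_map[[r]], signature_map[[s]])
      if (ov > overlap_threshold) {
        eclipsed_by[[s]] <- r
        provenance[[r]] <- c(provenance[[r]], s)
      }
    }
  }
  structure(list(retained = retained, signatures = signature_map,
                 provenance = provenance,
                 eclipsed_by = eclipsed_by[!is.na(eclipsed_by)],
                 overlap_threshold = overlap_threshold),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d references retained, %d eclipsed (overlap > %g)\n",
              length(x$retained), length(x$eclipsed_by), x$overlap_threshold))
  invisible(x)
}
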