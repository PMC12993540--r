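# The marker-discovery filtering cascade: annotation/signature/identity
# gates, cross-dataset conservation screen, redundancy removal, and
# full-length marker selection.

#' Filter clustered references to marker candidates
#'
#' Retains references whose annotation matches `annotation_pattern`
#' (case-insensitive regular expression), whose signature holds at least
#' `min_signature` contigs, and which share at least `min_identity` percent
#' identical residues when locally aligned against their representative
#' contig (the contig with the lowest E-value in their signature).
#'
#' @param result A `ClusterResult` from [cluster_references()].
#' @param library The `ReferenceLibrary` used to compute the signatures.
#' @param metagenome The `Metagenome` the signatures were computed in.
#' @param annotation_pattern Regular expression matched against the
#'   reference annotation (default `"terminase"`).
#' @param min_signature Minimum signature size.
#' @param min_identity Minimum percent identity to the representative contig.
#' @return data.frame of marker candidates: `ref_id`, `annotation`,
#'   `signature_size`, `rep_contig_id`, `identity_to_rep`, `fragment_seq`
#'   (the representative contig's sequence — the candidate marker fragment).
#' @export
filter_candidates <- function(result, library, metagenome,
                              annotation_pattern = "terminase",
                              min_signature = 5L, min_identity = 10) {
  stopifnot(is(result, "ClusterResult"), is(library, "ReferenceLibrary"))
  contigs <- if (is(metagenome, "Metagenome")) metagenome$contigs else
    as_aa_set(metagenome)
  rows <- list()
  for (rid in result$retained) {
    sig <- result$signatures[[rid]]
    ann <- library$genes$annotation[match(rid, library$genes$ref_id)]
    if (is.na(ann) || !grepl(annotation_pattern, ann, ignore.case = TRUE)) next
    if (length(sig$contig_ids) < min_signature) next
    rep_id <- sig$representative
    rep_seq <- as.character(contigs[[rep_id]])
    hit <- align_local(as.character(library$seqs[[rid]]), rep_seq,
                       query_id = rid, subject_id = rep_id)
    ident <- if (is.null(hit)) 0 else hit$percent_identity
    if (ident < min_identity) next
    rows[[length(rows) + 1L]] <- data.frame(
      ref_id = rid, annotation = ann,
      signature_size = length(sig$contig_ids),
      rep_contig_id = rep_id, identity_to_rep = ident,
      fragment_seq = rep_seq, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_id = character(0), annotation = character(0),
               signature_size = integer(0), rep_contig_id = character(0),
               identity_to_rep = numeric(0), fragment_seq = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-dataset conservation screen
#'
#' Retains candidates whose marker fragment reaches at least `min_identity`
#' percent identity in a significant alignment (`E <= e_max`) against any
#' contig of an independent second metagenome. The significance gate keeps
#' chance short high-identity local alignments from qualifying.
#'
#' @param candidates data.frame from [filter_candidates()].
#' @param second_metagenome A `Metagenome` (or `AAStringSet`) from an
#'   independent dataset.
#' @param min_identity Minimum percent identity in the second dataset.
#' @param e_max Significance gate for qualifying alignments.
#' @return The retained subset of `candidates` with an extra
#'   `cross_identity` column (best qualifying identity).
#' @export
cross_dataset_screen <- function(candidates, second_metagenome,
                                 min_identity = 75, e_max = 0.001) {
  contigs <- if (is(second_metagenome, "Metagenome")) second_metagenome$contigs
    else as_aa_set(second_metagenome)
  keep <- logical(nrow(candidates))
  cross <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    hits <- search_database(candidates$fragment_seq[i], contigs, e_max = e_max,
                            query_id = candidates$ref_id[i])
    if (nrow(hits)) {
      cross[i] <- max(hits$percent_identity)
      keep[i] <- cross[i] >= min_identity
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out$cross_identity <- cross[keep]
  rownames(out) <- NULL
  out
}

#' Remove redundant (mutually homologous) candidates
#'
#' All-vs-all local alignment of the candidate fragments; any pair with
#' `E <= e_max` is homologous. Candidates are grouped into connected
#' components of the homology graph and one representative is kept per
#' component: the candidate with the largest signature (ties broken by
#' lexical ref id).
#'
#' @param candidates data.frame of candidates (>= 1 row).
#' @param e_max Homology E-value threshold.
#' @return The surviving subset, with attribute `"groups"` mapping each
#'   survivor to the ref ids of its component.
#' @export
remove_redundant <- function(candidates, e_max = 0.001) {
  n <- nrow(candidates)
  if (n < 1L) stop("need at least one candidate", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- candidates$fragment_seq[i]
      b <- candidates$fragment_seq[j]
      hit <- align_local(a, b)
      if (!is.null(hit)) {
        ev <- karlin_evalue(hit$raw_score, query_len = nchar(a),
                            db_residues = nchar(b))
        if (ev <= e_max) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- connected_components(adj)
  survivors <- integer(0)
  groups <- list()
  for (g in sort(unique(comp))) {
    members <- which(comp == g)
    pick <- members[order(-candidates$signature_size[members],
                          candidates$ref_id[members])][1L]
    survivors <- c(survivors, pick)
    groups[[candidates$ref_id[pick]]] <- candidates$ref_id[members]
  }
  survivors <- sort(survivors)
  out <- candidates[survivors, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  out
}

# Connected components of an undirected adjacency matrix (BFS).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Select a full-length marker sequence for a candidate fragment
#'
#' Collects from every database the sequences reaching at least
#' `min_identity` percent identity to the candidate fragment, builds a
#' center-star multiple alignment of the collected set, and returns the
#' sequence maximising the equal-database-weighted mean percent identity to
#' all other collected sequences, where alignment columns in which a
#' sequence has a gap (including end gaps from shortness) contribute zero —
#' so shorter sequences are penalised. Ties: longer sequence, then lexical
#' id.
#'
#' The per-pair identity on the common alignment is
#' `100 * #\{columns with identical non-gap residues\} / #\{columns where
#' either sequence is non-gap\}`; per-database means are averaged with equal
#' weight per database, so large databases do not dominate.
#'
#' @param candidate One-row data.frame (a row of the candidate table) or a
#'   list with `ref_id` and `fragment_seq`.
#' @param databases Named list of `AAStringSet`s (full-length sequence
#'   collections, e.g. reference databases from different studies).
#' @param min_identity Collection gate (percent identity to the fragment).
#' @param band Expected full-length band in aa; membership is recorded as
#'   `in_band` on the result.
#' @return list of class `"FullLengthMarker"`: `name`, `sequence`,
#'   `source_db`, `source_id`, `mean_weighted_identity`, `length_aa`,
#'   `in_band`, `n_collected`; or a list with `status = "no_qualifying_sequence"`
#'   when no database sequence passes the gate (reported, not raised).
#' @export
select_full_length <- function(candidate, databases, min_identity = 70,
                               band = c(400, 800)) {
  frag <- if (is.data.frame(candidate)) candidate$fragment_seq[1L] else
    candidate$fragment_seq
  name <- if (is.data.frame(candidate)) candidate$ref_id[1L] else candidate$ref_id
  stopifnot(is.list(databases), length(names(databases)) == length(databases))

  collected <- character(0); src <- character(0)
  for (db_name in names(databases)) {
    db <- as_aa_set(databases[[db_name]])
    if (is.null(names(db))) names(db) <- sprintf("%s_%04d", db_name, seq_along(db))
    for (i in seq_along(db)) {
      hit <- align_local(frag, as.character(db[[i]]))
      if (!is.null(hit) && hit$percent_identity >= min_identity) {
        id <- paste0(db_name, "::", names(db)[i])
        collected[id] <- as.character(db[[i]])
        src[id] <- db_name
      }
    }
  }
  if (!length(collected))
    return(list(status = "no_qualifying_sequence", name = name))

  if (length(collected) == 1L) {
    best_id <- names(collected)[1L]
    score <- 100
  } else {
    msa <- center_star_msa(collected)
    score_tab <- score_weighted_identity(msa, src)
    ord <- order(-score_tab, -nchar(collected), names(collected))
    best_id <- names(collected)[ord[1L]]
    score <- score_tab[[best_id]]
  }
  seq <- unname(collected[best_id])
  structure(list(name = name, sequence = seq, source_db = unname(src[best_id]),
                 source_id = sub("^[^:]*::", "", best_id),
                 mean_weighted_identity = unname(score),
                 length_aa = nchar(seq),
                 in_band = nchar(seq) >= band[1L] && nchar(seq) <= band[2L],
                 n_collected = length(collected)),
            class = "FullLengthMarker")
}

# Equal-database-weighted mean identity of each row of an alignment matrix
# against the other rows; gap columns of the scored row contribute 0.
score_weighted_identity <- function(msa, src) {
  ids <- rownames(msa)
  out <- setNames(numeric(length(ids)), ids)
  for (s in ids) {
    per_db <- c()
    for (db in unique(src)) {
      others <- ids[src[ids] == db & ids != s]
      if (!length(others)) next
      vals <- vapply(others, function(t) pair_column_identity(msa[s, ], msa[t, ]), 0)
      per_db <- c(per_db, mean(vals))
    }
    out[s] <- if (length(per_db)) mean(per_db) else 100
  }
  out
}

pair_column_identity <- function(a, b) {
  either <- !(is_gap(a) & is_gap(b))
  match <- a == b & !is_gap(a)
  if (!any(either)) return(0)
  100 * sum(match) / sum(either)
}

#' @export
print.FullLengthMarker <- function(x, ...) {
  cat(sprintf("FullLengthMarker '%s': %d aa from %s (weighted identity %.1f%%%s)\n",
              x$name, x$length_aa, x$source_db, x$mean_weighted_identity,
              if (x$in_band) "" else "; outside full-length band"))
  invisible(x)
}
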