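# Homolog collection from isolate databases, OTU consolidation of isolates,
# and construction/export of alignment matrices for external phylogenetics
# tools (network/tree estimation itself is out of scope).

#' Collect close marker homologs from an isolate database
#'
#' Retains isolate sequences whose best local alignment against the marker
#' reaches at least `min_identity` percent identity across at least
#' `min_coverage` of the marker length.
#'
#' @param marker A `FullLengthMarker` or protein sequence.
#' @param isolate_db Named `AAStringSet` of isolate protein sequences.
#' @param metadata Optional data.frame with `id`, `species`, `body_region`,
#'   `health_status`, `host` columns (curated labels, consumed as given —
#'   never inferred). Rows are matched to `isolate_db` by `id`.
#' @param min_identity Percent identity gate.
#' @param min_coverage Fraction of the marker length the alignment must
#'   span.
#' @return data.frame of hits: `id`, `percent_identity`, `coverage`,
#'   `span_aa`, `seq`, plus any metadata columns.
#' @export
collect_homologs <- function(marker, isolate_db, metadata = NULL,
                             min_identity = 70, min_coverage = 0.90) {
  db <- as_aa_set(isolate_db)
  if (length(db) == 0L) stop("isolate database must be non-empty", call. = FALSE)
  if (is.null(names(db))) names(db) <- sprintf("iso%04d", seq_along(db))
  mseq <- marker_seq(marker)
  mlen <- nchar(mseq)
  rows <- list()
  for (i in seq_along(db)) {
    hit <- align_local(mseq, as.character(db[[i]]),
                       query_id = marker_name(marker), subject_id = names(db)[i])
    if (is.null(hit)) next
    coverage <- (hit$query_end - hit$query_start) / mlen
    if (hit$percent_identity >= min_identity && coverage >= min_coverage) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = names(db)[i], percent_identity = hit$percent_identity,
        coverage = coverage, span_aa = hit$span_aa,
        seq = as.character(db[[i]]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), percent_identity = numeric(0),
               coverage = numeric(0), span_aa = integer(0),
               seq = character(0), stringsAsFactors = FALSE)
  if (!is.null(metadata) && nrow(out)) {
    keep <- setdiff(names(metadata), "seq")
    out <- merge(out, metadata[, keep, drop = FALSE], by = "id",
                 all.x = TRUE, sort = TRUE)
  }
  attr(out, "marker_length") <- mlen
  rownames(out) <- NULL
  out
}

#' Consolidate isolate hits into per-group OTU representatives
#'
#' Within each metadata group (default: species x body region x
#' health-related status; use `group_keys = "species"` for non-human
#' isolates), isolates are clustered by single linkage at amino-acid
#' distance `<= otu_threshold`, counting only pairwise alignments spanning
#' at least `min_span` of the marker length (pairs with shorter alignments
#' are treated as unlinked). One representative is kept per cluster: the
#' longest sequence, ties broken lexically by id. Records with missing
#' metadata are routed to an `"unassigned"` group and logged.
#'
#' @param hits data.frame from [collect_homologs()] (needs `id`, `seq` and
#'   the grouping columns).
#' @param otu_threshold Maximum within-cluster distance (1 - identity).
#' @param min_span Minimum alignment span as a fraction of marker length.
#' @param group_keys Metadata columns defining groups.
#' @param marker_length Marker length (defaults to the attribute left by
#'   [collect_homologs()]).
#' @return data.frame of representatives (`id`, `group`, `otu`, `n_members`,
#'   `seq`, ...), with attribute `"unassigned"` listing re-routed ids.
#' @export
consolidate_isolates <- function(hits, otu_threshold = 0.03, min_span = 0.98,
                                 group_keys = c("species", "body_region",
                                                "health_status"),
                                 marker_length = NULL) {
  if (!nrow(hits)) return(hits)
  mlen <- marker_length %||% attr(hits, "marker_length")
  if (is.null(mlen)) mlen <- max(nchar(hits$seq))
  missing_keys <- setdiff(group_keys, names(hits))
  if (length(missing_keys))
    stop("hits lack grouping columns: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  key_vals <- hits[, group_keys, drop = FALSE]
  incomplete <- apply(key_vals, 1L, function(r) any(is.na(r) | r == ""))
  group <- ifelse(incomplete, "unassigned",
                  apply(key_vals, 1L, paste, collapse = "|"))
  unassigned <- hits$id[incomplete]

  out <- list()
  for (g in sort(unique(group))) {
    sub <- hits[group == g, , drop = FALSE]
    comp <- otu_components(sub$seq, sub$id, otu_threshold, min_span, mlen)
    for (cl in sort(unique(comp))) {
      members <- which(comp == cl)
      pick <- members[order(-nchar(sub$seq[members]), sub$id[members])][1L]
      row <- sub[pick, , drop = FALSE]
      row$group <- g
      row$otu <- sprintf("%s#%d", g, cl)
      row$n_members <- length(members)
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  attr(out, "marker_length") <- mlen
  out
}

# Single-linkage components at distance <= threshold; pairs whose best
# local alignment spans < min_span * marker_length are unlinked.
otu_components <- function(seqs, ids, threshold, min_span, marker_length) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        hit <- align_local(seqs[i], seqs[j])
        if (is.null(hit)) next
        if (hit$span_aa >= min_span * marker_length &&
            (1 - hit$percent_identity / 100) <= threshold)
          adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  connected_components(adj)
}

#' Build a phylogenetic alignment matrix for a marker
#'
#' Applies the inclusion rules (best local alignment against the marker
#' spanning at least `min_span_aa` alignment columns at `>= min_identity`
#' percent identity), then builds a center-star multiple alignment of the
#' marker, the passing metagenome-derived sequences and the isolate
#' representatives, with the marker as center.
#'
#' @param marker A `FullLengthMarker` or named protein sequence.
#' @param metagenome_seqs Named `AAStringSet`/character of metagenome-derived
#'   sequences (may be empty).
#' @param representatives data.frame from [consolidate_isolates()] (or any
#'   data.frame with `id` and `seq`), may be `NULL`.
#' @param min_span_aa,min_identity Inclusion rules.
#' @param provenance Optional data.frame (`id` + annotation columns) merged
#'   into the per-row provenance.
#' @return list of class `"PhyloMatrix"`: `marker_name`, `alignment`
#'   (character matrix), `n_columns`, `provenance`, `coverage_fraction`
#'   (mean fraction of the marker row covered by non-gap columns of each
#'   row), `excluded` (ids failing inclusion); or a list with
#'   `status = "refused"` when fewer than 4 sequences qualify (network and
#'   tree tools need at least 4 taxa).
#' @export
build_matrix <- function(marker, metagenome_seqs = NULL, representatives = NULL,
                         min_span_aa = 400L, min_identity = 70,
                         provenance = NULL) {
  mseq <- marker_seq(marker)
  mname <- marker_name(marker)
  cand <- character(0); src <- character(0)
  if (!is.null(metagenome_seqs) && length(metagenome_seqs)) {
    ms <- as_aa_set(metagenome_seqs)
    if (is.null(names(ms))) names(ms) <- sprintf("mg%04d", seq_along(ms))
    cand <- c(cand, setNames(as.character(ms), names(ms)))
    src <- c(src, setNames(rep("metagenome", length(ms)), names(ms)))
  }
  if (!is.null(representatives) && nrow(representatives)) {
    cand <- c(cand, setNames(representatives$seq, representatives$id))
    src <- c(src, setNames(rep("isolate", nrow(representatives)),
                           representatives$id))
  }
  if (anyDuplicated(names(cand)))
    stop("duplicate sequence ids in matrix input", call. = FALSE)
  pass <- logical(length(cand))
  for (i in seq_along(cand)) {
    hit <- align_local(mseq, cand[[i]])
    pass[i] <- !is.null(hit) && hit$span_aa >= min_span_aa &&
      hit$percent_identity >= min_identity
  }
  included <- cand[pass]
  if (length(included) + 1L < 4L)
    return(list(status = "refused", marker_name = mname,
                n_included = length(included) + 1L,
                reason = "fewer than 4 sequences pass the inclusion rules"))
  seqs <- c(setNames(mseq, mname), included)
  msa <- center_star_msa(seqs, center = mname)
  marker_row <- msa[mname, ]
  cover <- vapply(rownames(msa), function(r)
    sum(!is_gap(msa[r, ]) & !is_gap(marker_row)) / sum(!is_gap(marker_row)), 0)
  prov <- data.frame(id = rownames(msa),
                     source = c("marker", unname(src[names(included)])),
                     coverage = unname(cover), stringsAsFactors = FALSE)
  if (!is.null(provenance))
    prov <- merge(prov, provenance, by = "id", all.x = TRUE, sort = FALSE)
  prov <- prov[match(rownames(msa), prov$id), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(marker_name = mname, alignment = msa,
                 n_columns = ncol(msa), provenance = prov,
                 coverage_fraction = mean(cover[-1L]),
                 excluded = names(cand)[!pass]),
            class = "PhyloMatrix")
}

#' @export
print.PhyloMatrix <- function(x, ...) {
  cat(sprintf("PhyloMatrix '%s': %d sequences x %d columns (mean marker coverage %.1f%%)\n",
              x$marker_name, nrow(x$alignment), x$n_columns,
              100 * x$coverage_fraction))
  invisible(x)
}

#' Export a phylogenetic matrix
#'
#' Writes the alignment as aligned FASTA, relaxed PHYLIP, or NEXUS (protein
#' data block; per-taxon provenance is carried as comments in the taxa
#' block). [import_matrix()] reads all three back losslessly (sequence
#' content and order).
#'
#' @param matrix A `PhyloMatrix`.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, format = c("fasta", "phylip", "nexus"), path) {
  stopifnot(is(matrix, "PhyloMatrix"))
  format <- match.arg(format)
  m <- matrix$alignment
  rows <- apply(m, 1L, paste, collapse = "")
  ids <- rownames(m)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(rows, ids)),
                                path)
  } else if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf(" %d %d", length(ids), ncol(m)), con)
    writeLines(sprintf("%s  %s", ids, rows), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    prov <- matrix$provenance
    notes <- vapply(seq_along(ids), function(i) {
      extra <- prov[i, setdiff(names(prov), "id"), drop = FALSE]
      paste(sprintf("%s=%s", names(extra), vapply(extra, as.character, "")),
            collapse = " ")
    }, "")
    writeLines(c("#NEXUS", "", "BEGIN TAXA;",
                 sprintf("  DIMENSIONS NTAX=%d;", length(ids)),
                 "  TAXLABELS",
                 sprintf("    %s [%s]", ids, notes),
                 "  ;", "END;", "", "BEGIN CHARACTERS;",
                 sprintf("  DIMENSIONS NCHAR=%d;", ncol(m)),
                 "  FORMAT DATATYPE=PROTEIN GAP=- MISSING=?;",
                 "  MATRIX",
                 sprintf("    %s  %s", ids, rows),
                 "  ;", "END;"), con)
  }
  invisible(path)
}

#' Import an exported phylogenetic matrix
#'
#' @param path File written by [export_matrix()].
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return Named character vector of aligned rows, in file order.
#' @export
import_matrix <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    return(setNames(as.character(ss), names(ss)))
  }
  lines <- readLines(path)
  if (format == "phylip") {
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    return(setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L)))
  }
  inside <- FALSE
  out <- character(0)
  for (ln in lines) {
    t <- trimws(ln)
    if (grepl("^MATRIX$", t)) { inside <- TRUE; next }
    if (inside && t == ";") break
    if (inside && nzchar(t)) {
      parts <- strsplit(t, "[[:space:]]+")[[1]]
      out[parts[1L]] <- parts[2L]
    }
  }
  out
}
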