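# Presence calling of markers in metagenomes and prevalence/co-occurrence
# summaries across subjects and habitats.

#' Presence-call thresholds
#'
#' A marker is *present* in a metagenome when any alignment spanning at
#' least `present_min_span` aa exceeds `present_min_identity` percent
#' identity; it is *absent* when no alignment spanning at least
#' `absent_min_span` aa exceeds `absent_max_identity` (the permissive
#' absence rule guards against calling low-coverage samples absent);
#' otherwise the call is *indeterminate*.
#'
#' @param present_min_span,present_min_identity Presence rule (aa, percent).
#' @param absent_min_span,absent_max_identity Absence rule (aa, percent).
#' @return list of class `"presence_thresholds"`.
#' @export
presence_thresholds <- function(present_min_span = 150L,
                                present_min_identity = 70,
                                absent_min_span = 75L,
                                absent_max_identity = 40) {
  structure(list(present_min_span = present_min_span,
                 present_min_identity = present_min_identity,
                 absent_min_span = absent_min_span,
                 absent_max_identity = absent_max_identity),
            class = "presence_thresholds")
}

marker_seq <- function(marker) {
  if (is(marker, "FullLengthMarker")) return(marker$sequence)
  as.character(as_aa_string(marker))
}

marker_name <- function(marker, default = "marker") {
  if (is(marker, "FullLengthMarker")) return(marker$name)
  if (!is.null(names(marker))) return(names(marker)[1])
  default
}

# Best local alignment of the marker against every contig: span + identity.
scan_metagenome <- function(marker, metagenome) {
  contigs <- if (is(metagenome, "Metagenome")) metagenome$contigs else
    as_aa_set(metagenome)
  if (length(contigs) == 0L)
    return(data.frame(contig_id = character(0), span_aa = integer(0),
                      percent_identity = numeric(0)))
  pa <- Biostrings::pairwiseAlignment(
    pattern = contigs, subject = Biostrings::AAString(marker_seq(marker)),
    type = "local", substitutionMatrix = scoring_matrix(),
    gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(pa)
  keep <- sc > 0
  data.frame(contig_id = names(contigs)[keep],
             span_aa = nchar(pa)[keep],
             percent_identity = 100 * Biostrings::nmatch(pa)[keep] / nchar(pa)[keep],
             stringsAsFactors = FALSE)
}

#' Three-state presence call of a marker in a metagenome
#'
#' @param marker A `FullLengthMarker` or protein sequence.
#' @param metagenome A `Metagenome` or `AAStringSet` of contigs.
#' @param thresholds A [presence_thresholds()] object.
#' @return One-row data.frame: `marker`, `metagenome_id`, `state`
#'   (`"present"`, `"absent"` or `"indeterminate"`), `max_identity` (best
#'   percent identity among alignments meeting the presence span; `NA` when
#'   none) and `best_span_aa`.
#' @export
call_presence <- function(marker, metagenome, thresholds = presence_thresholds()) {
  th <- thresholds
  scan <- scan_metagenome(marker, metagenome)
  long <- scan[scan$span_aa >= th$present_min_span, , drop = FALSE]
  present <- any(long$percent_identity > th$present_min_identity)
  weak <- scan[scan$span_aa >= th$absent_min_span, , drop = FALSE]
  absent <- !any(weak$percent_identity > th$absent_max_identity)
  state <- if (present) "present" else if (absent) "absent" else "indeterminate"
  data.frame(
    marker = marker_name(marker),
    metagenome_id = if (is(metagenome, "Metagenome")) metagenome$id else NA_character_,
    state = state,
    max_identity = if (nrow(long)) max(long$percent_identity) else NA_real_,
    best_span_aa = if (nrow(scan)) max(scan$span_aa) else 0L,
    stringsAsFactors = FALSE)
}

# Presence calls of one marker across all metagenomes of a cohort.
compute_presence_calls <- function(marker, cohort, thresholds = presence_thresholds()) {
  stopifnot(is(cohort, "Cohort"))
  calls <- lapply(cohort$metagenomes, function(mg)
    call_presence(marker, mg, thresholds))
  calls <- do.call(rbind, calls)
  cbind(cohort$design[match(calls$metagenome_id, cohort$design$metagenome_id),
                      c("subject", "habitat", "visit")],
        calls, row.names = NULL)
}

#' Marker prevalence matrix across cohort groups
#'
#' The cell for marker x group is the maximum percent identity (over
#' alignments meeting the span threshold) across all metagenomes of the
#' group; a group is positive when its cell exceeds `identity_threshold`.
#' Prevalence per marker is the fraction of groups with data that are
#' positive.
#'
#' @param markers Named list of `FullLengthMarker`s (or a named character
#'   vector / `AAStringSet` of marker sequences).
#' @param cohort A `Cohort`.
#' @param grouping `"subject"` (presence anywhere in the subject) or
#'   `"subject_habitat"`.
#' @param identity_threshold Percent identity a group's cell must exceed.
#' @param min_span Minimum alignment span (aa) entering the cells; recorded
#'   in the result metadata.
#' @return list of class `"PrevalenceMatrix"`: `values` (markers x groups
#'   max-identity matrix, `NA` = no qualifying alignment), `positive`
#'   (logical layer), `prevalence` (named vector), plus the grouping and
#'   thresholds used.
#' @export
prevalence_matrix <- function(markers, cohort,
                              grouping = c("subject", "subject_habitat"),
                              identity_threshold = 70, min_span = 150L) {
  grouping <- match.arg(grouping)
  stopifnot(is(cohort, "Cohort"))
  markers <- as_marker_list(markers)
  design <- cohort$design
  group_of <- if (grouping == "subject") design$subject else
    paste(design$subject, design$habitat, sep = ":")
  groups <- sort(unique(group_of))
  vals <- matrix(NA_real_, nrow = length(markers), ncol = length(groups),
                 dimnames = list(names(markers), groups))
  for (mk in names(markers)) {
    for (i in seq_len(nrow(design))) {
      mg <- cohort$metagenomes[[design$metagenome_id[i]]]
      scan <- scan_metagenome(markers[[mk]], mg)
      scan <- scan[scan$span_aa >= min_span, , drop = FALSE]
      if (!nrow(scan)) next
      g <- group_of[i]
      vals[mk, g] <- max(vals[mk, g], max(scan$percent_identity), na.rm = TRUE)
    }
  }
  positive <- !is.na(vals) & vals > identity_threshold
  prevalence <- rowMeans(positive)
  structure(list(values = vals, positive = positive, prevalence = prevalence,
                 grouping = grouping, identity_threshold = identity_threshold,
                 min_span = min_span),
            class = "PrevalenceMatrix")
}

as_marker_list <- function(markers) {
  if (is(markers, "FullLengthMarker")) markers <- list(markers)
  if (is(markers, "AAStringSet")) markers <- as.character(markers)
  if (is.character(markers)) markers <- as.list(markers)
  if (is.null(names(markers)) || any(names(markers) == ""))
    names(markers) <- vapply(seq_along(markers), function(i)
      marker_name(markers[[i]], sprintf("marker%02d", i)), "")
  markers
}

#' @export
print.PrevalenceMatrix <- function(x, ...) {
  cat(sprintf("PrevalenceMatrix: %d markers x %d %s groups (identity > %g, span >= %d aa)\n",
              nrow(x$values), ncol(x$values), x$grouping, x$identity_threshold,
              x$min_span))
  print(round(x$prevalence, 3))
  invisible(x)
}

#' Pairwise marker co-occurrence and rank correlation
#'
#' For every marker pair (including self pairs): the fraction of groups
#' positive for both, and the Spearman rank correlation (midrank ties) of
#' the two max-identity vectors across groups. The correlation is `NA`
#' when either vector is constant.
#'
#' @param matrix A `PrevalenceMatrix` (needs >= 2 markers for non-trivial
#'   pairs).
#' @param identity_threshold Threshold for the positivity layer (defaults
#'   to the matrix's own).
#' @return data.frame: `marker_a`, `marker_b`, `cooccurrence`, `spearman`.
#' @export
pair_cooccurrence <- function(matrix, identity_threshold = NULL) {
  stopifnot(is(matrix, "PrevalenceMatrix"))
  thr <- identity_threshold %||% matrix$identity_threshold
  vals <- matrix$values
  pos <- !is.na(vals) & vals > thr
  mk <- rownames(vals)
  rows <- list()
  for (i in seq_along(mk)) {
    for (j in seq(i, length(mk))) {
      vi <- vals[i, ]; vj <- vals[j, ]
      vi[is.na(vi)] <- 0; vj[is.na(vj)] <- 0
      rho <- if (length(unique(vi)) < 2L || length(unique(vj)) < 2L) NA_real_
        else suppressWarnings(cor(vi, vj, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        marker_a = mk[i], marker_b = mk[j],
        cooccurrence = mean(pos[i, ] & pos[j, ]),
        spearman = rho, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
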