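# Temporal persistence of phage families between consecutive visits:
# the f_switch statistic.

# Presence state of one marker per (subject, visit) in one habitat, taking
# the subject's first two visits with data and, within a cell, the
# lexically first metagenome (deterministic "one metagenome per habitat").
habitat_visit_states <- function(marker, cohort, habitat, thresholds,
                                 calls = NULL) {
  if (is.null(calls)) calls <- compute_presence_calls(marker, cohort, thresholds)
  calls <- calls[calls$habitat == habitat, , drop = FALSE]
  calls <- calls[order(calls$subject, calls$visit, calls$metagenome_id), ,
                 drop = FALSE]
  calls <- calls[!duplicated(calls[, c("subject", "visit")]), , drop = FALSE]
  calls
}

#' Temporal switching statistic f_switch for one marker and habitat
#'
#' For every subject with metagenomes at two visits of the habitat, the
#' marker's presence is called at the subject's first two visits with data;
#' subjects with an indeterminate call at either visit are excluded from
#' numerator and denominator. `f_switch` is the fraction of the remaining
#' subjects whose state differs between the two visits (present at visit 1
#' and absent at visit 2, or vice versa).
#'
#' @param marker A `FullLengthMarker` or protein sequence.
#' @param cohort A `Cohort`.
#' @param habitat Habitat name.
#' @param thresholds A [presence_thresholds()] object.
#' @param calls Optional precomputed calls from an internal presence scan
#'   (reused across habitats to avoid re-aligning).
#' @return list of class `"SwitchStat"`: `marker`, `habitat`, `n_subjects`
#'   (determinate at both visits), `n_switch`, `f_switch` (`NA` when no
#'   eligible subjects), `transitions` (2x2 present/absent table, visit 1 x
#'   visit 2), `excluded_subjects`.
#' @export
compute_f_switch <- function(marker, cohort, habitat,
                             thresholds = presence_thresholds(),
                             calls = NULL) {
  stopifnot(is(cohort, "Cohort"))
  st <- habitat_visit_states(marker, cohort, habitat, thresholds, calls)
  per_subj <- split(st, st$subject)
  states <- lapply(per_subj, function(d) {
    if (nrow(d) < 2L) return(NULL)
    d$state[1:2]
  })
  states <- states[!vapply(states, is.null, TRUE)]
  finish_switch_stat(marker_name(marker), habitat, states)
}

finish_switch_stat <- function(marker, habitat, states) {
  determinate <- vapply(states, function(s) all(s != "indeterminate"), TRUE)
  excluded <- names(states)[!determinate]
  states <- states[determinate]
  lv <- c("present", "absent")
  tab <- table(factor(vapply(states, `[`, "", 1L), levels = lv),
               factor(vapply(states, `[`, "", 2L), levels = lv),
               dnn = c("visit1", "visit2"))
  n <- length(states)
  n_switch <- sum(vapply(states, function(s) s[1L] != s[2L], TRUE))
  structure(list(marker = marker, habitat = habitat,
                 n_subjects = n, n_switch = n_switch,
                 f_switch = if (n > 0) n_switch / n else NA_real_,
                 transitions = tab, excluded_subjects = excluded),
            class = "SwitchStat")
}

#' f_switch with the oral cavity aggregated into one ecosystem
#'
#' Per subject and visit the marker is *present* when present in any oral
#' habitat, *absent* only when absent in every oral habitat, and
#' indeterminate otherwise; switching is then computed as in
#' [compute_f_switch()] on the aggregated states, using each subject's
#' first two visits with data in any oral habitat.
#'
#' @param marker A `FullLengthMarker` or protein sequence.
#' @param cohort A `Cohort`.
#' @param oral_habitats Character vector of habitat names to aggregate.
#' @param thresholds A [presence_thresholds()] object.
#' @param calls Optional precomputed presence calls.
#' @return A `"SwitchStat"` with habitat `"oral-aggregate"`.
#' @export
compute_f_switch_oral_aggregate <- function(marker, cohort, oral_habitats,
                                            thresholds = presence_thresholds(),
                                            calls = NULL) {
  stopifnot(is(cohort, "Cohort"), length(oral_habitats) >= 1L)
  if (is.null(calls)) calls <- compute_presence_calls(marker, cohort, thresholds)
  calls <- calls[calls$habitat %in% oral_habitats, , drop = FALSE]
  calls <- calls[order(calls$subject, calls$visit, calls$habitat,
                       calls$metagenome_id), , drop = FALSE]
  calls <- calls[!duplicated(calls[, c("subject", "habitat", "visit")]), ,
                 drop = FALSE]
  agg_state <- function(states) {
    if (any(states == "present")) "present"
    else if (all(states == "absent")) "absent"
    else "indeterminate"
  }
  states <- list()
  for (subj in unique(calls$subject)) {
    d <- calls[calls$subject == subj, , drop = FALSE]
    visits <- sort(unique(d$visit))
    if (length(visits) < 2L) next
    v12 <- visits[1:2]
    states[[subj]] <- vapply(v12, function(v)
      agg_state(d$state[d$visit == v]), "")
  }
  finish_switch_stat(marker_name(marker), "oral-aggregate", states)
}

#' @export
print.SwitchStat <- function(x, ...) {
  cat(sprintf("SwitchStat %s @ %s: f_switch = %s (%d/%d subjects, %d excluded)\n",
              x$marker, x$habitat,
              ifelse(is.na(x$f_switch), "NA", sprintf("%.3f", x$f_switch)),
              x$n_switch, x$n_subjects, length(x$excluded_subjects)))
  invisible(x)
}
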