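#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic study system: a reference library
#' partitioned into gene families, metagenomes carrying fragmented,
#' point-mutated copies of planted family members plus unrelated background
#' contigs, a longitudinal cohort (subjects x habitats x visits) with
#' per-family presence and switching probabilities, and barcoded amplicon
#' runs with a per-base substitution error rate.
#'
#' Defaults emulate the study system the pipeline is designed for: TerL-sized
#' genes (~550 aa, i.e. ~1650 nt), plaque-metagenome-like contigs
#' (mean 112 +/- 56 aa, i.e. ~336 +/- 167 nt, floored at 50 aa ~ a 300 bp
#' assembly minimum), five planted fragment copies per family, and
#' two-visit cohorts.
#'
#' @param seed Master integer seed; every generator derives its own stream
#'   from it (see [stream_seed()]), so identical `seed` + config gives
#'   byte-identical outputs.
#' @param n_families Number of gene families in the reference library.
#' @param genes_per_family Reference genes per family (mutated copies of a
#'   family ancestor).
#' @param gene_length_aa Named numeric `c(mean=, sd=)` of gene length (aa).
#' @param family_divergence Per-site substitution probability applied to
#'   family members and planted fragments, in `[0, 0.6]`. Equals the expected
#'   amino-acid divergence from the reference because substitutions always
#'   change the residue.
#' @param terminase_fraction Fraction of families annotated as large
#'   terminase (TerL); the rest receive decoy annotations.
#' @param n_background_contigs Unrelated (uniform-composition) contigs per
#'   metagenome.
#' @param contig_length_aa Named numeric `c(mean=, sd=)` of contig length.
#' @param min_contig_aa Lower truncation bound for contig lengths.
#' @param copies_per_family Fragment copies emitted per planted family.
#' @param n_subjects,visits Cohort dimensions.
#' @param habitats Character vector of habitat names (defines the habitat
#'   dimension of the cohort).
#' @param presence_prob Probability a family is present in a subject x habitat
#'   at visit 1. Scalar, per-family vector, or families x habitats matrix.
#' @param switch_prob Probability a family's presence state flips between
#'   consecutive visits. Same shapes as `presence_prob`.
#' @param amplicon_error_rate Per-base substitution probability of the
#'   simulated sequencer.
#' @param amplicon_reads Reads generated per sample x marker.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [generate_reference_library()], [generate_metagenome()],
#'   [generate_cohort()], [generate_amplicon_run()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_families = 5, n_background_contigs = 50)
sim_config <- function(seed = 1L,
                       n_families = 20L,
                       genes_per_family = 1L,
                       gene_length_aa = c(mean = 550, sd = 60),
                       family_divergence = 0.15,
                       terminase_fraction = 1,
                       n_background_contigs = 4000L,
                       contig_length_aa = c(mean = 112, sd = 56),
                       min_contig_aa = 50L,
                       copies_per_family = 5L,
                       n_subjects = 10L,
                       habitats = "supragingival_plaque",
                       visits = 2L,
                       presence_prob = 0.8,
                       switch_prob = 0.1,
                       amplicon_error_rate = 0.001,
                       amplicon_reads = 100L) {
  cfg <- list(seed = as.integer(seed),
              n_families = as.integer(n_families),
              genes_per_family = as.integer(genes_per_family),
              gene_length_aa = gene_length_aa,
              family_divergence = family_divergence,
              terminase_fraction = terminase_fraction,
              n_background_contigs = as.integer(n_background_contigs),
              contig_length_aa = contig_length_aa,
              min_contig_aa = as.integer(min_contig_aa),
              copies_per_family = as.integer(copies_per_family),
              n_subjects = as.integer(n_subjects),
              habitats = as.character(habitats),
              visits = as.integer(visits),
              presence_prob = presence_prob,
              switch_prob = switch_prob,
              amplicon_error_rate = amplicon_error_rate,
              amplicon_reads = as.integer(amplicon_reads))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop(sprintf("invalid sim_config: '%s' must be a count >= 1", field),
           call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
      stop(sprintf("invalid sim_config: '%s' must lie in [0, 1]", field),
           call. = FALSE)
  }
  chk_meansd <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 2L || !all(c("mean", "sd") %in% names(v)) ||
        v[["mean"]] <= 0 || v[["sd"]] < 0)
      stop(sprintf("invalid sim_config: '%s' must be c(mean=, sd=) with mean > 0",
                   field), call. = FALSE)
  }
  for (f in c("n_families", "genes_per_family", "copies_per_family",
              "n_subjects", "visits", "min_contig_aa", "amplicon_reads"))
    chk_count(f)
  if (cfg$n_background_contigs < 0)
    stop("invalid sim_config: 'n_background_contigs' must be >= 0", call. = FALSE)
  for (f in c("presence_prob", "switch_prob", "amplicon_error_rate",
              "terminase_fraction"))
    chk_prob(f)
  chk_meansd("gene_length_aa")
  chk_meansd("contig_length_aa")
  d <- cfg$family_divergence
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 0.6)
    stop("invalid sim_config: 'family_divergence' must lie in [0, 0.6]",
         call. = FALSE)
  if (length(cfg$habitats) < 1L)
    stop("invalid sim_config: 'habitats' must name at least one habitat",
         call. = FALSE)
  invisible(cfg)
}

# Expand a presence/switch probability spec to a families x habitats matrix.
expand_prob <- function(p, families, habitats, field) {
  nf <- length(families); nh <- length(habitats)
  if (is.matrix(p)) {
    if (nrow(p) != nf || ncol(p) != nh)
      stop(sprintf("'%s' matrix must be %d families x %d habitats", field, nf, nh),
           call. = FALSE)
    m <- p
  } else if (length(p) == 1L) {
    m <- matrix(p, nf, nh)
  } else if (length(p) == nf) {
    m <- matrix(rep(p, nh), nf, nh)
  } else {
    stop(sprintf("'%s' must be scalar, per-family, or families x habitats", field),
         call. = FALSE)
  }
  dimnames(m) <- list(families, habitats)
  m
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map directly onto [sim_config()] arguments;
#' `gene_length_aa`/`contig_length_aa` are given as two-element maps with
#' `mean` and `sd` keys.
#'
#' @param path Path to a YAML file.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (f in c("gene_length_aa", "contig_length_aa"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}
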