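#' Planted-family recovery benchmark for signature clustering
#'
#' Measures the sensitivity of the signature-clustering discovery engine on
#' synthetic metagenomes: each replicate plants `n_families` gene families
#' (one reference gene each; `copies_per_family` fragment copies at a
#' per-family divergence drawn uniformly from `divergence_range`) among
#' `n_background` unrelated contigs, computes signatures at `e_max`, runs
#' greedy clustering at `overlap_threshold`, and scores a family as
#' detected when its reference is retained.
#'
#' @param seeds Integer vector; one replicate per seed.
#' @param n_families Planted families per replicate.
#' @param copies_per_family Fragment copies per family.
#' @param n_background Background contigs per metagenome.
#' @param divergence_range Per-family divergence range (uniform draw).
#' @param contig_length_aa Fragment length distribution, `c(mean=, sd=)`.
#' @param e_max,overlap_threshold Clustering parameters.
#' @return data.frame with one row per replicate (`seed`,
#'   `n_retained`, `n_detected`, `detected_fraction`); the mean detected
#'   fraction is in attribute `"mean_detected"`.
#' @export
#' @examples
#' \donttest{
#' bench <- marker_recovery_benchmark(seeds = 1:2, n_background = 500)
#' attr(bench, "mean_detected")
#' }
marker_recovery_benchmark <- function(seeds = 1:10, n_families = 20L,
                                      copies_per_family = 5L,
                                      n_background = 4000L,
                                      divergence_range = c(0, 0.30),
                                      contig_length_aa = c(mean = 112, sd = 56),
                                      e_max = 0.001, overlap_threshold = 0.5) {
  rows <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    cfg <- sim_config(seed = seed, n_families = n_families,
                      genes_per_family = 1L,
                      contig_length_aa = contig_length_aa,
                      n_background_contigs = n_background,
                      copies_per_family = copies_per_family)
    lib <- generate_reference_library(cfg)
    fams <- unique(lib$genes$family_id)
    div <- with_stream(seed, "benchmark_divergence",
                       setNames(runif(length(fams), divergence_range[1],
                                      divergence_range[2]), fams))
    mg <- generate_metagenome(lib, fams, cfg, id = sprintf("bench%03d", seed),
                              divergence = div)$metagenome
    sigs <- compute_signatures(lib, mg, e_max = e_max)
    cl <- cluster_references(sigs, overlap_threshold = overlap_threshold)
    fam_of <- setNames(lib$genes$family_id, lib$genes$ref_id)
    detected <- fams %in% unname(fam_of[cl$retained])
    rows[[i]] <- data.frame(seed = seed, n_retained = length(cl$retained),
                            n_detected = sum(detected),
                            detected_fraction = mean(detected))
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_detected") <- mean(out$detected_fraction)
  out
}
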