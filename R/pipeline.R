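# End-to-end pipeline driver: synthesis (optional) -> signature clustering
# -> discovery cascade -> prevalence -> temporal -> primer design ->
# phylogenetic exports, with a JSON run manifest for provenance.

#' Pipeline configuration
#'
#' Collects every stage threshold (at its standard default) plus the
#' synthetic-study shape. The full configuration is serialised into the
#' output directory's manifest for provenance.
#'
#' @param seed Master seed for all synthetic inputs.
#' @param library_fasta,library_annotations Optional paths to a reference
#'   library (protein FASTA) and its annotation TSV (`ref_id`, `family_id`,
#'   `annotation` columns); when `NULL`, a synthetic library is generated.
#' @param sim Overrides for [sim_config()] fields (list).
#' @param e_max Signature / homology E-value cutoff.
#' @param overlap_threshold Stringent-overlap threshold for clustering.
#' @param min_signature,min_identity_rep Candidate gates (signature size,
#'   percent identity to the representative contig).
#' @param cross_min_identity Cross-dataset conservation gate (percent).
#' @param full_length_min_identity Full-length collection gate (percent).
#' @param identity_threshold Prevalence positivity threshold (percent).
#' @param min_span Alignment span (aa) for presence cells.
#' @param thresholds A [presence_thresholds()] object.
#' @param otu_threshold,phylo_min_span_aa,phylo_min_identity Phylogenetic
#'   preparation gates.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            library_fasta = NULL,
                            library_annotations = NULL,
                            sim = list(),
                            e_max = 0.001,
                            overlap_threshold = 0.5,
                            min_signature = 5L,
                            min_identity_rep = 10,
                            cross_min_identity = 75,
                            full_length_min_identity = 70,
                            identity_threshold = 70,
                            min_span = 150L,
                            thresholds = presence_thresholds(),
                            otu_threshold = 0.03,
                            phylo_min_span_aa = 400L,
                            phylo_min_identity = 70) {
  structure(as.list(environment()), class = "pipeline_config")
}

default_pipeline_sim <- function(seed, overrides) {
  base <- list(seed = seed, n_families = 10L, genes_per_family = 3L,
               terminase_fraction = 0.7, family_divergence = 0.08,
               n_background_contigs = 250L, copies_per_family = 6L,
               n_subjects = 6L, habitats = c("tongue_dorsum", "buccal_mucosa"),
               visits = 2L, presence_prob = 0.8, switch_prob = 0.15)
  do.call(sim_config, modifyList(base, overrides))
}

#' Run the full marker-discovery pipeline
#'
#' Executes synthesis (unless a library is supplied) -> signature
#' computation and greedy clustering -> the candidate filtering cascade ->
#' full-length marker selection -> cohort prevalence and co-occurrence ->
#' temporal switching -> primer design for the first marker -> phylogenetic
#' matrix export, writing TSV/FASTA/NEXUS outputs and a JSON manifest into
#' `out_dir`. Fully deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created; must be writable).
#' @return The run report (named list), invisibly. The same content is
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(is(config, "pipeline_config"))
  for (p in c(config$library_fasta, config$library_annotations)) {
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist: ", p, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- default_pipeline_sim(config$seed, config$sim)
  report <- list(seed = config$seed,
                 thresholds = list(
                   e_max = config$e_max,
                   overlap_threshold = config$overlap_threshold,
                   min_signature = config$min_signature,
                   min_identity_rep = config$min_identity_rep,
                   cross_min_identity = config$cross_min_identity,
                   full_length_min_identity = config$full_length_min_identity,
                   identity_threshold = config$identity_threshold,
                   min_span = config$min_span,
                   presence = unclass(config$thresholds)),
                 stages = list())

  # --- synth ---------------------------------------------------------------
  if (is.null(config$library_fasta)) {
    library <- generate_reference_library(scfg)
  } else {
    seqs <- Biostrings::readAAStringSet(config$library_fasta)
    genes <- read.delim(config$library_annotations, stringsAsFactors = FALSE)
    library <- structure(list(seqs = seqs, genes = genes,
                              ancestors = Biostrings::AAStringSet()),
                         class = "ReferenceLibrary")
  }
  fams <- unique(library$genes$family_id)
  mgA <- generate_metagenome(library, fams, scfg, id = "datasetA")$metagenome
  mgB <- generate_metagenome(library, fams, scfg, id = "datasetB")$metagenome
  # cohort metagenomes carry a lighter background than the discovery
  # datasets: presence calling only needs enough unrelated contigs to
  # exercise the absence rule
  ccfg <- unclass(scfg)
  ccfg$n_background_contigs <- min(ccfg$n_background_contigs, 50L)
  ccfg <- do.call(sim_config, ccfg)
  cohort <- generate_cohort(library, ccfg, id_prefix = "cohort")
  write_fasta(library, file.path(out_dir, "reference_library.fasta"))
  write_tsv(cohort$presence, file.path(out_dir, "cohort_truth_presence.tsv"))
  report$stages$synth <- list(n_refs = length(library$seqs),
                              n_families = length(fams),
                              n_metagenomes = length(cohort$metagenomes))

  # --- mcrl ----------------------------------------------------------------
  sigs <- compute_signatures(library, mgA, e_max = config$e_max)
  clus <- cluster_references(sigs, overlap_threshold = config$overlap_threshold)
  report$stages$mcrl <- list(n_signatures = length(sigs),
                             n_retained = length(clus$retained))

  # --- discover ------------------------------------------------------------
  cand <- filter_candidates(clus, library, mgA,
                            min_signature = config$min_signature,
                            min_identity = config$min_identity_rep)
  cand2 <- cross_dataset_screen(cand, mgB,
                                min_identity = config$cross_min_identity,
                                e_max = config$e_max)
  cand3 <- if (nrow(cand2)) remove_redundant(cand2, e_max = config$e_max) else cand2
  markers <- list()
  for (i in seq_len(nrow(cand3))) {
    fl <- select_full_length(cand3[i, ],
                             databases = list(reference = library$seqs),
                             min_identity = config$full_length_min_identity)
    if (is(fl, "FullLengthMarker")) markers[[fl$name]] <- fl
  }
  report$stages$discover <- list(n_candidates = nrow(cand),
                                 n_cross = nrow(cand2),
                                 n_nonredundant = nrow(cand3),
                                 n_markers = length(markers),
                                 markers = names(markers))
  if (length(markers)) {
    write_fasta(Biostrings::AAStringSet(
      vapply(markers, function(m) m$sequence, "")),
      file.path(out_dir, "markers.fasta"))
  }
  write_tsv(cand3, file.path(out_dir, "candidates.tsv"))

  # --- prevalence ----------------------------------------------------------
  if (length(markers)) {
    pm <- prevalence_matrix(markers, cohort, grouping = "subject",
                            identity_threshold = config$identity_threshold,
                            min_span = config$min_span)
    co <- pair_cooccurrence(pm)
    write_tsv(as.data.frame(pm$values), file.path(out_dir, "prevalence_matrix.tsv"))
    write_tsv(co, file.path(out_dir, "cooccurrence.tsv"))
    report$stages$prevalence <- list(prevalence = as.list(pm$prevalence))

    # --- temporal ----------------------------------------------------------
    sw <- list()
    for (mk in names(markers)) {
      calls <- compute_presence_calls(markers[[mk]], cohort, config$thresholds)
      for (h in scfg$habitats) {
        st <- compute_f_switch(markers[[mk]], cohort, h,
                               thresholds = config$thresholds, calls = calls)
        sw[[length(sw) + 1L]] <- data.frame(
          marker = mk, habitat = h, n_subjects = st$n_subjects,
          n_switch = st$n_switch, f_switch = st$f_switch,
          stringsAsFactors = FALSE)
      }
      if (length(scfg$habitats) > 1L) {
        st <- compute_f_switch_oral_aggregate(markers[[mk]], cohort,
                                              scfg$habitats,
                                              thresholds = config$thresholds,
                                              calls = calls)
        sw[[length(sw) + 1L]] <- data.frame(
          marker = mk, habitat = "oral-aggregate", n_subjects = st$n_subjects,
          n_switch = st$n_switch, f_switch = st$f_switch,
          stringsAsFactors = FALSE)
      }
    }
    sw <- do.call(rbind, sw)
    write_tsv(sw, file.path(out_dir, "f_switch.tsv"))
    report$stages$temporal <- list(n_rows = nrow(sw),
                                   mean_f_switch = mean(sw$f_switch, na.rm = TRUE))

    # --- primers (first marker) --------------------------------------------
    mk1 <- markers[[1L]]
    fam <- library$genes$family_id[match(mk1$source_id, library$genes$ref_id)]
    kin <- library$genes$ref_id[library$genes$family_id %in% fam]
    kin_seqs <- library$seqs[kin]
    half <- seq_len(ceiling(length(kin_seqs) / 2))
    msas <- list(datasetA = as_aln_matrix(kin_seqs[half]),
                 datasetB = as_aln_matrix(kin_seqs[-half]))
    msas <- Filter(function(m) nrow(m) > 0, msas)
    profile <- build_profile(msas)
    anchors <- find_anchors(profile)
    primer_rows <- list()
    n_rejected <- 0L
    for (a in anchors[anchors > 12]) {
      pr <- design_primer(msas, a, "forward", profile = profile)
      if (is(pr, "DegeneratePrimer")) {
        primer_rows[[length(primer_rows) + 1L]] <- data.frame(
          marker = mk1$name, anchor = a, direction = "forward",
          sequence = pr$sequence, degeneracy = pr$degeneracy,
          tm_mid = pr$tm[["mid"]], motif = pr$target_motif,
          stringsAsFactors = FALSE)
        if (length(primer_rows) >= 2L) break
      } else {
        n_rejected <- n_rejected + 1L
      }
    }
    primers <- if (length(primer_rows)) do.call(rbind, primer_rows) else
      data.frame()
    write_tsv(primers, file.path(out_dir, "primers.tsv"))
    report$stages$primers <- list(n_anchors = length(anchors),
                                  n_designed = nrow(primers),
                                  n_rejected = n_rejected)

    # --- phyloprep ---------------------------------------------------------
    kin_mat <- kin_seqs[setdiff(names(kin_seqs), mk1$name)]
    if (length(library$ancestors) && fam %in% names(library$ancestors)) {
      anc <- library$ancestors[fam]
      names(anc) <- paste0(fam, "_ancestor")
      kin_mat <- c(as_aa_set(kin_mat), anc)
    }
    pmat <- build_matrix(mk1, metagenome_seqs = kin_mat,
                         min_span_aa = config$phylo_min_span_aa,
                         min_identity = config$phylo_min_identity)
    if (is(pmat, "PhyloMatrix")) {
      export_matrix(pmat, "fasta", file.path(out_dir, "phylo_matrix.fasta"))
      export_matrix(pmat, "nexus", file.path(out_dir, "phylo_matrix.nex"))
      report$stages$phyloprep <- list(n_rows = nrow(pmat$alignment),
                                      n_columns = pmat$n_columns,
                                      coverage = pmat$coverage_fraction)
    } else {
      report$stages$phyloprep <- list(status = pmat$status)
    }
  }

  report$outputs <- sort(list.files(out_dir))
  jsonlite::write_json(report, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
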