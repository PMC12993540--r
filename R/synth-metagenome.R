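#' Generate a synthetic translated metagenome with planted gene families
#'
#' For each planted family, emits `copies_per_family` contig fragments: the
#' fragment length is drawn from the configured contig-length distribution,
#' its start position uniformly within the source gene, and its residues are
#' point-mutated at the family divergence rate. Unrelated background contigs
#' of uniform residue composition are added, and the contig order is
#' shuffled. Ground truth records the origin of every contig.
#'
#' @param library A `ReferenceLibrary`.
#' @param planted Character vector of family ids to plant (may be empty).
#' @param config A [sim_config()] object.
#' @param id Metagenome identifier (also seeds this metagenome's RNG stream).
#' @param subject,habitat,visit Optional cohort metadata carried on the
#'   metagenome.
#' @param divergence Optional named per-family divergence overriding
#'   `config$family_divergence` (names = family ids).
#' @return list with components `metagenome` (class `"Metagenome"`: `id`,
#'   `contigs` as `AAStringSet`, `subject`, `habitat`, `visit`) and `truth`
#'   (data.frame: `contig_id`, `origin` family id or `"background"`,
#'   `gene_id`, `start0`, `length_aa`, `truncated`, `divergence`,
#'   `metagenome_id`, `subject`, `habitat`, `visit`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, n_families = 2, n_background_contigs = 5)
#' lib <- generate_reference_library(cfg)
#' mg <- generate_metagenome(lib, "fam001", cfg, id = "demo")
#' mg$truth[, c("contig_id", "origin")]
generate_metagenome <- function(library, planted, config, id = "mg1",
                                subject = NA_character_, habitat = NA_character_,
                                visit = NA_integer_, divergence = NULL) {
  validate_sim_config(config)
  stopifnot(is(library, "ReferenceLibrary"))
  planted <- as.character(planted)
  known <- unique(library$genes$family_id)
  if (length(planted) && !all(planted %in% known))
    stop("planted families not in library: ",
         paste(setdiff(planted, known), collapse = ", "), call. = FALSE)

  with_stream(config$seed, paste0("metagenome:", id), {
    mu <- config$contig_length_aa[["mean"]]
    sdv <- config$contig_length_aa[["sd"]]
    seqs <- character(0)
    truth <- list()
    for (fam in sort(planted)) {
      fam_genes <- library$genes$ref_id[library$genes$family_id == fam]
      d <- if (!is.null(divergence) && fam %in% names(divergence))
        divergence[[fam]] else config$family_divergence
      for (k in seq_len(config$copies_per_family)) {
        gid <- if (length(fam_genes) == 1L) fam_genes else sample(fam_genes, 1L)
        gene <- as.character(library$seqs[[gid]])
        glen <- nchar(gene)
        flen <- draw_lengths(1L, mu, sdv, config$min_contig_aa)
        truncated <- flen > glen
        if (truncated) flen <- glen
        start0 <- sample.int(glen - flen + 1L, 1L) - 1L
        frag <- mutate_protein(substr(gene, start0 + 1L, start0 + flen), d)
        seqs <- c(seqs, frag)
        truth[[length(truth) + 1L]] <- data.frame(
          origin = fam, gene_id = gid, start0 = start0, length_aa = flen,
          truncated = truncated, divergence = d, stringsAsFactors = FALSE)
      }
    }
    nb <- config$n_background_contigs
    if (nb > 0) {
      blens <- draw_lengths(nb, mu, sdv, config$min_contig_aa)
      seqs <- c(seqs, vapply(blens, random_protein, ""))
      truth[[length(truth) + 1L]] <- data.frame(
        origin = "background", gene_id = NA_character_, start0 = NA_integer_,
        length_aa = blens, truncated = FALSE, divergence = NA_real_,
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(origin = character(0), gene_id = character(0),
                 start0 = integer(0), length_aa = integer(0),
                 truncated = logical(0), divergence = numeric(0))
    n <- length(seqs)
    perm <- if (n > 0) sample.int(n) else integer(0)
    seqs <- seqs[perm]
    truth <- truth[perm, , drop = FALSE]
    ids <- sprintf("%s_c%04d", id, seq_len(n))
    truth <- cbind(data.frame(contig_id = ids, stringsAsFactors = FALSE), truth)
    truth$metagenome_id <- id
    truth$subject <- subject
    truth$habitat <- habitat
    truth$visit <- visit
    rownames(truth) <- NULL
    mg <- structure(list(id = id,
                         contigs = Biostrings::AAStringSet(setNames(seqs, ids)),
                         subject = subject, habitat = habitat, visit = visit),
                    class = "Metagenome")
    list(metagenome = mg, truth = truth)
  })
}

#' @export
print.Metagenome <- function(x, ...) {
  cat(sprintf("Metagenome '%s': %d contigs (subject=%s habitat=%s visit=%s)\n",
              x$id, length(x$contigs), x$subject, x$habitat, x$visit))
  invisible(x)
}

#' Generate a longitudinal synthetic cohort
#'
#' Simulates subjects x habitats x visits. For each subject x habitat cell,
#' per-family presence at visit 1 is Bernoulli(`presence_prob`); at each
#' later visit the state flips with probability `switch_prob`. One metagenome
#' is generated per cell, planting exactly the families present there.
#'
#' @param library A `ReferenceLibrary`.
#' @param config A [sim_config()] object (`n_subjects`, `habitats`, `visits`,
#'   `presence_prob`, `switch_prob` control the design).
#' @param id_prefix Prefix of metagenome identifiers.
#' @return list of class `"Cohort"` with `metagenomes` (named list of
#'   `Metagenome`), `design` (one row per metagenome), `presence` (the true
#'   per subject x habitat x visit x family presence table) and `truth`
#'   (row-bound contig-level ground truth of all metagenomes).
#' @export
generate_cohort <- function(library, config, id_prefix = "sim") {
  validate_sim_config(config)
  stopifnot(is(library, "ReferenceLibrary"))
  fams <- unique(library$genes$family_id)
  pp <- expand_prob(config$presence_prob, fams, config$habitats, "presence_prob")
  sp <- expand_prob(config$switch_prob, fams, config$habitats, "switch_prob")

  presence <- with_stream(config$seed, "cohort", {
    rows <- list()
    for (s in seq_len(config$n_subjects)) {
      for (h in config$habitats) {
        state <- rbinom(length(fams), 1L, pp[, h]) == 1L
        for (v in seq_len(config$visits)) {
          if (v > 1L) {
            flip <- rbinom(length(fams), 1L, sp[, h]) == 1L
            state <- xor(state, flip)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sprintf("S%03d", s), habitat = h, visit = v,
            family_id = fams, present = state, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  cells <- unique(presence[, c("subject", "habitat", "visit")])
  mgs <- vector("list", nrow(cells))
  truths <- vector("list", nrow(cells))
  design <- cells
  design$metagenome_id <- NA_character_
  for (i in seq_len(nrow(cells))) {
    s <- cells$subject[i]; h <- cells$habitat[i]; v <- cells$visit[i]
    sel <- presence$subject == s & presence$habitat == h & presence$visit == v
    planted <- presence$family_id[sel & presence$present]
    mid <- sprintf("%s_%s_%s_v%d", id_prefix, s, h, v)
    res <- generate_metagenome(library, planted, config, id = mid,
                               subject = s, habitat = h, visit = v)
    mgs[[i]] <- res$metagenome
    truths[[i]] <- res$truth
    design$metagenome_id[i] <- mid
  }
  names(mgs) <- design$metagenome_id
  structure(list(metagenomes = mgs, design = design, presence = presence,
                 truth = do.call(rbind, truths)),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d metagenomes (%d subjects x %d habitats x %d visits)\n",
              length(x$metagenomes), length(unique(x$design$subject)),
              length(unique(x$design$habitat)), max(x$design$visit)))
  invisible(x)
}

#' Write a ground-truth or result table as TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
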