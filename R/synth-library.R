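#' Generate a synthetic annotated reference library
#'
#' Builds `n_families` gene families, each descended from an independent
#' random ancestor protein; family members are point-mutated copies of the
#' ancestor at rate `family_divergence`. A configurable fraction of families
#' is annotated as large terminase (TerL); the rest carry decoy phage-gene
#' annotations. Sequences use the 20 standard amino acids only.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"ReferenceLibrary"` with components:
#'   \describe{
#'     \item{seqs}{`AAStringSet` of reference genes, named by `ref_id`.}
#'     \item{genes}{data.frame with `ref_id`, `family_id`, `annotation`,
#'       `is_terminase`, `length_aa` (the ground truth of the library).}
#'     \item{ancestors}{`AAStringSet` of family ancestor sequences, named by
#'       `family_id`.}
#'   }
#' @export
#' @examples
#' lib <- generate_reference_library(sim_config(seed = 1, n_families = 3))
#' lib$genes
generate_reference_library <- function(config) {
  validate_sim_config(config)
  decoys <- c("major capsid protein", "portal protein", "tail fiber protein",
              "baseplate wedge protein", "holin", "integrase")
  with_stream(config$seed, "reference_library", {
    nf <- config$n_families
    n_terl <- round(config$terminase_fraction * nf)
    fam_ids <- sprintf("fam%03d", seq_len(nf))
    is_terl <- seq_len(nf) <= n_terl
    lens <- draw_lengths(nf, config$gene_length_aa[["mean"]],
                         config$gene_length_aa[["sd"]],
                         floor = max(100L, config$min_contig_aa))
    ancestors <- vapply(lens, random_protein, "")
    genes <- vector("list", nf)
    for (i in seq_len(nf)) {
      ann <- if (is_terl[i]) "large terminase subunit (TerL)" else
        decoys[((i - 1L) %% length(decoys)) + 1L]
      gseq <- vapply(seq_len(config$genes_per_family), function(j)
        mutate_protein(ancestors[i], config$family_divergence), "")
      genes[[i]] <- data.frame(
        ref_id = sprintf("%s_g%02d", fam_ids[i], seq_len(config$genes_per_family)),
        family_id = fam_ids[i],
        annotation = ann,
        is_terminase = is_terl[i],
        length_aa = nchar(gseq),
        stringsAsFactors = FALSE)
      genes[[i]]$seq <- gseq
    }
    genes <- do.call(rbind, genes)
    seqs <- Biostrings::AAStringSet(setNames(genes$seq, genes$ref_id))
    genes$seq <- NULL
    anc <- Biostrings::AAStringSet(setNames(ancestors, fam_ids))
    structure(list(seqs = seqs, genes = genes, ancestors = anc),
              class = "ReferenceLibrary")
  })
}

#' @export
print.ReferenceLibrary <- function(x, ...) {
  cat(sprintf("ReferenceLibrary: %d genes in %d families (%d terminase-annotated)\n",
              length(x$seqs), length(unique(x$genes$family_id)),
              sum(x$genes$is_terminase)))
  invisible(x)
}

#' Write a sequence set to FASTA
#'
#' Thin deterministic wrapper over [Biostrings::writeXStringSet()].
#'
#' @param x An `AAStringSet`/`DNAStringSet`, a `ReferenceLibrary`, or a
#'   `Metagenome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is(x, "ReferenceLibrary")) x <- x$seqs
  if (is(x, "Metagenome")) x <- x$contigs
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
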