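# Synthetic-data generators: validation, determinism, distributional checks.

test_that("config validation names the offending field", {
  expect_error(sim_config(presence_prob = 1.5), "presence_prob")
  expect_error(sim_config(family_divergence = 0.7), "family_divergence")
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(switch_prob = -0.1), "switch_prob")
  expect_error(sim_config(gene_length_aa = c(550, 60)), "gene_length_aa")
})

test_that("zero-divergence libraries reproduce their ancestors and output is byte-deterministic", {
  cfg0 <- sim_config(seed = 1, n_families = 1, genes_per_family = 1,
                     family_divergence = 0)
  lib0 <- generate_reference_library(cfg0)
  expect_identical(as.character(lib0$seqs[[1]]),
                   as.character(lib0$ancestors[[1]]))

  cfg <- sim_config(seed = 7, n_families = 20, genes_per_family = 3)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_reference_library(cfg), f1)
  write_fasta(generate_reference_library(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # stream isolation: generating a metagenome in between does not perturb
  # the library stream
  lib_a <- generate_reference_library(cfg)
  invisible(generate_metagenome(lib_a, "fam001", cfg, id = "x"))
  lib_b <- generate_reference_library(cfg)
  expect_identical(as.character(lib_a$seqs), as.character(lib_b$seqs))
})

test_that("the mutation sampler realises the configured divergence", {
  cfg <- sim_config(seed = 11, n_families = 1, genes_per_family = 400,
                    gene_length_aa = c(mean = 300, sd = 0),
                    family_divergence = 0.3)
  lib <- generate_reference_library(cfg)
  anc <- as.character(lib$ancestors[[1]])
  d <- vapply(as.character(lib$seqs), div_frac, 0, b = anc)
  expect_lt(abs(mean(d) - 0.3), 0.02)
})

test_that("metagenome planting: empty planting, exact substrings at zero divergence, copy bookkeeping", {
  cfg <- sim_config(seed = 3, n_families = 3, family_divergence = 0,
                    n_background_contigs = 30, copies_per_family = 10)
  lib <- generate_reference_library(cfg)

  empty <- generate_metagenome(lib, character(0), cfg, id = "none")
  expect_true(all(empty$truth$origin == "background"))
  expect_equal(length(empty$metagenome$contigs), 30)

  one <- generate_metagenome(lib, "fam001", cfg, id = "one")
  planted <- one$truth[one$truth$origin == "fam001", ]
  expect_equal(nrow(planted), 10)
  for (i in seq_len(nrow(planted))) {
    frag <- as.character(one$metagenome$contigs[[planted$contig_id[i]]])
    gene <- as.character(lib$seqs[[planted$gene_id[i]]])
    expect_true(grepl(frag, gene, fixed = TRUE))
  }

  two <- generate_metagenome(lib, c("fam001", "fam002"), cfg, id = "two")
  counts <- table(two$truth$origin)
  expect_equal(unname(counts[["fam001"]]), 10)
  expect_equal(unname(counts[["fam002"]]), 10)
  # ground truth is complete: every contig appears exactly once
  expect_setequal(two$truth$contig_id, names(two$metagenome$contigs))
  expect_false(anyDuplicated(two$truth$contig_id) > 0)
})

test_that("contig lengths follow the configured distribution away from the floor", {
  cfg <- sim_config(seed = 5, n_families = 1,
                    contig_length_aa = c(mean = 200, sd = 30),
                    min_contig_aa = 50, n_background_contigs = 1500)
  lib <- generate_reference_library(cfg)
  mg <- generate_metagenome(lib, character(0), cfg, id = "bg")
  lens <- Biostrings::width(mg$metagenome$contigs)
  expect_lt(abs(mean(lens) - 200), 3)
  expect_lt(abs(sd(lens) - 30), 3)
})

test_that("cohort switching follows the configured probabilities", {
  base <- list(seed = 13, n_families = 2, genes_per_family = 1,
               n_background_contigs = 2, copies_per_family = 1,
               habitats = "tongue_dorsum", visits = 2)

  cfg0 <- do.call(sim_config, c(base, list(switch_prob = 0, n_subjects = 15)))
  lib <- generate_reference_library(cfg0)
  co0 <- generate_cohort(lib, cfg0)
  v1 <- co0$presence[co0$presence$visit == 1, ]
  v2 <- co0$presence[co0$presence$visit == 2, ]
  expect_identical(v1$present, v2$present)

  cfg1 <- do.call(sim_config, c(base, list(presence_prob = 1, switch_prob = 0,
                                           n_subjects = 10)))
  co1 <- generate_cohort(lib, cfg1)
  expect_true(all(co1$presence$present))

  cfg2 <- do.call(sim_config, c(base, list(switch_prob = 0.3, n_subjects = 200)))
  co2 <- generate_cohort(lib, cfg2)
  p <- co2$presence[order(co2$presence$subject, co2$presence$family_id,
                          co2$presence$visit), ]
  v1 <- p[p$visit == 1, ]; v2 <- p[p$visit == 2, ]
  disc <- mean(v1$present != v2$present)
  expect_lt(abs(disc - 0.3), 0.07)
})

test_that("amplicon runs reconstruct inserts exactly without errors and hit the error expectation", {
  markers <- data.frame(marker = "HB1", fwd_primer = "ACGTGGC",
                        rev_primer = "TTGCAGC",
                        template = strrep("ACGT", 20),
                        stringsAsFactors = FALSE)
  bc <- data.frame(sample = c("s1", "s2"), barcode = c("AAAAAA", "CCCCCC"),
                   stringsAsFactors = FALSE)

  cfg0 <- sim_config(seed = 9, amplicon_error_rate = 0, amplicon_reads = 20)
  run <- generate_amplicon_run(markers, bc, cfg0)
  expected <- function(b) paste0(
    b, markers$fwd_primer, markers$template,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(markers$rev_primer))))
  for (i in seq_len(nrow(run$r1))) {
    b <- bc$barcode[match(run$truth$sample[i], bc$sample)]
    expect_identical(run$r1$seq[i], expected(b))
    expect_identical(run$r2$seq[i], as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(run$r1$seq[i]))))
  }
  # demultiplexing truth partitions the reads
  expect_equal(sort(unique(run$truth$sample)), c("s1", "s2"))
  expect_equal(nrow(run$truth), 40)
  expect_false(anyDuplicated(run$truth$id) > 0)

  # error model: ~ L * e substitutions per read
  markers$template <- strrep("GATC", 70)   # read length 300 with bc+primers
  cfg1 <- sim_config(seed = 10, amplicon_error_rate = 0.01,
                     amplicon_reads = 1000)
  run1 <- generate_amplicon_run(markers, bc[1, ], cfg1)
  L <- nchar(run1$r1$seq[1])
  expect_equal(L, 300)
  expect_lt(abs(mean(run1$truth$n_errors_r1) - L * 0.01), 0.3)

  # barcode collisions are rejected
  bad <- data.frame(sample = c("a", "b"), barcode = c("AAAAAA", "AAAAAT"))
  expect_error(generate_amplicon_run(markers, bad, cfg0), "Hamming")
})
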