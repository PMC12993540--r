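# Temporal persistence (f_switch) between consecutive visits.

present_contigs <- function(marker, tag) {
  setNames(c(marker_slice(marker, 31, 200), rand_prot(150)),
           paste0(tag, c("_hit", "_bg")))
}
absent_contigs <- function(tag) {
  setNames(vapply(1:3, function(i) rand_prot(120), ""), paste0(tag, "_bg", 1:3))
}

test_that("f_switch counts discordant determinate subjects", {
  set.seed(51)
  marker <- setNames(rand_prot(480), "mk")
  # 10 subjects, both visits; subjects 1-3 switch, the rest are stable
  specs <- list()
  for (s in 1:10) {
    for (v in 1:2) {
      present <- if (s <= 3) (v == 1) else (s %% 2 == 0)
      specs[[length(specs) + 1]] <- list(
        subject = sprintf("S%02d", s), habitat = "tongue", visit = v,
        contigs = if (present) present_contigs(marker, sprintf("s%dv%d", s, v))
                  else absent_contigs(sprintf("s%dv%d", s, v)))
    }
  }
  co <- mk_cohort(specs)
  st <- compute_f_switch(marker, co, "tongue")
  expect_equal(st$n_subjects, 10)
  expect_equal(st$n_switch, 3)
  expect_equal(st$f_switch, 0.3)
  expect_equal(sum(st$transitions), 10)
  expect_equal(unname(st$transitions["present", "absent"]), 3)

  # identical visits give f_switch = 0
  specs0 <- list()
  for (s in 1:4) for (v in 1:2)
    specs0[[length(specs0) + 1]] <- list(
      subject = sprintf("S%02d", s), habitat = "tongue", visit = v,
      contigs = present_contigs(marker, sprintf("q%d", s)))
  expect_equal(compute_f_switch(marker, mk_cohort(specs0), "tongue")$f_switch, 0)
})

test_that("indeterminate calls exclude a subject from both numerator and denominator", {
  set.seed(52)
  marker <- setNames(rand_prot(480), "mk")
  fuzzy <- setNames(mut_prot(marker_slice(marker, 41, 160), 0.45), "fz")
  specs <- list(
    list(subject = "S01", habitat = "tongue", visit = 1,
         contigs = present_contigs(marker, "a")),
    list(subject = "S01", habitat = "tongue", visit = 2,
         contigs = absent_contigs("b")),
    list(subject = "S02", habitat = "tongue", visit = 1, contigs = fuzzy),
    list(subject = "S02", habitat = "tongue", visit = 2,
         contigs = present_contigs(marker, "c")))
  st <- compute_f_switch(marker, mk_cohort(specs), "tongue")
  expect_equal(st$n_subjects, 1)
  expect_equal(st$f_switch, 1)
  expect_equal(st$excluded_subjects, "S02")
})

test_that("oral aggregation uses any-present/all-absent and its denominator can exceed per-habitat ones", {
  set.seed(53)
  marker <- setNames(rand_prot(480), "mk")
  fuzzy <- function(tag) setNames(mut_prot(marker_slice(marker, 41, 160), 0.45),
                                  paste0(tag, "_fz"))
  # present in the tongue only, both visits: aggregate present, no switch
  sp1 <- list(
    list(subject = "S01", habitat = "tongue", visit = 1,
         contigs = present_contigs(marker, "a")),
    list(subject = "S01", habitat = "palate", visit = 1,
         contigs = absent_contigs("b")),
    list(subject = "S01", habitat = "tongue", visit = 2,
         contigs = present_contigs(marker, "c")),
    list(subject = "S01", habitat = "palate", visit = 2,
         contigs = absent_contigs("d")))
  st1 <- compute_f_switch_oral_aggregate(marker, mk_cohort(sp1),
                                         c("tongue", "palate"))
  expect_equal(st1$f_switch, 0)

  # one habitat present at visit 1, all absent at visit 2: a switch
  sp2 <- list(
    list(subject = "S01", habitat = "tongue", visit = 1,
         contigs = present_contigs(marker, "a")),
    list(subject = "S01", habitat = "palate", visit = 1,
         contigs = absent_contigs("b")),
    list(subject = "S01", habitat = "tongue", visit = 2,
         contigs = absent_contigs("c")),
    list(subject = "S01", habitat = "palate", visit = 2,
         contigs = absent_contigs("d")))
  st2 <- compute_f_switch_oral_aggregate(marker, mk_cohort(sp2),
                                         c("tongue", "palate"))
  expect_equal(st2$f_switch, 1)

  # constructed counterexample: the aggregate f_switch exceeds every
  # per-habitat f_switch because the exclusion rules act on different
  # subjects per habitat
  sp3 <- list(
    # S01: tongue switches present -> absent; palate absent throughout
    list(subject = "S01", habitat = "tongue", visit = 1,
         contigs = present_contigs(marker, "a")),
    list(subject = "S01", habitat = "palate", visit = 1,
         contigs = absent_contigs("b")),
    list(subject = "S01", habitat = "tongue", visit = 2,
         contigs = absent_contigs("c")),
    list(subject = "S01", habitat = "palate", visit = 2,
         contigs = absent_contigs("d")),
    # S02: tongue stable absent; palate indeterminate at visit 1 (so the
    # aggregate is indeterminate and S02 drops from the aggregate)
    list(subject = "S02", habitat = "tongue", visit = 1,
         contigs = absent_contigs("e")),
    list(subject = "S02", habitat = "palate", visit = 1,
         contigs = fuzzy("f")),
    list(subject = "S02", habitat = "tongue", visit = 2,
         contigs = absent_contigs("g")),
    list(subject = "S02", habitat = "palate", visit = 2,
         contigs = absent_contigs("h")))
  co3 <- mk_cohort(sp3)
  agg <- compute_f_switch_oral_aggregate(marker, co3, c("tongue", "palate"))
  tng <- compute_f_switch(marker, co3, "tongue")
  pal <- compute_f_switch(marker, co3, "palate")
  expect_equal(agg$f_switch, 1)      # S01 switches, S02 excluded
  expect_equal(tng$f_switch, 0.5)    # S01 switches, S02 stable
  expect_equal(pal$f_switch, 0)      # S01 stable, S02 excluded
  expect_gt(agg$f_switch, max(tng$f_switch, pal$f_switch))
})

test_that("the generated switching probability is recovered and calls are threshold-robust", {
  cfg <- sim_config(seed = 54, n_families = 1, genes_per_family = 1,
                    family_divergence = 0.05, n_subjects = 100, visits = 2,
                    habitats = "buccal_mucosa", presence_prob = 0.7,
                    switch_prob = 0.36,
                    contig_length_aa = c(mean = 200, sd = 20),
                    min_contig_aa = 160, n_background_contigs = 5,
                    copies_per_family = 2)
  lib <- generate_reference_library(cfg)
  co <- generate_cohort(lib, cfg)
  marker <- setNames(as.character(lib$seqs[[1]]), "fam001")
  calls <- phagemark:::compute_presence_calls(marker, co)
  st <- compute_f_switch(marker, co, "buccal_mucosa", calls = calls)
  expect_gt(st$n_subjects, 80)
  expect_lt(abs(st$f_switch - 0.36), 0.1)

  # lowering the presence identity threshold from 70 to 55 leaves the
  # statistic unchanged when planted divergence is far below the threshold
  th55 <- presence_thresholds(present_min_identity = 55)
  st55 <- compute_f_switch(marker, co, "buccal_mucosa", thresholds = th55)
  expect_equal(st55$f_switch, st$f_switch)
})
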