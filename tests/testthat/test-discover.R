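# The marker-discovery filtering cascade.

make_discovery_fixture <- function(seed = 31, divergence = 0.05,
                                   terminase_fraction = 0.5,
                                   copies = 6L, n_fam = 6L) {
  cfg <- sim_config(seed = seed, n_families = n_fam, genes_per_family = 1,
                    family_divergence = divergence,
                    terminase_fraction = terminase_fraction,
                    contig_length_aa = c(mean = 130, sd = 15),
                    min_contig_aa = 90, n_background_contigs = 100,
                    copies_per_family = copies)
  lib <- generate_reference_library(cfg)
  fams <- unique(lib$genes$family_id)
  mg <- generate_metagenome(lib, fams, cfg, id = "d1")$metagenome
  cl <- cluster_references(compute_signatures(lib, mg))
  list(cfg = cfg, lib = lib, fams = fams, mg = mg, cl = cl)
}

test_that("candidate gates: annotation, signature size, representative identity", {
  fx <- make_discovery_fixture()
  cand <- filter_candidates(fx$cl, fx$lib, fx$mg)
  terl <- fx$lib$genes$ref_id[fx$lib$genes$is_terminase]
  # only terminase-annotated references pass; containment in ground truth
  expect_true(all(cand$ref_id %in% terl))
  expect_true(all(cand$signature_size >= 5))
  expect_true(all(cand$identity_to_rep >= 10))
  expect_gt(nrow(cand), 0)

  # decoy-annotated reference is rejected even with a strong signature
  decoy <- setdiff(fx$cl$retained, terl)
  expect_false(any(decoy %in% cand$ref_id))

  # a signature of size 4 fails the size gate
  fx4 <- make_discovery_fixture(seed = 32, copies = 4L)
  cand4 <- filter_candidates(fx4$cl, fx4$lib, fx4$mg)
  sizes <- vapply(fx4$cl$signatures[fx4$cl$retained],
                  function(s) length(s$contig_ids), 0L)
  expect_true(all(sizes <= 4))
  expect_equal(nrow(cand4), 0)
})

test_that("the cross-dataset screen separates conserved from diverged families", {
  cfg <- sim_config(seed = 33, n_families = 2, genes_per_family = 1,
                    family_divergence = 0.05, terminase_fraction = 1,
                    contig_length_aa = c(mean = 130, sd = 10),
                    min_contig_aa = 100, n_background_contigs = 60,
                    copies_per_family = 6)
  lib <- generate_reference_library(cfg)
  mgA <- generate_metagenome(lib, c("fam001", "fam002"), cfg, id = "A",
                             divergence = c(fam001 = 0.05, fam002 = 0.05))
  # second dataset: fam001 stays conserved, fam002 drifts far
  mgB <- generate_metagenome(lib, c("fam001", "fam002"), cfg, id = "B",
                             divergence = c(fam001 = 0.05, fam002 = 0.4))
  cl <- cluster_references(compute_signatures(lib, mgA$metagenome))
  cand <- filter_candidates(cl, lib, mgA$metagenome)
  expect_equal(sort(cand$ref_id), c("fam001_g01", "fam002_g01"))
  kept <- cross_dataset_screen(cand, mgB$metagenome)
  expect_true("fam001_g01" %in% kept$ref_id)
  expect_false("fam002_g01" %in% kept$ref_id)

  # a metagenome containing the identical fragment always retains it
  ident <- mk_metagenome("ident", setNames(cand$fragment_seq, cand$ref_id))
  expect_equal(nrow(cross_dataset_screen(cand, ident)), nrow(cand))

  # background-only second dataset rejects everything
  bg <- generate_metagenome(lib, character(0), cfg, id = "bg")$metagenome
  expect_equal(nrow(cross_dataset_screen(cand, bg)), 0)
})

test_that("redundancy removal keeps one candidate per homology component", {
  set.seed(404)
  anc <- vapply(1:3, function(i) rand_prot(120), "")
  frags <- c()
  for (g in 1:3) for (k in 1:3)
    frags[sprintf("cand%d%d", g, k)] <- mut_prot(anc[g], 0.1)
  cand <- data.frame(ref_id = names(frags),
                     signature_size = c(9, 5, 7, 6, 8, 4, 3, 10, 2),
                     fragment_seq = unname(frags), stringsAsFactors = FALSE)
  out <- remove_redundant(cand)

  # oracle: connected components via igraph over the same homology relation
  n <- nrow(cand)
  edges <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sc <- sw_score_oracle(cand$fragment_seq[i], cand$fragment_seq[j])
    ev <- karlin_evalue(sc, nchar(cand$fragment_seq[i]),
                        nchar(cand$fragment_seq[j]))
    if (sc > 0 && ev <= 0.001) edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  expect_equal(nrow(out), length(unique(comp)))
  expected <- vapply(split(seq_len(n), comp), function(m)
    cand$ref_id[m[order(-cand$signature_size[m], cand$ref_id[m])][1]], "")
  expect_setequal(out$ref_id, unname(expected))

  # survivors are pairwise non-homologous
  again <- remove_redundant(out)
  expect_equal(nrow(again), nrow(out))

  # two identical fragments collapse; non-homologous sets pass unchanged
  dup <- cand[c(1, 1), ]; dup$ref_id <- c("x1", "x2")
  expect_equal(nrow(remove_redundant(dup)), 1)
  indep <- data.frame(ref_id = c("a", "b", "c"), signature_size = 5,
                      fragment_seq = vapply(1:3, function(i) rand_prot(100), ""),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(remove_redundant(indep)), 3)
})

test_that("full-length selection maximizes the gap-penalized equal-weighted identity", {
  set.seed(505)
  # singleton database
  frag <- rand_prot(150)
  marker_full <- paste0(rand_prot(150), frag, rand_prot(150))
  fl <- select_full_length(list(ref_id = "cand1", fragment_seq = frag),
                           list(db1 = c(only = marker_full)))
  expect_s3_class(fl, "FullLengthMarker")
  expect_equal(fl$sequence, marker_full)
  expect_equal(fl$mean_weighted_identity, 100)

  # a full-length sequence beats a half-length identical fragment
  half <- substr(marker_full, 1, 225)
  fl2 <- select_full_length(list(ref_id = "cand1", fragment_seq = frag),
                            list(db1 = c(full = marker_full, half = half)))
  expect_equal(fl2$source_id, "full")

  # 8 homologs across 3 databases vs an independent recomputation of the
  # scoring formula on the same alignment
  anc <- rand_prot(420)
  seqs <- c(full1 = mut_prot(anc, 0.03),
            full2 = mut_prot(anc, 0.05),
            trunc1 = substr(mut_prot(anc, 0.03), 1, 280),
            full3 = mut_prot(anc, 0.08),
            trunc2 = substr(mut_prot(anc, 0.05), 60, 420),
            full4 = mut_prot(anc, 0.04),
            full5 = mut_prot(anc, 0.06),
            trunc3 = substr(mut_prot(anc, 0.02), 1, 350))
  dbs <- list(dbA = Biostrings::AAStringSet(seqs[1:3]),
              dbB = Biostrings::AAStringSet(seqs[4:5]),
              dbC = Biostrings::AAStringSet(seqs[6:8]))
  frag2 <- substr(anc, 100, 260)
  fl3 <- select_full_length(list(ref_id = "cand2", fragment_seq = frag2), dbs)
  expect_s3_class(fl3, "FullLengthMarker")

  # oracle: collect with the same gate, rescore on the same center-star
  # alignment with an independently coded formula
  src <- c(dbA = 3, dbB = 2, dbC = 3)
  collected <- setNames(unname(seqs),
                        paste0(rep(names(src), src), "::", names(seqs)))
  keep <- vapply(seqs, function(s) {
    h <- align_local(frag2, s)
    !is.null(h) && h$percent_identity >= 70
  }, TRUE)
  collected <- collected[keep]
  msa <- center_star_msa(collected)
  dbtag <- sub("::.*", "", rownames(msa))
  pct <- function(a, b) {
    ga <- a %in% c("-", "."); gb <- b %in% c("-", ".")
    100 * sum(a == b & !ga) / sum(!(ga & gb))
  }
  score <- setNames(numeric(nrow(msa)), rownames(msa))
  for (s in rownames(msa)) {
    per_db <- c()
    for (d in unique(dbtag)) {
      others <- rownames(msa)[dbtag == d & rownames(msa) != s]
      if (!length(others)) next
      per_db <- c(per_db, mean(vapply(others, function(t)
        pct(msa[s, ], msa[t, ]), 0)))
    }
    score[s] <- mean(per_db)
  }
  lens <- nchar(collected[names(score)])
  best <- names(score)[order(-score, -lens, names(score))][1]
  expect_equal(paste0(fl3$source_db, "::", fl3$source_id), best)
  expect_equal(fl3$mean_weighted_identity, unname(score[best]))

  # no qualifying sequence is reported, not raised
  miss <- select_full_length(list(ref_id = "c", fragment_seq = rand_prot(120)),
                             list(db1 = c(x = rand_prot(400))))
  expect_equal(miss$status, "no_qualifying_sequence")
})

test_that("center-star alignment preserves sequences and builds one frame", {
  set.seed(606)
  anc <- rand_prot(200)
  seqs <- c(a = anc, b = mut_prot(anc, 0.1), c = substr(anc, 40, 160),
            d = mut_prot(substr(anc, 1, 150), 0.05))
  msa <- center_star_msa(seqs)
  expect_equal(attr(msa, "center"), "a")
  expect_equal(nrow(msa), 4)
  degapped <- apply(msa, 1, function(r) paste(r[r != "-"], collapse = ""))
  expect_identical(degapped[names(seqs)], seqs)
  # identical sequences align without gaps
  same <- center_star_msa(c(x = anc, y = anc, z = anc))
  expect_equal(ncol(same), nchar(anc))
  expect_false(any(same == "-"))
})
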