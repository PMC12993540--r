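# Amplicon read processing: joining, quality filtering, demultiplexing,
# OTU clustering.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
qstr <- function(q) rawToChar(as.raw(q + 33L))

test_that("pair joining accepts only mismatch-free full overlaps", {
  s <- "ACGTACGTGGCCTTAA"
  r1 <- data.frame(id = "r1", seq = s, qual = qstr(rep(35, 16)))
  r2 <- data.frame(id = "r1", seq = rc(s), qual = qstr(c(rep(38, 8), rep(30, 8))))
  j <- join_pairs(r1, r2)
  expect_equal(j$status, "joined")
  expect_equal(nchar(j$read$seq), 16)
  # joined quality is the per-base maximum (r2 reversed)
  expect_equal(phagemark:::phred_ints(j$read$qual),
               pmax(rep(35, 16), rev(c(rep(38, 8), rep(30, 8)))))

  # one mismatching base: eliminated
  bad <- r2; substr(bad$seq, 5, 5) <- chartr("ACGT", "TGCA", substr(bad$seq, 5, 5))
  jb <- join_pairs(r1, bad)
  expect_equal(jb$status, "rejected")
  expect_equal(jb$reason, "overlap_mismatch")

  # length mismatch: rejected with its own reason
  short <- data.frame(id = "r1", seq = substr(rc(s), 1, 10), qual = qstr(rep(35, 10)))
  expect_equal(join_pairs(r1, short)$reason, "length_mismatch")
})

test_that("join acceptance tracks the substitution error model", {
  markers <- data.frame(marker = "HB1", fwd_primer = "ACGTGGC",
                        rev_primer = "TTGCAGC",
                        template = strrep("GATC", 25), stringsAsFactors = FALSE)
  bc <- data.frame(sample = "s1", barcode = "AAAAAA")
  e <- 0.01
  cfg <- sim_config(seed = 71, amplicon_error_rate = e, amplicon_reads = 800)
  run <- generate_amplicon_run(markers, bc, cfg)
  jt <- phagemark:::join_read_table(run$r1, run$r2)
  L <- nchar(run$r1$seq[1])
  # per base the mates disagree w.p. 2e(1-e) + (2/3)e^2
  p_dis <- 2 * e * (1 - e) + (2 / 3) * e^2
  expected <- (1 - p_dis)^L
  got <- nrow(jt$reads) / nrow(run$r1)
  expect_lt(abs(got - expected), 0.05)
  # accounting is exact
  expect_equal(nrow(jt$reads) + nrow(jt$discards), nrow(run$r1))
})

test_that("the quality filter exempts the first and last two bases", {
  mk <- function(id, quals) data.frame(id = id, seq = strrep("A", length(quals)),
                                       qual = qstr(quals))
  reads <- rbind(mk("all40", rep(40, 30)),
                 mk("edge20", c(20, rep(40, 29))),
                 mk("inner20", c(rep(40, 15), 20, rep(40, 14))),
                 mk("tail29", c(rep(40, 28), 29, 40)))
  qf <- quality_filter(reads, phred_min = 30, exempt_ends = 2)
  expect_setequal(qf$reads$id, c("all40", "edge20", "tail29"))
  expect_equal(qf$discards$id, "inner20")
})

test_that("demultiplexing is exact on clean reads, detects barcode errors, and conserves counts", {
  markers <- data.frame(marker = c("HA", "HB1"),
                        fwd_primer = c("ACGTGGC", "GGATCCA"),
                        rev_primer = c("TTGCAGC", "CATGCAG"),
                        template = c(strrep("GATC", 20), strrep("CCTA", 22)),
                        stringsAsFactors = FALSE)
  bc <- data.frame(sample = c("s1", "s2"), barcode = c("AAAAAA", "CCCCCC"))
  expected_len <- c(HA = 80L, HB1 = 88L)

  cfg0 <- sim_config(seed = 72, amplicon_error_rate = 0, amplicon_reads = 25)
  run <- generate_amplicon_run(markers, bc, cfg0)
  jt <- phagemark:::join_read_table(run$r1, run$r2)
  dm <- demultiplex(jt$reads, bc, markers, expected_len)
  expect_equal(nrow(dm$bins), nrow(run$truth))
  m <- merge(dm$bins, run$truth, by = "id")
  expect_true(all(m$sample.x == m$sample.y))
  expect_true(all(m$marker.x == m$marker.y))
  # inserts reconstruct the templates exactly
  expect_true(all(m$insert == markers$template[match(m$marker.x, markers$marker)]))

  # one substituted barcode base is detected and discarded
  poisoned <- jt$reads[1, ]
  substr(poisoned$seq, 2, 2) <- "G"
  dm1 <- demultiplex(poisoned, bc, markers, expected_len)
  expect_equal(nrow(dm1$bins), 0)
  expect_equal(dm1$discards$stage, "barcode")

  # ambiguous barcode tables are a configuration error
  expect_error(demultiplex(jt$reads,
                           data.frame(sample = c("a", "b"),
                                      barcode = c("AAAAAA", "AAAAAC")),
                           markers, expected_len),
               "Hamming")

  # noisy run: perfect precision, sub-100% recall, exact accounting
  cfg1 <- sim_config(seed = 73, amplicon_error_rate = 0.01,
                     amplicon_reads = 150)
  runN <- generate_amplicon_run(markers, bc, cfg1)
  jtN <- phagemark:::join_read_table(runN$r1, runN$r2)
  dmN <- demultiplex(jtN$reads, bc, markers, expected_len)
  expect_equal(nrow(jtN$reads) + nrow(jtN$discards), nrow(runN$r1))
  expect_equal(nrow(dmN$bins) + nrow(dmN$discards), nrow(jtN$reads))
  mN <- merge(dmN$bins, runN$truth, by = "id")
  expect_true(all(mN$sample.x == mN$sample.y))   # no cross-assignment
  expect_true(all(mN$marker.x == mN$marker.y))
  expect_lt(nrow(dmN$bins), nrow(runN$r1))       # recall < 100%
})

test_that("OTU clustering: limits, invariants, and order stability", {
  set.seed(74)
  dna <- c("A", "C", "G", "T")
  rand_dna <- function(n) paste(sample(dna, n, replace = TRUE), collapse = "")
  mut_dna <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(dna, ch[i]), 1)
    paste(ch, collapse = "")
  }

  # all-identical input collapses to one OTU
  same <- setNames(rep(rand_dna(120), 6), paste0("r", 1:6))
  o1 <- cluster_otus(same, 0.95)
  expect_length(o1$representatives, 1)

  # threshold 1.0 separates every unique sequence
  base <- rand_dna(100)
  uniq <- setNames(c(base, mut_dna(base, 1), mut_dna(base, 2)), paste0("u", 1:3))
  expect_length(cluster_otus(uniq, 1.0)$representatives, 3)

  # 30-sequence set: membership satisfies the representative-identity
  # invariant, re-checked independently
  centers <- vapply(1:5, function(i) rand_dna(150), "")
  seqs <- c()
  for (ci in 1:5) {
    seqs[paste0("c", ci, "_0")] <- centers[ci]
    for (k in 1:5) seqs[paste0("c", ci, "_", k)] <- mut_dna(centers[ci], 3)
  }
  # skew abundances so centroid order is deterministic and meaningful
  seqs <- c(seqs, setNames(rep(centers[1], 4), paste0("dup", 1:4)))
  otus <- cluster_otus(seqs, 0.95)
  expect_equal(nrow(otus$assignments), length(seqs))
  expect_false(anyDuplicated(otus$assignments$id) > 0)
  ident <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 2, gapExtension = 1)
    Biostrings::nmatch(pa) / nchar(pa)
  }
  for (r in names(otus$clusters)) {
    rep_seq <- otus$representatives[[r]]
    for (id in otus$clusters[[r]]) {
      expect_gte(ident(seqs[[id]], rep_seq), 0.95)
    }
  }

  # identical multiset in another order gives identical clusters
  perm <- sample(length(seqs))
  otus2 <- cluster_otus(seqs[perm], 0.95)
  expect_identical(otus$representatives, otus2$representatives)
  expect_identical(lapply(otus$clusters, sort), lapply(otus2$clusters, sort))
})
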