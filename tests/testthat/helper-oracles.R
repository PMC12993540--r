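# Independent oracles and small fixture builders shared across tests.
# These deliberately re-implement the logic under test from scratch.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_prot <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

mut_prot <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA, ch[i]), 1)
  paste(ch, collapse = "")
}

div_frac <- function(a, b) {
  mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

blosum62x <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0
  m[, "X"] <- 0
  m
})

# Quadratic-time affine-gap Smith-Waterman score (gap of length k costs
# open + k * ext), independent of the package's alignment backend.
sw_score_oracle <- function(a, b, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-1e9, n + 1, m + 1)
  F <- matrix(-1e9, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + blosum62x[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Construct a signature object as compute_signatures() would emit it.
fake_sig <- function(ref_id, contig_ids, best_e) {
  e <- setNames(seq(best_e, best_e * 10, length.out = length(contig_ids)),
                contig_ids)
  list(ref_id = ref_id, contig_ids = contig_ids,
       representative = contig_ids[1], best_e = best_e, e_values = e)
}

fake_sigmap <- function(sigs) {
  names(sigs) <- vapply(sigs, function(s) s$ref_id, "")
  class(sigs) <- "SignatureMap"
  sigs
}

# Brute-force re-evaluation of the greedy retention rule, written as a
# straightforward loop over a priority table.
greedy_oracle <- function(sigmap, threshold = 0.5) {
  tab <- data.frame(ref = names(sigmap),
                    size = vapply(sigmap, function(s) length(s$contig_ids), 0L),
                    best = vapply(sigmap, function(s) s$best_e, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$size, tab$best, tab$ref), ]
  alive <- setNames(rep(TRUE, nrow(tab)), tab$ref)
  retained <- character(0)
  for (r in tab$ref) {
    if (!alive[[r]]) next
    retained <- c(retained, r)
    alive[[r]] <- FALSE
    for (s in names(alive)[alive]) {
      shared <- length(intersect(sigmap[[r]]$contig_ids, sigmap[[s]]$contig_ids))
      frac <- shared / min(length(sigmap[[r]]$contig_ids),
                           length(sigmap[[s]]$contig_ids))
      if (frac > threshold) alive[[s]] <- FALSE
    }
  }
  retained
}

# Build a Metagenome object directly from named contig sequences.
mk_metagenome <- function(id, contigs, subject = NA, habitat = NA, visit = NA) {
  structure(list(id = id, contigs = Biostrings::AAStringSet(contigs),
                 subject = subject, habitat = habitat, visit = visit),
            class = "Metagenome")
}

# Build a Cohort object from a list of metagenome specs:
# list(list(subject=, habitat=, visit=, contigs=), ...)
mk_cohort <- function(specs) {
  mgs <- list()
  design <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    id <- sprintf("mg_%s_%s_v%d_%02d", sp$subject, sp$habitat, sp$visit, i)
    mgs[[id]] <- mk_metagenome(id, sp$contigs, sp$subject, sp$habitat, sp$visit)
    design[[i]] <- data.frame(subject = sp$subject, habitat = sp$habitat,
                              visit = sp$visit, metagenome_id = id,
                              stringsAsFactors = FALSE)
  }
  structure(list(metagenomes = mgs, design = do.call(rbind, design),
                 presence = NULL, truth = NULL), class = "Cohort")
}

# Fragment presence fixtures: a verbatim slice of the marker (=> present),
# an empty/background set (=> absent), or a heavily mutated slice
# (=> indeterminate).
marker_slice <- function(marker_seq, start, len) {
  substr(marker_seq, start, start + len - 1)
}
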