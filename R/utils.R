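# Shared internal helpers.

# The 20 standard amino acids (one-letter), fixed order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible RNG seed for a labelled generator stream
#'
#' Each synthetic-data generator draws from its own RNG stream derived from
#' the master seed and a stable text label, so adding one generator to a
#' workflow never perturbs the output of another.
#'
#' @param seed Master integer seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "reference_library")
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + abs(seed)) %% 2147483647)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_stream <- function(seed, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(stream_seed(seed, label))
  expr
}

# Random protein of length n, uniform over the 20 standard residues.
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Point-mutate a protein at per-site rate `rate`; substitutions are uniform
# over the 19 other residues, so every mutation is observable as divergence.
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Integer lengths from a normal(mean, sd), clamped below at `floor`.
draw_lengths <- function(n, mean, sd, floor) {
  pmax(as.integer(round(rnorm(n, mean, sd))), as.integer(floor))
}

# Proportion of differing sites between two equal-length strings.
seq_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

as_aa_string <- function(x) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  Biostrings::AAString(x)
}

as_aa_set <- function(x) {
  if (is(x, "AAStringSet")) return(x)
  Biostrings::AAStringSet(x)
}

# Convert an aligned sequence collection (equal-width AAStringSet or
# character matrix) to a character matrix of single residues.
as_aln_matrix <- function(x) {
  if (is.matrix(x) && is.character(x)) return(x)
  if (is(x, "AAMultipleAlignment")) x <- as(x, "AAStringSet")
  if (is(x, "AAStringSet") || is(x, "DNAStringSet")) x <- as.character(x)
  if (is.character(x)) {
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("alignment frame mismatch: unequal row widths")
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
    return(m)
  }
  stop("cannot interpret input as an alignment")
}

is_gap <- function(x) x == "-" | x == "."
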