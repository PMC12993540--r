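# Synthetic barcoded amplicon runs (paired FASTQ with ground truth).

DNA4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

# Substitute bases at per-base rate; returns list(seq, n_errors).
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_errors = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(DNA4, chars[i]), 1L)
  list(seq = paste(chars, collapse = ""), n_errors = length(hit))
}

phred_string <- function(q) rawToChar(as.raw(q + 33L))

phred_ints <- function(s) as.integer(charToRaw(s)) - 33L

# Sample one concrete expansion of an IUPAC-degenerate primer.
sample_expansion <- function(primer) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(primer, "", fixed = TRUE)[[1]]], "")
  paste(vapply(sets, function(b) if (length(b) == 1L) b else sample(b, 1L), ""),
        collapse = "")
}

dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a synthetic barcoded paired-end amplicon run
#'
#' Emulates targeted sequencing of marker amplicons: each forward read is
#' `barcode + forward primer + insert + revcomp(reverse primer)` (a concrete
#' expansion is sampled per read for degenerate primers), and the reverse
#' read is the full reverse complement, so the pair overlap spans the entire
#' fragment. Per-base substitution errors are injected independently into
#' both mates at `config$amplicon_error_rate`; Phred qualities are drawn
#' uniformly from 35--40.
#'
#' @param markers data.frame with columns `marker`, `fwd_primer`,
#'   `rev_primer` (IUPAC nucleotide strings) and `template` (the concrete
#'   insert sequence amplified for that marker).
#' @param barcode_map data.frame with columns `sample` and `barcode`;
#'   barcodes must be unique, equal-length, and pairwise Hamming distance
#'   >= 2 (error-detecting).
#' @param config A [sim_config()] object (`amplicon_reads`,
#'   `amplicon_error_rate`, `seed`).
#' @param dir Optional directory; when given, `R1.fastq`, `R2.fastq` and
#'   `truth.tsv` are written there.
#' @return list with `r1` and `r2` (data.frames `id`, `seq`, `qual` with
#'   Phred+33 quality strings) and `truth` (data.frame `id`, `sample`,
#'   `marker`, `n_errors_r1`, `n_errors_r2`, `error_injected`).
#' @export
generate_amplicon_run <- function(markers, barcode_map, config, dir = NULL) {
  validate_sim_config(config)
  stopifnot(all(c("marker", "fwd_primer", "rev_primer", "template") %in% names(markers)),
            all(c("sample", "barcode") %in% names(barcode_map)))
  validate_barcodes(barcode_map$barcode)

  with_stream(config$seed, "amplicon_run", {
    r1 <- list(); r2 <- list(); truth <- list()
    for (si in seq_len(nrow(barcode_map))) {
      bc <- barcode_map$barcode[si]
      for (mi in seq_len(nrow(markers))) {
        for (k in seq_len(config$amplicon_reads)) {
          fwd <- sample_expansion(markers$fwd_primer[mi])
          rev <- sample_expansion(markers$rev_primer[mi])
          frag <- paste0(bc, fwd, markers$template[mi], dna_revcomp(rev))
          id <- sprintf("%s_%s_r%04d", barcode_map$sample[si],
                        markers$marker[mi], k)
          m1 <- mutate_dna(frag, config$amplicon_error_rate)
          m2 <- mutate_dna(dna_revcomp(frag), config$amplicon_error_rate)
          L <- nchar(frag)
          r1[[length(r1) + 1L]] <- data.frame(
            id = id, seq = m1$seq,
            qual = phred_string(sample(35:40, L, replace = TRUE)),
            stringsAsFactors = FALSE)
          r2[[length(r2) + 1L]] <- data.frame(
            id = id, seq = m2$seq,
            qual = phred_string(sample(35:40, L, replace = TRUE)),
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            id = id, sample = barcode_map$sample[si],
            marker = markers$marker[mi], n_errors_r1 = m1$n_errors,
            n_errors_r2 = m2$n_errors,
            error_injected = (m1$n_errors + m2$n_errors) > 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- list(r1 = do.call(rbind, r1), r2 = do.call(rbind, r2),
                truth = do.call(rbind, truth))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_fastq(out$r1, file.path(dir, "R1.fastq"))
      write_fastq(out$r2, file.path(dir, "R2.fastq"))
      write_tsv(out$truth, file.path(dir, "truth.tsv"))
    }
    out
  })
}

validate_barcodes <- function(barcodes) {
  if (anyDuplicated(barcodes))
    stop("barcode collision: duplicated barcodes in map", call. = FALSE)
  if (length(unique(nchar(barcodes))) != 1L)
    stop("barcodes must all have the same length", call. = FALSE)
  if (length(barcodes) > 1L) {
    for (p in seq_len(length(barcodes) - 1L)) {
      for (q in seq(p + 1L, length(barcodes))) {
        d <- sum(strsplit(barcodes[p], "")[[1]] != strsplit(barcodes[q], "")[[1]])
        if (d < 2L)
          stop(sprintf("ambiguous barcode table: '%s' and '%s' are within Hamming distance 1",
                       barcodes[p], barcodes[q]), call. = FALSE)
      }
    }
  }
  invisible(barcodes)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#'
#' @param path FASTQ path (Phred+33).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(dna), seq = as.character(dna),
             qual = as.character(S4Vectors::mcols(dna)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
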