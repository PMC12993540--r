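# Protein local alignment, percent identity and E-values: the alignment
# contract consumed by every other stage. The backend is exact
# Smith-Waterman (Biostrings::pairwiseAlignment) with BLOSUM62 and affine
# gaps (open 11, extend 1), i.e. the scoring system of default blastp.

# BLOSUM62 with X scoring 0 against everything (cached).
scoring_matrix <- function() {
  m <- .pkg_env$blosum62x
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    if ("X" %in% rownames(m)) {
      m["X", ] <- 0L
      m[, "X"] <- 0L
    }
    .pkg_env$blosum62x <- m
  }
  m
}

# Karlin-Altschul parameters for gapped BLOSUM62/11/1.
KA_LAMBDA <- 0.267
KA_K <- 0.041
KA_H <- 0.14

check_protein <- function(x, what) {
  s <- as.character(x)
  if (length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop(sprintf("%s must be a non-empty protein sequence", what), call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), c(AA20, "X"))
  if (length(bad))
    stop(sprintf("%s contains non-standard residues: %s", what,
                 paste(bad, collapse = "")), call. = FALSE)
  s
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with BLOSUM62, gap open 11, gap extend 1 (the
#' scoring system of default `blastp`). `X` residues score 0 against
#' everything. Percent identity is `100 * identities / aligned columns`.
#'
#' @param query,subject Protein sequences (character, `AAString`, or
#'   length-1 `AAStringSet`); names of character vectors or set elements are
#'   used as ids.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param query_id,subject_id Optional ids recorded in the hit.
#' @return One-row data.frame (an alignment hit) with `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `e_value` (`NA`; fill with
#'   [karlin_evalue()] against a database size), `span_aa`, `identities`,
#'   `percent_identity`, and 0-based half-open intervals `query_start`,
#'   `query_end`, `subject_start`, `subject_end`. `NULL` when the optimal
#'   local score is not positive.
#' @export
#' @examples
#' align_local("ACDEF", "ACNEF")[, c("span_aa", "identities", "percent_identity")]
align_local <- function(query, subject, gap_open = 11, gap_extend = 1,
                        query_id = NULL, subject_id = NULL) {
  qid <- query_id %||% (if (!is.null(names(query))) names(query)[1] else "query")
  sid <- subject_id %||% (if (!is.null(names(subject))) names(subject)[1] else "subject")
  q <- check_protein(query, "query")
  s <- check_protein(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(s),
    type = "local", substitutionMatrix = scoring_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  span <- nchar(pa)
  ids <- Biostrings::nmatch(pa)
  data.frame(
    query_id = qid, subject_id = sid,
    raw_score = sc,
    bit_score = (KA_LAMBDA * sc - log(KA_K)) / log(2),
    e_value = NA_real_,
    span_aa = span, identities = ids,
    percent_identity = 100 * ids / span,
    query_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    stringsAsFactors = FALSE)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m' * n' * exp(-lambda * S)` with the standard edge-length
#' correction: the length adjustment `l` solves
#' `l = ln(K * (m - l) * (n - N*l)) / H` (iterated to a fixed point), and
#' `m' = max(m - l, 1)`, `n' = max(n - N*l, N)`. Parameters default to the
#' gapped BLOSUM62/11/1 values lambda = 0.267, K = 0.041, H = 0.14.
#'
#' @param score Raw alignment score(s); vectorised.
#' @param query_len Query length `m` (residues).
#' @param db_residues Total database length `n` (residues).
#' @param n_seqs Number of database sequences `N`.
#' @param lambda,K,H Karlin-Altschul parameters.
#' @param length_correct Apply the edge-length correction (default). Without
#'   it, E is exactly linear in `db_residues`.
#' @return Numeric vector of E-values (monotone decreasing in `score`).
#' @export
#' @examples
#' karlin_evalue(60, query_len = 500, db_residues = 1e6, n_seqs = 2000)
karlin_evalue <- function(score, query_len, db_residues, n_seqs = 1L,
                          lambda = KA_LAMBDA, K = KA_K, H = KA_H,
                          length_correct = TRUE) {
  stopifnot(query_len > 0, db_residues > 0, n_seqs >= 1)
  m <- query_len; n <- db_residues; N <- n_seqs
  l <- 0
  if (length_correct) {
    for (i in 1:50) {
      arg <- K * max(m - l, 1) * max(n - N * l, N)
      l_new <- max(log(arg), 0) / H
      # damped update; also never let the adjustment consume either length
      l_new <- min(l_new, m - 1, (n - N) / N)
      l_new <- max(l_new, 0)
      if (abs(l_new - l) < 1e-6) { l <- l_new; break }
      l <- (l + l_new) / 2
    }
  }
  m_eff <- max(m - l, 1)
  n_eff <- max(n - N * l, N)
  K * m_eff * n_eff * exp(-lambda * score)
}

# Score-only Smith-Waterman of many sequences against one subject.
local_scores <- function(queries, subject, gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    pattern = as_aa_set(queries), subject = as_aa_string(subject),
    type = "local", substitutionMatrix = scoring_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Search a protein database with a query sequence
#'
#' Aligns the query against every database sequence (exact Smith-Waterman),
#' attaches Karlin-Altschul E-values computed against the whole database
#' size, and returns the hits with `E <= e_max`, sorted by ascending E-value
#' (ties: descending bit score, then lexical subject id). One best local
#' alignment is reported per database sequence.
#'
#' @param query Protein sequence.
#' @param database Named `AAStringSet` (or named character vector).
#' @param e_max E-value threshold.
#' @param query_id Optional query id.
#' @return data.frame of alignment hits (zero rows if none qualify).
#' @export
search_database <- function(query, database, e_max = 0.001, query_id = NULL) {
  db <- as_aa_set(database)
  if (length(db) == 0L) stop("database must be non-empty", call. = FALSE)
  if (is.null(names(db))) names(db) <- sprintf("seq%04d", seq_along(db))
  q <- check_protein(query, "query")
  qid <- query_id %||% (if (!is.null(names(query))) names(query)[1] else "query")
  n_db <- sum(Biostrings::width(db))
  scores <- Biostrings::pairwiseAlignment(
    pattern = db, subject = Biostrings::AAString(q), type = "local",
    substitutionMatrix = scoring_matrix(), gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  ev <- karlin_evalue(scores, query_len = nchar(q),
                      db_residues = n_db, n_seqs = length(db))
  keep <- which(ev <= e_max & scores > 0)
  if (!length(keep)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      e_value = numeric(0), span_aa = integer(0),
                      identities = integer(0), percent_identity = numeric(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_start = integer(0), subject_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, lapply(keep, function(i) {
    h <- align_local(q, as.character(db[[i]]), query_id = qid,
                     subject_id = names(db)[i])
    h$e_value <- ev[i]
    h
  }))
  hits <- hits[order(hits$e_value, -hits$bit_score, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}
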