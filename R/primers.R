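# CODEHOP-style degenerate primer design against protein marker alignments:
# a maximally degenerate 3' core encoding conserved amino-acid motifs plus a
# non-degenerate 5' consensus clamp, with degeneracy, melting-temperature,
# GC-clamp and secondary-structure screening.

GC_BASES <- c("G", "C")

iupac_sets <- function() {
  m <- .pkg_env$iupac_sets
  if (is.null(m)) {
    m <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
    .pkg_env$iupac_sets <- m
  }
  m
}

# sorted base string -> IUPAC code
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- vapply(iupac_sets(), function(b) paste(sort(b), collapse = ""), "")
  hit <- names(codes)[codes == key]
  if (!length(hit)) stop("no IUPAC code for base set: ", key, call. = FALSE)
  hit[1L]
}

#' Expand a degenerate IUPAC nucleotide string to all concrete sequences
#'
#' @param x IUPAC string.
#' @param max_expansions Safety cap on the number of expansions.
#' @return Character vector of concrete ACGT sequences (sorted).
#' @export
expand_iupac <- function(x, max_expansions = 100000L) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  sets <- iupac_sets()[chars]
  if (anyNA(names(sets)) || any(!chars %in% names(iupac_sets())))
    stop("invalid IUPAC symbol in: ", x, call. = FALSE)
  n <- prod(lengths(sets))
  if (n > max_expansions) stop("too many expansions: ", n, call. = FALSE)
  out <- do.call(expand.grid,
                 c(rev(sets), list(stringsAsFactors = FALSE)))
  sort(apply(out[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Compress concrete sequences to the minimal covering IUPAC string
#'
#' Per position, the IUPAC code of the union of observed bases. For any
#' valid degenerate string `x`, `compress_iupac(expand_iupac(x)) == x`.
#'
#' @param seqs Equal-length concrete sequences.
#' @return IUPAC string.
#' @export
compress_iupac <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  paste(apply(m, 2L, function(col) iupac_code_for(col)), collapse = "")
}

#' Fold-degeneracy of a degenerate primer
#'
#' Product of the per-position alternative counts.
#'
#' @param x IUPAC string.
#' @return Integer degeneracy.
#' @export
primer_degeneracy <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(iupac_sets())))
    stop("invalid IUPAC symbol in: ", x, call. = FALSE)
  prod(lengths(iupac_sets()[chars]))
}

codons_for_residues <- function(residues) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc %in% residues]
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Largest "exact" degenerate codon box for a residue set: a cartesian
# product of per-position base sets that (a) contains only codons of the
# residue set and (b) covers every residue in the set. A naive IUPAC union
# of all codons violates (a) for residues like Leu (closure YTN encodes
# Phe), so the box is found exhaustively over per-position base subsets.
# Returns list(sets, codons, degeneracy) or NULL when no box covers all
# residues (possible for mixed residue sets, or under 3'-end restriction).
exact_codon_box <- function(residues, allowed_codons = NULL) {
  allowed <- allowed_codons %||% codons_for_residues(residues)
  allowed <- intersect(allowed, codons_for_residues(residues))
  if (!length(allowed)) return(NULL)
  pos_bases <- lapply(1:3, function(p) unique(substr(allowed, p, p)))
  subsets <- function(v) {
    unlist(lapply(seq_along(v), function(k)
      utils::combn(v, k, simplify = FALSE)), recursive = FALSE)
  }
  best <- NULL
  for (a1 in subsets(pos_bases[[1]])) for (a2 in subsets(pos_bases[[2]])) {
    for (a3 in subsets(pos_bases[[3]])) {
      box <- as.vector(outer(outer(a1, a2, paste0), a3, paste0))
      if (!all(box %in% allowed)) next
      if (!all(residues %in% translate_codons(box))) next
      deg <- length(a1) * length(a2) * length(a3)
      key <- paste(iupac_code_for(a1), iupac_code_for(a2), iupac_code_for(a3),
                   sep = "")
      if (is.null(best) || deg > best$degeneracy ||
          (deg == best$degeneracy && key < best$key)) {
        best <- list(sets = list(a1, a2, a3), codons = box, degeneracy = deg,
                     key = key)
      }
    }
  }
  best
}

box_iupac <- function(box) {
  paste(vapply(box$sets, iupac_code_for, ""), collapse = "")
}

# Preferred codon per amino acid used for the non-degenerate consensus
# clamp when no codon-usage table derived from nucleotide alignments is
# supplied (a standard bacterial high-usage choice).
DEFAULT_CODON_USAGE <- c(
  A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG")

#' Column conservation profile over one protein alignment per dataset
#'
#' All dataset alignments must share one coordinate frame (equal widths;
#' build them against a common center, e.g. with [center_star_msa()] seeded
#' by the marker). Residue frequencies are computed per dataset (over
#' non-gap rows) and averaged with equal dataset weights, so datasets with
#' many sequences do not dominate. The anchor score is the column's
#' information content in bits, `log2(20) + sum p log2 p`, a
#' relative-entropy conservation score against a uniform residue
#' background (maximum ~4.32 bits for an invariant column).
#'
#' @param msas Named list with one alignment per dataset (character matrix
#'   or equal-width `AAStringSet`).
#' @return data.frame of class `"ConservationProfile"`: `column`,
#'   `consensus` (equal-weighted majority residue), `consensus_identity`
#'   (percent), `anchor_score` (bits), `spanned` (column covered by every
#'   dataset). The equal-weighted frequency matrix is kept in attribute
#'   `"freqs"`.
#' @export
build_profile <- function(msas) {
  stopifnot(is.list(msas), length(msas) >= 1L)
  mats <- lapply(msas, as_aln_matrix)
  widths <- vapply(mats, ncol, 0L)
  if (length(unique(widths)) != 1L)
    stop("alignment frame mismatch: dataset alignments differ in width",
         call. = FALSE)
  W <- widths[[1L]]
  freqs <- matrix(0, nrow = length(AA20), ncol = W, dimnames = list(AA20, NULL))
  spanned <- rep(TRUE, W)
  for (j in seq_len(W)) {
    per_ds <- list()
    for (m in mats) {
      col <- m[, j]
      col <- col[!is_gap(col)]
      if (!length(col)) { spanned[j] <- FALSE; next }
      tab <- table(factor(col, levels = AA20))
      per_ds[[length(per_ds) + 1L]] <- as.numeric(tab) / sum(tab)
    }
    if (length(per_ds))
      freqs[, j] <- Reduce(`+`, per_ds) / length(per_ds)
  }
  consensus <- apply(freqs, 2L, function(p) AA20[order(-p, AA20)[1L]])
  cons_id <- 100 * freqs[cbind(match(consensus, AA20), seq_len(W))]
  score <- apply(freqs, 2L, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(0)
    log2(20) + sum(p * log2(p))
  })
  out <- data.frame(column = seq_len(W), consensus = consensus,
                    consensus_identity = cons_id, anchor_score = score,
                    spanned = spanned, stringsAsFactors = FALSE)
  attr(out, "freqs") <- freqs
  class(out) <- c("ConservationProfile", class(out))
  out
}

#' Candidate 3' anchor positions in a conservation profile
#'
#' Columns whose conservation (anchor) score reaches `bit_min` bits,
#' restricted to regions spanned by all datasets.
#'
#' @param profile A `ConservationProfile`.
#' @param bit_min Minimum anchor score in bits.
#' @return Integer vector of qualifying columns.
#' @export
find_anchors <- function(profile, bit_min = 3.5) {
  stopifnot(is(profile, "ConservationProfile"))
  profile$column[profile$anchor_score >= bit_min & profile$spanned]
}

#' Design constraints for degenerate primers
#'
#' @param max_degeneracy Fold-degeneracy cap for the whole primer.
#' @param consensus_min Minimum equal-weighted consensus identity (percent)
#'   required of every core column.
#' @param tm_target,tm_tol Melting-temperature target and tolerance (deg C)
#'   for the clamp-length selection (applied to the midpoint of the Tm
#'   range over degenerate expansions).
#' @param core_codons Core lengths (in codons) to try, in order.
#' @param min_residue_freq Residues rarer than this in the core columns may
#'   be dropped to respect the degeneracy cap.
#' @param clamp_max_codons Maximum clamp length in codons.
#' @param max_self_run,max_dimer3_run Rejection caps on the
#'   self-complementarity (hairpin/homodimer proxy) and 3' cross-
#'   complementarity diagnostics.
#' @param conc_nM,na_mM Primer and monovalent-salt concentrations for the
#'   nearest-neighbor Tm model.
#' @return list of class `"primer_constraints"`.
#' @export
primer_constraints <- function(max_degeneracy = 64L, consensus_min = 90,
                               tm_target = 60, tm_tol = 2,
                               core_codons = c(4L, 3L),
                               min_residue_freq = 0.05,
                               clamp_max_codons = 8L,
                               max_self_run = 8L, max_dimer3_run = 4L,
                               conc_nM = 500, na_mM = 50) {
  structure(as.list(environment()), class = "primer_constraints")
}

primer_reject <- function(reason, detail = NULL) {
  structure(list(status = "rejected", reason = reason, detail = detail),
            class = "PrimerRejection")
}

#' Design one CODEHOP-style degenerate primer at an anchor position
#'
#' Builds a maximally degenerate 3' core over the anchor-region residues
#' (every expansion of the core translates into the column residue sets;
#' the 3'-terminal codon is restricted so the primer ends in G or C) and a
#' non-degenerate 5' consensus clamp whose length is chosen so the primer
#' melting temperature reaches the target. Enforcement order for the
#' degeneracy cap: shorten the core, then drop residues rarer than
#' `min_residue_freq`, then reject.
#'
#' @param msas Named list of dataset alignments (as in [build_profile()]).
#' @param anchor Anchor column (the 3'-end residue of a forward core; the
#'   5'-most core residue of a reverse primer's target motif).
#' @param direction `"forward"` or `"reverse"` (reverse primers are built
#'   on the reverse complement of the coding frame).
#' @param constraints A [primer_constraints()] object.
#' @param profile Optional precomputed `ConservationProfile`.
#' @param codon_usage Named character vector amino acid -> preferred codon
#'   for the clamp (defaults to a standard bacterial usage table; supply
#'   your own to match the codon bias of nucleotide alignments).
#' @return A `"DegeneratePrimer"` (fields: `direction`, `sequence`, `core`,
#'   `clamp`, `degeneracy`, `tm` (min/mid/max over expansions),
#'   `gc_clamp`, `target_motif`, `core_columns`, `residue_sets`,
#'   `dropped_residues`, `diagnostics`) or a `"PrimerRejection"` whose
#'   `reason` names the first constraint that could not be met.
#' @export
design_primer <- function(msas, anchor, direction = c("forward", "reverse"),
                          constraints = primer_constraints(),
                          profile = NULL, codon_usage = NULL) {
  direction <- match.arg(direction)
  cst <- constraints
  usage <- codon_usage %||% DEFAULT_CODON_USAGE
  if (is.null(profile)) profile <- build_profile(msas)
  freqs <- attr(profile, "freqs")
  W <- nrow(profile)

  core_design <- NULL
  for (k in cst$core_codons) {
    cols <- if (direction == "forward") seq(anchor - k + 1L, anchor) else
      seq(anchor, anchor + k - 1L)
    if (min(cols) < 1L || max(cols) > W) next
    if (!all(profile$spanned[cols])) next
    if (!all(profile$consensus_identity[cols] >= cst$consensus_min)) {
      core_design <- core_design %||% primer_reject(
        "consensus", sprintf("core column consensus identity below %g%%",
                             cst$consensus_min))
      next
    }
    sets <- lapply(cols, function(j) AA20[freqs[, j] > 0])
    dropped <- character(0)
    repeat {
      # 3'-terminal codon restricted to codons giving a terminal G/C
      boxes <- vector("list", k)
      ok <- TRUE
      for (ci in seq_len(k)) {
        residues <- sets[[ci]]
        allowed <- NULL
        terminal <- (direction == "forward" && ci == k) ||
          (direction == "reverse" && ci == 1L)
        if (terminal) {
          all_cod <- codons_for_residues(residues)
          allowed <- if (direction == "forward")
            all_cod[substr(all_cod, 3, 3) %in% GC_BASES] else
            all_cod[substr(all_cod, 1, 1) %in% GC_BASES]
        }
        box <- exact_codon_box(residues, allowed)
        if (is.null(box)) { ok <- FALSE; bad <- ci; break }
        boxes[[ci]] <- box
      }
      if (!ok) {
        # shed the rarest residue of the failing column, if any is rare
        j <- cols[bad]
        residues <- sets[[bad]]
        if (length(residues) > 1L) {
          rare <- residues[order(freqs[residues, j], residues)][1L]
          sets[[bad]] <- setdiff(residues, rare)
          dropped <- c(dropped, sprintf("%s@%d", rare, j))
          next
        }
        core_design <- primer_reject("gc_clamp",
          "no codon of the anchor residue yields a G/C primer terminus")
        break
      }
      deg <- prod(vapply(boxes, function(b) b$degeneracy, 0))
      if (deg <= cst$max_degeneracy) {
        core_design <- list(cols = cols, sets = sets, boxes = boxes,
                            degeneracy = deg, dropped = dropped, k = k)
        break
      }
      # over the cap: drop the rarest sufficiently-rare residue anywhere
      cand <- NULL
      for (ci in seq_len(k)) {
        j <- cols[ci]
        for (r in sets[[ci]]) {
          if (length(sets[[ci]]) == 1L) next
          f <- freqs[r, j]
          if (f < cst$min_residue_freq &&
              (is.null(cand) || f < cand$f ||
               (f == cand$f && r < cand$r))) {
            cand <- list(ci = ci, r = r, f = f)
          }
        }
      }
      if (is.null(cand)) {
        core_design <- primer_reject("degeneracy",
          sprintf("core degeneracy %d exceeds cap %d", deg, cst$max_degeneracy))
        break
      }
      sets[[cand$ci]] <- setdiff(sets[[cand$ci]], cand$r)
      dropped <- c(dropped, sprintf("%s@%d", cand$r, cols[cand$ci]))
    }
    if (!is(core_design, "PrimerRejection")) break
  }
  if (is.null(core_design))
    return(primer_reject("span", "anchor region not spanned by all datasets"))
  if (is(core_design, "PrimerRejection")) return(core_design)

  core_nt <- paste(vapply(core_design$boxes, box_iupac, ""), collapse = "")

  # clamp: consensus residues upstream (forward) / downstream (reverse) of
  # the core, one preferred codon each; length chosen to hit the Tm target.
  clamp_cols_all <- if (direction == "forward")
    rev(seq_len(min(core_design$cols) - 1L)) else
    seq(max(core_design$cols) + 1L, length.out = max(0L, W - max(core_design$cols)))
  clamp_cols_all <- clamp_cols_all[seq_len(min(length(clamp_cols_all),
                                               cst$clamp_max_codons))]
  clamp_cols_all <- clamp_cols_all[profile$spanned[clamp_cols_all]]

  best <- NULL
  for (len in 0:length(clamp_cols_all)) {
    cols_used <- if (len == 0) integer(0) else clamp_cols_all[seq_len(len)]
    res <- profile$consensus[cols_used]
    codons <- unname(usage[res])
    if (anyNA(codons)) next
    clamp_nt <- if (direction == "forward")
      paste(rev(codons), collapse = "") else paste(codons, collapse = "")
    coding <- if (direction == "forward") paste0(clamp_nt, core_nt) else
      paste0(core_nt, clamp_nt)
    primer <- if (direction == "forward") coding else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    tm <- tm_range(primer, conc_nM = cst$conc_nM, na_mM = cst$na_mM)
    dist <- abs(tm[["mid"]] - cst$tm_target)
    if (is.null(best) || dist < best$dist) {
      best <- list(primer = primer, clamp = clamp_nt, coding = coding,
                   tm = tm, dist = dist, len = len)
    }
  }
  if (is.null(best) || best$dist > cst$tm_tol)
    return(primer_reject("tm",
      sprintf("no clamp length reaches Tm %g +/- %g (closest %.1f)",
              cst$tm_target, cst$tm_tol,
              if (is.null(best)) NA_real_ else best$tm[["mid"]])))

  diag <- check_primer(best$primer, conc_nM = cst$conc_nM, na_mM = cst$na_mM)
  if (diag$self_comp_run > cst$max_self_run)
    return(primer_reject("hairpin",
      sprintf("self-complementary run %d exceeds cap %d",
              diag$self_comp_run, cst$max_self_run)))
  if (diag$homodimer_run3 > cst$max_dimer3_run)
    return(primer_reject("homodimer",
      sprintf("3' self-complementary run %d exceeds cap %d",
              diag$homodimer_run3, cst$max_dimer3_run)))

  motif <- paste(vapply(core_design$sets, function(s)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]"), ""),
    collapse = "")
  structure(list(direction = direction, sequence = best$primer,
                 core = if (direction == "forward") core_nt else
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(core_nt))),
                 clamp = best$clamp,
                 degeneracy = primer_degeneracy(best$primer),
                 tm = best$tm, gc_clamp = diag$gc_clamp,
                 target_motif = motif,
                 core_columns = core_design$cols,
                 residue_sets = core_design$sets,
                 dropped_residues = core_design$dropped,
                 diagnostics = diag),
            class = "DegeneratePrimer")
}

#' @export
print.DegeneratePrimer <- function(x, ...) {
  cat(sprintf("DegeneratePrimer (%s): 5'-%s-3'\n", x$direction, x$sequence))
  cat(sprintf("  core %s | clamp %s | motif %s\n", x$core, x$clamp, x$target_motif))
  cat(sprintf("  degeneracy %d-fold | Tm %.1f (%.1f-%.1f) C | GC clamp %s\n",
              x$degeneracy, x$tm[["mid"]], x$tm[["min"]], x$tm[["max"]],
              x$gc_clamp))
  invisible(x)
}

# ---- primer diagnostics ----------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Can position sets x, y (IUPAC chars) base-pair?
comp_possible_matrix <- function(a, b) {
  sa <- iupac_sets()[strsplit(a, "")[[1]]]
  sb <- iupac_sets()[strsplit(b, "")[[1]]]
  outer(seq_along(sa), seq_along(sb), Vectorize(function(i, j)
    any(COMPLEMENT[sa[[i]]] %in% sb[[j]])))
}

# Longest antiparallel complementary run between IUPAC strings a and b
# (any offset); with `min_sep`, only pairs (i, j) of a vs itself separated
# by at least min_sep positions count (hairpin proxy).
longest_comp_run <- function(a, b, min_sep = 0L) {
  M <- comp_possible_matrix(a, b)
  n <- nrow(M); m <- ncol(M)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (min_sep > 0L && j - i < min_sep) next
      run <- 0L
      ii <- i; jj <- j
      while (ii <= n && jj >= 1L && M[ii, jj]) {
        run <- run + 1L
        ii <- ii + 1L; jj <- jj - 1L
      }
      best <- max(best, run)
    }
  }
  best
}

# Longest complementary run that includes a's 3' terminus (primer-dimer
# extension proxy).
comp_run_3prime <- function(a, b) {
  M <- comp_possible_matrix(a, b)
  n <- nrow(M)
  best <- 0L
  for (j in seq_len(ncol(M))) {
    run <- 0L
    ii <- n; jj <- j
    while (ii >= 1L && jj <= ncol(M) && M[ii, jj]) {
      run <- run + 1L
      ii <- ii - 1L; jj <- jj + 1L
    }
    best <- max(best, run)
  }
  best
}

# Nearest-neighbor Tm (SantaLucia 1998 unified parameters) of a concrete
# primer at concentration conc_nM with na_mM monovalent salt.
nn_tm <- function(seq, conc_nM = 500, na_mM = 50) {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, TG = -22.7,
          GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (any(!chars %in% names(COMPLEMENT)))
    stop("nn_tm requires a concrete ACGT sequence", call. = FALSE)
  nn <- paste0(chars[-length(chars)], chars[-1L])
  H <- sum(dH[nn])
  S <- sum(dS[nn])
  # initiation terms
  init <- function(b) if (b %in% GC_BASES) c(h = 0.1, s = -2.8) else
    c(h = 2.3, s = 4.1)
  H <- H + init(chars[1L])[["h"]] + init(chars[length(chars)])[["h"]]
  S <- S + init(chars[1L])[["s"]] + init(chars[length(chars)])[["s"]]
  S <- S + 0.368 * (length(chars) - 1L) * log(na_mM / 1000)
  R <- 1.987
  ct <- conc_nM * 1e-9
  H * 1000 / (S + R * log(ct / 4)) - 273.15
}

# Tm range over the least- and most-stable expansions of a degenerate
# primer (per position: the weakest = A/T-preferring, strongest =
# G/C-preferring concrete base).
tm_range <- function(primer, conc_nM = 500, na_mM = 50) {
  sets <- iupac_sets()[strsplit(toupper(primer), "")[[1]]]
  pick <- function(bases, pref) {
    b <- intersect(pref, bases)
    if (length(b)) b[1L] else bases[1L]
  }
  weak <- paste(vapply(sets, pick, "", pref = c("A", "T", "G", "C")), collapse = "")
  strong <- paste(vapply(sets, pick, "", pref = c("G", "C", "A", "T")), collapse = "")
  lo <- nn_tm(weak, conc_nM, na_mM)
  hi <- nn_tm(strong, conc_nM, na_mM)
  c(min = min(lo, hi), mid = (lo + hi) / 2, max = max(lo, hi))
}

#' Diagnostics for a (degenerate) primer
#'
#' Reports fold-degeneracy, the nearest-neighbor melting-temperature range
#' over the least- and most-stable degenerate expansions, GC-clamp status
#' (3'-terminal base certainly G/C), the longest self-complementary run
#' (hairpin proxy, requiring a minimal loop separation), the longest
#' 3'-anchored self-complementary run (homodimer proxy) and, when a
#' partner is supplied, the longest 3'-anchored cross-complementary run
#' (heterodimer proxy).
#'
#' @param primer IUPAC string or `DegeneratePrimer`.
#' @param partner Optional partner primer for the heterodimer check.
#' @param conc_nM,na_mM Tm model parameters.
#' @return list: `degeneracy`, `tm` (named min/mid/max), `gc_clamp`,
#'   `self_comp_run`, `homodimer_run3`, `heterodimer_run3` (`NA` without a
#'   partner).
#' @export
check_primer <- function(primer, partner = NULL, conc_nM = 500, na_mM = 50) {
  p <- if (is(primer, "DegeneratePrimer")) primer$sequence else toupper(primer)
  chars <- strsplit(p, "")[[1]]
  if (any(!chars %in% names(iupac_sets())))
    stop("invalid IUPAC symbol in primer", call. = FALSE)
  q <- if (is.null(partner)) NULL else
    if (is(partner, "DegeneratePrimer")) partner$sequence else toupper(partner)
  last <- iupac_sets()[[chars[length(chars)]]]
  list(degeneracy = primer_degeneracy(p),
       tm = tm_range(p, conc_nM, na_mM),
       gc_clamp = all(last %in% GC_BASES),
       self_comp_run = longest_comp_run(p, p, min_sep = 4L),
       homodimer_run3 = comp_run_3prime(p, p),
       heterodimer_run3 = if (is.null(q)) NA_integer_ else comp_run_3prime(p, q))
}
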