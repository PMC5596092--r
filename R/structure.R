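#' Minimum-free-energy secondary structure
#'
#' Folds one RNA (or DNA; T is mapped to U) sequence under the package's
#' simplified nearest-neighbor model ([energy_model()]): stacking energies
#' for adjacent pairs, linear hairpin/bulge/internal-loop penalties, a
#' linear multiloop model, hairpin loops of at least 3 nt, pairs restricted
#' to AU/UA/GC/CG/GU/UG, no pseudoknots. Ties are resolved deterministically
#' with a preference for fewer pairs. The MFE is never positive: the empty
#' structure (energy 0) is always available.
#'
#' @param seq sequence string; alphabet A/C/G/U (T accepted and mapped).
#' @return object of class `fold_result`: `sequence` (RNA), `structure`
#'   (dot-bracket), `energy` (kcal/mol, <= 0), `n_pairs`, `pairs` (matrix of
#'   1-based pair positions).
#' @export
fold_mfe <- function(seq) {
  if (nchar(seq) < 1) stop("sequence must be non-empty")
  rna <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", rna)) stop("invalid alphabet: expected A/C/G/U(T)")
  codes <- seq_codes(rna)
  mod <- energy_model()
  res <- .fold_engine(list(codes), mod$stack, mod$params)
  structure(list(sequence = rna, structure = res$structure,
                 energy = res$energy, n_pairs = res$n_pairs,
                 pairs = res$pairs), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("energy %.2f kcal/mol, %d pairs\n", x$energy, x$n_pairs))
  invisible(x)
}

#' Consensus fold of a pairwise alignment
#'
#' Folds a two-row gapped alignment under the consensus rule: a column pair
#' may form only if both rows form a legal RNA pair there (gap columns can
#' never pair); stack energies are averaged over the rows and every
#' compensatory column pair (both rows substituted, both still pairing)
#' receives the model's compensatory bonus.
#'
#' @param rows character vector of two equal-length gapped sequences
#'   ("-" for gaps).
#' @return `fold_result` over alignment columns.
#' @export
consensus_fold <- function(rows) {
  if (length(rows) != 2) stop("expected exactly two alignment rows")
  if (length(unique(nchar(rows))) != 1) stop("rows of unequal length")
  rna <- chartr("Tt", "Uu", toupper(rows))
  codes <- lapply(rna, seq_codes)
  mod <- energy_model()
  res <- .fold_engine(codes, mod$stack, mod$params)
  structure(list(sequence = rna, structure = res$structure,
                 energy = res$energy, n_pairs = res$n_pairs,
                 pairs = res$pairs), class = "fold_result")
}

#' Dinucleotide-preserving shuffle
#'
#' Shuffles a sequence while preserving all 16 dinucleotide counts and the
#' first and last nucleotide (Eulerian-walk shuffle). Sampling is uniform
#' over the valid shuffles: edge orderings are drawn uniformly and rejected
#' until the walk is Eulerian.
#'
#' @param seq DNA or RNA string, length >= 2.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is used.
#' @return shuffled sequence string (same alphabet as the input).
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (nchar(seq) < 2) stop("sequence must have length >= 2")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  letters_used <- unique(chars)
  # successor lists (multigraph edges)
  succ <- split(chars[-1], factor(chars[-n], levels = letters_used))
  for (try in seq_len(10000)) {
    perm <- lapply(succ, function(v) if (length(v) > 1) sample(v) else v)
    ptr <- stats::setNames(rep(1L, length(perm)), names(perm))
    out <- character(n)
    out[1] <- chars[1]
    cur <- chars[1]
    ok <- TRUE
    for (i in 2:n) {
      k <- ptr[[cur]]
      edges <- perm[[cur]]
      if (k > length(edges)) { ok <- FALSE; break }
      nxt <- edges[k]
      ptr[[cur]] <- k + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok && sum(vapply(names(perm), function(v)
      length(perm[[v]]) - (ptr[[v]] - 1L), 0L)) == 0L) {
      return(paste(out, collapse = ""))
    }
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}

#' Thermodynamic z-score of a sequence
#'
#' Compares the native MFE with the MFE distribution of
#' dinucleotide-preserving shuffles: `z = (native - mean) / sd` with the
#' n-1 standard deviation; by convention `z = 0` when the shuffle SD is 0
#' (for example when nothing can pair). Strongly negative z indicates a
#' structure more stable than the sequence composition explains.
#'
#' @param seq sequence string.
#' @param n_shuffles number of shuffles (default 100).
#' @param seed RNG seed for the shuffle stream.
#' @return list with `z`, `native_energy`, `shuffle_mean`, `shuffle_sd`,
#'   `n_shuffles`.
#' @export
structure_zscore <- function(seq, n_shuffles = 100, seed = 1) {
  native <- fold_mfe(seq)$energy
  set.seed(seed)
  es <- vapply(seq_len(n_shuffles), function(i)
    fold_mfe(dinucleotide_shuffle(seq))$energy, 0)
  m <- mean(es)
  s <- stats::sd(es)
  z <- if (is.na(s) || s == 0) 0 else (native - m) / s
  list(z = z, native_energy = native, shuffle_mean = m,
       shuffle_sd = if (is.na(s)) 0 else s, n_shuffles = n_shuffles)
}

#' Structure conservation index of a pairwise alignment
#'
#' `SCI = E_consensus / mean(E_single)`, where the single energies are the
#' MFEs of the two degapped rows and the consensus energy comes from
#' [consensus_fold()]. An alignment of identical rows has SCI exactly 1
#' whenever its MFE is negative; SCI is 0 when the rows fold to nothing.
#' Values near 1 (or above, with compensatory support) indicate a conserved
#' fold; values near 0 indicate that the two rows cannot fold consistently.
#'
#' @param rows character vector of two equal-length gapped sequences.
#' @return list with `sci`, `e_consensus`, `e_single`, and the consensus
#'   `fold_result`.
#' @export
structure_conservation_index <- function(rows) {
  if (length(rows) != 2) stop("expected exactly two alignment rows")
  if (length(unique(nchar(rows))) != 1) stop("rows of unequal length")
  cons <- consensus_fold(rows)
  singles <- vapply(rows, function(r)
    fold_mfe(gsub("-", "", r, fixed = TRUE))$energy, 0)
  m <- mean(singles)
  sci <- if (m == 0) 0 else cons$energy / m
  list(sci = sci, e_consensus = cons$energy, e_single = unname(singles),
       consensus = cons)
}

#' Covariation score over a consensus structure
#'
#' Sums pairing evidence over the paired columns of a consensus structure:
#' +1 for a compensatory double substitution that preserves pairing, +0.5
#' for a consistent single substitution (for example GC to GU), and -1 for
#' a substitution that breaks the pair in either row (a gap breaks the
#' pair). Identical columns contribute 0, so unrelated mutations drive the
#' score negative while structure-preserving evolution drives it positive.
#'
#' @param rows character vector of two equal-length gapped sequences.
#' @param consensus_structure dot-bracket string over alignment columns; if
#'   missing, the [consensus_fold()] structure is used.
#' @return numeric net covariation score.
#' @export
covariation_score <- function(rows, consensus_structure = NULL) {
  if (length(rows) != 2) stop("expected exactly two alignment rows")
  rna <- chartr("Tt", "Uu", toupper(rows))
  if (is.null(consensus_structure))
    consensus_structure <- consensus_fold(rows)$structure
  if (nchar(consensus_structure) != nchar(rna[1]))
    stop("structure length does not match the alignment")
  pr <- db_pairs(consensus_structure)
  if (nrow(pr) == 0) return(0)
  c1 <- seq_codes(rna[1]); c2 <- seq_codes(rna[2])
  score <- 0
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    p1 <- pair_type(c1[i], c1[j]); p2 <- pair_type(c2[i], c2[j])
    if (p1 == 0L || p2 == 0L) { score <- score - 1; next }
    nsub <- (c1[i] != c2[i]) + (c1[j] != c2[j])
    score <- score + if (nsub == 2L) 1 else if (nsub == 1L) 0.5 else 0
  }
  score
}

#' Default thresholds for the structure classification
#'
#' @param z_max maximum thermodynamic z-score (default -2).
#' @param sci_min minimum structure conservation index (default 0.6).
#' @param cov_min minimum covariation score (default 0).
#' @param min_paired minimum number of base pairs in the native MFE
#'   structure (default 20; the "minimum stem length" criterion counted as
#'   total paired positions across helices, not one contiguous helix).
#' @return list of thresholds.
#' @export
structure_thresholds <- function(z_max = -2, sci_min = 0.6, cov_min = 0,
                                 min_paired = 20) {
  list(z_max = z_max, sci_min = sci_min, cov_min = cov_min,
       min_paired = min_paired)
}

#' Classify a conserved block as structured RNA or not
#'
#' Combines a thermodynamic criterion (shuffle z-score of the block
#' sequence), a comparative criterion (structure conservation index and
#' covariation, averaged over the supporting pairwise alignments) and a stem-size
#' criterion (base pairs in the native MFE structure). A block counts as
#' "structured" only when all three pass, mirroring the
#' intersection-of-evidence selection used in comparative sRNA screens.
#'
#' @param block conserved block from [find_conserved_blocks()], or any list
#'   with `seq` and optionally `hits` (with `q_aln`/`s_aln` rows).
#' @param thresholds list from [structure_thresholds()].
#' @param n_shuffles shuffles for the z-score.
#' @param seed RNG seed for the shuffle stream.
#' @return object of class `structure_scores`: native energy and structure,
#'   z components, sci, covariation, n_pairs, pass flags and `structured`.
#' @export
classify_structured <- function(block, thresholds = structure_thresholds(),
                                n_shuffles = 100, seed = 1) {
  if (is.null(block$seq)) stop("block must carry its reference sequence")
  native <- fold_mfe(block$seq)
  zres <- structure_zscore(block$seq, n_shuffles = n_shuffles, seed = seed)
  sci <- NA_real_; cov <- NA_real_
  if (!is.null(block$hits) && nrow(block$hits) > 0) {
    # comparative evidence averaged over all supporting genomes, the
    # pairwise analogue of scoring one multiple alignment
    per_hit <- lapply(seq_len(nrow(block$hits)), function(h) {
      rows <- c(block$hits$q_aln[h], block$hits$s_aln[h])
      scires <- structure_conservation_index(rows)
      c(sci = scires$sci,
        cov = covariation_score(rows, scires$consensus$structure))
    })
    per_hit <- do.call(rbind, per_hit)
    sci <- mean(per_hit[, "sci"])
    cov <- mean(per_hit[, "cov"])
  }
  pass_thermo <- zres$z <= thresholds$z_max
  pass_compar <- !is.na(sci) && sci >= thresholds$sci_min &&
    !is.na(cov) && cov >= thresholds$cov_min
  pass_stem <- native$n_pairs >= thresholds$min_paired
  structure(list(
    block_id = block$block_id %||% NA_character_,
    native_energy = native$energy, structure = native$structure,
    n_pairs = native$n_pairs, z = zres$z,
    shuffle_mean = zres$shuffle_mean, shuffle_sd = zres$shuffle_sd,
    n_shuffles = n_shuffles, sci = sci, covariation = cov,
    pass_thermo = pass_thermo, pass_compar = pass_compar,
    pass_stem = pass_stem,
    structured = pass_thermo && pass_compar && pass_stem),
    class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  cat(sprintf(
    "<structure_scores> %s: E=%.2f, %d pairs, z=%.2f, sci=%.2f, cov=%.1f -> %s\n",
    x$block_id, x$native_energy, x$n_pairs, x$z,
    ifelse(is.na(x$sci), NaN, x$sci), ifelse(is.na(x$covariation), NaN, x$covariation),
    if (isTRUE(x$structured)) "structured" else "not structured"))
  invisible(x)
}

#' Screen a list of conserved blocks for structure
#'
#' @param blocks list from [find_conserved_blocks()].
#' @param thresholds list from [structure_thresholds()].
#' @param n_shuffles shuffles per block for the z-score.
#' @param seed RNG seed; block `i` uses `seed + i` so the screen is
#'   reproducible and order-independent per block.
#' @return list with `scores` (per block) and `structured` (the subset of
#'   blocks classified as structured RNA).
#' @export
screen_structures <- function(blocks, thresholds = structure_thresholds(),
                              n_shuffles = 100, seed = 1) {
  scores <- lapply(seq_along(blocks), function(i)
    classify_structured(blocks[[i]], thresholds, n_shuffles, seed + i))
  keep <- vapply(scores, function(s) isTRUE(s$structured), TRUE)
  list(scores = scores, structured = blocks[keep],
       structured_scores = scores[keep])
}
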