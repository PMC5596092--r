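#' Default local-alignment scoring scheme
#'
#' BLASTN-like regime: match +2, mismatch -3, affine gaps with open -5 and
#' extend -2 (a gap of length L scores `gap_open + L * gap_extend`).
#'
#' @param match,mismatch,gap_open,gap_extend score components.
#' @return list of scoring parameters.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal local alignment (Smith-Waterman-Gotoh)
#'
#' Exact affine-gap local alignment of two DNA strings. Among equal-scoring
#' optima the alignment with the smallest query start, then smallest subject
#' start, is returned. Returns `NULL` when no positive-scoring alignment
#' exists.
#'
#' @param a,b DNA strings (query, subject).
#' @param scoring scoring scheme from [align_scoring()].
#' @return list with score, q_start/q_end/s_start/s_end (1-based inclusive),
#'   gapped alignment strings `q_aln`/`s_aln`, identity (fraction of
#'   ungapped columns), and column counts; or `NULL`.
#' @export
local_align <- function(a, b, scoring = align_scoring()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  res <- .sw_align(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  if (res$score <= 0) return(NULL)
  res
}

#' Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, found by root bracketing to
#' |f| < 1e-9. `K` is estimated by simulation: Gumbel moment matching on the
#' maximal ungapped segment score of random sequence pairs (200 pairs of
#' 300 nt under a fixed internal calibration seed), via
#' `E[Smax] = (ln(K m n) + gamma) / lambda`. Ungapped theory is applied to
#' gapped scores downstream, the standard approximation at this scale.
#' Results are cached per scoring scheme and composition.
#'
#' @param scoring scoring scheme from [align_scoring()].
#' @param base_comp background base composition (A, C, G, T), summing to 1.
#' @return list with `lambda` and `K`.
#' @export
estimate_ka_params <- function(scoring, base_comp = rep(0.25, 4)) {
  stopifnot(length(base_comp) == 4, abs(sum(base_comp) - 1) < 1e-8)
  key <- paste(c(scoring$match, scoring$mismatch, scoring$gap_open,
                 scoring$gap_extend, signif(base_comp, 6)), collapse = "_")
  if (!is.null(.pkg_env$ka_cache[[key]])) return(.pkg_env$ka_cache[[key]])
  p <- outer(base_comp, base_comp)
  s <- matrix(scoring$mismatch, 4, 4)
  diag(s) <- scoring$match
  escore <- sum(p * s)
  if (escore >= 0)
    stop("expected score per aligned pair must be negative")
  if (scoring$match <= 0)
    stop("match score must be positive")
  f <- function(l) sum(p * exp(l * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- stats::uniroot(f, c(1e-9, hi), tol = 1e-12)$root
  stopifnot(abs(f(lambda)) < 1e-9)
  K <- with_seed(20170908L, {
    m0 <- 300L; reps <- 200L
    smax <- vapply(seq_len(reps), function(i) {
      a <- paste(sample(c("A", "C", "G", "T"), m0, TRUE, base_comp), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), m0, TRUE, base_comp), collapse = "")
      .ungapped_max_score(a, b, scoring$match, scoring$mismatch)
    }, 0)
    exp(lambda * mean(smax) - 0.5772156649) / (m0 * as.numeric(m0))
  })
  out <- list(lambda = lambda, K = K)
  if (is.null(.pkg_env$ka_cache)) .pkg_env$ka_cache <- list()
  .pkg_env$ka_cache[[key]] <- out
  out
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' alignments at least this good between a query of length `m` and a
#' database of length `n`.
#'
#' @param score alignment score.
#' @param m query length (nt).
#' @param n database length (nt).
#' @param params list with `lambda` and `K` from [estimate_ka_params()].
#' @return numeric E-value.
#' @export
evalue <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Find IGR segments conserved across genomes
#'
#' Aligns every IGR of the focal genome against both strands of every IGR of
#' every other genome, keeps hits with `E <= evalue_max`, merges hits whose
#' focal intervals reciprocally overlap by at least 50% into conserved
#' blocks, and drops blocks supported by fewer than `min_genomes` non-focal
#' genomes. The subject database length for the E-value is the total IGR
#' length of the subject genome. Deterministic: no randomness is used.
#'
#' @param igrs_by_genome named list (genome id -> IGR data.frame from
#'   [extract_igrs_genome()], including `seq`).
#' @param focal_genome name of the focal genome.
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param min_genomes minimum number of supporting non-focal genomes.
#' @param scoring scoring scheme.
#' @return list of conserved blocks; each block is a list with block_id,
#'   replicon, start, end (focal coordinates), igr_id, seq (plus strand),
#'   n_genomes, best_evalue, and a data.frame of supporting `hits` carrying
#'   the gapped alignment rows.
#' @export
find_conserved_blocks <- function(igrs_by_genome, focal_genome,
                                  evalue_max = 1e-5, min_genomes = 2,
                                  scoring = align_scoring()) {
  if (length(igrs_by_genome) < 2)
    stop("need at least 2 genomes to search for conservation")
  if (!focal_genome %in% names(igrs_by_genome))
    stop("unknown focal genome: ", focal_genome)
  params <- estimate_ka_params(scoring)
  focal <- igrs_by_genome[[focal_genome]]
  subjects <- igrs_by_genome[names(igrs_by_genome) != focal_genome]
  hits <- list()
  for (qi in seq_len(nrow(focal))) {
    qseq <- focal$seq[qi]
    m <- nchar(qseq)
    for (sg in names(subjects)) {
      sig <- subjects[[sg]]
      n_db <- sum(nchar(sig$seq))
      for (si in seq_len(nrow(sig))) {
        for (strand in c("+", "-")) {
          sseq <- if (strand == "+") sig$seq[si] else revcomp(sig$seq[si])
          al <- local_align(qseq, sseq, scoring)
          if (is.null(al)) next
          E <- evalue(al$score, m, n_db, params)
          if (E > evalue_max) next
          slen <- nchar(sseq)
          s_start <- if (strand == "+") al$s_start else slen - al$s_end + 1L
          s_end <- if (strand == "+") al$s_end else slen - al$s_start + 1L
          hits[[length(hits) + 1]] <- data.frame(
            query_igr_id = focal$id[qi], q_replicon = focal$replicon_id[qi],
            f_start = focal$start[qi] + al$q_start - 1L,
            f_end = focal$start[qi] + al$q_end - 1L,
            subject_genome = sg, subject_igr_id = sig$id[si],
            subject_replicon = sig$replicon_id[si],
            s_start = sig$start[si] + s_start - 1L,
            s_end = sig$start[si] + s_end - 1L,
            subject_strand = strand, score = al$score, evalue = E,
            identity = al$identity, q_aln = al$q_aln, s_aln = al$s_aln,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) return(list())
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$evalue, hits$f_start), , drop = FALSE]
  blocks <- list()
  for (h in seq_len(nrow(hits))) {
    row <- hits[h, ]
    placed <- FALSE
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      if (blk$igr_id != row$query_igr_id) next
      ov <- min(blk$end, row$f_end) - max(blk$start, row$f_start) + 1L
      if (ov <= 0) next
      rec <- min(ov / (blk$end - blk$start + 1L),
                 ov / (row$f_end - row$f_start + 1L))
      if (rec >= 0.5) {
        blocks[[b]]$hits <- rbind(blk$hits, row)
        blocks[[b]]$start <- min(blk$start, row$f_start)
        blocks[[b]]$end <- max(blk$end, row$f_end)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      blocks[[length(blocks) + 1]] <- list(
        igr_id = row$query_igr_id, replicon = row$q_replicon,
        start = row$f_start, end = row$f_end, hits = row)
    }
  }
  # reference interval = majority-support core: the positions covered by a
  # strict majority of the supporting hits (stray extensions of individual
  # alignments do not stretch the block); clip to the IGR, attach sequence
  # and support counts, drop weak blocks
  igr_lookup <- stats::setNames(seq_len(nrow(focal)), focal$id)
  out <- list()
  for (blk in blocks) {
    ig <- focal[igr_lookup[[blk$igr_id]], ]
    need <- floor(nrow(blk$hits) / 2) + 1L
    offs <- blk$start:blk$end
    depth <- rowSums(matrix(vapply(seq_len(nrow(blk$hits)), function(h)
      offs >= blk$hits$f_start[h] & offs <= blk$hits$f_end[h],
      logical(length(offs))), nrow = length(offs)))
    if (any(depth >= need)) {
      core <- range(offs[depth >= need])
      blk$start <- core[1]
      blk$end <- core[2]
    }
    blk$start <- max(blk$start, ig$start)
    blk$end <- min(blk$end, ig$end)
    blk$n_genomes <- length(unique(blk$hits$subject_genome))
    if (blk$n_genomes < min_genomes) next
    blk$best_evalue <- min(blk$hits$evalue)
    blk$seq <- substring(ig$seq, blk$start - ig$start + 1L,
                         blk$end - ig$start + 1L)
    blk$block_id <- sprintf("blk_%s_%d", blk$igr_id, blk$start)
    out[[length(out) + 1]] <- blk
  }
  ord <- order(vapply(out, function(b) b$start, 0))
  out[ord]
}

#' Export conserved blocks as a TSV table
#'
#' @param blocks list from [find_conserved_blocks()].
#' @param path optional output path; when `NULL` the data.frame is returned
#'   only.
#' @return data.frame of block summaries.
#' @export
blocks_to_table <- function(blocks, path = NULL) {
  df <- do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$block_id, replicon = b$replicon, igr_id = b$igr_id,
    start = b$start, end = b$end, length = b$end - b$start + 1L,
    n_genomes = b$n_genomes, best_evalue = b$best_evalue,
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(block_id = character(), replicon = character(),
                                    igr_id = character(), start = integer(),
                                    end = integer(), length = integer(),
                                    n_genomes = integer(), best_evalue = numeric())
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' Export the supporting alignments of conserved blocks as A2M-style text
#'
#' Each supporting hit becomes a pair of gapped FASTA records (focal row
#' first), named `<block_id>|<genome>|<replicon>:<start>-<end>(<strand>)`.
#'
#' @param blocks list from [find_conserved_blocks()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
blocks_to_alignments <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    for (h in seq_len(nrow(b$hits))) {
      hit <- b$hits[h, ]
      writeLines(sprintf(">%s|focal|%s:%d-%d(+)", b$block_id,
                         hit$q_replicon, hit$f_start, hit$f_end), con)
      writeLines(hit$q_aln, con)
      writeLines(sprintf(">%s|%s|%s:%d-%d(%s)", b$block_id,
                         hit$subject_genome, hit$subject_replicon,
                         hit$s_start, hit$s_end, hit$subject_strand), con)
      writeLines(hit$s_aln, con)
    }
  }
  invisible(path)
}
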