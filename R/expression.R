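#' Call transcription units from a coverage track
#'
#' A transcription unit is a maximal run of positions with coverage at or
#' above `threshold`; runs separated by gaps of at most `merge_gap` nt are
#' merged, and merged runs shorter than `min_len` are dropped. Boundaries
#' are the first and last above-threshold positions. The default threshold
#' is `max(5, 0.5 * median nonzero coverage)` of the track, a scale-free
#' rule that tracks library depth.
#'
#' @param coverage numeric per-base coverage vector (one strand).
#' @param threshold calling threshold; `NULL` for the default rule.
#' @param merge_gap maximum gap merged into one unit (nt).
#' @param min_len minimum unit length (nt).
#' @param replicon_id,strand,condition annotations copied to the output.
#' @return data.frame of units: replicon_id, strand, condition, start, end,
#'   length, mean_coverage.
#' @export
call_transcription_units <- function(coverage, threshold = NULL,
                                     merge_gap = 50, min_len = 50,
                                     replicon_id = NA_character_,
                                     strand = NA_character_,
                                     condition = NA_character_) {
  if (is.null(threshold)) {
    nz <- coverage[coverage > 0]
    threshold <- max(5, 0.5 * if (length(nz) > 0) stats::median(nz) else 0)
  }
  above <- coverage >= threshold
  empty <- data.frame(replicon_id = character(), strand = character(),
                      condition = character(), start = integer(),
                      end = integer(), length = integer(),
                      mean_coverage = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by <= merge_gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= merge_gap) merged$end[nrow(merged)] <- runs$end[k]
      else merged <- rbind(merged, runs[k, ])
    }
  }
  merged$length <- merged$end - merged$start + 1L
  merged <- merged[merged$length >= min_len, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  merged$mean_coverage <- vapply(seq_len(nrow(merged)), function(k)
    mean(coverage[merged$start[k]:merged$end[k]]), 0)
  data.frame(replicon_id = replicon_id, strand = strand,
             condition = condition, start = merged$start, end = merged$end,
             length = merged$length, mean_coverage = merged$mean_coverage,
             threshold = threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call transcription units on every track of a coverage set
#'
#' @param covset a `coverage_set`.
#' @param ... passed to [call_transcription_units()].
#' @return data.frame of units across conditions and strands.
#' @export
call_tus_covset <- function(covset, ...) {
  out <- list()
  for (cond in names(covset$tracks)) {
    tr <- covset$tracks[[cond]]
    for (s in c("+", "-")) {
      out[[paste(cond, s)]] <- call_transcription_units(
        tr$coverage[[s]], replicon_id = tr$replicon_id, strand = s,
        condition = cond, ...)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match predicted candidates to called transcription units
#'
#' Each candidate is matched (same replicon and strand) to the transcription
#' unit with the greatest reciprocal overlap, requiring at least
#' `min_reciprocal_overlap`; unmatched candidates get `detected = FALSE`.
#' Start/stop agreement flags are set when the sequenced boundary lies
#' within `boundary_tol` nt of the predicted one. Opposite-strand units
#' overlapping the candidate span are reported in `opposite_strand`.
#'
#' @param candidates candidate data.frame.
#' @param tus transcription-unit data.frame (typically the union over
#'   conditions).
#' @param boundary_tol tolerance (nt) for "approximate" boundary matches.
#' @param min_reciprocal_overlap minimum reciprocal overlap fraction.
#' @return candidates with columns detected, seq_start, seq_end, seq_length,
#'   start_match, stop_match, opposite_strand added.
#' @export
match_candidates_to_tus <- function(candidates, tus, boundary_tol = 20,
                                    min_reciprocal_overlap = 0.5) {
  n <- nrow(candidates)
  candidates$detected <- FALSE
  candidates$seq_start <- NA_integer_
  candidates$seq_end <- NA_integer_
  candidates$seq_length <- NA_integer_
  candidates$start_match <- NA
  candidates$stop_match <- NA
  candidates$opposite_strand <- FALSE
  if (n == 0 || nrow(tus) == 0) return(candidates)
  for (i in seq_len(n)) {
    cs <- candidates$start[i]; ce <- candidates$end[i]
    same <- tus[tus$replicon_id == candidates$replicon_id[i] &
                  tus$strand == candidates$strand[i], , drop = FALSE]
    opp <- tus[tus$replicon_id == candidates$replicon_id[i] &
                 tus$strand != candidates$strand[i], , drop = FALSE]
    if (nrow(opp) > 0) {
      ov <- pmin(opp$end, ce) - pmax(opp$start, cs) + 1
      candidates$opposite_strand[i] <- any(ov > 0)
    }
    if (nrow(same) == 0) next
    ov <- pmin(same$end, ce) - pmax(same$start, cs) + 1
    rec <- pmin(ov / (ce - cs + 1), ov / (same$end - same$start + 1))
    rec[ov <= 0] <- 0
    k <- which.max(rec)
    if (rec[k] < min_reciprocal_overlap) next
    candidates$detected[i] <- TRUE
    candidates$seq_start[i] <- same$start[k]
    candidates$seq_end[i] <- same$end[k]
    candidates$seq_length[i] <- same$end[k] - same$start[k] + 1L
    # boundary agreement in transcription direction: start = 5' end
    if (candidates$strand[i] == "+") {
      candidates$start_match[i] <- abs(same$start[k] - cs) <= boundary_tol
      candidates$stop_match[i] <- abs(same$end[k] - ce) <= boundary_tol
    } else {
      candidates$start_match[i] <- abs(same$end[k] - ce) <= boundary_tol
      candidates$stop_match[i] <- abs(same$start[k] - cs) <= boundary_tol
    }
  }
  candidates
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (library_size * length)`.
#'
#' @param count reads assigned to the feature.
#' @param library_size total mapped reads in the library.
#' @param length feature length (nt).
#' @return numeric RPKM (vectorised).
#' @export
rpkm <- function(count, library_size, length) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(length <= 0)) stop("length must be positive")
  count * 1e9 / (library_size * length)
}

# reads assigned to [start,end] on `strand`: a read counts when at least
# half of its length overlaps the interval; falls back to coverage-sum /
# read_len when no read table is available
count_reads_interval <- function(track, start, end, strand) {
  if (!is.null(track$reads) && nrow(track$reads) > 0) {
    rs <- track$reads[track$reads$strand == strand, , drop = FALSE]
    if (nrow(rs) == 0) return(0L)
    ov <- pmin(rs$end, end) - pmax(rs$start, start) + 1
    sum(ov >= 0.5 * (rs$end - rs$start + 1))
  } else {
    sum(track$coverage[[strand]][start:end]) / track$read_len
  }
}

#' Per-condition expression table for candidates
#'
#' For every candidate with a sequenced interval, counts strand-matched
#' reads over that interval per condition (a read counts when at least half
#' of it overlaps), converts to RPKM, and reports condition ratios relative
#' to the first condition, rounded half-up to 2 decimals (full precision is
#' kept in `*_raw` columns). Candidates without a sequenced interval get
#' zero counts; ratios are `NA` when the reference-condition RPKM is 0.
#' Cis-regulatory candidates are excluded from the trans-sRNA detection
#' summary attached as attribute `"summary"`.
#'
#' @param candidates candidates annotated by [match_candidates_to_tus()].
#' @param covset a `coverage_set` with tracks for every condition.
#' @param conditions condition names; the first is the reference (ratios
#'   are `<cond>/<reference>`).
#' @return data.frame in published-table shape: candidate id, sequenced
#'   interval and strand, length, per-condition rpkm, and ratio columns.
#' @export
expression_table <- function(candidates, covset,
                             conditions = c("FC", "MN", "SN")) {
  missing_conds <- setdiff(conditions, names(covset$tracks))
  if (length(missing_conds) > 0)
    stop("coverage tracks missing for condition(s): ",
         paste(missing_conds, collapse = ", "))
  ref <- conditions[1]
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    det <- isTRUE(candidates$detected[i])
    st <- if (det) candidates$seq_start[i] else candidates$start[i]
    en <- if (det) candidates$seq_end[i] else candidates$end[i]
    len <- en - st + 1L
    rk <- vapply(conditions, function(cond) {
      tr <- covset$tracks[[cond]]
      cnt <- if (det) count_reads_interval(tr, st, en, candidates$strand[i]) else 0
      rpkm(cnt, tr$library_size, len)
    }, 0)
    row <- data.frame(candidate = candidates$id[i],
                      detected = if (det) "yes" else "no",
                      seq_start = if (det) st else NA_integer_,
                      seq_end = if (det) en else NA_integer_,
                      strand = candidates$strand[i], length = len,
                      stringsAsFactors = FALSE)
    for (cond in conditions) row[[paste0(cond, "_rpkm")]] <- rk[[cond]]
    for (cond in conditions[-1]) {
      ratio <- if (rk[[ref]] > 0) rk[[cond]] / rk[[ref]] else NA_real_
      row[[paste0(cond, "_", ref, "_raw")]] <- ratio
      row[[paste0(cond, "_", ref)]] <- round_half_up(ratio, 2)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cis <- if (!is.null(candidates$cis_regulatory)) candidates$cis_regulatory
         else rep(FALSE, nrow(candidates))
  trans <- !cis
  attr(out, "summary") <- list(
    n_trans = sum(trans),
    n_trans_detected = sum(trans & candidates$detected),
    n_cis_excluded = sum(cis))
  out
}
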