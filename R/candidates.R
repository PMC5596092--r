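#' Assemble sRNA candidates from structured blocks
#'
#' Produces one candidate per structured conserved block. The transcribed
#' strand is taken as the strand whose MFE is lower; energies within
#' 2 kcal/mol count as a tie (the energy model is nearly strand-symmetric
#' for Watson-Crick structures), resolved by the terminator evidence in the
#' candidate's signal windows -- tail U count first, since hairpins read the
#' same on both strands, then composite score -- then "+".
#' Promoter evidence is searched in the 150 nt upstream of the candidate's
#' 5' end, terminator evidence in the candidate's 3' half plus 50 nt
#' downstream; signal evidence annotates but never eliminates a candidate.
#'
#' @param blocks structured blocks (e.g. `screen_structures()$structured`).
#' @param scores matching list of `structure_scores`.
#' @param genome named list of [replicon] objects holding the blocks.
#' @param igrs IGR data.frame for the focal genome (for flanking genes).
#' @param id_prefix candidate id prefix (default "cand_s").
#' @param promoter_window,terminator_flank signal search windows (nt).
#' @param signal_opts list with optional `promoter` and `terminator`
#'   sub-lists passed to [scan_promoters()] / [find_terminators()].
#' @return data.frame of candidates (one row per block) with coordinates,
#'   strand, flanking genes, evidence columns and sequence.
#' @export
assemble_candidates <- function(blocks, scores, genome, igrs,
                                id_prefix = "cand_s",
                                promoter_window = 150,
                                terminator_flank = 50,
                                signal_opts = list()) {
  if (length(blocks) == 0)
    return(data.frame(id = character(), replicon_id = character(),
                      replicon_kind = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      igr_id = character(), left_gene = character(),
                      right_gene = character(), family = character(),
                      cis_regulatory = logical(), best_evalue = numeric(),
                      z = numeric(), sci = numeric(), covariation = numeric(),
                      n_pairs = integer(), promoter = logical(),
                      promoter_score = numeric(), terminator = logical(),
                      terminator_score = numeric(), seq = character(),
                      stringsAsFactors = FALSE))
  reps <- stats::setNames(genome, vapply(genome, function(r) r$id, ""))
  igr_lookup <- stats::setNames(seq_len(nrow(igrs)), igrs$id)
  rows <- list()
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    sc <- scores[[i]]
    rep <- reps[[blk$replicon]]
    e_plus <- fold_mfe(blk$seq)$energy
    e_minus <- fold_mfe(revcomp(blk$seq))$energy
    len <- blk$end - blk$start + 1L

    term_hits <- list()
    for (strand in c("+", "-")) {
      if (strand == "+") {
        w_start <- blk$start + len %/% 2L
        w_end <- min(rep$length, blk$end + terminator_flank)
      } else {
        w_start <- max(1L, blk$start - terminator_flank)
        w_end <- blk$end - len %/% 2L
      }
      wseq <- substring(rep$sequence, w_start, w_end)
      th <- find_terminators(wseq, strand,
                             config = signal_opts$terminator %||% list())
      if (nrow(th) > 0) th$position <- th$position + w_start - 1L
      term_hits[[strand]] <- th
    }
    best_term_score <- vapply(term_hits, function(h)
      if (nrow(h) > 0) max(h$score) else -Inf, 0)
    # hairpins read the same on both strands; the poly-U tail is the
    # strand-specific part of a terminator, so compare tail U counts first
    best_term_u <- vapply(term_hits, function(h)
      if (nrow(h) > 0) max(h$u_count) else -1L, 0)

    # the energy model is nearly symmetric under reverse complement for
    # Watson-Crick-dominated structures, so MFE differences below 2 kcal/mol
    # are not meaningful: they count as a tie and the strand-specific
    # terminator evidence decides
    strand <- if (e_plus < e_minus - 2.0) "+"
      else if (e_minus < e_plus - 2.0) "-"
      else if (best_term_u[["-"]] > best_term_u[["+"]]) "-"
      else if (best_term_u[["+"]] > best_term_u[["-"]]) "+"
      else if (best_term_score[["-"]] > best_term_score[["+"]]) "-"
      else if (best_term_score[["+"]] > best_term_score[["-"]]) "+"
      else if (e_plus <= e_minus) "+" else "-"

    if (strand == "+") {
      p_start <- max(1L, blk$start - promoter_window)
      p_end <- blk$start - 1L
    } else {
      p_start <- blk$end + 1L
      p_end <- min(rep$length, blk$end + promoter_window)
    }
    prom <- if (p_end >= p_start) {
      scan_promoters(substring(rep$sequence, p_start, p_end), strand,
                     pwm_pair = signal_opts$pwm_pair %||% sigma70_pwms(),
                     score_min = signal_opts$promoter_score_min %||% 14)
    } else scan_promoters("A", "+")
    term <- term_hits[[strand]]

    ig <- if (blk$igr_id %in% names(igr_lookup))
      igrs[igr_lookup[[blk$igr_id]], ] else NULL
    rows[[i]] <- data.frame(
      id = NA_character_, replicon_id = rep$id, replicon_kind = rep$kind,
      strand = strand, start = blk$start, end = blk$end, length = len,
      igr_id = blk$igr_id,
      left_gene = if (!is.null(ig)) ig$left_gene else NA_character_,
      right_gene = if (!is.null(ig)) ig$right_gene else NA_character_,
      family = "un", cis_regulatory = FALSE,
      best_evalue = blk$best_evalue, z = sc$z, sci = sc$sci,
      covariation = sc$covariation, n_pairs = sc$n_pairs,
      promoter = nrow(prom) > 0,
      promoter_score = if (nrow(prom) > 0) max(prom$score) else NA_real_,
      terminator = nrow(term) > 0,
      terminator_score = if (nrow(term) > 0) max(term$score) else NA_real_,
      seq = if (strand == "+") blk$seq else revcomp(blk$seq),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rep_order <- stats::setNames(seq_along(reps), names(reps))
  out <- out[order(rep_order[out$replicon_id], out$start), , drop = FALSE]
  out$id <- sprintf("%s%d", id_prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Label candidates against a known-RNA reference library
#'
#' Aligns each candidate (both strands) against a labelled RNA library and
#' assigns the family of the best alignment that meets both the identity
#' and E-value cutoffs; candidates without such a match keep family "un".
#' Families whose names match the configured cis-regulatory set
#' (riboswitches) set `cis_regulatory = TRUE`. Ties are broken by lowest
#' E-value, then lexicographic family name, so the labelling is independent
#' of library record order.
#'
#' @param candidates candidate data.frame from [assemble_candidates()].
#' @param library named character vector of library sequences (names carry
#'   the family label), or a FASTA path whose headers are family labels.
#' @param identity_min minimum alignment identity (default 0.6).
#' @param evalue_max maximum E-value (default 1e-5).
#' @param cis_families patterns marking cis-regulatory (riboswitch) families.
#' @param scoring alignment scoring scheme.
#' @return the candidate data.frame with `family` and `cis_regulatory`
#'   filled in.
#' @export
match_known_rnas <- function(candidates, library, identity_min = 0.6,
                             evalue_max = 1e-5,
                             cis_families = c("FMN", "TPP", "cobalamin",
                                              "glycine", "SAM"),
                             scoring = align_scoring()) {
  if (is.character(library) && length(library) == 1 && file.exists(library)) {
    ss <- Biostrings::readDNAStringSet(library)
    library <- stats::setNames(as.character(ss), names(ss))
  }
  if (length(library) == 0) return(candidates)
  params <- estimate_ka_params(scoring)
  n_db <- sum(nchar(library))
  fams <- names(library)
  for (ci in seq_len(nrow(candidates))) {
    cseq <- candidates$seq[ci]
    m <- nchar(cseq)
    best <- NULL
    for (li in order(fams)) {
      for (lseq in c(library[[li]], revcomp(library[[li]]))) {
        al <- local_align(cseq, lseq, scoring)
        if (is.null(al)) next
        E <- evalue(al$score, m, n_db, params)
        if (E > evalue_max || al$identity < identity_min) next
        if (is.null(best) || E < best$E -
            1e-12) {
          best <- list(E = E, family = fams[li])
        }
      }
    }
    if (!is.null(best)) {
      candidates$family[ci] <- best$family
      candidates$cis_regulatory[ci] <-
        any(vapply(cis_families, function(p)
          grepl(p, best$family, ignore.case = TRUE), TRUE))
    }
  }
  candidates
}

#' Count candidates per replicon
#'
#' @param candidates data.frame with a `replicon_id` (or `replicon_kind`)
#'   column.
#' @param by count by "replicon_id" or "replicon_kind".
#' @return named integer vector of counts.
#' @export
classify_replicon <- function(candidates, by = c("replicon_id", "replicon_kind")) {
  by <- match.arg(by)
  if (nrow(candidates) == 0) return(integer(0))
  counts <- table(candidates[[by]])
  stats::setNames(as.integer(counts), names(counts))
}

#' Read the bundled candidate-table fixture
#'
#' Machine-readable transcription of the published 40-candidate table for
#' the *M. huakuii* 7653R screen, used by the golden counting tests. Adds
#' derived columns: `replicon_id` (mapped from the IGR prefix: G ->
#' chromosome, Pa/Pb -> the two megaplasmids) and `detected` (whether an
#' RNA-seq product was observed).
#'
#' @return data.frame with one row per published candidate.
#' @export
read_table1 <- function() {
  f <- system.file("extdata", "table1.tsv", package = "srnascout")
  t1 <- utils::read.delim(f, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("pred_start", "pred_end", "pred_length"))
    t1[[col]] <- as.integer(t1[[col]])
  prefix <- sub("^IGR_([A-Za-z]+)-.*$", "\\1", t1$igr_id)
  t1$replicon_id <- c(G = "chromosome", Pa = "pMhu7653Ra",
                      Pb = "pMhu7653Rb")[prefix]
  t1$detected <- t1$seq_start != "no"
  t1$family <- t1$gene  # the published "Gene" column carries the family label
  t1
}

#' Read the bundled expression-table fixture
#'
#' Published per-condition RPKM values and condition ratios for the
#' conserved housekeeping sRNAs (FC free-living cells, MN 28-dpi mature
#' nodules, SN 50-dpi senescent nodules).
#'
#' @return data.frame with one row per published transcript.
#' @export
read_table2 <- function() {
  f <- system.file("extdata", "table2.tsv", package = "srnascout")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Summary counts over a candidate table
#'
#' The counting rules behind the pipeline report: total candidates,
#' candidates per replicon, known (family != "un") vs novel, and the
#' detected/undetected split among novel candidates.
#'
#' @param candidates data.frame with columns `family`, `replicon_id` and
#'   optionally `detected`.
#' @return list of counts.
#' @export
candidate_summary <- function(candidates) {
  novel <- candidates$family == "un"
  detected <- if (!is.null(candidates$detected)) candidates$detected
              else rep(NA, nrow(candidates))
  list(
    total = nrow(candidates),
    per_replicon = classify_replicon(candidates),
    annotated = sum(!novel),
    novel = sum(novel),
    novel_detected = sum(novel & detected, na.rm = TRUE),
    detected = sum(detected, na.rm = TRUE))
}

#' Export candidates as TSV, BED or GFF3
#'
#' BED output is 0-based half-open; GFF3 and TSV are 1-based inclusive.
#'
#' @param candidates candidate data.frame.
#' @param path output file.
#' @param format output format.
#' @return invisibly, `path`.
#' @export
export_candidates <- function(candidates, path,
                              format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(candidates[, setdiff(names(candidates), "seq")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "bed") {
    bed <- data.frame(chrom = candidates$replicon_id,
                      start = candidates$start - 1L, end = candidates$end,
                      name = candidates$id, score = 0,
                      strand = candidates$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(candidates) > 0) {
      rows <- sprintf(
        "%s\tsrnascout\tncRNA\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
        candidates$replicon_id, candidates$start, candidates$end,
        candidates$strand, candidates$id, candidates$family)
      writeLines(rows, con)
    }
  }
  invisible(path)
}
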