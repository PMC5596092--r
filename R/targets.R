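#' Extract translation-initiation windows for annotated genes
#'
#' Returns, for every gene, the sequence around its start codon in mRNA
#' sense orientation: `upstream` nt before to `downstream` nt after the
#' first base of the start codon (minus-strand genes are
#' reverse-complemented), clipped at replicon ends.
#'
#' @param rep a [replicon].
#' @param upstream,downstream window extent (nt) around the start codon.
#' @return data.frame: gene_id, strand, start, end (plus-strand
#'   coordinates of the window) and `seq` (sense orientation).
#' @export
extract_tir_windows <- function(rep, upstream = 60, downstream = 30) {
  stopifnot(inherits(rep, "replicon"))
  g <- rep$genes
  if (nrow(g) == 0)
    return(data.frame(gene_id = character(), strand = character(),
                      start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  st <- ifelse(g$strand == "+", pmax(1L, g$start - upstream),
               pmax(1L, g$end - downstream))
  en <- ifelse(g$strand == "+", pmin(rep$length, g$start + downstream),
               pmin(rep$length, g$end + upstream))
  seqs <- substring(rep$sequence, st, en)
  seqs <- ifelse(g$strand == "-", revcomp(seqs), seqs)
  data.frame(gene_id = g$id, strand = g$strand, start = st, end = en,
             seq = seqs, stringsAsFactors = FALSE)
}

# best gap-free antisense duplex between sRNA s and window w (both 5'->3',
# integer codes). A duplex pairs s[i + t] with w[j - t]; it must contain a
# contiguous Watson-Crick seed of >= seed_len pairs; G:U is allowed outside
# the seed. Energy = sum of nearest-neighbor stack terms over adjacent
# pairs. Returns NULL or list(energy, s_start, s_end, w_start, w_end).
best_duplex <- function(sc, wc, seed_len, model = energy_model()) {
  p <- length(sc); q <- length(wc)
  wc_pair <- function(a, b) (a == 1L & b == 4L) | (a == 4L & b == 1L) |
    (a == 2L & b == 3L) | (a == 3L & b == 2L)
  best <- NULL
  for (d in 2:(p + q)) {  # d = i + j (pairing s[i] with w[d - i])
    i_lo <- max(1L, d - q); i_hi <- min(p, d - 1L)
    if (i_hi - i_lo + 1L < seed_len) next
    i <- i_lo:i_hi
    a <- sc[i]; b <- wc[d - i]
    pt <- pair_type(a, b)
    valid <- pt != 0L
    wcv <- wc_pair(a, b)
    # maximal valid runs
    r <- rle(valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      if (length(run) < seed_len) next
      # need a WC sub-run of >= seed_len inside
      rw <- rle(wcv[run])
      if (!any(rw$values & rw$lengths >= seed_len)) next
      ptr <- pt[run]
      energy <- if (length(ptr) > 1)
        sum(model$stack[cbind(ptr[-length(ptr)], ptr[-1])]) else 0
      if (is.null(best) || energy < best$energy) {
        ii <- i[run]
        best <- list(energy = energy,
                     s_start = min(ii), s_end = max(ii),
                     w_start = min(d - ii), w_end = max(d - ii))
      }
    }
  }
  best
}

#' Predict mRNA targets of an sRNA by antisense hybridization
#'
#' Searches each translation-initiation window for gap-free antisense
#' duplexes with the sRNA: a contiguous Watson-Crick seed of at least
#' `seed_len` pairs, extended in both directions while pairing (G:U
#' allowed in the extension) remains possible, scored as the sum of
#' nearest-neighbor duplex stack energies. The best duplex per gene is
#' kept when its energy is at most `energy_max`; genes are ranked by
#' energy (ties by gene id). Accessibility of the target site is not
#' modelled: this is a hybridization-only score.
#'
#' @param srna_seq sRNA sequence (DNA or RNA, 5'->3').
#' @param windows data.frame from [extract_tir_windows()].
#' @param seed_len minimum seed length (default 7).
#' @param energy_max energy cutoff in kcal/mol (default -8).
#' @return data.frame of hits: gene_id, energy, srna_start/srna_end
#'   (1-based on the sRNA), window_start/window_end (1-based on the
#'   window), duplex strings.
#' @export
predict_interactions <- function(srna_seq, windows, seed_len = 7,
                                 energy_max = -8) {
  sc <- seq_codes(chartr("Tt", "Uu", toupper(srna_seq)))
  if (any(sc == 0L)) stop("invalid alphabet in sRNA sequence")
  mod <- energy_model()
  rows <- list()
  for (k in seq_len(nrow(windows))) {
    wcodes <- seq_codes(chartr("Tt", "Uu", toupper(windows$seq[k])))
    if (length(wcodes) == 0 || any(wcodes == 0L)) next
    hit <- best_duplex(sc, wcodes, seed_len, mod)
    if (is.null(hit) || hit$energy > energy_max) next
    sseg <- substring(chartr("Tt", "Uu", toupper(srna_seq)),
                      hit$s_start, hit$s_end)
    wseg <- substring(chartr("Tt", "Uu", toupper(windows$seq[k])),
                      hit$w_start, hit$w_end)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = windows$gene_id[k], energy = hit$energy,
      srna_start = hit$s_start, srna_end = hit$s_end,
      window_start = hit$w_start, window_end = hit$w_end,
      duplex_srna = sseg,
      duplex_mrna = paste(rev(strsplit(wseg, "")[[1]]), collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(), energy = numeric(),
                      srna_start = integer(), srna_end = integer(),
                      window_start = integer(), window_end = integer(),
                      duplex_srna = character(), duplex_mrna = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$energy, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
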