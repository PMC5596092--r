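#' Sigma-70 promoter position weight matrices
#'
#' Log-odds PWMs (base 2, uniform background) for the canonical -35
#' (TTGACA) and -10 (TATAAT) boxes, built from consensus frequencies with
#' small pseudocounts; shipped as a plain-text data file. Users may supply
#' their own matrices to [scan_promoters()] in the same shape.
#'
#' @return list with elements `m35` and `m10`, each a 4 x 6 matrix (rows
#'   A, C, G, T).
#' @export
sigma70_pwms <- function() {
  if (!is.null(.pkg_env$pwms)) return(.pkg_env$pwms)
  f <- system.file("extdata", "sigma70_pwm.tsv", package = "srnascout")
  tab <- utils::read.delim(f)
  mk <- function(box) {
    m <- t(as.matrix(tab[tab$box == box, c("A", "C", "G", "T")]))
    colnames(m) <- NULL
    log2(m / 0.25)
  }
  pwms <- list(m35 = mk("m35"), m10 = mk("m10"))
  .pkg_env$pwms <- pwms
  pwms
}

# sliding-window PWM scores over an encoded sequence (codes 1..4); returns a
# vector of scores for windows starting at 1..(n-w+1); windows containing
# non-ACGT get -Inf
pwm_scan <- function(codes, pwm) {
  w <- ncol(pwm)
  n <- length(codes)
  if (n < w) return(numeric(0))
  ns <- n - w + 1
  sc <- numeric(ns)
  bad <- logical(ns)
  for (k in seq_len(w)) {
    idx <- codes[k:(k + ns - 1)]
    ok <- idx >= 1 & idx <= 4
    bad <- bad | !ok
    sc <- sc + ifelse(ok, pwm[cbind(pmax(idx, 1), k)], 0)
  }
  sc[bad] <- -Inf
  sc
}

#' Scan for sigma-70 promoter motifs
#'
#' Finds all -35/-10 box pairs with a spacer in `spacer_range` and summed
#' log-odds score at least `score_min` on the requested strand. The minus
#' strand is scanned on the reverse complement and hit coordinates are
#' mapped back to plus-strand positions. The reported position is the
#' 3'-most base of the -10 box on the scanned strand.
#'
#' @param seq DNA string.
#' @param strand "+" or "-".
#' @param pwm_pair list with `m35`/`m10` matrices; default [sigma70_pwms()].
#' @param spacer_range allowed spacer lengths (nt) between the boxes.
#' @param score_min minimum summed log-odds score.
#' @return data.frame of hits, best first: type, strand, position, score,
#'   m35, m10 (box sequences), spacer.
#' @export
scan_promoters <- function(seq, strand = "+", pwm_pair = sigma70_pwms(),
                           spacer_range = c(15, 19), score_min = 14) {
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(seq)
  scan_seq <- if (strand == "+") toupper(seq) else revcomp(seq)
  codes <- seq_codes(scan_seq)
  s35 <- pwm_scan(codes, pwm_pair$m35)
  s10 <- pwm_scan(codes, pwm_pair$m10)
  hits <- list()
  for (sp in spacer_range[1]:spacer_range[2]) {
    off <- 6 + sp  # -10 box start relative to -35 box start
    i_max <- length(s10) - off
    if (i_max < 1) next
    i <- seq_len(min(length(s35), i_max))
    tot <- s35[i] + s10[i + off]
    keep <- which(is.finite(tot) & tot >= score_min)
    if (length(keep) == 0) next
    pos_scan <- keep + off + 5L  # 3'-most base of the -10 box, scanned strand
    hits[[length(hits) + 1]] <- data.frame(
      type = "promoter", strand = strand,
      position = if (strand == "+") pos_scan else n - pos_scan + 1L,
      score = tot[keep],
      m35 = substring(scan_seq, keep, keep + 5L),
      m10 = substring(scan_seq, keep + off, keep + off + 5L),
      spacer = sp, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(type = character(), strand = character(),
                      position = integer(), score = numeric(),
                      m35 = character(), m10 = character(),
                      spacer = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(-out$score, out$position), , drop = FALSE]
}

#' Scan for Rho-independent (intrinsic) terminators
#'
#' Enumerates hairpins within the configured stem/loop bounds on the
#' requested strand, scores each as
#' `composite = (-hairpin energy) + u_tail_weight * (# T in the 8 nt
#' downstream of the stem)` using the package energy model for the hairpin,
#' keeps hits with `composite >= score_min`, and reduces overlapping hits
#' to the best one. The reported position is the 3'-most base of the
#' hairpin on the scanned strand, mapped to plus-strand coordinates.
#'
#' @param seq DNA string.
#' @param strand "+" or "-".
#' @param config list: stem_min (4), stem_max (18), loop_min (3),
#'   loop_max (10), tail_len (8), u_tail_weight (1), score_min (12).
#' @return data.frame of hits, best first: type, strand, position, score,
#'   stem_bp, loop_nt, hairpin_energy, u_count.
#' @export
find_terminators <- function(seq, strand = "+", config = list()) {
  cfg <- utils::modifyList(list(stem_min = 4L, stem_max = 18L, loop_min = 3L,
                                loop_max = 10L, tail_len = 8L,
                                u_tail_weight = 1, score_min = 12), config)
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(seq)
  scan_seq <- if (strand == "+") toupper(seq) else revcomp(seq)
  codes <- seq_codes(chartr("T", "U", scan_seq))
  mod <- energy_model()
  rows <- list()
  for (s in cfg$stem_min:cfg$stem_max) {
    for (l in cfg$loop_min:cfg$loop_max) {
      span <- 2L * s + l
      if (span > n) next
      for (i in seq_len(n - span + 1L)) {
        left <- codes[i:(i + s - 1L)]
        right <- codes[(i + span - s):(i + span - 1L)]
        pts <- pair_type(left, rev(right))
        if (any(pts == 0L)) next
        e <- hairpin_penalty(l, mod)
        if (s > 1) e <- e + sum(mod$stack[cbind(pts[-s], pts[-1])])
        tail_start <- i + span
        tail <- codes[tail_start:min(n, tail_start + cfg$tail_len - 1L)]
        u <- sum(tail == 4L, na.rm = TRUE)
        comp <- -e + cfg$u_tail_weight * u
        if (comp < cfg$score_min) next
        rows[[length(rows) + 1]] <- c(i = i, span = span, stem = s, loop = l,
                                      energy = e, u = u, comp = comp)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(type = character(), strand = character(),
                      position = integer(), score = numeric(),
                      stem_bp = integer(), loop_nt = integer(),
                      hairpin_energy = numeric(), u_count = integer(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  m <- m[order(-m[, "comp"], m[, "i"]), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (a in seq_len(nrow(m))) {
    if (!keep[a]) next
    later <- which(keep & seq_len(nrow(m)) > a)
    if (length(later) == 0) next
    ov <- pmax(0, pmin(m[a, "i"] + m[a, "span"] - 1, m[later, "i"] + m[later, "span"] - 1) -
                 pmax(m[a, "i"], m[later, "i"]) + 1)
    keep[later[ov > 0]] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  end_scan <- m[, "i"] + m[, "span"] - 1L
  data.frame(
    type = "terminator", strand = strand,
    position = as.integer(if (strand == "+") end_scan else n - end_scan + 1L),
    score = m[, "comp"], stem_bp = as.integer(m[, "stem"]),
    loop_nt = as.integer(m[, "loop"]), hairpin_energy = m[, "energy"],
    u_count = as.integer(m[, "u"]), row.names = NULL,
    stringsAsFactors = FALSE)
}
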