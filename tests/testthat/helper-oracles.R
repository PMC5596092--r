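# Independent oracles used to cross-check the compiled implementations.
# These deliberately use different algorithms (exhaustive enumeration,
# explicit gap-length recursions) from the package's dynamic programs.

oracle_model <- function() srnascout::energy_model()

oracle_pair_type <- function(a, b) {
  key <- paste0(a, b)
  switch(key, CG = 1L, GC = 2L, GU = 3L, UG = 4L, AU = 5L, UA = 6L, 0L)
}

# energy of an explicit structure (pair list) by loop decomposition,
# mirroring the documented model: stacks, hairpin/bulge/internal penalties,
# linear multiloop. `chars` is a vector of RNA letters.
oracle_energy <- function(chars, pairs, model = oracle_model()) {
  p <- model$params
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  # children of a pair = pairs directly nested inside it
  enclosing <- function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    best <- 0L; bw <- Inf
    for (s in seq_len(nrow(pairs))) {
      if (s == r) next
      k <- pairs[s, 1]; l <- pairs[s, 2]
      if (k < i && j < l && (l - k) < bw) { best <- s; bw <- l - k }
    }
    best
  }
  parent <- vapply(seq_len(nrow(pairs)), enclosing, 0L)
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    kids <- which(parent == r)
    if (length(kids) == 0) {
      e <- e + p[["hairpin_a"]] + p[["hairpin_c"]] * ((j - i - 1) - 3)
    } else if (length(kids) == 1) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      L1 <- k - i - 1; L2 <- j - l - 1
      if (L1 == 0 && L2 == 0) {
        p1 <- oracle_pair_type(chars[i], chars[j])
        p2 <- oracle_pair_type(chars[k], chars[l])
        e <- e + model$stack[p1, p2]
      } else if (L1 == 0 || L2 == 0) {
        e <- e + p[["bulge_a"]] + p[["bulge_c"]] * (L1 + L2)
      } else {
        e <- e + p[["internal_a"]] + p[["internal_c"]] * (L1 + L2)
      }
    } else {
      inside <- (j - i - 1) -
        sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + p[["multi_a"]] + p[["multi_b"]] * (length(kids) + 1) +
        p[["multi_c"]] * inside
    }
  }
  unname(e)
}

# all nested structures (lists of pairs) of chars[i..j]; pairable with
# minimum hairpin loop 3 and interior loops implicitly unrestricted
oracle_enum_structures <- function(chars) {
  n <- length(chars)
  ok <- function(i, j) oracle_pair_type(chars[i], chars[j]) > 0 && j - i > 3
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)  # i unpaired
    for (k in (i + 4):j) {
      if (!ok(i, k)) next
      ins <- rec(i + 1, k - 1)
      aft <- if (k + 1 <= j) rec(k + 1, j) else list(NULL)
      for (a in ins) for (b in aft)
        out[[length(out) + 1]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# brute-force minimum free energy: enumerate every structure, score each
oracle_mfe <- function(seq, model = oracle_model()) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- oracle_enum_structures(chars)
  energies <- vapply(structs, function(s)
    oracle_energy(chars, s, model), 0)
  min(0, energies)
}

# local alignment optimum by an explicit gap-length recursion (lazy gaps),
# a different decomposition from the package's three-state Gotoh
oracle_local_score <- function(a, b, scoring = srnascout::align_scoring()) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  L <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) scoring$match else scoring$mismatch
      v <- L[i, j] + s
      for (k in seq_len(j - 1))
        v <- max(v, L[i + 1, j - k + 1] + scoring$gap_open + k * scoring$gap_extend)
      for (k in seq_len(i - 1))
        v <- max(v, L[i - k + 1, j + 1] + scoring$gap_open + k * scoring$gap_extend)
      L[i + 1, j + 1] <- max(0, v)
      best <- max(best, v)
    }
  }
  max(0, best)
}

# exhaustive gap-free antisense duplex enumeration (all offsets, all
# intervals, every position paired, WC seed of >= seed_len required)
oracle_best_duplex_energy <- function(srna, window, seed_len = 7,
                                      model = oracle_model()) {
  sc <- strsplit(chartr("T", "U", toupper(srna)), "")[[1]]
  wc <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  p <- length(sc); q <- length(wc)
  is_wc <- function(x, y) paste0(x, y) %in% c("AU", "UA", "CG", "GC")
  best <- Inf
  for (i in seq_len(p)) for (j in seq_len(q)) {
    # duplex starting at s[i] paired with w[j], extending i+, j-
    Lmax <- min(p - i + 1, j)
    for (L in seq_len(Lmax)) {
      ii <- i:(i + L - 1); jj <- j:(j - L + 1)
      pts <- vapply(seq_len(L), function(t)
        oracle_pair_type(sc[ii[t]], wc[jj[t]]), 0L)
      if (any(pts == 0L)) break
      wcrun <- vapply(seq_len(L), function(t)
        is_wc(sc[ii[t]], wc[jj[t]]), TRUE)
      r <- rle(wcrun)
      if (!any(r$values & r$lengths >= seed_len)) next
      e <- if (L > 1) sum(model$stack[cbind(pts[-L], pts[-1])]) else 0
      best <- min(best, e)
    }
  }
  if (is.infinite(best)) NULL else best
}

# exhaustive hypergeometric upper tail by enumerating all draws (M <= 20)
oracle_hyper_p <- function(M, K, n, k) {
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}
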