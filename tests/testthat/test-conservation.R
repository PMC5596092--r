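test_that("local alignment handles forced and empty cases", {
  a <- strrep("ACGTCAGTAC", 3)
  hit <- local_align(a, a)
  expect_equal(hit$score, 2 * 30)
  expect_equal(hit$identity, 1)
  expect_equal(c(hit$q_start, hit$q_end), c(1L, 30L))
  expect_null(local_align("AAAA", "TTTT"))
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("local alignment equals the explicit-gap oracle on short random pairs", {
  set.seed(91)
  for (case in 1:60) {
    a <- rand_dna_fixture(sample(4:12, 1))
    b <- rand_dna_fixture(sample(4:12, 1))
    hit <- local_align(a, b)
    got <- if (is.null(hit)) 0 else hit$score
    expect_equal(got, oracle_local_score(a, b),
                 label = sprintf("pair %s / %s", a, b))
  }
})

test_that("local alignment agrees with Biostrings on longer random pairs", {
  set.seed(14)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (case in 1:20) {
    a <- rand_dna_fixture(60)
    b <- rand_dna_fixture(60)
    hit <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(if (is.null(hit)) 0 else hit$score,
                 max(0, Biostrings::score(ref)))
  }
})

test_that("alignment score equals its own gapped-string reconstruction", {
  set.seed(4)
  sc <- align_scoring()
  for (case in 1:20) {
    a <- rand_dna_fixture(40); b <- rand_dna_fixture(40)
    hit <- local_align(a, b)
    if (is.null(hit)) next
    qa <- strsplit(hit$q_aln, "")[[1]]; sa <- strsplit(hit$s_aln, "")[[1]]
    e <- 0; gapq <- rle(qa == "-"); gaps <- rle(sa == "-")
    e <- sum(ifelse(qa == sa & qa != "-", sc$match,
                    ifelse(qa != "-" & sa != "-", sc$mismatch, 0)))
    ngapruns <- sum(gapq$values) + sum(gaps$values)
    ngapcols <- sum(qa == "-") + sum(sa == "-")
    e <- e + ngapruns * sc$gap_open + ngapcols * sc$gap_extend
    expect_equal(hit$score, e)
  }
})

test_that("Karlin-Altschul lambda satisfies its defining constraint and scales", {
  sc <- align_scoring(match = 1, mismatch = -2, gap_open = -5, gap_extend = -2)
  par <- estimate_ka_params(sc)
  p <- outer(rep(0.25, 4), rep(0.25, 4))
  s <- matrix(-2, 4, 4); diag(s) <- 1
  expect_lt(abs(sum(p * exp(par$lambda * s)) - 1), 1e-9)
  sc2 <- align_scoring(match = 2, mismatch = -4, gap_open = -10, gap_extend = -4)
  par2 <- estimate_ka_params(sc2)
  expect_equal(par2$lambda, par$lambda / 2, tolerance = 1e-6)
  expect_error(estimate_ka_params(align_scoring(match = 1, mismatch = 1)),
               "negative")
})

test_that("E-values are monotone in score and linear in search space", {
  par <- estimate_ka_params(align_scoring())
  scores <- seq(10, 100, by = 5)
  ev <- evalue(scores, 1e4, 1e4, par)
  expect_true(all(diff(ev) < 0))
  expect_equal(evalue(50, 1e4, 2e4, par), 2 * evalue(50, 1e4, 1e4, par))
  # smallest integer score reaching E <= 1e-5 agrees with the log-space route
  smin_direct <- min(which(vapply(1:200, function(s)
    evalue(s, 1e4, 1e4, par) <= 1e-5, TRUE)))
  smin_log <- ceiling((log(par$K) + 2 * log(1e4) + 5 * log(10)) / par$lambda)
  expect_equal(smin_direct, as.integer(smin_log))
})

test_that("a planted element is recovered as one block supported by all other genomes", {
  sim <- tiny_sim()
  blocks <- tiny_blocks()
  spans <- planted_spans(sim)
  n_other <- length(sim$genomes) - 1
  for (e in seq_len(nrow(spans))) {
    hit <- Filter(function(b)
      min(b$end, spans$end[e]) - max(b$start, spans$start[e]) > 0, blocks)
    expect_gte(length(hit), 1)
    expect_true(any(vapply(hit, function(b) b$n_genomes, 0L) == n_other))
  }
  # block intervals never extend beyond their source IGR
  igrs <- tiny_igrs()$sim1
  for (b in blocks) {
    ig <- igrs[igrs$id == b$igr_id, ]
    expect_true(b$start >= ig$start && b$end <= ig$end)
  }
})

test_that("conserved-block search is deterministic and validates its inputs", {
  igrs <- tiny_igrs()
  b1 <- blocks_to_table(find_conserved_blocks(igrs, "sim1"))
  b2 <- blocks_to_table(find_conserved_blocks(igrs, "sim1"))
  expect_identical(b1, b2)
  expect_error(find_conserved_blocks(igrs["sim1"], "sim1"), "at least 2")
  expect_length(find_conserved_blocks(igrs, "sim1", min_genomes = 10), 0)
})
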