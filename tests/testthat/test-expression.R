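test_that("transcription-unit calling finds rectangular pulses with exact boundaries", {
  cov <- numeric(2000)
  cov[1001:1200] <- 100
  tu <- call_transcription_units(cov, threshold = 10)
  expect_equal(nrow(tu), 1L)
  expect_equal(c(tu$start, tu$end), c(1001L, 1200L))
  expect_equal(tu$mean_coverage, 100)
})

test_that("nearby pulses merge and sub-threshold noise yields nothing", {
  cov <- numeric(1000)
  cov[101:200] <- 50
  cov[231:330] <- 50  # 30-nt gap
  tu <- call_transcription_units(cov, threshold = 10, merge_gap = 50)
  expect_equal(nrow(tu), 1L)
  expect_equal(c(tu$start, tu$end), c(101L, 330L))
  tu2 <- call_transcription_units(cov, threshold = 10, merge_gap = 20)
  expect_equal(nrow(tu2), 2L)
  set.seed(3)
  noise <- runif(1000, 0, 4.9)
  expect_equal(nrow(call_transcription_units(noise, threshold = 5)), 0L)
})

test_that("TU calling is idempotent", {
  set.seed(4)
  cov <- rpois(3000, 2) + ifelse(seq_len(3000) %in% 500:900, 60, 0)
  tu <- call_transcription_units(cov, threshold = 10)
  cov2 <- numeric(length(cov))
  for (k in seq_len(nrow(tu))) cov2[tu$start[k]:tu$end[k]] <- cov[tu$start[k]:tu$end[k]]
  tu2 <- call_transcription_units(cov2, threshold = 10)
  expect_equal(tu2[, c("start", "end")], tu[, c("start", "end")])
})

test_that("rpkm follows its closed form and arithmetic identities", {
  expect_equal(rpkm(0, 1e6, 100), 0)
  expect_equal(rpkm(10, 1e6, 100), 100)
  expect_equal(rpkm(20, 1e6, 100), 2 * rpkm(10, 1e6, 100))
  expect_equal(rpkm(10, 2e6, 100), rpkm(10, 1e6, 100) / 2)
  expect_equal(rpkm(10, 1e6, 200), rpkm(10, 1e6, 100) / 2)
  expect_error(rpkm(10, 0, 100), "library_size")
  expect_error(rpkm(10, 1e6, 0), "length")
})

test_that("every published ratio cell reproduces from its printed rpkm pair", {
  t2 <- read_table2()
  expect_equal(round_half_up(t2$mn_rpkm / t2$fc_rpkm, 2), t2$mn_fc)
  expect_equal(round_half_up(t2$sn_rpkm / t2$fc_rpkm, 2), t2$sn_fc)
  # spot values as printed
  s1 <- t2[t2$candidate == "MH_s1" & !t2$opposite_strand, ]
  expect_equal(round_half_up(s1$mn_rpkm / s1$fc_rpkm, 2), 0.27)
  s40 <- t2[t2$candidate == "MH_s40", ]
  expect_equal(round_half_up(s40$mn_rpkm / s40$fc_rpkm, 2), 1.69)
  expect_equal(t2$seq_end - t2$seq_start + 1L, t2$length)
})

test_that("candidate/TU matching applies reciprocal overlap and boundary tolerance", {
  cands <- data.frame(id = c("a", "b", "c"), replicon_id = "chr",
                      strand = c("-", "-", "+"),
                      start = c(2600L, 5000L, 9000L),
                      end = c(2657L, 5200L, 9100L),
                      stringsAsFactors = FALSE)
  tus <- data.frame(replicon_id = "chr", strand = c("-", "+"),
                    start = c(2599L, 2599L), end = c(2660L, 2660L),
                    condition = "FC", stringsAsFactors = FALSE)
  out <- match_candidates_to_tus(cands, tus, boundary_tol = 20)
  expect_true(out$detected[1])
  expect_equal(c(out$seq_start[1], out$seq_end[1]), c(2599L, 2660L))
  expect_true(out$start_match[1] && out$stop_match[1])
  expect_false(out$detected[2])   # zero overlap stays unmatched
  expect_false(out$detected[3])
  expect_false(out$opposite_strand[2])
  # an opposite-strand unit over the same span is flagged, not matched
  expect_true(out$opposite_strand[1])
})

test_that("expression table recovers planted RPKM and handles zero coverage", {
  sim <- tiny_sim()
  cov <- simulate_coverage(sim, seed = 77)
  spans <- planted_spans(sim)
  cands <- data.frame(id = spans$id, replicon_id = "sim1",
                      strand = spans$strand, start = spans$start,
                      end = spans$end, cis_regulatory = FALSE,
                      stringsAsFactors = FALSE)
  tus <- call_tus_covset(cov)
  ann <- match_candidates_to_tus(cands, tus)
  expect_true(all(ann$detected))
  tab <- expression_table(ann, cov)
  expect_equal(nrow(tab), nrow(spans))
  for (k in seq_len(nrow(tab))) {
    planted <- sim$manifest$expression[spans$id[k], ]
    for (cond in c("FC", "MN", "SN"))
      expect_lt(abs(tab[[paste0(cond, "_rpkm")]][k] - planted[[cond]]) /
                  planted[[cond]], 0.8)
  }
  # ratio definition and NA behaviour
  zero <- ann[1, ]; zero$detected <- FALSE
  ztab <- expression_table(zero, cov)
  expect_equal(ztab$FC_rpkm, 0)
  expect_true(is.na(ztab$MN_FC))
  expect_error(expression_table(ann, cov, conditions = c("FC", "XX")),
               "missing")
})

test_that("bedGraph round trip is exact", {
  sim <- tiny_sim()
  cov <- simulate_coverage(sim, seed = 5)
  d <- tempfile()
  write_coverage_bedgraph(cov, d)
  back <- read_coverage_bedgraph(d, "sim1", cov$replicon_length,
                                 sim$manifest$library_sizes)
  for (cond in names(cov$tracks))
    for (s in c("+", "-"))
      expect_identical(back$tracks[[cond]]$coverage[[s]],
                       cov$tracks[[cond]]$coverage[[s]])
})
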