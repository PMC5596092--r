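test_that("zero mutation rates reproduce the ancestor exactly", {
  sim <- simulate_genomes(tiny_synth_config(
    bg_sub_rate = 0, el_sub_rate = 0, indel_rate = 0), seed = 3)
  seqs <- vapply(sim$genomes, function(g) g[[1]]$sequence, "")
  expect_true(all(seqs == seqs[[1]]))
})

test_that("every planted element is recorded in every genome, inside an IGR", {
  sim <- tiny_sim()
  expect_length(sim$manifest$planted_elements, 3)
  for (el in sim$manifest$planted_elements) {
    expect_equal(nrow(el$coords), length(sim$genomes))
    for (g in names(sim$genomes)) {
      co <- el$coords[el$coords$genome == g, ]
      expect_equal(nrow(co), 1)
      igrs <- extract_igrs_genome(sim$genomes[[g]])
      inside <- any(igrs$start <= co$start & igrs$end >= co$end)
      expect_true(inside, label = sprintf("%s in an IGR of %s", el$element_id, g))
    }
  }
})

test_that("the same seed reproduces genomes and manifest bit for bit", {
  a <- simulate_genomes(tiny_synth_config(), seed = 11)
  b <- simulate_genomes(tiny_synth_config(), seed = 11)
  expect_identical(vapply(a$genomes, function(g) g[[1]]$sequence, ""),
                   vapply(b$genomes, function(g) g[[1]]$sequence, ""))
  expect_identical(a$manifest$expression, b$manifest$expression)
  expect_identical(a$manifest$planted_elements, b$manifest$planted_elements)
})

test_that("with full compensation, planted stems stay paired in all descendants", {
  sim <- simulate_genomes(tiny_synth_config(
    el_sub_rate = 0.15, compensatory_prob = 1), seed = 5)
  for (el in sim$manifest$planted_elements) {
    pr <- srnascout:::db_pairs(el$structure)
    for (g in names(sim$genomes)) {
      co <- el$coords[el$coords$genome == g, ]
      s <- substring(sim$genomes[[g]][[1]]$sequence, co$start, co$end)
      if (co$strand == "-") s <- revcomp(s)
      cc <- srnascout:::seq_codes(chartr("T", "U", s))
      pts <- srnascout:::pair_type(cc[pr[, 1]], cc[pr[, 2]])
      expect_true(all(pts > 0))
    }
  }
})

test_that("dinucleotide composition of descendants approaches the ancestor as rates shrink", {
  dinuc <- function(s) {
    v <- strsplit(s, "")[[1]]
    table(factor(paste0(v[-length(v)], v[-1]),
                 levels = as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))))
  }
  sim_lo <- simulate_genomes(tiny_synth_config(bg_sub_rate = 0.01,
                                               indel_rate = 0), seed = 9)
  sim_hi <- simulate_genomes(tiny_synth_config(bg_sub_rate = 0.4,
                                               indel_rate = 0), seed = 9)
  d_anc <- dinuc(sim_lo$genomes$sim1[[1]]$sequence)
  dist_lo <- sum(abs(dinuc(sim_lo$genomes$sim2[[1]]$sequence) - d_anc))
  d_anc_hi <- dinuc(sim_hi$genomes$sim1[[1]]$sequence)
  dist_hi <- sum(abs(dinuc(sim_hi$genomes$sim2[[1]]$sequence) - d_anc_hi))
  expect_lt(dist_lo, dist_hi)
})

test_that("infeasible generator configs fail before generation", {
  expect_error(simulate_genomes(tiny_synth_config(igr_len_range = c(60, 80))),
               "infeasible")
  expect_error(simulate_genomes(tiny_synth_config(bg_sub_rate = 1.5)),
               "rate")
  expect_error(simulate_genomes(tiny_synth_config(n_elements = 50)),
               "infeasible")
})

test_that("coverage conserves mass: total per track = reads placed x read length", {
  sim <- tiny_sim()
  cov <- simulate_coverage(sim, seed = 21)
  for (cond in names(cov$tracks)) {
    tr <- cov$tracks[[cond]]
    total <- sum(tr$coverage[["+"]]) + sum(tr$coverage[["-"]])
    expect_equal(total, sum(tr$reads$end - tr$reads$start + 1))
  }
})

test_that("an element with zero expression shows only background over its span", {
  sim <- tiny_sim()
  sim$manifest$expression[1, ] <- 0
  cov <- simulate_coverage(sim, config = list(background_reads = 0), seed = 2)
  el <- sim$manifest$planted_elements[[1]]
  co <- el$coords[el$coords$genome == "sim1", ]
  for (cond in names(cov$tracks)) {
    tr <- cov$tracks[[cond]]
    expect_equal(sum(tr$coverage[[co$strand]][co$start:co$end]), 0)
  }
})

test_that("doubling the library size leaves expected RPKM unchanged", {
  sim <- tiny_sim()
  el <- sim$manifest$planted_elements[[2]]
  co <- el$coords[el$coords$genome == "sim1", ]
  len <- co$end - co$start + 1
  expected <- sim$manifest$expression[el$element_id, "FC"]
  rpkms <- vapply(c(1, 2), function(mult) {
    s <- sim
    s$manifest$library_sizes <- sim$manifest$library_sizes * mult
    mean(vapply(1:30, function(k) {
      cv <- simulate_coverage(s, config = list(noise_dispersion = 1e-4,
                                               background_reads = 0),
                              seed = 1000 + k)
      tr <- cv$tracks$FC
      rpkm(srnascout:::count_reads_interval(tr, co$start, co$end, co$strand),
           tr$library_size, len)
    }, 0))
  }, 0)
  expect_lt(abs(rpkms[1] - rpkms[2]) / expected, 0.1)
  expect_lt(abs(rpkms[1] - expected) / expected, 0.1)
})
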