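test_that("folding handles unstructured and designed inputs", {
  f <- fold_mfe("AAAAAAAAAA")
  expect_equal(f$energy, 0)
  expect_equal(f$structure, "..........")
  expect_equal(f$n_pairs, 0L)
  hp <- fold_mfe("GGGGAAAACCCC")
  expect_equal(hp$structure, "((((....))))")
  expect_equal(hp$energy, oracle_mfe("GGGGAAAACCCC"))
  expect_error(fold_mfe("ACGX"), "alphabet")
  # energy is 0 iff there are no pairs, structure brackets are balanced
  set.seed(2)
  for (k in 1:20) {
    r <- fold_mfe(random_rna(sample(5:40, 1)))
    expect_equal(r$energy == 0, r$n_pairs == 0L)
    db <- strsplit(r$structure, "")[[1]]
    expect_equal(sum(db == "("), sum(db == ")"))
    if (r$n_pairs > 0) {
      expect_true(all(r$pairs[, 2] - r$pairs[, 1] > 3))  # hairpin loops >= 3
      cc <- srnascout:::seq_codes(r$sequence)
      expect_true(all(srnascout:::pair_type(cc[r$pairs[, 1]],
                                            cc[r$pairs[, 2]]) > 0))
    }
  }
})

test_that("MFE equals exhaustive enumeration on random short sequences", {
  set.seed(600)
  for (k in 1:60) {
    s <- random_rna(sample(6:16, 1))
    expect_equal(fold_mfe(s)$energy, oracle_mfe(s), label = s)
  }
})

test_that("dinucleotide shuffle preserves composition, endpoints, and is uniform", {
  set.seed(10)
  dinuc_counts <- function(s) {
    v <- strsplit(s, "")[[1]]
    table(factor(paste0(v[-length(v)], v[-1]),
                 levels = as.vector(outer(c("A","C","G","T","U"),
                                          c("A","C","G","T","U"), paste0))))
  }
  for (k in 1:25) {
    s <- rand_dna_fixture(sample(10:60, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, nchar(s), nchar(s)), substr(s, nchar(s), nchar(s)))
  }
  expect_equal(dinucleotide_shuffle("AAAA"), "AAAA")
  expect_error(dinucleotide_shuffle("A"), "length")
  # uniformity over the valid arrangements of an 8-mer
  s <- "ACGTCAGA"
  valid <- unique(vapply(combinat_perms(strsplit(s, "")[[1]]), function(p)
    paste(p, collapse = ""), ""))
  ref <- dinuc_counts(s)
  valid <- valid[vapply(valid, function(v)
    identical(dinuc_counts(v), ref) &&
      substr(v, 1, 1) == substr(s, 1, 1) &&
      substr(v, 8, 8) == substr(s, 8, 8), TRUE)]
  set.seed(77)
  draws <- vapply(1:3000, function(i) dinucleotide_shuffle(s), "")
  expect_setequal(unique(draws), valid)
  chi <- stats::chisq.test(table(factor(draws, levels = valid)))
  expect_gt(chi$p.value, 0.01)
})

test_that("z-scores separate designed hairpins from unstructured sequence", {
  expect_equal(structure_zscore(strrep("A", 40), 20, 1)$z, 0)
  set.seed(30)
  flank1 <- rand_dna_fixture(15, gc = 0.3)
  stem <- "GCGGCGCAGCGC"
  hp <- paste0(flank1, stem, "TTCG",
               revcomp(chartr("U", "T", stem)), rand_dna_fixture(15, gc = 0.3))
  hits <- sum(vapply(1:40, function(k)
    structure_zscore(hp, 60, seed = k)$z <= -2, TRUE))
  expect_gte(hits, 38)  # designed 12-bp hairpin is nearly always called
  # null calibration: random sequences have mean z near 0
  set.seed(31)
  zs <- vapply(1:60, function(k)
    structure_zscore(rand_dna_fixture(60, gc = 0.5), 40, seed = k)$z, 0)
  expect_lt(abs(mean(zs)), 0.3)
})

test_that("same seed gives the same z-score", {
  s <- rand_dna_fixture(50)
  expect_identical(structure_zscore(s, 30, seed = 4),
                   structure_zscore(s, 30, seed = 4))
})

test_that("SCI is 1 for identical structured rows and ~0 when one row cannot fold", {
  s <- "GGGCGCAAAGCGCCCAUAGGGCAAACCCUA"
  expect_equal(structure_conservation_index(c(s, s))$sci, 1.0)
  r <- structure_conservation_index(c(s, strrep("A", nchar(s))))
  expect_lt(r$sci, 0.05)
  expect_error(structure_conservation_index(c("ACGU", "ACG")), "unequal")
})

test_that("compensatory substitutions keep SCI above pair-breaking ones", {
  stem <- "GGCGCGCC"
  hp <- paste0(stem, "AAUU", revcomp(chartr("U", "T", stem)))
  hp <- chartr("T", "U", hp)
  # compensatory: swap three GC pairs to CG in row 2 (both partners change)
  comp <- hp
  substr(comp, 1, 1) <- "C"; substr(comp, 20, 20) <- "G"
  substr(comp, 3, 3) <- "A"; substr(comp, 18, 18) <- "U"
  substr(comp, 5, 5) <- "U"; substr(comp, 16, 16) <- "A"
  # inconsistent: change the same left partners only
  broken <- hp
  substr(broken, 1, 1) <- "C"; substr(broken, 3, 3) <- "A"
  substr(broken, 5, 5) <- "U"
  sci_comp <- structure_conservation_index(c(hp, comp))$sci
  sci_broken <- structure_conservation_index(c(hp, broken))$sci
  expect_gte(sci_comp, sci_broken)
  expect_gt(covariation_score(c(hp, comp)), 0)
})

test_that("covariation scoring follows the substitution table", {
  s <- "GGGGAAAACCCC"
  db <- "((((....))))"
  expect_equal(covariation_score(c(s, s), db), 0)
  comp <- "CGGGAAAACCCG"  # one compensatory double substitution
  expect_equal(covariation_score(c(s, comp), db), 1)
  single <- "UGGGAAAACCCC"  # GC -> UC breaks, G:C -> U:C invalid
  expect_equal(covariation_score(c(s, single), db), -1)
  gu <- "UGGGAAAACCCA"  # G:C -> U:A compensatory, still +1
  expect_equal(covariation_score(c(s, gu), db), 1)
  consistent <- "GGGUAAAACCCC"  # G:C -> U:C? no; col4 G->U keeps U:C invalid
  expect_equal(covariation_score(c(s, consistent), db), -1)
  wobble <- "GGGGAAAAUCCC"  # inner C->U gives G:U wobble, consistent single
  expect_equal(covariation_score(c(s, wobble), db), 0.5)
})

test_that("uncompensated stem substitutions drive the covariation score negative", {
  set.seed(55)
  stem <- "GGCGCCGGCGCC"
  hp <- chartr("T", "U", paste0(stem, "GAAA", revcomp(stem)))
  db <- paste0(strrep("(", 12), "....", strrep(")", 12))
  scores <- vapply(1:300, function(k) {
    v <- strsplit(hp, "")[[1]]
    stems <- c(1:12, 17:28)
    for (i in stems) if (runif(1) < 0.2)
      v[i] <- sample(setdiff(c("A", "C", "G", "U"), v[i]), 1)
    covariation_score(c(hp, paste(v, collapse = "")), db)
  }, 0)
  expect_lt(mean(scores), 0)
})

test_that("classification enforces the stem criterion and is threshold-monotone", {
  # a short hairpin: clearly stable but fewer than 20 pairs
  blk <- list(block_id = "b", seq = "GGGGGGGGAAAACCCCCCCC", hits = NULL)
  s <- classify_structured(blk, n_shuffles = 30, seed = 1)
  expect_lt(s$n_pairs, 20)
  expect_false(s$pass_stem)
  expect_false(s$structured)
  # relaxing every threshold can only keep or gain the structured label
  blocks <- tiny_blocks()
  strict <- structure_thresholds()
  loose <- structure_thresholds(z_max = 0, sci_min = 0, cov_min = -100,
                                min_paired = 0)
  for (b in blocks[seq_len(min(4, length(blocks)))]) {
    cs <- classify_structured(b, strict, n_shuffles = 40, seed = 2)
    cl <- classify_structured(b, loose, n_shuffles = 40, seed = 2)
    expect_true(!cs$structured || cl$structured)
  }
})
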