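test_that("IGR extraction returns the maximal inter-gene gaps", {
  rep <- toy_replicon()
  igrs <- extract_igrs(rep, min_len = 50)
  expect_equal(igrs$start, c(101L, 301L))
  expect_equal(igrs$end, c(200L, 400L))
  expect_equal(igrs$length, c(100L, 100L))
  expect_equal(igrs$left_gene, c("g1", "g2"))
  expect_equal(igrs$right_gene, c("g2", NA_character_))
  expect_equal(igrs$seq, substring(rep$sequence, igrs$start, igrs$end))
})

test_that("gaps shorter than min_len are dropped and overlaps are unioned", {
  set.seed(1)
  s <- rand_dna_fixture(400)
  short_gap <- replicon("r", s, data.frame(
    id = c("a", "b"), start = c(1L, 150L), end = c(100L, 300L),
    strand = c("+", "+")))
  igrs <- extract_igrs(short_gap, min_len = 50)
  expect_false(any(igrs$start == 101))  # 49-nt gap dropped
  overlapping <- replicon("r", s, data.frame(
    id = c("a", "b"), start = c(1L, 50L), end = c(100L, 200L),
    strand = c("+", "+")))
  igrs2 <- extract_igrs(overlapping, min_len = 50)
  expect_equal(nrow(igrs2), 1L)
  expect_equal(igrs2$start, 201L)
})

test_that("a replicon without genes yields one IGR spanning everything", {
  rep <- replicon("bare", rand_dna_fixture(120))
  igrs <- extract_igrs(rep)
  expect_equal(nrow(igrs), 1L)
  expect_equal(c(igrs$start, igrs$end), c(1L, 120L))
})

test_that("gene union plus all gaps tiles the replicon, IGRs are disjoint, order-invariant", {
  set.seed(33)
  for (case in 1:10) {
    n <- 2000L
    k <- sample(3:8, 1)
    st <- sort(sample(seq_len(n - 100), k))
    en <- pmin(n, st + sample(30:200, k, TRUE))
    rep <- replicon("r", rand_dna_fixture(n), data.frame(
      id = sprintf("g%d", seq_len(k)), start = st, end = en,
      strand = sample(c("+", "-"), k, TRUE)))
    igrs <- extract_igrs(rep, min_len = 1)
    union_len <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(st, en))))
    expect_equal(union_len + sum(igrs$length), n)
    if (nrow(igrs) > 1)
      expect_true(all(igrs$start[-1] > igrs$end[-nrow(igrs)]))
    for (g in seq_len(k))  # no IGR overlaps a gene
      expect_true(all(igrs$end < st[g] | igrs$start > en[g]))
    # shuffling the gene rows changes nothing
    perm <- sample(k)
    rep2 <- replicon("r", rep$sequence, rep$genes[perm, ])
    expect_equal(extract_igrs(rep2, min_len = 1), igrs)
  }
})

test_that("GenBank write/read round trip preserves the replicon", {
  rep <- toy_replicon()
  f <- tempfile(fileext = ".gbk")
  write_genome(list(rep), f, format = "genbank")
  back <- read_genome(f, format = "genbank")
  expect_length(back, 1)
  expect_equal(back[[1]]$sequence, rep$sequence)
  expect_equal(back[[1]]$length, rep$length)
  expect_equal(back[[1]]$genes$start, rep$genes$start)
  expect_equal(back[[1]]$genes$end, rep$genes$end)
  expect_equal(back[[1]]$genes$strand, rep$genes$strand)
  expect_equal(back[[1]]$genes$id, rep$genes$id)
})

test_that("FASTA+GFF3 write/read round trip preserves coordinates and strands", {
  rep <- toy_replicon()
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  write_genome(list(rep), fa, format = "fasta+gff3", gff = gff)
  back <- read_genome(fa, format = "fasta+gff3", gff = gff)
  expect_equal(back[[1]]$sequence, rep$sequence)
  expect_equal(back[[1]]$genes$start, rep$genes$start)
  expect_equal(back[[1]]$genes$strand, rep$genes$strand)
})

test_that("malformed and inconsistent genome files are rejected", {
  f <- tempfile()
  writeLines(c("LOCUS       broken 100 bp", "ORIGIN", "        1 acgt", "//"), f)
  expect_error(read_genome(f, format = "genbank"), "length")
  writeLines("not a genbank file", f)
  expect_error(read_genome(f, format = "genbank"), "LOCUS")
  expect_error(read_genome(tempfile(), format = "genbank"), "no such file")
  expect_error(replicon("x", "ACGT", data.frame(
    id = "g", start = 2L, end = 10L, strand = "+")), "coordinates")
})

test_that("BED export is 0-based half-open, bit-exact against coordinates", {
  rep <- toy_replicon()
  igrs <- extract_igrs(rep)
  f <- tempfile(fileext = ".bed")
  export_igrs(igrs, f, format = "bed")
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, igrs$start - 1L)
  expect_equal(bed$V3, igrs$end)
  expect_equal(bed$V3 - bed$V2, igrs$length)
})

test_that("synthetic multi-record genomes read back with the manifest's gene counts", {
  sim <- tiny_sim()
  f <- tempfile(fileext = ".gbk")
  write_genome(sim$genomes$sim1, f, format = "genbank")
  back <- read_genome(f, format = "genbank")
  expect_equal(nrow(back[[1]]$genes), nrow(sim$genomes$sim1[[1]]$genes))
  expect_equal(back[[1]]$sequence, sim$genomes$sim1[[1]]$sequence)
})
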