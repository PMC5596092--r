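# Shared fixtures. Expensive objects (tiny synthetic cohort + screens) are
# built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

tiny_synth_config <- function(...) {
  synth_config(n_genomes = 4, n_genes = 10, gene_len_range = c(200, 400),
               igr_len_range = c(150, 260), n_elements = 3, ...)
}

tiny_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_genomes(tiny_synth_config(), seed = 101)
  .fixture_env$sim
}

tiny_blocks <- function() {
  if (is.null(.fixture_env$blocks)) {
    sim <- tiny_sim()
    igrs <- lapply(sim$genomes, extract_igrs_genome)
    .fixture_env$igrs <- igrs
    .fixture_env$blocks <- find_conserved_blocks(igrs, "sim1")
  }
  .fixture_env$blocks
}

tiny_igrs <- function() { tiny_blocks(); .fixture_env$igrs }

tiny_screen <- function() {
  if (is.null(.fixture_env$screen))
    .fixture_env$screen <- screen_structures(tiny_blocks(), seed = 5)
  .fixture_env$screen
}

# planted element spans on the focal genome of a simulation
planted_spans <- function(sim, genome = "sim1") {
  do.call(rbind, lapply(sim$manifest$planted_elements, function(e)
    cbind(e$coords[e$coords$genome == genome, ], id = e$element_id)))
}

# a 400-nt toy replicon with two genes, used across the genome_io tests
toy_replicon <- function() {
  set.seed(7)
  replicon("toy", rand_dna_fixture(400),
           data.frame(id = c("g1", "g2"), start = c(1L, 201L),
                      end = c(100L, 300L), strand = c("+", "-"),
                      stringsAsFactors = FALSE))
}

rand_dna_fixture <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")

# all permutations of a small character vector (for the shuffle uniformity check)
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# best all-Watson-Crick gap-free duplex energy (no seed requirement)
wc_only_duplex_energy <- function(srna, win, model) {
  sc <- srnascout:::seq_codes(chartr("T", "U", toupper(srna)))
  wc <- srnascout:::seq_codes(chartr("T", "U", toupper(win)))
  best <- 0
  for (i in seq_along(sc)) for (j in seq_along(wc)) {
    L <- min(length(sc) - i + 1, j)
    pts <- integer(0)
    for (t in seq_len(L)) {
      pt <- srnascout:::pair_type(sc[i + t - 1], wc[j - t + 1])
      if (pt == 0L || pt %in% c(3L, 4L)) break
      pts <- c(pts, pt)
      if (length(pts) > 1)
        best <- min(best, sum(model$stack[cbind(pts[-length(pts)], pts[-1])]))
    }
  }
  best
}

# total stacking energy of a perfect Watson-Crick duplex on `seg`
sum_stack_energy <- function(seg) {
  mod <- energy_model()
  cc <- srnascout:::seq_codes(chartr("T", "U", seg))
  comp <- c(4L, 3L, 2L, 1L)[cc]
  pts <- srnascout:::pair_type(cc, comp)
  sum(mod$stack[cbind(pts[-length(pts)], pts[-1])])
}
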