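#' Default configuration for the synthetic genome generator
#'
#' The defaults describe the study conditions the generator emulates: five
#' related genomes of about 60 kb derived from a common ancestor, fifty
#' protein-coding gene placeholders, and eight structured sRNA-like elements
#' planted in intergenic regions. Elements are two designed stem-loops
#' followed by an intrinsic terminator (GC-rich hairpin + U8 tail) and are
#' optionally preceded by a sigma-70 promoter. Background sequence diverges
#' at `bg_sub_rate` per site; element sites diverge at `el_sub_rate` with
#' compensatory (pair-preserving) substitutions in stems at probability
#' `compensatory_prob`, so planted structure is conserved the way genuine
#' sRNAs are. Indels occur in intergenic background only.
#'
#' @param ... overrides for individual fields.
#' @return list of generator parameters.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_genomes = 5, n_genes = 50,
    gene_len_range = c(500, 1300), igr_len_range = c(150, 300),
    n_elements = 8, element_stem_len = 12,
    bg_sub_rate = 0.40, el_sub_rate = 0.05, compensatory_prob = 1.0,
    indel_rate = 0.05, gc = 0.6,
    promoter_prob = 1.0, terminator_prob = 1.0)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# designed element: two hairpins (stem s, loop 6, spacer 5) + terminator
# (stem 10, loop 4, U8 tail); returns list(seq, structure, pairs)
design_element <- function(stem_len, gc = 0.7, terminator = TRUE) {
  hp <- function(s, loop_len, loop_char = "A") {
    left <- strsplit(rand_dna(s, gc = gc), "")[[1]]
    loop <- strsplit(rand_dna(loop_len, gc = 0.2), "")[[1]]
    right <- rev(chartr("ACGT", "TGCA", left))
    list(seq = c(left, loop, right),
         db = c(rep("(", s), rep(".", loop_len), rep(")", s)))
  }
  h1 <- hp(stem_len, 6); h2 <- hp(stem_len, 6)
  spacer <- strsplit(rand_dna(5, gc = 0.3), "")[[1]]
  seq <- c(h1$seq, spacer, h2$seq)
  db <- c(h1$db, rep(".", 5), h2$db)
  if (terminator) {
    th <- hp(10, 4)
    seq <- c(seq, th$seq, rep("T", 8))
    db <- c(db, th$db, rep(".", 8))
  }
  list(seq = paste(seq, collapse = ""), structure = paste(db, collapse = ""))
}

db_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0); out <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      out <- rbind(out, c(j, i))
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out[order(out[, 1]), , drop = FALSE]
}

PROMOTER_CONSENSUS <- function() paste0("TTGACA", strrep("N", 0))

# substitute positions of a character vector at given rate; returns vector
mutate_bg <- function(chars, rate) {
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
  }
  chars
}

apply_indels <- function(chars, rate) {
  n_events <- stats::rbinom(1, length(chars), rate)
  if (n_events == 0) return(chars)
  for (e in seq_len(n_events)) {
    pos <- sample(length(chars), 1)
    len <- sample(1:3, 1)
    if (stats::runif(1) < 0.5 && length(chars) > len + 1) {
      keep <- setdiff(seq_along(chars), pos:min(pos + len - 1, length(chars)))
      chars <- chars[keep]
    } else {
      ins <- strsplit(rand_dna(len), "")[[1]]
      chars <- append(chars, ins, after = pos)
    }
  }
  chars
}

# element mutation preserving (or not) stem pairing
mutate_element <- function(chars, pairs, rate, comp_prob) {
  paired <- if (nrow(pairs) > 0) c(pairs[, 1], pairs[, 2]) else integer(0)
  unpaired <- setdiff(seq_along(chars), paired)
  for (i in unpaired) {
    if (stats::runif(1) < rate)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  if (nrow(pairs) > 0) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      # per-site substitution probability `rate` on each side of the pair
      if (stats::runif(1) < 2 * rate - rate^2) {
        if (stats::runif(1) < comp_prob) {
          # compensatory double change to a fresh Watson-Crick pair
          newb <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
          chars[i] <- newb
          chars[j] <- comp[[newb]]
        } else {
          side <- if (stats::runif(1) < 0.5) i else j
          chars[side] <- sample(setdiff(c("A", "C", "G", "T"), chars[side]), 1)
        }
      }
    }
  }
  chars
}

#' Simulate related genomes with planted structured sRNA elements
#'
#' Builds an ancestor genome of alternating gene placeholders and intergenic
#' regions, plants `n_elements` designed stem-loop elements (with promoter
#' and terminator signals) inside chosen IGRs, then derives the remaining
#' genomes by per-site substitution (compensatory inside stems) and
#' background-only indels. Everything planted is recorded in the returned
#' truth manifest.
#'
#' @param config list from [synth_config()].
#' @param seed integer RNG seed; the same seed reproduces the same genomes
#'   and manifest exactly.
#' @return list with `genomes` (named list; each genome a named list of
#'   [replicon]) and `manifest` (truth manifest: planted element coordinates
#'   per genome, structures, signals, expression levels, library sizes).
#' @export
simulate_genomes <- function(config = synth_config(), seed = 1) {
  cfg <- config
  stopifnot(cfg$n_genomes >= 1, cfg$n_genes >= 0)
  for (r in c("bg_sub_rate", "el_sub_rate", "compensatory_prob", "indel_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop("rate out of [0,1]: ", r)
  set.seed(seed)

  el_design <- design_element(cfg$element_stem_len, terminator = TRUE)
  el_len <- nchar(el_design$seq)  # representative; each element drawn anew
  prom_len <- 6 + 17 + 6
  if (el_len + prom_len + 20 > cfg$igr_len_range[2])
    stop("infeasible config: elements (", el_len + prom_len,
         " nt with promoter) do not fit the IGR length range")

  n_igr <- as.integer(cfg$n_genes) + 1L
  igr_lens <- sample(cfg$igr_len_range[1]:cfg$igr_len_range[2], n_igr, TRUE)
  gene_lens <- if (cfg$n_genes > 0)
    sample(cfg$gene_len_range[1]:cfg$gene_len_range[2], cfg$n_genes, TRUE)
  else integer(0)
  if (cfg$n_elements > cfg$n_genes - 1 && cfg$n_elements > n_igr - 2)
    stop("infeasible config: more elements than interior IGRs")

  # ancestor segments: alternate igr/gene; segments keep their role
  segs <- list()
  for (i in seq_len(cfg$n_genes)) {
    segs[[length(segs) + 1]] <- list(role = "igr", idx = i,
                                     chars = strsplit(rand_dna(igr_lens[i], cfg$gc), "")[[1]])
    segs[[length(segs) + 1]] <- list(role = "gene", idx = i,
                                     chars = strsplit(rand_dna(gene_lens[i], cfg$gc), "")[[1]],
                                     strand = sample(c("+", "-"), 1),
                                     tag = sprintf("SYN_%05d", i * 10))
  }
  segs[[length(segs) + 1]] <- list(role = "igr", idx = n_igr,
                                   chars = strsplit(rand_dna(igr_lens[n_igr], cfg$gc), "")[[1]])

  # plant elements into distinct interior IGRs
  interior <- 2:(n_igr - 1)
  el_igrs <- sort(sample(interior, cfg$n_elements))
  elements <- list()
  seg_igr_index <- vapply(segs, function(s)
    if (s$role == "igr") s$idx else NA_integer_, 1L)
  for (e in seq_len(cfg$n_elements)) {
    des <- design_element(cfg$element_stem_len, terminator =
                            stats::runif(1) < cfg$terminator_prob)
    has_prom <- stats::runif(1) < cfg$promoter_prob
    prom <- if (has_prom)
      paste0("TTGACA", rand_dna(17, gc = 0.4), "TATAAT") else ""
    strand <- sample(c("+", "-"), 1)
    cassette <- paste0(prom, des$seq)
    si <- which(seg_igr_index == el_igrs[e])
    igr_chars <- segs[[si]]$chars
    # overwrite a slice of the IGR, keeping its length
    room <- length(igr_chars) - nchar(cassette)
    off <- sample(5:(room - 5), 1)
    ins <- if (strand == "+") cassette else revcomp(cassette)
    igr_chars[(off + 1):(off + nchar(cassette))] <- strsplit(ins, "")[[1]]
    segs[[si]]$chars <- igr_chars
    # element span within the cassette: in sense orientation the element
    # always follows the promoter; on the plus strand of the genome a
    # minus-strand cassette is laid out reverse-complemented, so the
    # element occupies the left (5'-most) part of the inserted slice
    elements[[e]] <- list(
      element_id = sprintf("el%d", e), seg = si, offset = off,
      cassette_len = nchar(cassette), prom_len = nchar(prom),
      el_len = nchar(des$seq), strand = strand,
      structure = des$structure, pairs = db_pairs(des$structure),
      sequence = des$seq, has_promoter = has_prom,
      has_terminator = grepl("TTTTTTTT$", des$seq), family = "novel")
  }

  genome_ids <- sprintf("sim%d", seq_len(cfg$n_genomes))
  genomes <- list()
  coords <- list()  # element_id -> data.frame rows
  for (g in seq_len(cfg$n_genomes)) {
    gsegs <- segs
    if (g > 1) {
      for (si in seq_along(gsegs)) {
        role <- gsegs[[si]]$role
        eidx <- which(vapply(elements, function(el) el$seg == si, TRUE))
        if (role == "gene") {
          gsegs[[si]]$chars <- mutate_bg(gsegs[[si]]$chars, cfg$bg_sub_rate)
        } else if (length(eidx) == 0) {
          ch <- mutate_bg(gsegs[[si]]$chars, cfg$bg_sub_rate)
          gsegs[[si]]$chars <- apply_indels(ch, cfg$indel_rate)
        } else {
          # IGR containing a planted cassette: mutate flanks and element
          el <- elements[[eidx]]
          ch <- gsegs[[si]]$chars
          lo <- el$offset; hi <- el$offset + el$cassette_len
          left <- if (lo > 0) mutate_bg(ch[seq_len(lo)], cfg$bg_sub_rate) else character(0)
          right <- if (hi < length(ch))
            mutate_bg(ch[(hi + 1):length(ch)], cfg$bg_sub_rate) else character(0)
          cas <- ch[(lo + 1):hi]
          # orient to element sense strand for pair-aware mutation
          cas_sense <- if (el$strand == "+") cas else
            strsplit(revcomp(paste(cas, collapse = "")), "")[[1]]
          el_zone <- (el$prom_len + 1):(el$prom_len + el$el_len)
          elc <- cas_sense[el_zone]
          elc <- mutate_element(elc, el$pairs, cfg$el_sub_rate, cfg$compensatory_prob)
          cas_sense[el_zone] <- elc
          promz <- setdiff(seq_along(cas_sense), el_zone)
          if (length(promz) > 0)
            cas_sense[promz] <- mutate_bg(cas_sense[promz], cfg$el_sub_rate)
          cas <- if (el$strand == "+") cas_sense else
            strsplit(revcomp(paste(cas_sense, collapse = "")), "")[[1]]
          gsegs[[si]]$chars <- c(left, cas, right)
        }
      }
    }
    # assemble replicon and record coordinates
    pos <- 0L
    seq_parts <- character(length(gsegs))
    gene_rows <- list()
    for (si in seq_along(gsegs)) {
      s <- gsegs[[si]]
      L <- length(s$chars)
      if (s$role == "gene") {
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          id = s$tag, start = pos + 1L, end = pos + L, strand = s$strand,
          type = "CDS", product = "hypothetical protein",
          stringsAsFactors = FALSE)
      }
      eidx <- which(vapply(elements, function(el) el$seg == si, TRUE))
      if (length(eidx) == 1) {
        el <- elements[[eidx]]
        if (el$strand == "+") {
          st <- pos + el$offset + el$prom_len + 1L
          en <- st + el$el_len - 1L
        } else {
          # cassette inserted as revcomp(prom + element): element occupies the
          # 5' (left) part of the inserted slice, promoter the right
          st <- pos + el$offset + 1L
          en <- st + el$el_len - 1L
        }
        coords[[el$element_id]] <- rbind(
          coords[[el$element_id]],
          data.frame(genome = genome_ids[g], replicon = genome_ids[g],
                     start = st, end = en, strand = el$strand,
                     stringsAsFactors = FALSE))
      }
      seq_parts[si] <- paste(s$chars, collapse = "")
      pos <- pos + L
    }
    genes <- if (length(gene_rows) > 0) do.call(rbind, gene_rows) else NULL
    rep <- replicon(genome_ids[g], paste(seq_parts, collapse = ""), genes,
                    kind = "chromosome")
    genomes[[genome_ids[g]]] <- stats::setNames(list(rep), genome_ids[g])
  }

  expression <- matrix(
    round(exp(stats::runif(cfg$n_elements * 3, log(200), log(2000)))),
    nrow = cfg$n_elements, dimnames = list(
      vapply(elements, function(e) e$element_id, ""), c("FC", "MN", "SN")))
  manifest <- list(
    seed = seed, genomes = genome_ids, focal = genome_ids[1],
    planted_elements = lapply(elements, function(el) {
      list(element_id = el$element_id, family = el$family,
           structure = el$structure, sequence = el$sequence,
           has_promoter = el$has_promoter, has_terminator = el$has_terminator,
           coords = coords[[el$element_id]])
    }),
    expression = expression,
    library_sizes = c(FC = 1e6, MN = 1e6, SN = 1e6),
    background_rates = list(substitution = cfg$bg_sub_rate,
                            indel = cfg$indel_rate),
    config = cfg)
  list(genomes = genomes, manifest = manifest)
}

#' Simulate stranded RNA-seq coverage for planted elements
#'
#' For every planted element and condition, a negative-binomially distributed
#' read count with expectation `RPKM * library_size * length / 1e9` is drawn
#' and that many reads of length `read_len` are placed uniformly across the
#' element span on its strand; sparse background reads are scattered over
#' both strands. Per-base coverage is returned per condition and strand,
#' together with the read placements and library sizes.
#'
#' @param sim result of [simulate_genomes()] (genomes + manifest), or a
#'   single genome plus manifest.
#' @param config list: `read_len` (default 50), `noise_dispersion` (NB
#'   dispersion, default 0.1), `conditions`, `background_reads` per track
#'   (default: about 1x background coverage per strand, i.e.
#'   `2 * genome length / read_len`).
#' @param seed RNG seed.
#' @return object of class `coverage_set`: per condition, per strand
#'   coverage vectors for the focal genome, read tables, and library sizes.
#' @export
simulate_coverage <- function(sim, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(read_len = 50L, noise_dispersion = 0.1,
                                conditions = c("FC", "MN", "SN"),
                                background_reads = NULL), config)
  manifest <- sim$manifest
  if (!all(cfg$conditions %in% colnames(manifest$expression)))
    stop("manifest expression not defined for every condition")
  set.seed(seed)
  focal <- manifest$focal
  rep <- sim$genomes[[focal]][[1]]
  glen <- rep$length
  rl <- cfg$read_len
  if (is.null(cfg$background_reads))  # ~1x background coverage per strand
    cfg$background_reads <- as.integer(round(2 * glen / rl))
  tracks <- list()
  for (cond in cfg$conditions) {
    lib <- manifest$library_sizes[[cond]]
    reads <- list()
    for (el in manifest$planted_elements) {
      co <- el$coords[el$coords$genome == focal, ]
      span_len <- co$end - co$start + 1L
      expr <- manifest$expression[el$element_id, cond]
      mu <- expr * lib * span_len / 1e9
      count <- if (mu <= 0) 0L else
        stats::rnbinom(1, mu = mu, size = 1 / cfg$noise_dispersion)
      if (count > 0) {
        eff <- min(rl, span_len)
        starts <- sample(co$start:(co$end - eff + 1L), count, replace = TRUE)
        reads[[length(reads) + 1]] <- data.frame(
          start = starts, end = starts + eff - 1L, strand = co$strand,
          origin = el$element_id, stringsAsFactors = FALSE)
      }
    }
    if (cfg$background_reads > 0) {
      starts <- sample(seq_len(glen - rl + 1L), cfg$background_reads, TRUE)
      reads[[length(reads) + 1]] <- data.frame(
        start = starts, end = starts + rl - 1L,
        strand = sample(c("+", "-"), cfg$background_reads, TRUE),
        origin = "background", stringsAsFactors = FALSE)
    }
    reads <- if (length(reads) > 0) do.call(rbind, reads) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 origin = character())
    cov <- list("+" = numeric(glen), "-" = numeric(glen))
    for (s in c("+", "-")) {
      rs <- reads[reads$strand == s, , drop = FALSE]
      if (nrow(rs) > 0) {
        d <- numeric(glen + 1L)
        for (k in seq_len(nrow(rs))) {
          d[rs$start[k]] <- d[rs$start[k]] + 1
          d[rs$end[k] + 1L] <- d[rs$end[k] + 1L] - 1
        }
        cov[[s]] <- cumsum(d[seq_len(glen)])
      }
    }
    tracks[[cond]] <- list(replicon_id = rep$id, condition = cond,
                           coverage = cov, reads = reads,
                           library_size = lib, read_len = rl)
  }
  structure(list(tracks = tracks, focal = focal, replicon_length = glen,
                 conditions = cfg$conditions, seed = seed),
            class = "coverage_set")
}

#' Write coverage tracks as bedGraph (one file per condition and strand)
#'
#' @param covset a `coverage_set` from [simulate_coverage()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_coverage_bedgraph <- function(covset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cond in names(covset$tracks)) {
    tr <- covset$tracks[[cond]]
    for (s in c("+", "-")) {
      v <- tr$coverage[[s]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts0 <- ends - r$lengths  # 0-based half-open
      keep <- r$values != 0
      df <- data.frame(chrom = tr$replicon_id, start = starts0[keep],
                       end = ends[keep], value = r$values[keep])
      f <- file.path(dir, sprintf("cov_%s_%s.bedGraph", cond,
                                  if (s == "+") "plus" else "minus"))
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read bedGraph coverage tracks written by [write_coverage_bedgraph()]
#'
#' bedGraph is 0-based half-open; the conversion back to the package's
#' 1-based inclusive per-base vectors is exact.
#'
#' @param dir directory containing `cov_<condition>_<plus|minus>.bedGraph`.
#' @param replicon_id replicon identifier.
#' @param replicon_length replicon length (nt).
#' @param library_sizes named vector of total mapped reads per condition.
#' @param read_len read length used to generate the tracks.
#' @return a `coverage_set` (without read placements).
#' @export
read_coverage_bedgraph <- function(dir, replicon_id, replicon_length,
                                   library_sizes, read_len = 50L) {
  files <- list.files(dir, pattern = "^cov_.*\\.bedGraph$", full.names = TRUE)
  if (length(files) == 0) stop("no bedGraph tracks found in ", dir)
  conds <- unique(sub("^cov_([^_]+)_.*$", "\\1", basename(files)))
  tracks <- list()
  for (cond in conds) {
    cov <- list("+" = numeric(replicon_length), "-" = numeric(replicon_length))
    for (s in c("+", "-")) {
      f <- file.path(dir, sprintf("cov_%s_%s.bedGraph", cond,
                                  if (s == "+") "plus" else "minus"))
      if (!file.exists(f)) next
      gr <- rtracklayer::import(f, format = "bedGraph")
      st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
      for (k in seq_along(gr)) cov[[s]][st[k]:en[k]] <- gr$score[k]
    }
    tracks[[cond]] <- list(replicon_id = replicon_id, condition = cond,
                           coverage = cov, reads = NULL,
                           library_size = library_sizes[[cond]],
                           read_len = read_len)
  }
  structure(list(tracks = tracks, focal = NA_character_,
                 replicon_length = replicon_length, conditions = conds,
                 seed = NA_integer_), class = "coverage_set")
}
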