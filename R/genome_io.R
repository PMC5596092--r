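#' Construct a replicon
#'
#' A replicon bundles one DNA sequence (chromosome or plasmid) with its
#' annotated gene features. Coordinates are 1-based and fully inclusive
#' everywhere in this package; `length = end - start + 1`.
#'
#' @param id replicon identifier.
#' @param sequence DNA string over A/C/G/T/N.
#' @param genes data.frame with columns `id`, `start`, `end`, `strand`
#'   ("+"/"-"), and optionally `type` and `product`.
#' @param kind "chromosome" or "plasmid".
#' @return object of class `replicon`.
#' @export
replicon <- function(id, sequence, genes = NULL, kind = c("chromosome", "plasmid")) {
  kind <- match.arg(kind)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("replicon sequence may only contain A/C/G/T/N")
  len <- nchar(sequence)
  if (is.null(genes) || nrow(genes) == 0) {
    genes <- data.frame(id = character(), start = integer(), end = integer(),
                        strand = character(), type = character(),
                        product = character(), stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    if (is.null(genes$type)) genes$type <- "CDS"
    if (is.null(genes$product)) genes$product <- ""
    if (any(genes$start < 1 | genes$end > len | genes$start > genes$end))
      stop("gene coordinates outside [1, replicon length] in replicon ", id)
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(id = id, kind = kind, sequence = sequence, length = len,
                 genes = genes), class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s (%s), %d bp, %d gene features\n",
              x$id, x$kind, x$length, nrow(x$genes)))
  invisible(x)
}

#' Read an annotated genome
#'
#' Reads either a GenBank flat file (possibly multi-record) or a FASTA +
#' GFF3 pair into a list of [replicon] objects. Every annotated gene-like
#' feature (gene, CDS, tRNA, rRNA, ncRNA, tmRNA, pseudogene) becomes a gene
#' feature; replicon kind is taken from the record definition when it
#' mentions "plasmid", or from `kind_map`.
#'
#' @param path GenBank file, or FASTA file when `format = "fasta+gff3"`.
#' @param format input format.
#' @param gff GFF3 annotation path (required for `fasta+gff3`).
#' @param kind_map optional named character vector replicon id -> kind,
#'   overriding inferred kinds.
#' @return named list of [replicon] objects.
#' @export
read_genome <- function(path, format = c("genbank", "fasta+gff3"), gff = NULL,
                        kind_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  reps <- if (format == "genbank") read_genbank(path)
          else read_fasta_gff3(path, gff)
  if (!is.null(kind_map)) {
    for (i in seq_along(reps)) {
      k <- kind_map[reps[[i]]$id]
      if (!is.na(k)) reps[[i]]$kind <- match.arg(k, c("chromosome", "plasmid"))
    }
  }
  reps
}

read_fasta_gff3 <- function(path, gff) {
  if (is.null(gff)) stop("format 'fasta+gff3' needs a `gff` path")
  if (!file.exists(gff)) stop("no such file: ", gff)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  feats <- rtracklayer::import(gff, format = "gff3")
  keep <- as.character(feats$type) %in%
    c("gene", "CDS", "tRNA", "rRNA", "ncRNA", "tmRNA", "pseudogene")
  feats <- feats[keep]
  # prefer gene rows; fall back to the rest where no gene row covers them
  reps <- vector("list", length(seqs))
  names(reps) <- names(seqs)
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    f <- feats[as.character(GenomicRanges::seqnames(feats)) == id]
    if (length(f) > 0) {
      is_gene <- as.character(f$type) == "gene"
      f <- if (any(is_gene)) f[is_gene] else f
      lt <- f$locus_tag
      if (is.null(lt)) lt <- rep(NA_character_, length(f))
      ids <- ifelse(!is.na(lt), lt,
                    if (!is.null(f$ID)) f$ID else sprintf("%s_g%d", id, seq_along(f)))
      genes <- data.frame(
        id = ids,
        start = GenomicRanges::start(f), end = GenomicRanges::end(f),
        strand = as.character(GenomicRanges::strand(f)),
        type = as.character(f$type),
        product = if (!is.null(f$product)) as.character(f$product) else "",
        stringsAsFactors = FALSE)
      genes$strand[!genes$strand %in% c("+", "-")] <- "+"
    } else genes <- NULL
    kind <- if (grepl("plasmid", id, ignore.case = TRUE) || i > 1) "plasmid"
            else "chromosome"
    reps[[i]] <- replicon(id, as.character(seqs[[i]]), genes, kind)
  }
  reps
}

# Minimal GenBank flat-file reader (LOCUS/DEFINITION/FEATURES/ORIGIN). Only
# the qualifiers this pipeline needs (locus_tag, product) are retained.
read_genbank <- function(path) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("not a GenBank flat file (no LOCUS line): ", path)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts))
    stop("malformed GenBank file (missing record terminator //): ", path)
  reps <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    loc <- strsplit(trimws(block[1]), "\\s+")[[1]]
    if (length(loc) < 3 || is.na(suppressWarnings(as.integer(loc[3]))))
      stop("malformed LOCUS line in record ", r, " of ", path)
    id <- loc[2]
    decl_len <- as.integer(loc[3])
    defline <- grep("^DEFINITION", block, value = TRUE)
    kind <- if (length(defline) > 0 && grepl("plasmid", defline[1], ignore.case = TRUE))
      "plasmid" else "chromosome"
    fstart <- grep("^FEATURES", block)
    ostart <- grep("^ORIGIN", block)
    if (length(ostart) == 0) stop("record ", id, ": no ORIGIN section")
    seq_lines <- block[(ostart[1] + 1):(length(block) - 1)]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) != decl_len)
      stop("record ", id, ": LOCUS length ", decl_len,
           " != sequence length ", nchar(sequence))
    genes <- NULL
    if (length(fstart) > 0) {
      flines <- block[(fstart[1] + 1):(ostart[1] - 1)]
      fidx <- grep("^     \\S", flines)
      rows <- list()
      for (k in seq_along(fidx)) {
        from <- fidx[k]
        to <- if (k < length(fidx)) fidx[k + 1] - 1 else length(flines)
        ftype <- sub("^\\s+(\\S+).*$", "\\1", flines[from])
        if (!ftype %in% c("gene", "CDS", "tRNA", "rRNA", "ncRNA", "tmRNA",
                          "pseudogene")) next
        locstr <- paste(trimws(sub("^\\s+\\S+\\s*", "", flines[from])))
        strand <- if (grepl("complement", locstr)) "-" else "+"
        nums <- regmatches(locstr, gregexpr("[0-9]+", locstr))[[1]]
        if (length(nums) < 2) stop("record ", id, ": cannot parse location '",
                                   locstr, "'")
        st <- as.integer(nums[1]); en <- as.integer(nums[length(nums)])
        quals <- flines[(from + 1):to]
        getq <- function(q) {
          m <- grep(sprintf('^\\s+/%s="?', q), quals, value = TRUE)
          if (length(m) == 0) return(NA_character_)
          sub('"?\\s*$', "", sub(sprintf('^\\s+/%s="?', q), "", m[1]))
        }
        rows[[length(rows) + 1]] <- data.frame(
          id = getq("locus_tag"), start = st, end = en, strand = strand,
          type = ftype, product = getq("product") %|NA|% "",
          stringsAsFactors = FALSE)
      }
      if (length(rows) > 0) {
        genes <- do.call(rbind, rows)
        # collapse gene/CDS duplicates on the same span, prefer the gene row id
        key <- paste(genes$start, genes$end, genes$strand)
        genes <- genes[!duplicated(key), , drop = FALSE]
        genes$id[is.na(genes$id)] <- sprintf("%s_g%d", id, which(is.na(genes$id)))
        if (any(genes$end > nchar(sequence)))
          stop("record ", id, ": feature coordinates outside sequence")
      }
    }
    reps[[id]] <- replicon(id, sequence, genes, kind)
  }
  reps
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Write a genome to disk
#'
#' @param genome named list of [replicon] objects.
#' @param path output file; for `fasta+gff3` this is the FASTA path.
#' @param format output format.
#' @param gff GFF3 output path for `fasta+gff3`.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, path, format = c("genbank", "fasta+gff3"),
                         gff = NULL) {
  format <- match.arg(format)
  if (format == "genbank") {
    con <- file(path, "w")
    on.exit(close(con))
    for (rep in genome) {
      writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                         rep$id, rep$length), con)
      writeLines(sprintf("DEFINITION  %s %s.", rep$id, rep$kind), con)
      writeLines("FEATURES             Location/Qualifiers", con)
      if (nrow(rep$genes) > 0) {
        for (i in seq_len(nrow(rep$genes))) {
          g <- rep$genes[i, ]
          locstr <- if (g$strand == "-")
            sprintf("complement(%d..%d)", g$start, g$end)
          else sprintf("%d..%d", g$start, g$end)
          writeLines(sprintf("     %-16s%s", g$type, locstr), con)
          writeLines(sprintf('                     /locus_tag="%s"', g$id), con)
          if (nzchar(g$product))
            writeLines(sprintf('                     /product="%s"', g$product), con)
        }
      }
      writeLines("ORIGIN", con)
      s <- tolower(rep$sequence)
      pos <- seq(1, nchar(s), by = 60)
      for (p in pos) {
        chunk <- substr(s, p, min(p + 59, nchar(s)))
        parts <- substring(chunk, seq(1, nchar(chunk), 10),
                           pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        writeLines(sprintf("%9d %s", p, paste(parts, collapse = " ")), con)
      }
      writeLines("//", con)
    }
    return(invisible(path))
  }
  if (is.null(gff)) gff <- sub("\\.(fa|fasta|fna)$", ".gff3", path)
  seqs <- Biostrings::DNAStringSet(vapply(genome, function(r) r$sequence, ""))
  names(seqs) <- vapply(genome, function(r) r$id, "")
  Biostrings::writeXStringSet(seqs, path)
  rows <- list()
  for (rep in genome) {
    if (nrow(rep$genes) == 0) next
    g <- rep$genes
    rows[[rep$id]] <- data.frame(
      seqid = rep$id, source = "srnascout", type = g$type, start = g$start,
      end = g$end, score = ".", strand = g$strand, phase = ".",
      attributes = sprintf("ID=%s;locus_tag=%s%s", g$id, g$id,
                           ifelse(nzchar(g$product),
                                  paste0(";product=", g$product), "")),
      stringsAsFactors = FALSE)
  }
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  close(con)
  if (length(rows) > 0) {
    suppressWarnings(utils::write.table(
      do.call(rbind, rows), gff, sep = "\t", quote = FALSE,
      col.names = FALSE, row.names = FALSE, append = TRUE))
  }
  invisible(c(path, gff))
}

#' Extract intergenic regions from a replicon
#'
#' IGRs are the maximal gaps between the union of annotated gene intervals,
#' including the gap before the first gene and after the last one. IGRs are
#' strandless; gaps shorter than `min_len` are dropped. A replicon with no
#' genes yields a single IGR spanning the whole sequence.
#'
#' @param rep a [replicon].
#' @param min_len minimum IGR length to keep (nt), default 50.
#' @param tag replicon tag used in IGR ids (`IGR_<tag>-<ordinal>`); defaults
#'   to the replicon id.
#' @return data.frame with columns id, replicon_id, start, end, length,
#'   left_gene, right_gene, seq.
#' @export
extract_igrs <- function(rep, min_len = 50, tag = NULL) {
  stopifnot(inherits(rep, "replicon"))
  tag <- tag %||% rep$id
  if (nrow(rep$genes) == 0) {
    gaps <- IRanges::IRanges(start = 1, end = rep$length)
  } else {
    gir <- IRanges::reduce(IRanges::IRanges(rep$genes$start, rep$genes$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1, rep$length), gir)
  }
  gaps <- gaps[IRanges::width(gaps) >= min_len]
  if (length(gaps) == 0) {
    return(data.frame(id = character(), replicon_id = character(),
                      start = integer(), end = integer(), length = integer(),
                      left_gene = character(), right_gene = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  st <- IRanges::start(gaps); en <- IRanges::end(gaps)
  lg <- vapply(st, function(s) {
    cand <- rep$genes$end < s
    if (!any(cand)) return(NA_character_)
    rep$genes$id[which(cand)[which.max(rep$genes$end[cand])]]
  }, "")
  rg <- vapply(en, function(e) {
    cand <- rep$genes$start > e
    if (!any(cand)) return(NA_character_)
    rep$genes$id[which(cand)[which.min(rep$genes$start[cand])]]
  }, "")
  data.frame(
    id = sprintf("IGR_%s-%d", tag, seq_along(st)),
    replicon_id = rep$id, start = st, end = en, length = en - st + 1L,
    left_gene = lg, right_gene = rg,
    seq = substring(rep$sequence, st, en), stringsAsFactors = FALSE)
}

#' Extract IGRs for a whole genome
#'
#' @param genome named list of [replicon] objects.
#' @param min_len minimum IGR length (nt).
#' @param tag_map optional named vector replicon id -> tag for IGR ids
#'   (e.g. `c(chr = "G", pA = "Pa")`).
#' @return data.frame of IGRs across replicons.
#' @export
extract_igrs_genome <- function(genome, min_len = 50, tag_map = NULL) {
  out <- lapply(genome, function(rep) {
    tg <- if (!is.null(tag_map) && !is.na(tag_map[rep$id])) tag_map[[rep$id]]
          else rep$id
    extract_igrs(rep, min_len = min_len, tag = tg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export IGRs as BED (0-based half-open) or TSV
#'
#' @param igrs data.frame from [extract_igrs].
#' @param path output path.
#' @param format "bed" or "tsv".
#' @return invisibly, `path`.
#' @export
export_igrs <- function(igrs, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- data.frame(chrom = igrs$replicon_id, start = igrs$start - 1L,
                      end = igrs$end, name = igrs$id)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(igrs[, setdiff(names(igrs), "seq")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
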