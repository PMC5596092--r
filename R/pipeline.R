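#' Build a pipeline configuration
#'
#' Collects every stage's inputs and thresholds into one validated list.
#' Inputs can be in-memory objects (from [simulate_genomes()] /
#' [simulate_coverage()]) or file paths; optional stages (known-RNA
#' labelling, expression validation, target prediction, GO enrichment) are
#' skipped when their inputs are absent.
#'
#' @param genomes named list: genome id -> named list of [replicon]s; or
#'   `NULL` with `genome_paths` given.
#' @param genome_paths named character vector of GenBank files (one per
#'   genome), read with [read_genome()].
#' @param focal id of the focal genome (default: first).
#' @param igr_min_len minimum IGR length (nt).
#' @param evalue_max conservation E-value cutoff.
#' @param min_genomes minimum supporting genomes per conserved block.
#' @param thresholds structure thresholds ([structure_thresholds()]).
#' @param n_shuffles shuffles per block for the z-score.
#' @param known_rna_library FASTA path or named character vector.
#' @param coverage a `coverage_set` or directory of bedGraph tracks.
#' @param conditions condition names (first = reference for ratios).
#' @param annotation gene-to-GO table (data.frame or TSV path with columns
#'   gene_id, term_id, namespace, term_name).
#' @param category_map term-to-class table (data.frame or TSV path).
#' @param target_opts list: seed_len, energy_max for target prediction.
#' @param id_prefix candidate id prefix.
#' @param seed RNG seed recorded in all outputs.
#' @param out_dir optional output directory for TSV artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes = NULL, genome_paths = NULL, focal = NULL,
                            igr_min_len = 50, evalue_max = 1e-5,
                            min_genomes = 2,
                            thresholds = structure_thresholds(),
                            n_shuffles = 100, known_rna_library = NULL,
                            coverage = NULL,
                            conditions = c("FC", "MN", "SN"),
                            annotation = NULL, category_map = NULL,
                            target_opts = list(seed_len = 7, energy_max = -8),
                            id_prefix = "cand_s", seed = 1, out_dir = NULL) {
  if (is.null(genomes) && is.null(genome_paths))
    stop("pipeline_config: either `genomes` or `genome_paths` is required")
  if (!is.null(genome_paths)) {
    missing <- genome_paths[!file.exists(genome_paths)]
    if (length(missing) > 0)
      stop("pipeline_config: missing genome file(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(
    genomes = genomes, genome_paths = genome_paths, focal = focal,
    igr_min_len = igr_min_len, evalue_max = evalue_max,
    min_genomes = min_genomes, thresholds = thresholds,
    n_shuffles = n_shuffles, known_rna_library = known_rna_library,
    coverage = coverage, conditions = conditions, annotation = annotation,
    category_map = category_map, target_opts = target_opts,
    id_prefix = id_prefix, seed = seed, out_dir = out_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(structure_thresholds, y$thresholds)
  if (!is.null(y$genome_paths)) y$genome_paths <- unlist(y$genome_paths)
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the sRNA discovery pipeline end to end
#'
#' Stage order: IGR extraction, cross-genome conservation, structure
#' screening, signal annotation + candidate assembly, known-RNA labelling,
#' RNA-seq transcription-unit validation with RPKM, target prediction for
#' novel candidates, and GO enrichment of predicted targets. Optional
#' stages with missing inputs are skipped with a logged notice. With a
#' fixed seed the run is fully deterministic.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with candidates, blocks, structure scores, transcription
#'   units, expression table, target table, enrichment table, category
#'   summary, summary counts and run metadata.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)

  genomes <- run_stage("genome_io", {
    if (!is.null(config$genomes)) config$genomes
    else lapply(config$genome_paths, read_genome)
  })
  focal <- config$focal %||% names(genomes)[1]
  say("genome_io: %d genomes, focal = %s", length(genomes), focal)

  igrs <- run_stage("igr_extraction",
    lapply(genomes, extract_igrs_genome, min_len = config$igr_min_len))
  say("igr_extraction: %s IGRs (focal %d)",
      paste(vapply(igrs, nrow, 0L), collapse = "/"), nrow(igrs[[focal]]))

  blocks <- run_stage("conservation_screen",
    find_conserved_blocks(igrs, focal, evalue_max = config$evalue_max,
                          min_genomes = config$min_genomes))
  say("conservation_screen: %d conserved blocks (E <= %g, >= %d genomes)",
      length(blocks), config$evalue_max, config$min_genomes)

  screened <- run_stage("structure_screen",
    screen_structures(blocks, thresholds = config$thresholds,
                      n_shuffles = config$n_shuffles, seed = config$seed))
  say("structure_screen: %d/%d blocks classified structured",
      length(screened$structured), length(blocks))

  candidates <- run_stage("candidate_assembly",
    assemble_candidates(screened$structured, screened$structured_scores,
                        genomes[[focal]], igrs[[focal]],
                        id_prefix = config$id_prefix))
  say("candidate_assembly: %d candidates", nrow(candidates))

  if (!is.null(config$known_rna_library)) {
    candidates <- run_stage("known_rna_labelling",
      match_known_rnas(candidates, config$known_rna_library))
    say("known_rna_labelling: %d known / %d novel",
        sum(candidates$family != "un"), sum(candidates$family == "un"))
  } else say("known_rna_labelling: skipped (no library)")

  tus <- NULL; expr_tab <- NULL
  if (!is.null(config$coverage)) {
    covset <- config$coverage
    tus <- run_stage("tu_calling", call_tus_covset(covset))
    # validate against the union of per-condition units: merge by interval
    candidates <- run_stage("tu_matching",
      match_candidates_to_tus(candidates, tus))
    expr_tab <- run_stage("expression",
      expression_table(candidates, covset, conditions = config$conditions))
    say("expression: %d/%d candidates detected in coverage",
        sum(candidates$detected), nrow(candidates))
  } else {
    say("expression: skipped (no coverage)")
    if (nrow(candidates) > 0) candidates$detected <- NA
  }

  targets <- NULL
  if (nrow(candidates) > 0) {
    novel <- candidates[candidates$family == "un", , drop = FALSE]
    if (nrow(novel) > 0) {
      windows <- run_stage("tir_windows",
        do.call(rbind, lapply(genomes[[focal]], extract_tir_windows)))
      targets <- run_stage("target_prediction", {
        out <- list()
        for (i in seq_len(nrow(novel))) {
          hits <- predict_interactions(
            novel$seq[i], windows,
            seed_len = config$target_opts$seed_len %||% 7,
            energy_max = config$target_opts$energy_max %||% -8)
          if (nrow(hits) > 0) {
            hits <- cbind(srna_id = novel$id[i], hits)
            out[[novel$id[i]]] <- hits
          }
        }
        if (length(out) > 0) {
          res <- do.call(rbind, out); rownames(res) <- NULL; res
        } else NULL
      })
      say("target_prediction: %d interactions for %d novel sRNAs",
          if (is.null(targets)) 0L else nrow(targets), nrow(novel))
    }
  }

  enrichment <- NULL; categories <- NULL
  if (!is.null(config$annotation) && !is.null(targets)) {
    ann <- config$annotation
    if (is.character(ann)) ann <- utils::read.delim(ann, stringsAsFactors = FALSE)
    universe <- unique(unlist(lapply(genomes[[focal]],
                                     function(r) r$genes$id)))
    tgt <- unique(targets$gene_id)
    enrichment <- run_stage("go_enrichment",
      hypergeom_enrichment(tgt, ann, universe))
    if (!is.null(config$category_map)) {
      cm <- config$category_map
      if (is.character(cm)) cm <- utils::read.delim(cm, stringsAsFactors = FALSE)
      categories <- run_stage("category_summary",
        category_summary(tgt, ann, cm))
    }
    say("go_enrichment: %d terms tested", nrow(enrichment))
  } else say("go_enrichment: skipped")

  summary_counts <- candidate_summary(candidates)
  meta <- list(seed = config$seed, focal = focal,
               n_genomes = length(genomes),
               timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  result <- list(candidates = candidates,
                 blocks = blocks_to_table(blocks),
                 structure_scores = screened$scores, tus = tus,
                 expression = expr_tab, targets = targets,
                 enrichment = enrichment, categories = categories,
                 summary = summary_counts, igrs = igrs, meta = meta)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(result$candidates, "candidates.tsv")
  wt(result$blocks, "conserved_blocks.tsv")
  wt(result$tus, "transcription_units.tsv")
  wt(result$expression, "expression.tsv")
  wt(result$targets, "targets.tsv")
  wt(result$enrichment, "enrichment.tsv")
  wt(result$categories, "categories.tsv")
  cfg_path <- file.path(config$out_dir, "config.yaml")
  dump <- config[c("focal", "igr_min_len", "evalue_max", "min_genomes",
                   "thresholds", "n_shuffles", "conditions", "id_prefix",
                   "seed")]
  yaml::write_yaml(dump, cfg_path)
  meta <- c(result$meta, list(config_md5 = unname(tools::md5sum(cfg_path))))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Report tables and summary counts for a pipeline run
#'
#' Builds the published-table-style report: a candidate table (one row per
#' candidate with coordinates, family and evidence), an expression table,
#' and summary counts (total, per replicon, known/novel split,
#' detected/undetected split) computed with the same counting rules that
#' the fixture-based golden tests validate.
#'
#' @param result a [run_pipeline()] result, or any candidate data.frame
#'   with `family`, `replicon_id` and optionally `detected` columns.
#' @param out_dir optional directory for `report_candidates.tsv`,
#'   `report_expression.tsv` and `report_summary.tsv`.
#' @return list with `candidate_table`, `expression_table` and `counts`.
#' @export
make_report <- function(result, out_dir = NULL) {
  if (is.data.frame(result)) {
    candidates <- result
    expr_tab <- NULL
  } else {
    candidates <- result$candidates
    expr_tab <- result$expression
  }
  counts <- candidate_summary(candidates)
  keep <- intersect(c("id", "candidate", "replicon_id", "strand", "start",
                      "end", "length", "igr_id", "left_gene", "right_gene",
                      "seq_start", "seq_end", "seq_length", "family",
                      "detected"), names(candidates))
  cand_tab <- candidates[, keep, drop = FALSE]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cand_tab, file.path(out_dir, "report_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(expr_tab))
      utils::write.table(expr_tab, file.path(out_dir, "report_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    su <- data.frame(metric = c("total", "annotated", "novel",
                                "novel_detected",
                                paste0("replicon_", names(counts$per_replicon))),
                     value = c(counts$total, counts$annotated, counts$novel,
                               counts$novel_detected,
                               unname(counts$per_replicon)))
    utils::write.table(su, file.path(out_dir, "report_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(candidate_table = cand_tab, expression_table = expr_tab,
       counts = counts)
}
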