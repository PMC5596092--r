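#' Hypergeometric GO-term enrichment of a target gene set
#'
#' For every annotated term, tests whether the target set is enriched:
#' `p = P(X >= k)` with `X ~ Hypergeometric(M, K, n)` where `M` is the
#' universe size, `K` the universe genes carrying the term, `n` the target
#' set size and `k` the target genes carrying it (upper tail, computed in
#' log-space by `phyper`). P-values are Benjamini-Hochberg adjusted within
#' each GO namespace. Unannotated genes stay in the universe count.
#'
#' @param target_ids character vector of target gene ids (subset of the
#'   universe).
#' @param annotation data.frame with columns gene_id, term_id, namespace,
#'   term_name (already propagated; one row per gene-term assignment).
#' @param universe_ids character vector of universe gene ids.
#' @return data.frame sorted by p: term_id, term_name, namespace, k, K, n,
#'   M, p, fdr.
#' @export
hypergeom_enrichment <- function(target_ids, annotation, universe_ids) {
  target_ids <- unique(target_ids)
  universe_ids <- unique(universe_ids)
  if (!all(target_ids %in% universe_ids))
    stop("target set must be a subset of the universe")
  empty <- data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), M = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  if (length(target_ids) == 0) return(empty)
  ann <- annotation[annotation$gene_id %in% universe_ids, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id", "namespace", "term_name")])
  if (nrow(ann) == 0) return(empty)
  M <- length(universe_ids)
  n <- length(target_ids)
  terms <- unique(ann[, c("term_id", "namespace", "term_name")])
  terms <- terms[order(terms$term_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(terms)), function(t) {
    sub <- ann[ann$term_id == terms$term_id[t] &
                 ann$namespace == terms$namespace[t], , drop = FALSE]
    K <- length(unique(sub$gene_id))
    k <- length(intersect(unique(sub$gene_id), target_ids))
    p <- if (k == 0) 1.0 else
      stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[t], term_name = terms$term_name[t],
               namespace = terms$namespace[t], k = k, K = K, n = n, M = M,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$fdr[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' WEGO-style functional category summary
#'
#' Summarises target-gene annotation by top-level class per namespace:
#' a gene may count in several classes; percentages are gene-class
#' assignments over all assignments in the namespace, times 100, rounded
#' half-up to integers.
#'
#' @param target_ids character vector of target gene ids.
#' @param annotation data.frame (gene_id, term_id, namespace, term_name).
#' @param category_map data.frame (term_id, class) mapping terms to
#'   top-level classes.
#' @return data.frame: namespace, class, n_genes, percent.
#' @export
category_summary <- function(target_ids, annotation, category_map) {
  ann <- annotation[annotation$gene_id %in% target_ids, , drop = FALSE]
  ann <- merge(ann, category_map, by = "term_id")
  if (nrow(ann) == 0)
    return(data.frame(namespace = character(), class = character(),
                      n_genes = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  asg <- unique(ann[, c("gene_id", "namespace", "class")])
  rows <- list()
  for (ns in sort(unique(asg$namespace))) {
    sub <- asg[asg$namespace == ns, , drop = FALSE]
    counts <- table(sub$class)
    rows[[ns]] <- data.frame(
      namespace = ns, class = names(counts),
      n_genes = as.integer(counts),
      percent = round_half_up(100 * as.integer(counts) / sum(counts), 0),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
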