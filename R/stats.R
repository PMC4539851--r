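#' Per-annotation statistics
#'
#' Collects the basic statistics table for one annotation: counts of CDS,
#' tRNA, rRNA and ncRNA features, genes involved in at least one internal
#' overlap (genes, not pairs), pseudogenes, frameshifted and discontiguous
#' genes, the hypothetical/functional split of CDS products, CDS with and
#' without a gene symbol, and conserved-hypothetical CDS. Conserved
#' hypotheticals are counted inside `hypothetical_products` (and again in
#' `conserved`), so `hypothetical_products + non_hypothetical_products = cds`.
#'
#' @param ann an [annotation].
#' @param offset overlap tolerance passed to [detect_internal_overlaps()].
#' @return an `annotation_stats` named list of counts with a `total` equal to
#'   `cds + trna + rrna + ncrna`.
#' @examples
#' ann <- generate_annotation(30, replicon_length = 90000, seed = 4)
#' summarize_annotation(ann)
#' @export
summarize_annotation <- function(ann, offset = 0.02) {
  stopifnot(inherits(ann, "annotation"))
  g <- ann$genes
  cds <- g$feature_type == "CDS"
  ov <- detect_internal_overlaps(ann, offset)
  hypo <- g$product_category %in% c("hypothetical", "conserved-hypothetical")
  stats <- list(
    label = ann$label,
    cds = sum(cds),
    trna = sum(g$feature_type == "tRNA"),
    rrna = sum(g$feature_type == "rRNA"),
    ncrna = sum(g$feature_type == "ncRNA"),
    overlapping_genes = length(unique(c(ov$uid1, ov$uid2))),
    pseudogenes = sum(g$is_pseudo),
    frameshifted = sum(g$is_frameshifted),
    discontiguous = sum(g$is_discontiguous),
    hypothetical_products = sum(cds & hypo),
    non_hypothetical_products = sum(cds & !hypo),
    conserved = sum(cds & g$product_category == "conserved-hypothetical"),
    with_gene_symbol = sum(cds & !is.na(g$gene_symbol)),
    without_gene_symbol = sum(cds & is.na(g$gene_symbol)),
    total = nrow(g))
  structure(stats, class = "annotation_stats")
}

#' @export
print.annotation_stats <- function(x, ...) {
  cat(sprintf("<annotation_stats> %s\n", x$label))
  for (f in setdiff(names(x), "label"))
    cat(sprintf("  %-26s %d\n", f, x[[f]]))
  invisible(x)
}

#' Write the annotations-information table
#'
#' One row per statistic, one column per annotation label, tab-delimited —
#' the "annotations information" output group.
#'
#' @param stats_list list of `annotation_stats`, one per annotation.
#' @param path output path.
#' @return invisibly, the exported data frame.
#' @export
write_stats_table <- function(stats_list, path) {
  fields <- c("cds", "trna", "rrna", "ncrna", "overlapping_genes",
              "pseudogenes", "frameshifted", "discontiguous",
              "hypothetical_products", "non_hypothetical_products",
              "conserved", "with_gene_symbol", "without_gene_symbol", "total")
  tab <- data.frame(feature = fields)
  for (s in stats_list)
    tab[[s$label]] <- vapply(fields, function(f) s[[f]], 1L)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
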