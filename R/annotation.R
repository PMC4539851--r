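#' Construct an annotation object
#'
#' An `annotation` is one labelled gene set for one genome: the in-memory
#' model of a GenBank feature table restricted to the four counted feature
#' types (CDS, tRNA, rRNA, ncRNA). Genes live in a data frame with one row per
#' feature; coordinates are 1-based inclusive with `start <= stop` on both
#' strands, matching the GenBank convention. Discontiguous (join) features
#' keep their segments in a list column and expose the outer span as
#' `start`/`stop`.
#'
#' @param genes data frame of gene records. Required columns: `replicon_id`,
#'   `feature_type` (one of CDS/tRNA/rRNA/ncRNA), `strand` (`"+"`/`"-"`),
#'   `start`, `stop`. Optional columns (defaulted when absent): `locus_tag`,
#'   `gene_symbol`, `product`, `note`, `is_pseudo`, `is_frameshifted`,
#'   `segments` (list of 2-column start/stop matrices), `product_category`,
#'   `uid`.
#' @param label short name of the annotation method, e.g. `"NCBI"`.
#' @param genome_name genome short name.
#' @param is_reference whether this annotation is the designated reference.
#' @param replicon_lengths optional named integer vector of replicon lengths
#'   (used when writing GenBank fixtures).
#' @param patterns product pattern list used to fill `product_category` when
#'   it is not supplied; see [classify_product()].
#' @return An object of class `annotation`.
#' @examples
#' ann <- annotation(
#'   data.frame(replicon_id = "chr", feature_type = "CDS", strand = "+",
#'              start = 100, stop = 1099, product = "hypothetical protein"),
#'   label = "demo")
#' ann
#' @export
annotation <- function(genes, label, genome_name = "genome",
                       is_reference = FALSE, replicon_lengths = NULL,
                       patterns = default_product_patterns()) {
  stopifnot(is.data.frame(genes), is.character(label), length(label) == 1L)
  required <- c("replicon_id", "feature_type", "strand", "start", "stop")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("genes is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  n <- nrow(genes)
  g <- data.frame(
    uid = if ("uid" %in% names(genes)) as.character(genes$uid)
          else make_uids(label, n),
    replicon_id = as.character(genes$replicon_id),
    feature_type = as.character(genes$feature_type),
    strand = as.character(genes$strand),
    start = as.integer(genes$start),
    stop = as.integer(genes$stop),
    locus_tag = opt_chr(genes, "locus_tag", n),
    gene_symbol = opt_chr(genes, "gene_symbol", n),
    product = opt_chr(genes, "product", n),
    note = opt_chr(genes, "note", n),
    is_pseudo = opt_lgl(genes, "is_pseudo", n),
    is_frameshifted = opt_lgl(genes, "is_frameshifted", n),
    stringsAsFactors = FALSE
  )
  g$segments <- if ("segments" %in% names(genes)) genes$segments
                else replicate(n, NULL, simplify = FALSE)
  g$segments <- lapply(seq_len(n), function(i) {
    seg <- g$segments[[i]]
    if (is.null(seg) || !nrow(seg))
      seg <- cbind(start = g$start[i], stop = g$stop[i])
    storage.mode(seg) <- "integer"
    colnames(seg) <- c("start", "stop")
    seg
  })
  g$is_discontiguous <- vapply(g$segments, nrow, 1L) > 1L
  # outer span is defined by the segments for compound locations
  g$start <- vapply(g$segments, function(s) min(s[, "start"]), 1L)
  g$stop <- vapply(g$segments, function(s) max(s[, "stop"]), 1L)
  g$product_category <-
    if ("product_category" %in% names(genes)) as.character(genes$product_category)
    else classify_product(g$product, g$note, patterns)

  ann <- structure(
    list(label = label, genome_name = genome_name, genes = g,
         is_reference = isTRUE(is_reference),
         replicon_lengths = replicon_lengths),
    class = "annotation")
  validate_annotation(ann)
  ann
}

make_uids <- function(label, n) {
  if (n == 0L) character(0) else sprintf("%s_%05d", label, seq_len(n))
}

opt_chr <- function(df, col, n) {
  if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, n)
}
opt_lgl <- function(df, col, n) {
  if (col %in% names(df)) {
    x <- as.logical(df[[col]])
    x[is.na(x)] <- FALSE
    x
  } else rep(FALSE, n)
}

validate_annotation <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$uid)) stop("gene uids must be unique within an annotation")
  bad_type <- setdiff(unique(g$feature_type), c("CDS", "tRNA", "rRNA", "ncRNA"))
  if (length(bad_type))
    stop("unsupported feature type(s): ", paste(bad_type, collapse = ", "))
  if (!all(g$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (nrow(g)) {
    if (any(g$start < 1L) || any(g$start > g$stop))
      stop("coordinates must satisfy 1 <= start <= stop")
    seg_ok <- vapply(g$segments, function(s)
      all(s[, "start"] >= 1L & s[, "start"] <= s[, "stop"]), TRUE)
    if (!all(seg_ok)) stop("every segment must satisfy 1 <= start <= stop")
  }
  invisible(ann)
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s (%s)%s\n", x$label, x$genome_name,
              if (x$is_reference) " [reference]" else ""))
  tab <- table(factor(x$genes$feature_type,
                      levels = c("CDS", "tRNA", "rRNA", "ncRNA")))
  cat(sprintf("  %d genes on %d replicon(s): %s\n",
              nrow(x$genes), length(unique(x$genes$replicon_id)),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.annotation <- function(object, offset = 0.02, ...) {
  summarize_annotation(object, offset = offset)
}

# genes ordered by (replicon_id, start, stop) for stable output
sort_genes <- function(g) {
  g[order(g$replicon_id, g$start, g$stop, g$uid), , drop = FALSE]
}
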