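#' Symmetric annotation similarity score
#'
#' The similarity between annotations X and Z is the matched fraction of the
#' pooled gene set, expressed as a percentage:
#' \deqn{2 \cdot 100 \cdot (Identical + Similar) / (Total_x + Total_z)}
#' It is symmetric in X and Z, equals 100 for self-comparison, and is
#' reported half-up rounded to two decimals.
#'
#' @param identical number of identical gene pairs.
#' @param similar number of similar gene pairs.
#' @param total_x,total_z total gene counts of the two annotations.
#' @return the score as a percentage with two decimals.
#' @examples
#' similarity_score(2421, 126, 3048, 3089) # 83.00
#' similarity_score(2780, 71, 3048, 3088)  # 92.93
#' @export
similarity_score <- function(identical, similar, total_x, total_z) {
  stopifnot(identical >= 0, similar >= 0, total_x >= 0, total_z >= 0)
  if (total_x + total_z == 0)
    stop("similarity score undefined: both annotations are empty")
  if (identical + similar > min(total_x, total_z))
    stop("matched pairs cannot exceed the smaller annotation's total")
  round_half_up((identical + similar) / (total_x + total_z) * 2 * 100, 2)
}

#' Reference-relative comparison report
#'
#' Summarises a [match_genes()] table with annotation `z` taken as the
#' reference. False negatives (FN) are reference genes the query misses:
#' `fn_short_overlap` counts reference genes whose best counterpart is only a
#' short overlap, `fn_no_overlap` those with no counterpart at all. False
#' positives (FP) are the analogous query-side categories. Identical and
#' similar counts are additionally broken down by feature type, and the
#' identical/similar/FN categories are expressed as percentages of the
#' reference total (half-up, two decimals).
#'
#' @param table a `match_table`.
#' @param x the query annotation.
#' @param z the reference annotation (`z` side of the table).
#' @return a `comparison_report` object.
#' @examples
#' a <- generate_annotation(15, replicon_length = 50000, seed = 3, label = "A")
#' reference_report(match_genes(a, a), a, a)
#' @export
reference_report <- function(table, x, z) {
  stopifnot(inherits(table, "match_table"),
            inherits(x, "annotation"), inherits(z, "annotation"))
  total_x <- nrow(x$genes)
  total_z <- nrow(z$genes)
  zs <- table$z_status
  xs <- table$x_status
  n_id <- sum(zs == "identical")
  n_sim <- sum(zs == "similar")

  by_type <- function(status) {
    uids <- table$pairs$uid_z[table$pairs$status == status]
    types <- z$genes$feature_type[match(uids, z$genes$uid)]
    counts <- table(factor(types, levels = c("CDS", "rRNA", "tRNA", "ncRNA")))
    setNames(as.integer(counts), names(counts))
  }

  report <- structure(list(
    x_label = table$x_label, z_label = table$z_label,
    identical = n_id, similar = n_sim,
    total_x = total_x, total_z = total_z,
    similarity_score = similarity_score(n_id, n_sim, total_x, total_z),
    fn_short_overlap = sum(zs == "unique_with_overlap"),
    fn_no_overlap = sum(zs == "unique_without_overlap"),
    fp_short_overlap = sum(xs == "unique_with_overlap"),
    fp_no_overlap = sum(xs == "unique_without_overlap"),
    identical_by_type = by_type("identical"),
    similar_by_type = by_type("similar")),
    class = "comparison_report")
  report$percent <- c(
    identical = percent_of(report$identical, total_z),
    similar = percent_of(report$similar, total_z),
    fn_short_overlap = percent_of(report$fn_short_overlap, total_z),
    fn_no_overlap = percent_of(report$fn_no_overlap, total_z))
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs reference %s\n",
              x$x_label, x$z_label))
  print(comparison_report_table(x), row.names = FALSE, right = FALSE)
  invisible(x)
}

# Table-2-shaped data frame for printing/export
comparison_report_table <- function(r) {
  breakdown <- function(b)
    sprintf("CDS=%d rRNA=%d tRNA=%d ncRNA=%d",
            b[["CDS"]], b[["rRNA"]], b[["tRNA"]], b[["ncRNA"]])
  data.frame(
    `Gene calls` = c("Detected identical", "Detected similar",
                     "FN - Short overlap", "FN - No overlap",
                     "FP - Short overlap", "FP-No overlap",
                     "Similarity score"),
    Count = c(r$identical, r$similar, r$fn_short_overlap, r$fn_no_overlap,
              r$fp_short_overlap, r$fp_no_overlap, NA),
    Breakdown = c(breakdown(r$identical_by_type),
                  breakdown(r$similar_by_type), "", "", "", "", ""),
    `Percent of reference genes` = c(
      fmt_pct(r$percent[["identical"]]), fmt_pct(r$percent[["similar"]]),
      fmt_pct(r$percent[["fn_short_overlap"]]),
      fmt_pct(r$percent[["fn_no_overlap"]]), "-", "-",
      sprintf("%.2f %%", r$similarity_score)),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a comparison report as a tab-delimited table
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return invisibly, the exported data frame.
#' @export
write_comparison_table <- function(report, path) {
  tab <- comparison_report_table(report)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "-")
  invisible(tab)
}
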