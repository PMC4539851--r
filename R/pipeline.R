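#' Configure a comparison run
#'
#' Bundles the inputs and options of one pipeline run. At least two inputs
#' are needed for comparison mode; a single input triggers statistics-only
#' mode. When `first_is_reference` is `TRUE`, the first-listed annotation is
#' the reference every other annotation is scored against.
#'
#' @param inputs character vector of GenBank file paths.
#' @param labels unique annotation labels, one per input (defaults to the
#'   names of `inputs`, else the file base names).
#' @param outdir output directory (created if missing).
#' @param genome_name genome short name used in file names.
#' @param offset end-deviation tolerance as a fraction of the shorter gene's
#'   length; default 0.02 (2 percent).
#' @param first_is_reference score every other annotation against the first.
#' @param patterns product pattern list; see [default_product_patterns()].
#' @param emit_plots write summary PNG charts in addition to the tables.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs, labels = NULL, outdir, genome_name = "genome",
                       offset = 0.02, first_is_reference = TRUE,
                       patterns = default_product_patterns(),
                       emit_plots = FALSE) {
  stopifnot(length(inputs) >= 1L, offset >= 0, offset < 1)
  if (is.null(labels))
    labels <- names(inputs) %||%
      tools::file_path_sans_ext(basename(inputs))
  if (length(labels) != length(inputs))
    stop("need exactly one label per input")
  if (anyDuplicated(labels))
    stop("labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(inputs = unname(inputs), labels = unname(labels),
                 outdir = outdir, genome_name = genome_name, offset = offset,
                 first_is_reference = isTRUE(first_is_reference),
                 patterns = patterns, emit_plots = isTRUE(emit_plots)),
            class = "run_config")
}

#' Run the full annotation-comparison pipeline
#'
#' Parses every input, then writes the five output groups to `outdir`:
#' the annotations-information statistics table; one comparison-to-reference
#' report per non-reference input (when a reference is designated); the
#' all-against-all similarity matrix; the Venn region-count table; and the
#' extended annotations (EA, unique, EUA, EUA_clean) as tab-delimited tables
#' plus GFF3, with a small self-contained HTML summary page. Pseudogene flags
#' are propagated across identical/similar pairs before the extended views
#' are derived. With a single input only the statistics table is produced.
#' Re-running with the same configuration rewrites byte-identical tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the parsed annotations, match tables,
#'   reports, similarity matrix, clusters, Venn counts, extended views and
#'   the vector of files written.
#' @examples
#' truth <- generate_annotation(15, replicon_length = 60000, seed = 12)
#' f1 <- tempfile(fileext = ".gbk"); write_genbank(truth, f1)
#' f2 <- tempfile(fileext = ".gbk")
#' write_genbank(perturb_annotation(truth, perturbation_spec(
#'   seed = 3, end_shift_fraction = 0.2), label = "AM1")$variant, f2)
#' out <- run_pipeline(run_config(c(NCBI = f1, AM1 = f2),
#'                                outdir = tempfile("beacon_out")))
#' out$similarity_matrix
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  out_file <- function(name) {
    p <- file.path(config$outdir, sprintf("%s_%s", config$genome_name, name))
    written <<- c(written, p)
    p
  }

  anns <- lapply(seq_along(config$inputs), function(i)
    parse_genbank(config$inputs[[i]], label = config$labels[[i]],
                  is_reference = config$first_is_reference && i == 1L,
                  patterns = config$patterns))
  message(sprintf("parsed %d annotation(s): %s",
                  length(anns),
                  paste(sprintf("%s (%d genes)", config$labels,
                                vapply(anns, function(a) nrow(a$genes), 1L)),
                        collapse = ", ")))

  # group 1: annotations information
  stats_list <- lapply(anns, summarize_annotation, offset = config$offset)
  write_stats_table(stats_list, out_file("annotations_information.tsv"))

  result <- list(config = config, annotations = anns, stats = stats_list,
                 files = written)
  if (length(anns) < 2L) {
    message("single input: statistics-only mode")
    result$files <- written
    return(invisible(result))
  }

  tables <- pair_tables(anns, config$offset)
  anns <- propagate_pseudo_all(anns, tables)

  # group 2: comparison to reference
  reports <- list()
  if (config$first_is_reference) {
    for (i in seq_along(anns)[-1]) {
      tab <- tables[[pair_key(1L, i)]]
      # reference is the z side of match_genes(x = non-reference, z = ref);
      # pair tables are keyed (1, i) with annotation 1 as x, so swap roles
      swapped <- swap_match_table(tab)
      rep_i <- reference_report(swapped, x = anns[[i]], z = anns[[1]])
      reports[[anns[[i]]$label]] <- rep_i
      write_comparison_table(rep_i, out_file(sprintf(
        "comparison_%s_vs_%s.tsv", anns[[i]]$label, anns[[1]]$label)))
    }
  }

  # group 4 (matrix + Venn counts)
  simmat <- pairwise_matrix(anns, config$offset)
  write.table(data.frame(label = rownames(simmat), simmat,
                         check.names = FALSE),
              out_file("similarity_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- build_clusters(anns, config$offset, tables = tables)
  venn <- intersection_counts(clusters)
  write.table(venn, out_file("venn_regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # group 3: extended annotations
  ea <- derive_ea(clusters, anns)
  uniq <- collect_unique(clusters, anns)
  eua <- derive_eua(ea, uniq)
  eua_clean <- clean_eua(eua)
  views <- list(EA = ea, unique = uniq, EUA = eua, EUA_clean = eua_clean)
  for (nm in names(views)) {
    write_extension_table(views[[nm]], out_file(sprintf("%s.tsv", nm)))
    if (nm != "unique")
      write_gff3(views[[nm]], out_file(sprintf("%s.gff3", nm)))
  }

  # group 5: static summary page
  write_summary_html(out_file("summary.html"), config, stats_list, reports,
                     simmat, venn, views)

  if (config$emit_plots)
    render_summary(config, stats_list, venn, written)

  message(sprintf("wrote %d files to %s", length(written), config$outdir))
  invisible(list(config = config, annotations = anns, stats = stats_list,
                 tables = tables, reports = reports,
                 similarity_matrix = simmat, clusters = clusters,
                 venn = venn, views = views, files = written))
}

# reverse the x/z roles of a match table
swap_match_table <- function(tab) {
  structure(list(
    x_label = tab$z_label, z_label = tab$x_label, offset = tab$offset,
    pairs = data.frame(uid_x = tab$pairs$uid_z, uid_z = tab$pairs$uid_x,
                       status = tab$pairs$status,
                       start_deviation = tab$pairs$start_deviation,
                       stop_deviation = tab$pairs$stop_deviation,
                       shared_bp = tab$pairs$shared_bp,
                       same_frame = tab$pairs$same_frame,
                       relative_frameshift = tab$pairs$relative_frameshift,
                       stringsAsFactors = FALSE),
    x_status = tab$z_status, z_status = tab$x_status,
    relative_frameshift_x = tab$relative_frameshift_z,
    relative_frameshift_z = tab$relative_frameshift_x),
    class = "match_table")
}

# propagate pseudo flags across all pairs until stable (flags only ever
# turn on, so the fixpoint is reached in at most length(anns) sweeps)
propagate_pseudo_all <- function(anns, tables) {
  n <- length(anns)
  repeat {
    before <- vapply(anns, function(a) sum(a$genes$is_pseudo), 1L)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        upd <- propagate_pseudo(tables[[pair_key(i, j)]], anns[[i]], anns[[j]])
        anns[[i]] <- upd$x
        anns[[j]] <- upd$z
      }
    }
    after <- vapply(anns, function(a) sum(a$genes$is_pseudo), 1L)
    if (identical(before, after)) break
  }
  anns
}

write_summary_html <- function(path, config, stats_list, reports, simmat,
                               venn, views) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html_table <- function(df) {
    head <- paste(sprintf("<th>%s</th>", esc(names(df))), collapse = "")
    rows <- apply(df, 1, function(r)
      sprintf("<tr>%s</tr>",
              paste(sprintf("<td>%s</td>", esc(as.character(r))),
                    collapse = "")))
    sprintf("<table border='1' cellpadding='3'><tr>%s</tr>%s</table>",
            head, paste(rows, collapse = "\n"))
  }
  stat_df <- data.frame(feature = c("cds", "trna", "rrna", "ncrna", "total"))
  for (s in stats_list)
    stat_df[[s$label]] <- c(s$cds, s$trna, s$rrna, s$ncrna, s$total)
  view_df <- data.frame(
    view = names(views),
    total = vapply(views, function(v) v$stats$total, 1L),
    orphan = vapply(views, function(v)
      sprintf("%d (%s)", v$stats$orphan, fmt_pct(v$stats$orphan_pct)), ""),
    functional = vapply(views, function(v)
      sprintf("%d (%s)", v$stats$functional,
              fmt_pct(v$stats$functional_pct)), ""))
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>%s annotation comparison</title></head><body>",
            esc(config$genome_name)),
    sprintf("<h1>%s: annotation comparison summary</h1>",
            esc(config$genome_name)),
    "<h2>Annotations information</h2>", html_table(stat_df),
    "<h2>Similarity matrix (%)</h2>",
    html_table(data.frame(label = rownames(simmat), simmat,
                          check.names = FALSE)),
    "<h2>Venn regions</h2>", html_table(venn),
    "<h2>Extended annotations</h2>", html_table(view_df),
    if (length(reports)) c(
      "<h2>Comparison to reference</h2>",
      unlist(lapply(names(reports), function(nm) c(
        sprintf("<h3>%s vs %s</h3>", esc(nm),
                esc(reports[[nm]]$z_label)),
        html_table(comparison_report_table(reports[[nm]])))))),
    "</body></html>")
  writeLines(parts, path)
}

#' Render optional summary plots
#'
#' Writes a grouped bar chart of the per-annotation statistics and a bar
#' chart of the Venn region counts as PNG files. Any plotting failure (e.g. a
#' missing graphics device in a headless build) degrades to a warning,
#' never an error.
#'
#' @param config a [run_config()].
#' @param stats_list list of `annotation_stats`.
#' @param venn a `venn_counts` data frame.
#' @param written internal vector of files already written (used for naming).
#' @return invisibly, the paths of any images written.
#' @export
render_summary <- function(config, stats_list, venn, written = character(0)) {
  imgs <- character(0)
  try_plot <- function(name, expr) {
    path <- file.path(config$outdir,
                      sprintf("%s_%s", config$genome_name, name))
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr()
      TRUE
    }, error = function(e) {
      warning("plot skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) imgs <<- c(imgs, path)
  }
  fields <- c("cds", "trna", "rrna", "ncrna", "pseudogenes",
              "hypothetical_products", "non_hypothetical_products")
  mat <- vapply(stats_list, function(s)
    vapply(fields, function(f) s[[f]], 1L), integer(length(fields)))
  colnames(mat) <- vapply(stats_list, function(s) s$label, "")
  try_plot("stats.png", function()
    graphics::barplot(t(mat), beside = TRUE, las = 2,
                      legend.text = colnames(mat),
                      main = "Annotation statistics"))
  if (length(config$labels) <= 5L)
    try_plot("venn_regions.png", function()
      graphics::barplot(venn$count, names.arg = venn$region, las = 2,
                        main = "Gene-cluster support regions"))
  invisible(imgs)
}
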