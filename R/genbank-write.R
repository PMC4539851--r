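#' Write an annotation as a GenBank flat file
#'
#' Emits a minimal but valid GenBank flat file (LOCUS / DEFINITION / FEATURES
#' / ORIGIN skeleton, one record per replicon) that [parse_genbank()] reads
#' back into the identical annotation. Minus-strand genes are written as
#' `complement(start..stop)`, discontiguous genes as `join(...)` of their
#' segments, pseudogenes with a bare `/pseudo` qualifier. The ORIGIN block is
#' filled with `a` since sequence content is never read by this package.
#'
#' @param ann an [annotation].
#' @param path output file path; when `NULL` the text is returned invisibly
#'   without writing.
#' @return invisibly, the character vector of file lines.
#' @examples
#' ann <- generate_annotation(3, replicon_length = 10000, seed = 7)
#' txt <- write_genbank(ann)
#' head(txt)
#' @export
write_genbank <- function(ann, path = NULL) {
  stopifnot(inherits(ann, "annotation"))
  g <- ann$genes
  replicons <- unique(g$replicon_id)
  if (!length(replicons)) replicons <- "replicon1"
  out <- character(0)
  for (rep_id in replicons) {
    sub <- g[g$replicon_id == rep_id, , drop = FALSE]
    len <- ann$replicon_lengths[rep_id]
    if (is.null(ann$replicon_lengths) || is.na(len))
      len <- if (nrow(sub)) max(sub$stop) + 100L else 1000L
    out <- c(out,
      sprintf("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2000",
              rep_id, len),
      sprintf("DEFINITION  %s.", ann$genome_name),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", len))
    for (i in seq_len(nrow(sub))) {
      seg <- sub$segments[[i]]
      spans <- sprintf("%d..%d", seg[, "start"], seg[, "stop"])
      loc <- if (length(spans) > 1L)
        sprintf("join(%s)", paste(spans, collapse = ",")) else spans
      if (sub$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-16s%s", sub$feature_type[i], loc))
      qual <- function(name, value) {
        if (!is.na(value)) sprintf("                     /%s=\"%s\"", name, value)
      }
      note_val <- sub$note[i]
      if (sub$is_frameshifted[i] &&
          (is.na(note_val) || !grepl("frameshift", note_val, ignore.case = TRUE)))
        note_val <- if (is.na(note_val)) "frameshift"
                    else paste(note_val, "frameshift")
      out <- c(out,
        qual("locus_tag", sub$locus_tag[i]),
        qual("gene", sub$gene_symbol[i]),
        qual("product", sub$product[i]),
        if (sub$is_pseudo[i]) "                     /pseudo",
        qual("note", note_val))
    }
    out <- c(out, "ORIGIN", origin_block(len), "//")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

origin_block <- function(len) {
  pos <- seq(1L, len, by = 60L)
  vapply(pos, function(p) {
    n <- min(60L, len - p + 1L)
    chunks <- strsplit(strrep("a", n), "")[[1]]
    groups <- split(chunks, ceiling(seq_along(chunks) / 10))
    sprintf("%9d %s", p, paste(vapply(groups, paste, "", collapse = ""),
                               collapse = " "))
  }, "")
}
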