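#' Derive the extended annotation (EA)
#'
#' The EA holds one merged gene per cluster supported by two or more
#' annotations: the genes that significantly overlap on the same replicon and
#' strand (and in the same frame for CDS). Representative coordinates are
#' taken from the reference member when the cluster has one, otherwise from
#' the member of the first-listed supporting annotation; all member product
#' descriptions are retained, labelled by their annotation method. A merged
#' gene is `functional` if at least one member carries a functional product
#' description, `hypothetical` otherwise; it is flagged pseudo or frameshifted
#' if any member is.
#'
#' @param clusters a `gene_clusters` object from [build_clusters()].
#' @param annotations the same list of [annotation] objects the clusters were
#'   built from (flags are read after any pseudogene propagation).
#' @return an `extended_view` of kind `"EA"`.
#' @examples
#' a <- generate_annotation(10, replicon_length = 40000, seed = 9, label = "A")
#' b <- a; b$label <- "B"
#' derive_ea(build_clusters(list(a, b)), list(a, b))
#' @export
derive_ea <- function(clusters, annotations) {
  stopifnot(inherits(clusters, "gene_clusters"))
  keep <- vapply(clusters$clusters, nrow, 1L) >= 2L
  new_extended_view("EA", clusters$clusters[keep], clusters$labels,
                    annotations)
}

#' Collect genes unique to one annotation
#'
#' One merged gene per singleton cluster, grouped by source annotation (in
#' input order) and carrying that annotation's function description.
#'
#' @inheritParams derive_ea
#' @return an `extended_view` of kind `"unique"`.
#' @export
collect_unique <- function(clusters, annotations) {
  stopifnot(inherits(clusters, "gene_clusters"))
  singles <- clusters$clusters[vapply(clusters$clusters, nrow, 1L) == 1L]
  src <- vapply(singles, function(cl) cl$label[1], "")
  ord <- order(match(src, clusters$labels))
  new_extended_view("unique", singles[ord], clusters$labels, annotations)
}

#' Expand the EA with the unique genes (EUA)
#'
#' Concatenates the EA and the unique lists derived from the same cluster
#' set and sorts by coordinates, so that `|EUA| = |EA| + |unique|` by
#' construction.
#'
#' @param ea the `extended_view` of kind `"EA"`.
#' @param unique_view the `extended_view` of kind `"unique"`.
#' @return an `extended_view` of kind `"EUA"`.
#' @export
derive_eua <- function(ea, unique_view) {
  stopifnot(inherits(ea, "extended_view"), ea$kind == "EA",
            inherits(unique_view, "extended_view"),
            unique_view$kind == "unique")
  keys <- function(v) unlist(lapply(v$genes$member_uids, paste,
                                    collapse = ";"))
  if (length(intersect(keys(ea), keys(unique_view))))
    stop("EA and unique views overlap; they must come from one cluster set")
  genes <- rbind(ea$genes, unique_view$genes)
  genes <- genes[order(genes$replicon_id, genes$start, genes$stop), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  out <- structure(list(kind = "EUA", genes = genes, labels = ea$labels),
                   class = "extended_view")
  out$stats <- extension_stats(out)
  stopifnot(nrow(out$genes) == nrow(ea$genes) + nrow(unique_view$genes))
  out
}

#' Clean form of the EUA
#'
#' Drops every merged gene flagged as pseudogene or frameshifted (including
#' flags acquired through pseudogene propagation); order is preserved and the
#' operation is idempotent.
#'
#' @param eua an `extended_view` of kind `"EUA"` (or `"EUA_clean"`).
#' @return an `extended_view` of kind `"EUA_clean"`.
#' @export
clean_eua <- function(eua) {
  stopifnot(inherits(eua, "extended_view"),
            eua$kind %in% c("EUA", "EUA_clean"))
  genes <- eua$genes[!(eua$genes$is_pseudo | eua$genes$is_frameshifted), ,
                     drop = FALSE]
  rownames(genes) <- NULL
  out <- structure(list(kind = "EUA_clean", genes = genes,
                        labels = eua$labels),
                   class = "extended_view")
  out$stats <- extension_stats(out)
  out
}

# shared constructor: clusters -> merged-gene table
new_extended_view <- function(kind, cluster_list, labels, annotations) {
  ann_by_label <- setNames(annotations,
                           vapply(annotations, function(a) a$label, ""))
  ref_label <- {
    refs <- labels[vapply(ann_by_label[labels], function(a)
      isTRUE(a$is_reference), TRUE)]
    if (length(refs)) refs[1] else NA_character_
  }
  rows <- lapply(cluster_list, function(cl) {
    support <- labels[labels %in% cl$label]     # canonical input order
    cl <- cl[match(support, cl$label), , drop = FALSE]
    members <- lapply(seq_len(nrow(cl)), function(k) {
      a <- ann_by_label[[cl$label[k]]]
      a$genes[match(cl$uid[k], a$genes$uid), , drop = FALSE]
    })
    rep_idx <- if (!is.na(ref_label) && ref_label %in% support)
      match(ref_label, support) else 1L
    rep_gene <- members[[rep_idx]]
    products <- vapply(members, function(m) m$product %||% NA_character_, "")
    categories <- vapply(members, function(m) m$product_category, "")
    data.frame(
      replicon_id = rep_gene$replicon_id, start = rep_gene$start,
      stop = rep_gene$stop, strand = rep_gene$strand,
      feature_type = rep_gene$feature_type,
      locus_tag = rep_gene$locus_tag,
      support = paste(support, collapse = ";"),
      n_support = length(support),
      descriptions = I(list(setNames(products, support))),
      member_uids = I(list(paste(support, cl$uid, sep = ":"))),
      is_pseudo = any(vapply(members, function(m) m$is_pseudo, TRUE)),
      is_frameshifted = any(vapply(members, function(m) m$is_frameshifted,
                                   TRUE)),
      merged_category = if (any(categories == "functional")) "functional"
                        else "hypothetical",
      stringsAsFactors = FALSE)
  })
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon_id = character(0), start = integer(0),
               stop = integer(0), strand = character(0),
               feature_type = character(0), locus_tag = character(0),
               support = character(0), n_support = integer(0),
               descriptions = I(list()), member_uids = I(list()),
               is_pseudo = logical(0), is_frameshifted = logical(0),
               merged_category = character(0), stringsAsFactors = FALSE)
  if (kind == "EA" && nrow(genes)) {
    genes <- genes[order(genes$replicon_id, genes$start, genes$stop), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  out <- structure(list(kind = kind, genes = genes, labels = labels),
                   class = "extended_view")
  out$stats <- extension_stats(out)
  out
}

#' Statistics for an extended view
#'
#' Counts per feature type, total, pseudo/frameshift count, and the
#' orphan/functional split with percentages of the view's total (half-up, two
#' decimals; blank for an empty view). A merged gene counts as functional iff
#' any supporting annotation assigned a functional product.
#'
#' @param view an `extended_view`.
#' @return a named list of counts and percentages.
#' @examples
#' percent_of(672, 3029) # the shape of the orphan percentage
#' @export
extension_stats <- function(view) {
  stopifnot(inherits(view, "extended_view"))
  g <- view$genes
  total <- nrow(g)
  orphan <- sum(g$merged_category == "hypothetical")
  functional <- sum(g$merged_category == "functional")
  list(kind = view$kind,
       cds = sum(g$feature_type == "CDS"),
       rrna = sum(g$feature_type == "rRNA"),
       trna = sum(g$feature_type == "tRNA"),
       ncrna = sum(g$feature_type == "ncRNA"),
       frameshift_pseudo = sum(g$is_pseudo | g$is_frameshifted),
       total = total,
       orphan = orphan,
       orphan_pct = percent_of(orphan, total),
       functional = functional,
       functional_pct = percent_of(functional, total))
}

#' @export
print.extended_view <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<extended_view> %s: %d genes (CDS=%d rRNA=%d tRNA=%d ncRNA=%d)\n",
              x$kind, s$total, s$cds, s$rrna, s$trna, s$ncrna))
  cat(sprintf("  orphan %d (%s), functional %d (%s)\n",
              s$orphan, fmt_pct(s$orphan_pct),
              s$functional, fmt_pct(s$functional_pct)))
  invisible(x)
}

#' Complement one annotation's functions from the others
#'
#' The per-annotation "complemented" view: the annotation's own gene set in
#' which a hypothetical member of a support-\eqn{\ge 2} cluster is re-labelled
#' functional when another cluster member supplies a functional description.
#' Returns the annotation's gene table with a `complemented_category` column
#' plus the resulting orphan/functional counts.
#'
#' @param clusters a `gene_clusters` object.
#' @param annotations the list of [annotation] objects.
#' @param label which annotation to complement.
#' @return list with `genes` (data frame) and `stats` (orphan/functional
#'   counts and percentages).
#' @export
complemented_view <- function(clusters, annotations, label) {
  stopifnot(inherits(clusters, "gene_clusters"),
            label %in% clusters$labels)
  ann <- annotations[[match(label, vapply(annotations,
                                          function(a) a$label, ""))]]
  g <- ann$genes
  cat0 <- ifelse(g$product_category == "functional", "functional",
                 "hypothetical")
  for (cl in clusters$clusters) {
    if (nrow(cl) < 2L || !label %in% cl$label) next
    own <- cl$uid[cl$label == label]
    others <- cl[cl$label != label, , drop = FALSE]
    other_cats <- vapply(seq_len(nrow(others)), function(k) {
      a <- annotations[[match(others$label[k],
                              vapply(annotations, function(x) x$label, ""))]]
      a$genes$product_category[match(others$uid[k], a$genes$uid)]
    }, "")
    if (any(other_cats == "functional"))
      cat0[match(own, g$uid)] <- "functional"
  }
  g$complemented_category <- cat0
  total <- nrow(g)
  orphan <- sum(cat0 == "hypothetical")
  list(genes = g,
       stats = list(label = label, total = total, orphan = orphan,
                    orphan_pct = percent_of(orphan, total),
                    functional = total - orphan,
                    functional_pct = percent_of(total - orphan, total)))
}

#' Write an extended view as a tab-delimited table
#'
#' Columns: replicon, start, stop, strand, type, support labels, one product
#' column per annotation label, and the pseudo/frameshift/category flags —
#' the "extended annotations" output group.
#'
#' @param view an `extended_view`.
#' @param path output path.
#' @return invisibly, the exported data frame.
#' @export
write_extension_table <- function(view, path) {
  g <- view$genes
  tab <- data.frame(replicon = g$replicon_id, start = g$start, stop = g$stop,
                    strand = g$strand, type = g$feature_type,
                    support = g$support, stringsAsFactors = FALSE)
  for (lab in view$labels)
    tab[[paste0("product_", lab)]] <- vapply(g$descriptions, function(d) {
      if (lab %in% names(d) && !is.na(d[[lab]])) d[[lab]] else ""
    }, "")
  tab$pseudo <- g$is_pseudo
  tab$frameshifted <- g$is_frameshifted
  tab$category <- g$merged_category
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
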