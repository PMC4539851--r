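#' Detect overlapping genes within one annotation
#'
#' Reports every unordered pair of genes on the same replicon and strand that
#' shares at least one base pair. A pair is a `significant` overlap when both
#' end deviations are at most `offset` times the shorter gene's length, and a
#' `short` overlap otherwise.
#'
#' @param ann an [annotation].
#' @param offset end-deviation tolerance as a fraction of the shorter gene's
#'   length.
#' @return data frame with columns `uid1`, `uid2`, `kind`.
#' @examples
#' ann <- annotation(data.frame(
#'   replicon_id = "chr", feature_type = "CDS", strand = "+",
#'   start = c(100, 600), stop = c(1099, 1599)), label = "demo")
#' detect_internal_overlaps(ann)
#' @export
detect_internal_overlaps <- function(ann, offset = 0.02) {
  stopifnot(inherits(ann, "annotation"), offset >= 0, offset < 1)
  g <- ann$genes
  out <- list()
  for (rep_id in unique(g$replicon_id)) {
    for (st in c("+", "-")) {
      idx <- which(g$replicon_id == rep_id & g$strand == st)
      if (length(idx) < 2L) next
      ir <- IRanges::IRanges(g$start[idx], g$stop[idx])
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
      if (!length(hits)) next
      i <- idx[S4Vectors::queryHits(hits)]
      j <- idx[S4Vectors::subjectHits(hits)]
      lmin <- pmin(gene_length(g$start[i], g$stop[i]),
                   gene_length(g$start[j], g$stop[j]))
      sig <- abs(g$start[i] - g$start[j]) <= offset * lmin &
             abs(g$stop[i] - g$stop[j]) <= offset * lmin
      out[[length(out) + 1L]] <- data.frame(
        uid1 = g$uid[pmin(i, j)], uid2 = g$uid[pmax(i, j)],
        kind = ifelse(sig, "significant", "short"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(uid1 = character(0), uid2 = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$uid1, res$uid2), , drop = FALSE]
}
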