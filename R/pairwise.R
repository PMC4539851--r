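#' Reading frame of a CDS
#'
#' The frame index in `{0, 1, 2}` is the mod-3 phase of the translation-start
#' end: `start %% 3` on the plus strand, `stop %% 3` on the minus strand. Two
#' CDS are in the same frame iff they are on the same strand with equal frame
#' index. Discontiguous (join) CDS have no single frame and return `NA`; they
#' are excluded from frame checks.
#'
#' @param gene a one-row gene data frame (or list) with `feature_type`,
#'   `strand`, `start`, `stop`, `is_discontiguous`.
#' @return integer frame index, or `NA` for discontiguous CDS.
#' @examples
#' g <- data.frame(feature_type = "CDS", strand = "+", start = 1000,
#'                 stop = 2000, is_discontiguous = FALSE)
#' cds_frame(g)
#' @export
cds_frame <- function(gene) {
  if (!all(gene$feature_type == "CDS"))
    stop("cds_frame is defined for CDS features only")
  frame_vec(gene$strand, gene$start, gene$stop,
            isTRUE(gene$is_discontiguous) | gene$is_discontiguous)
}

frame_vec <- function(strand, start, stop, discontiguous) {
  out <- ifelse(strand == "+", start %% 3L, stop %% 3L)
  out[discontiguous] <- NA_integer_
  as.integer(out)
}

status_levels <- c("identical", "similar", "unique_with_overlap",
                   "unique_without_overlap")

# Vectorised pair classification over parallel rows of a and b.
# Returns status, per-end deviations, shared bp, same_frame and the relative
# frameshift flag (significant in-offset overlap of two CDS in different
# frames).
classify_rows <- function(a, b, offset) {
  n <- nrow(a)
  start_dev <- abs(a$start - b$start)
  stop_dev <- abs(a$stop - b$stop)
  shared <- shared_bp(a$start, a$stop, b$start, b$stop)
  lmin <- pmin(gene_length(a$start, a$stop), gene_length(b$start, b$stop))
  same_strand <- a$strand == b$strand
  overlaps <- shared >= 1L
  same_type <- a$feature_type == b$feature_type
  exact <- start_dev == 0L & stop_dev == 0L
  within_offset <- start_dev <= offset * lmin & stop_dev <= offset * lmin

  both_cds <- a$feature_type == "CDS" & b$feature_type == "CDS"
  fa <- frame_vec(a$strand, a$start, a$stop, a$is_discontiguous)
  fb <- frame_vec(b$strand, b$start, b$stop, b$is_discontiguous)
  # same_frame is defined only for same-strand CDS pairs with both frames known
  same_frame <- rep(NA, n)
  known <- both_cds & same_strand & !is.na(fa) & !is.na(fb)
  same_frame[known] <- fa[known] == fb[known]
  frame_ok <- !both_cds | is.na(same_frame) | same_frame

  status <- rep("unique_without_overlap", n)
  over <- same_strand & overlaps
  status[over] <- "unique_with_overlap"
  status[over & same_type & within_offset & frame_ok] <- "similar"
  status[over & same_type & exact] <- "identical"
  rel_fs <- over & both_cds & within_offset & !is.na(same_frame) & !same_frame

  data.frame(status = status, start_deviation = start_dev,
             stop_deviation = stop_dev, shared_bp = pmax(shared, 0L),
             same_frame = same_frame, relative_frameshift = rel_fs)
}

#' Classify one pair of genes from two annotations
#'
#' Applies the four-way status taxonomy to a single gene pair. Genes on
#' different strands or with no shared base pair are mutually
#' `unique_without_overlap`. Same-strand genes with exactly equal start and
#' stop (and equal feature type) are `identical`. A pair sharing at least one
#' base pair whose start and stop deviations are each at most
#' `offset` times the shorter gene's length (significant overlap) is
#' `similar`, provided both are non-CDS or the two CDS are in the same frame;
#' a significant overlap of CDS in different frames is a relative frameshift
#' and classes as `unique_with_overlap`, as does any other same-strand
#' overlap (short overlap) or a feature-type mismatch.
#'
#' @param a,b one-row gene data frames on the same replicon.
#' @param offset end-deviation tolerance as a fraction of the shorter gene's
#'   length (default 0.02, i.e. 2 percent).
#' @return list with `status`, `start_deviation`, `stop_deviation`,
#'   `shared_bp`, `same_frame`, `relative_frameshift`.
#' @examples
#' g <- function(start, stop, strand = "+", type = "CDS")
#'   data.frame(replicon_id = "chr", feature_type = type, strand = strand,
#'              start = start, stop = stop, is_discontiguous = FALSE)
#' classify_pair(g(1000, 2000), g(1006, 2000))$status  # similar
#' classify_pair(g(1000, 2000), g(1100, 2100))$status  # unique_with_overlap
#' @export
classify_pair <- function(a, b, offset = 0.02) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L, offset >= 0, offset < 1)
  if (a$replicon_id != b$replicon_id)
    stop("classify_pair requires genes on the same replicon")
  if (!"is_discontiguous" %in% names(a)) a$is_discontiguous <- FALSE
  if (!"is_discontiguous" %in% names(b)) b$is_discontiguous <- FALSE
  as.list(classify_rows(a, b, offset))
}

#' Match the genes of two annotations one-to-one
#'
#' Every gene of annotation `x` is compared against the genes of annotation
#' `z` on the same replicon. Candidate pairs (same strand, at least one shared
#' base pair) are classified with [classify_pair()] and greedily matched
#' one-to-one with preference order identical > similar > unique_with_overlap,
#' ties broken by smallest total end deviation, then largest shared bp, then
#' lowest partner coordinates. Genes left unpaired get status
#' `unique_without_overlap`.
#'
#' @param x,z [annotation] objects describing the same genome.
#' @param offset end-deviation tolerance; see [classify_pair()].
#' @return A `match_table` object: `pairs` (matched uid pairs with status,
#'   deviations and frame agreement), `x_status` / `z_status` (named status
#'   vectors covering every gene), and relative-frameshift uid sets.
#' @examples
#' a <- generate_annotation(20, replicon_length = 60000, seed = 2, label = "A")
#' m <- match_genes(a, a)
#' table(m$x_status)
#' @export
match_genes <- function(x, z, offset = 0.02) {
  stopifnot(inherits(x, "annotation"), inherits(z, "annotation"))
  gx <- x$genes
  gz <- z$genes
  shared_rep <- intersect(unique(gx$replicon_id), unique(gz$replicon_id))
  if (nrow(gx) && nrow(gz) && !length(shared_rep))
    stop("annotations share no replicon ids; map replicon names before comparing")

  cand <- candidate_pairs(gx, gz, shared_rep)
  if (nrow(cand)) {
    cls <- classify_rows(gx[cand$ix, , drop = FALSE],
                         gz[cand$iz, , drop = FALSE], offset)
    cand <- cbind(cand, cls)
    cand <- cand[cand$status != "unique_without_overlap", , drop = FALSE]
  } else {
    cand <- cbind(cand, classify_rows(gx[0, ], gz[0, ], offset))
  }

  pairs <- greedy_match(cand, gx, gz)
  x_status <- setNames(rep("unique_without_overlap", nrow(gx)), gx$uid)
  z_status <- setNames(rep("unique_without_overlap", nrow(gz)), gz$uid)
  x_status[pairs$uid_x] <- pairs$status
  z_status[pairs$uid_z] <- pairs$status

  structure(list(
    x_label = x$label, z_label = z$label, offset = offset,
    pairs = pairs, x_status = x_status, z_status = z_status,
    relative_frameshift_x = pairs$uid_x[pairs$relative_frameshift],
    relative_frameshift_z = pairs$uid_z[pairs$relative_frameshift]),
    class = "match_table")
}

# same-strand overlapping index pairs via IRanges
candidate_pairs <- function(gx, gz, shared_rep) {
  out <- list()
  for (rep_id in shared_rep) {
    for (st in c("+", "-")) {
      ix <- which(gx$replicon_id == rep_id & gx$strand == st)
      iz <- which(gz$replicon_id == rep_id & gz$strand == st)
      if (!length(ix) || !length(iz)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(gx$start[ix], gx$stop[ix]),
        IRanges::IRanges(gz$start[iz], gz$stop[iz]))
      if (!length(hits)) next
      out[[length(out) + 1L]] <- data.frame(
        ix = ix[S4Vectors::queryHits(hits)],
        iz = iz[S4Vectors::subjectHits(hits)])
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(ix = integer(0),
                                                       iz = integer(0))
}

greedy_match <- function(cand, gx, gz) {
  empty <- data.frame(uid_x = character(0), uid_z = character(0),
                      status = character(0), start_deviation = integer(0),
                      stop_deviation = integer(0), shared_bp = integer(0),
                      same_frame = logical(0), relative_frameshift = logical(0))
  if (!nrow(cand)) return(empty)
  rank <- match(cand$status, status_levels)
  total_dev <- cand$start_deviation + cand$stop_deviation
  ord <- order(rank, total_dev, -cand$shared_bp,
               gz$start[cand$iz], gx$start[cand$ix],
               gz$uid[cand$iz], gx$uid[cand$ix])
  cand <- cand[ord, , drop = FALSE]
  x_free <- rep(TRUE, nrow(gx))
  z_free <- rep(TRUE, nrow(gz))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (x_free[cand$ix[i]] && z_free[cand$iz[i]]) {
      keep[i] <- TRUE
      x_free[cand$ix[i]] <- FALSE
      z_free[cand$iz[i]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(uid_x = gx$uid[cand$ix], uid_z = gz$uid[cand$iz],
             status = cand$status, start_deviation = cand$start_deviation,
             stop_deviation = cand$stop_deviation, shared_bp = cand$shared_bp,
             same_frame = cand$same_frame,
             relative_frameshift = cand$relative_frameshift,
             stringsAsFactors = FALSE)
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %s vs %s (offset %.3g)\n",
              x$x_label, x$z_label, x$offset))
  cat("  x:", paste(sprintf("%s=%d", status_levels,
                            tabulate(match(x$x_status, status_levels), 4L)),
                    collapse = " "), "\n")
  cat("  z:", paste(sprintf("%s=%d", status_levels,
                            tabulate(match(x$z_status, status_levels), 4L)),
                    collapse = " "), "\n")
  invisible(x)
}

#' Propagate pseudogene flags across matched annotations
#'
#' For every identical or similar pair in which exactly one member is flagged
#' as a pseudogene, the flag is copied to the other member. The operation is
#' idempotent and never clears a flag; pairs with only a short overlap are
#' untouched.
#'
#' @param table a `match_table` from [match_genes()].
#' @param x,z the two annotations the table was computed from.
#' @return list with updated `x` and `z` annotations.
#' @export
propagate_pseudo <- function(table, x, z) {
  stopifnot(inherits(table, "match_table"))
  p <- table$pairs[table$pairs$status %in% c("identical", "similar"), ,
                   drop = FALSE]
  if (nrow(p)) {
    px <- x$genes$is_pseudo[match(p$uid_x, x$genes$uid)]
    pz <- z$genes$is_pseudo[match(p$uid_z, z$genes$uid)]
    both <- px | pz
    x$genes$is_pseudo[match(p$uid_x, x$genes$uid)] <- both
    z$genes$is_pseudo[match(p$uid_z, z$genes$uid)] <- both
  }
  list(x = x, z = z)
}
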