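# Synthetic ground-truth annotations and AM-like perturbed variants.
# These emulate the disagreements real annotation methods show on one genome
# (end shifts, frame-breaking start shifts, missed and extra genes,
# pseudogene calls) with a truth log, so the matcher can be scored against a
# known answer without any external data.

functional_vocabulary <- c(
  "DNA polymerase III subunit alpha", "ATP synthase subunit beta",
  "elongation factor Tu", "50S ribosomal protein L2",
  "DNA gyrase subunit B", "chaperonin GroEL",
  "ABC transporter ATP-binding protein", "RNA polymerase sigma factor",
  "citrate synthase", "aminopeptidase N")

# run code with a private RNG stream; the global .Random.seed is untouched
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic annotation
#'
#' Places `n_genes` non-overlapping genes on one circularised replicon,
#' mixing CDS (multiple-of-3 lengths between 300 and 1500 bp), tRNA, rRNA and
#' ncRNA on both strands, with a configurable fraction of hypothetical
#' products. Genes are separated by at least `min_gap` bp so that perturbed
#' variants remain unambiguous. Output is a deterministic function of `seed`.
#'
#' @param n_genes number of genes (>= 0).
#' @param replicon_length replicon size in bp; generation fails when the
#'   genes cannot be packed with the requested gap.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param label annotation label.
#' @param genome_name genome short name.
#' @param replicon_id LOCUS name.
#' @param min_gap minimum intergenic gap in bp.
#' @param hypothetical_fraction fraction of CDS with a hypothetical product.
#' @param cds_fraction fraction of genes that are CDS (the remainder is split
#'   across the three RNA types).
#' @return an [annotation].
#' @examples
#' generate_annotation(10, replicon_length = 40000, seed = 1)
#' @export
generate_annotation <- function(n_genes, replicon_length = 100000L, seed = 1L,
                                label = "truth", genome_name = "synthetic",
                                replicon_id = "chr1", min_gap = 150L,
                                hypothetical_fraction = 0.3,
                                cds_fraction = 0.85) {
  stopifnot(n_genes >= 0, replicon_length >= 1, min_gap >= 0,
            hypothetical_fraction >= 0, hypothetical_fraction <= 1)
  if (n_genes == 0L)
    return(annotation(
      data.frame(replicon_id = character(0), feature_type = character(0),
                 strand = character(0), start = integer(0),
                 stop = integer(0)),
      label = label, genome_name = genome_name,
      replicon_lengths = setNames(as.integer(replicon_length), replicon_id)))

  with_seed(seed, {
    types <- sample(c("CDS", "tRNA", "rRNA", "ncRNA"), n_genes, replace = TRUE,
                    prob = c(cds_fraction, (1 - cds_fraction) * 0.6,
                             (1 - cds_fraction) * 0.2,
                             (1 - cds_fraction) * 0.2))
    lens <- vapply(types, function(t) switch(t,
      CDS = 3L * sample(100:500, 1L),
      tRNA = sample(72:90, 1L),
      rRNA = sample(1500:2900, 1L),
      ncRNA = sample(100:400, 1L)), 1L)
    need <- sum(lens) + (n_genes + 1L) * min_gap
    if (need > replicon_length)
      stop(sprintf("cannot pack %d genes (%d bp incl. gaps) into %d bp",
                   n_genes, need, replicon_length))
    slack <- replicon_length - need
    extra <- if (slack > 0)
      as.integer(stats::rmultinom(1, slack, rep(1, n_genes + 1L))) else
      rep(0L, n_genes + 1L)
    gaps <- min_gap + extra
    starts <- integer(n_genes)
    pos <- 1L
    for (i in seq_len(n_genes)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    is_cds <- types == "CDS"
    hypo <- is_cds & stats::runif(n_genes) < hypothetical_fraction
    products <- rep(NA_character_, n_genes)
    products[is_cds & !hypo] <- sample(functional_vocabulary,
                                       sum(is_cds & !hypo), replace = TRUE)
    products[hypo] <- "hypothetical protein"
    products[!is_cds] <- paste(types[!is_cds], "gene product")
    symbols <- rep(NA_character_, n_genes)
    with_sym <- which(is_cds & !hypo & stats::runif(n_genes) < 0.6)
    symbols[with_sym] <- sprintf("gen%s", LETTERS[(seq_along(with_sym) %% 26) + 1L])

    annotation(
      data.frame(replicon_id = replicon_id, feature_type = types,
                 strand = strands, start = starts,
                 stop = starts + lens - 1L,
                 locus_tag = sprintf("SYN_%04d", seq_len(n_genes)),
                 gene_symbol = symbols, product = products,
                 stringsAsFactors = FALSE),
      label = label, genome_name = genome_name,
      replicon_lengths = setNames(as.integer(replicon_length), replicon_id))
  })
}

#' Specify a perturbation of a synthetic annotation
#'
#' Describes how an AM-like variant differs from the ground truth. Fractions
#' apply to eligible genes and the assignments are disjoint, so each variant
#' gene has exactly one intended match status: end shifts within the offset
#' give `similar`, shifts beyond it give `unique_with_overlap`, frame-breaking
#' 1-2 bp CDS start shifts give `unique_with_overlap` plus a relative
#' frameshift, dropped truth genes become reference-unique, and inserted
#' genes become query-unique.
#'
#' @param seed integer seed for the perturbation draw.
#' @param end_shift_fraction fraction of genes given an in-offset end shift.
#' @param beyond_offset_fraction fraction given a shift beyond the offset.
#' @param frameshift_fraction fraction of CDS given a frame-breaking shift.
#' @param drop_fraction fraction of truth genes removed from the variant.
#' @param insert_count number of extra genes inserted into free gaps.
#' @param pseudo_fraction fraction of otherwise untouched variant genes
#'   flagged as pseudogenes.
#' @param hypothetical_fraction fraction of variant CDS whose product is
#'   rewritten as hypothetical.
#' @param offset the comparison offset the shifts are calibrated against.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(seed = 1L, end_shift_fraction = 0,
                              beyond_offset_fraction = 0,
                              frameshift_fraction = 0, drop_fraction = 0,
                              insert_count = 0L, pseudo_fraction = 0,
                              hypothetical_fraction = 0, offset = 0.02) {
  fracs <- c(end_shift_fraction, beyond_offset_fraction, frameshift_fraction,
             drop_fraction, pseudo_fraction, hypothetical_fraction)
  stopifnot(all(fracs >= 0), all(fracs <= 1), insert_count >= 0,
            offset >= 0, offset < 1)
  structure(list(seed = seed, end_shift_fraction = end_shift_fraction,
                 beyond_offset_fraction = beyond_offset_fraction,
                 frameshift_fraction = frameshift_fraction,
                 drop_fraction = drop_fraction,
                 insert_count = as.integer(insert_count),
                 pseudo_fraction = pseudo_fraction,
                 hypothetical_fraction = hypothetical_fraction,
                 offset = offset),
            class = "perturbation_spec")
}

#' Perturb a synthetic annotation into an AM-like variant
#'
#' Applies a [perturbation_spec()] to a ground-truth annotation and returns
#' the variant together with a truth log recording, for every truth and
#' variant gene, the intended [match_genes()] status. All shifts move gene
#' ends inward (shrinking the gene), so perturbed genes never collide with
#' their neighbours and the intended status is unambiguous.
#'
#' @param ann the ground-truth [annotation].
#' @param spec a `perturbation_spec`.
#' @param label label for the variant annotation.
#' @return list with `variant` (an [annotation]) and `truth_log` (data frame
#'   with columns `source_uid`, `variant_uid`, `intended_status`,
#'   `relative_frameshift`).
#' @examples
#' truth <- generate_annotation(20, replicon_length = 80000, seed = 11)
#' out <- perturb_annotation(truth, perturbation_spec(
#'   seed = 2, end_shift_fraction = 0.2, drop_fraction = 0.1), label = "AM1")
#' table(out$truth_log$intended_status)
#' @export
perturb_annotation <- function(ann, spec, label = "variant") {
  stopifnot(inherits(ann, "annotation"), inherits(spec, "perturbation_spec"))
  g <- ann$genes
  n <- nrow(g)
  offset <- spec$offset

  with_seed(spec$seed, {
    pool <- sample(n)   # random disjoint assignment of perturbation roles
    take <- function(k) {
      k <- min(k, length(pool))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    idx_drop <- take(round(spec$drop_fraction * n))
    idx_shift <- take(round(spec$end_shift_fraction * n))
    cds_pool <- pool[g$feature_type[pool] == "CDS"]
    idx_frame <- head(cds_pool, round(spec$frameshift_fraction * n))
    pool <- setdiff(pool, idx_frame)
    idx_beyond <- take(round(spec$beyond_offset_fraction * n))

    v <- g
    status <- rep("identical", n)
    rel_fs <- rep(FALSE, n)

    for (i in idx_shift) {           # in-offset shift -> similar
      len <- gene_length(v$start[i], v$stop[i])
      if (v$feature_type[i] == "CDS") {
        dmax <- floor(offset * len / (1 + offset))
        d <- 3L * max(1L, sample(seq_len(max(1L, dmax %/% 3L)), 1L))
        if (d > dmax) d <- 3L
      } else {
        d <- max(1L, min(floor(offset * (len - 1L)), sample(1:3, 1L)))
      }
      v$start[i] <- v$start[i] + d
      v$segments[[i]] <- cbind(start = v$start[i], stop = v$stop[i])
      status[i] <- "similar"
    }
    for (i in idx_beyond) {          # beyond-offset shift -> short overlap
      len <- gene_length(v$start[i], v$stop[i])
      d <- ceiling(offset * len) + 30L
      d <- d + (3L - d %% 3L) %% 3L  # keep the frame: status is about ends
      if (d >= len) d <- len - 1L
      v$start[i] <- v$start[i] + d
      v$segments[[i]] <- cbind(start = v$start[i], stop = v$stop[i])
      status[i] <- "unique_with_overlap"
    }
    for (i in idx_frame) {           # small frame-breaking shift
      len <- gene_length(v$start[i], v$stop[i])
      # shift the translation-start end by 1 bp (within the offset for any
      # CDS of >= 300 bp at the default 2 % offset)
      if (v$strand[i] == "+") v$start[i] <- v$start[i] + 1L
      else v$stop[i] <- v$stop[i] - 1L
      v$segments[[i]] <- cbind(start = v$start[i], stop = v$stop[i])
      status[i] <- "unique_with_overlap"
      rel_fs[i] <- TRUE
      stopifnot(1 <= offset * (len - 1L))
    }
    keep <- setdiff(seq_len(n), idx_drop)
    v <- v[keep, , drop = FALSE]
    src_uid <- g$uid[keep]
    rel_fs_v <- rel_fs[keep]
    status_v <- status[keep]

    # extra genes inserted into gaps that no truth gene touches
    if (spec$insert_count > 0L) {
      len_rep <- unname(ann$replicon_lengths[1]) %||% (max(g$stop) + 5000L)
      ins <- place_inserts(g, spec$insert_count, len_rep)
      if (nrow(ins)) {
        ins_rows <- data.frame(
          uid = NA_character_,
          replicon_id = if (n) g$replicon_id[1] else "chr1",
          feature_type = "CDS", strand = ins$strand, start = ins$start,
          stop = ins$stop, locus_tag = NA_character_,
          gene_symbol = NA_character_,
          product = "hypothetical protein", note = NA_character_,
          is_pseudo = FALSE, is_frameshifted = FALSE,
          stringsAsFactors = FALSE)
        ins_rows$segments <- lapply(seq_len(nrow(ins)), function(k)
          cbind(start = ins$start[k], stop = ins$stop[k]))
        ins_rows$is_discontiguous <- FALSE
        ins_rows$product_category <- "hypothetical"
        v <- rbind(v, ins_rows[names(v)])
        src_uid <- c(src_uid, rep(NA_character_, nrow(ins)))
        rel_fs_v <- c(rel_fs_v, rep(FALSE, nrow(ins)))
        status_v <- c(status_v, rep("unique_without_overlap", nrow(ins)))
      }
    }

    ord <- order(v$start)
    v <- v[ord, , drop = FALSE]
    src_uid <- src_uid[ord]
    rel_fs_v <- rel_fs_v[ord]
    status_v <- status_v[ord]

    untouched <- which(status_v == "identical")
    idx_pseudo <- untouched[stats::runif(length(untouched)) <
                              spec$pseudo_fraction]
    v$is_pseudo[idx_pseudo] <- TRUE
    cds_v <- which(v$feature_type == "CDS" & !is.na(src_uid))
    idx_hypo <- cds_v[stats::runif(length(cds_v)) < spec$hypothetical_fraction]
    if (length(idx_hypo)) {
      v$product[idx_hypo] <- "hypothetical protein"
      v$product_category[idx_hypo] <- "hypothetical"
    }

    v$uid <- NULL
    variant <- annotation(v, label = label, genome_name = ann$genome_name,
                          replicon_lengths = ann$replicon_lengths)

    truth_log <- rbind(
      data.frame(source_uid = src_uid, variant_uid = variant$genes$uid,
                 intended_status = status_v, relative_frameshift = rel_fs_v,
                 stringsAsFactors = FALSE),
      if (length(idx_drop))
        data.frame(source_uid = g$uid[idx_drop], variant_uid = NA_character_,
                   intended_status = "unique_without_overlap",
                   relative_frameshift = FALSE, stringsAsFactors = FALSE))
    list(variant = variant, truth_log = truth_log)
  })
}

# non-overlapping insert positions in gaps >= 2*margin + length
place_inserts <- function(g, count, replicon_length, margin = 40L) {
  occ <- g[order(g$start), , drop = FALSE]
  gaps <- data.frame(from = c(1L, occ$stop + 1L),
                     to = c(occ$start - 1L, replicon_length))
  gaps <- gaps[gaps$to - gaps$from + 1L >= 300L + 2L * margin, , drop = FALSE]
  out <- data.frame(start = integer(0), stop = integer(0),
                    strand = character(0))
  for (k in seq_len(min(count, nrow(gaps)))) {
    from <- gaps$from[k] + margin
    to <- min(gaps$to[k] - margin, from + 299L)
    if (to - from + 1L < 150L) next
    out <- rbind(out, data.frame(start = from, stop = to,
                                 strand = sample(c("+", "-"), 1L),
                                 stringsAsFactors = FALSE))
  }
  out
}
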