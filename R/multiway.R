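#' All-against-all similarity matrix
#'
#' Runs [match_genes()] on every pair of annotations and fills a symmetric
#' matrix of similarity scores; the diagonal is 100 by definition
#' (self-comparison).
#'
#' @param annotations list of two or more [annotation] objects with unique
#'   labels.
#' @param offset end-deviation tolerance; see [classify_pair()].
#' @return numeric matrix with annotation labels as dimnames.
#' @examples
#' a <- generate_annotation(15, replicon_length = 50000, seed = 5, label = "A")
#' b <- a; b$label <- "B"
#' pairwise_matrix(list(a, b))
#' @export
pairwise_matrix <- function(annotations, offset = 0.02) {
  check_annotation_list(annotations)
  labels <- vapply(annotations, function(a) a$label, "")
  n <- length(annotations)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tab <- match_genes(annotations[[i]], annotations[[j]], offset)
      s <- similarity_score(sum(tab$pairs$status == "identical"),
                            sum(tab$pairs$status == "similar"),
                            nrow(annotations[[i]]$genes),
                            nrow(annotations[[j]]$genes))
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

check_annotation_list <- function(annotations) {
  stopifnot(is.list(annotations), length(annotations) >= 2L)
  if (!all(vapply(annotations, inherits, TRUE, "annotation")))
    stop("annotations must be a list of annotation objects")
  labels <- vapply(annotations, function(a) a$label, "")
  if (anyDuplicated(labels))
    stop("annotation labels must be unique: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  invisible(labels)
}

#' Cluster genes across multiple annotations
#'
#' Builds gene clusters from the pairwise identical/similar matches of all
#' annotation pairs under the clique rule: a gene joins a cluster only if it
#' is matched (identical or similar) with every current member from the other
#' annotations, and each cluster holds at most one gene per annotation.
#' Clusters are seeded greedily in input-annotation order and extended through
#' later annotations; genes absorbed by no multi-annotation cluster become
#' singleton (`unique`) clusters. The result is deterministic given the input
#' order and the [match_genes()] tie-breaks.
#'
#' @param annotations list of two or more [annotation] objects.
#' @param offset end-deviation tolerance; see [classify_pair()].
#' @param tables optional precomputed list of `match_table`s named
#'   `"i|j"` for annotation indices `i < j` (computed when `NULL`).
#' @return a `gene_clusters` object: a list of clusters, each a data frame
#'   with columns `label` and `uid`, plus the label vector.
#' @examples
#' a <- generate_annotation(10, replicon_length = 40000, seed = 6, label = "A")
#' b <- a; b$label <- "B"
#' cl <- build_clusters(list(a, b))
#' table(vapply(cl$clusters, nrow, 1L))
#' @export
build_clusters <- function(annotations, offset = 0.02, tables = NULL) {
  labels <- check_annotation_list(annotations)
  n <- length(annotations)
  if (is.null(tables)) tables <- pair_tables(annotations, offset)

  # edges[[i]][[j]]: named uid map (annotation i gene -> annotation j gene)
  # restricted to identical/similar matches; one-to-one by construction
  edges <- vector("list", n)
  for (i in seq_len(n)) edges[[i]] <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- tables[[pair_key(i, j)]]$pairs
      p <- p[p$status %in% c("identical", "similar"), , drop = FALSE]
      edges[[i]][[j]] <- setNames(p$uid_z, p$uid_x)
      edges[[j]][[i]] <- setNames(p$uid_x, p$uid_z)
    }
  }

  assigned <- lapply(annotations, function(a)
    setNames(rep(FALSE, nrow(a$genes)), a$genes$uid))
  clusters <- list()
  for (i in seq_len(n)) {
    for (uid in annotations[[i]]$genes$uid) {
      if (assigned[[i]][[uid]]) next
      member_ann <- i
      member_uid <- uid
      if (i < n) {
        for (j in seq(i + 1, n)) {
          # clique rule: every current member must map to the same gene of j
          cand <- vapply(seq_along(member_ann), function(k) {
            map <- edges[[member_ann[k]]][[j]]
            unname(map[member_uid[k]]) %||% NA_character_
          }, "")
          if (anyNA(cand) || length(unique(cand)) != 1L) next
          if (assigned[[j]][[cand[1]]]) next
          member_ann <- c(member_ann, j)
          member_uid <- c(member_uid, cand[1])
        }
      }
      for (k in seq_along(member_ann))
        assigned[[member_ann[k]]][[member_uid[k]]] <- TRUE
      clusters[[length(clusters) + 1L]] <- data.frame(
        label = labels[member_ann], uid = member_uid,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(clusters = clusters, labels = labels, offset = offset),
            class = "gene_clusters")
}

pair_key <- function(i, j) paste(i, j, sep = "|")

# all pairwise match tables, keyed "i|j" with i < j
pair_tables <- function(annotations, offset) {
  n <- length(annotations)
  tables <- list()
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      tables[[pair_key(i, j)]] <-
        match_genes(annotations[[i]], annotations[[j]], offset)
  tables
}

#' @export
print.gene_clusters <- function(x, ...) {
  sizes <- vapply(x$clusters, nrow, 1L)
  cat(sprintf("<gene_clusters> %d clusters over %s\n",
              length(x$clusters), paste(x$labels, collapse = ", ")))
  cat(sprintf("  common (support >= 2): %d; unique: %d\n",
              sum(sizes >= 2L), sum(sizes == 1L)))
  invisible(x)
}

#' Venn-style intersection counts
#'
#' Counts clusters per support set: each cluster increments exactly the
#' region equal to the set of annotation labels it contains. All non-empty
#' label subsets are reported (zeroes included), in order of subset size then
#' input-annotation order — the textual equivalent of the Venn diagram.
#'
#' @param clusters a `gene_clusters` object from [build_clusters()].
#' @return a `venn_counts` data frame with columns `region` (labels joined by
#'   `&`) and `count`.
#' @examples
#' a <- generate_annotation(10, replicon_length = 40000, seed = 8, label = "A")
#' b <- a; b$label <- "B"
#' intersection_counts(build_clusters(list(a, b)))
#' @export
intersection_counts <- function(clusters) {
  stopifnot(inherits(clusters, "gene_clusters"))
  labels <- clusters$labels
  subsets <- all_subsets(labels)
  keys <- vapply(subsets, paste, "", collapse = "&")
  counts <- setNames(rep(0L, length(keys)), keys)
  for (cl in clusters$clusters) {
    support <- labels[labels %in% cl$label]   # canonical label order
    key <- paste(support, collapse = "&")
    counts[key] <- counts[key] + 1L
  }
  structure(data.frame(region = keys, count = as.integer(counts),
                       stringsAsFactors = FALSE),
            class = c("venn_counts", "data.frame"))
}

all_subsets <- function(labels) {
  n <- length(labels)
  out <- list()
  for (size in seq_len(n)) {
    combos <- utils::combn(labels, size, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("<venn_counts>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
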