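relabel <- function(ann, label) {
  ann$label <- label
  ann$genes$uid <- sprintf("%s_%05d", label, seq_len(nrow(ann$genes)))
  ann
}

test_that("identical annotations cluster with full support", {
  a <- generate_annotation(15, replicon_length = 60000L, seed = 31,
                           label = "A")
  anns <- list(a, relabel(a, "B"), relabel(a, "C"))
  cl <- build_clusters(anns)
  expect_equal(length(cl$clusters), 15L)
  expect_true(all(vapply(cl$clusters, nrow, 1L) == 3L))
})

test_that("chained matches do not merge unrelated genes", {
  # A shares g1 with B; B shares g2 with C; g1 and g2 are unrelated
  a <- annotation(gene_df(c(1000, 50000), c(1999, 50999)), label = "A")
  b <- annotation(gene_df(c(1000, 30000), c(1999, 30999)), label = "B")
  cc <- annotation(gene_df(c(30000, 70000), c(30999, 70999)), label = "C")
  cl <- build_clusters(list(a, b, cc))
  sig <- cluster_signature(cl$clusters)
  expect_equal(length(cl$clusters), 4L)
  expect_true(paste("A:A_00001", "B:B_00001", sep = ",") %in% sig)
  expect_true(paste("B:B_00002", "C:C_00001", sep = ",") %in% sig)
  expect_true("A:A_00002" %in% sig)
  expect_true("C:C_00002" %in% sig)
})

test_that("clustering agrees with brute-force clique enumeration", {
  for (seed in 1:10) {
    anns <- list(
      random_annotation(30, seed = seed, label = "A"),
      random_annotation(30, seed = seed + 100, label = "B"),
      random_annotation(30, seed = seed + 200, label = "C"))
    got <- build_clusters(anns, offset = 0.05)
    want <- oracle_clusters(anns, offset = 0.05)
    expect_equal(cluster_signature(got$clusters), cluster_signature(want))
  }
})

test_that("cluster sizes conserve the pooled gene count", {
  anns <- list(
    random_annotation(40, seed = 41, label = "A"),
    random_annotation(35, seed = 42, label = "B"),
    random_annotation(30, seed = 43, label = "C"))
  cl <- build_clusters(anns)
  expect_equal(sum(vapply(cl$clusters, nrow, 1L)),
               sum(vapply(anns, function(a) nrow(a$genes), 1L)))
  # every gene appears in exactly one cluster
  keys <- unlist(lapply(cl$clusters, function(x)
    paste(x$label, x$uid, sep = ":")))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("clustering is invariant under annotation relabeling", {
  anns <- list(random_annotation(25, seed = 51, label = "A"),
               random_annotation(25, seed = 52, label = "B"))
  renamed <- list(relabel(anns[[1]], "X1"), relabel(anns[[2]], "X2"))
  sig1 <- cluster_signature(build_clusters(anns)$clusters)
  sig2 <- cluster_signature(build_clusters(renamed)$clusters)
  expect_equal(gsub("X1", "A", gsub("X2", "B", sig2)), sig1)
})

test_that("venn regions count clusters by support set", {
  a <- generate_annotation(12, replicon_length = 50000L, seed = 61,
                           label = "A")
  b <- relabel(a, "B")
  cl <- build_clusters(list(a, b))
  vc <- intersection_counts(cl)
  expect_equal(vc$count[vc$region == "A&B"], 12L)
  expect_equal(vc$count[vc$region == "A"], 0L)
  expect_equal(vc$count[vc$region == "B"], 0L)
})

test_that("a constructed 7-region design yields exact venn counts", {
  # seven disjoint loci; each locus is annotated by one label subset
  loci <- data.frame(start = seq(1000, 61000, by = 10000))
  loci$stop <- loci$start + 899
  subsets <- list("A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"),
                  c("A", "B", "C"))
  mk <- function(lab) {
    idx <- which(vapply(subsets, function(s) lab %in% s, TRUE))
    annotation(gene_df(loci$start[idx], loci$stop[idx]), label = lab)
  }
  anns <- list(mk("A"), mk("B"), mk("C"))
  vc <- intersection_counts(build_clusters(anns))
  expect_equal(nrow(vc), 7L)
  expect_true(all(vc$count == 1L))
  # per-label totals equal each annotation's cluster membership count
  for (lab in c("A", "B", "C")) {
    in_region <- vapply(vc$region, function(r)
      lab %in% strsplit(r, "&", fixed = TRUE)[[1]], TRUE)
    expect_equal(sum(vc$count[in_region]), 4L)
  }
})

test_that("the similarity matrix is symmetric with a 100 diagonal", {
  truth <- generate_annotation(25, replicon_length = 100000L, seed = 71,
                               label = "REF")
  v1 <- perturb_annotation(truth, perturbation_spec(
    seed = 1, end_shift_fraction = 0.2), label = "AM1")$variant
  v2 <- perturb_annotation(truth, perturbation_spec(
    seed = 2, drop_fraction = 0.2), label = "AM2")$variant
  anns <- list(truth, v1, v2)
  m <- pairwise_matrix(anns)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 100))
  # compositional consistency with an independent pairwise run
  tab <- match_genes(truth, v2)
  s <- similarity_score(sum(tab$pairs$status == "identical"),
                        sum(tab$pairs$status == "similar"),
                        nrow(truth$genes), nrow(v2$genes))
  expect_equal(m["REF", "AM2"], s)
  # two identical annotations score 100 off-diagonal
  m2 <- pairwise_matrix(list(truth, relabel(truth, "COPY")))
  expect_equal(m2["REF", "COPY"], 100.00)
})
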