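# two annotations agreeing on two genes (one with a functional description on
# one side only), plus one unique gene each
ext_fixture <- function() {
  a <- annotation(gene_df(
    start = c(1000, 5000, 9000), stop = c(1999, 5999, 9999),
    product = c("hypothetical protein", "DNA gyrase subunit B",
                "hypothetical protein"),
    locus_tag = c("A1", "A2", "A3")), label = "A")
  b <- annotation(gene_df(
    start = c(1000, 5000, 20000), stop = c(1999, 5999, 20999),
    product = c("gyrase subunit B", "hypothetical protein",
                "citrate synthase"),
    locus_tag = c("B1", "B2", "B3")), label = "B")
  list(anns = list(a, b), clusters = build_clusters(list(a, b)))
}

test_that("the EA keeps support>=2 clusters with all member descriptions", {
  fx <- ext_fixture()
  ea <- derive_ea(fx$clusters, fx$anns)
  expect_equal(ea$kind, "EA")
  expect_equal(nrow(ea$genes), 2L)
  # gene 1: hypothetical in A, functional in B -> functional, both listed
  d <- ea$genes$descriptions[[1]]
  expect_equal(names(d), c("A", "B"))
  expect_equal(unname(d["A"]), "hypothetical protein")
  expect_equal(unname(d["B"]), "gyrase subunit B")
  expect_equal(ea$genes$merged_category, c("functional", "functional"))
  expect_equal(ea$genes$support, c("A;B", "A;B"))
})

test_that("EA representative coordinates honour the reference", {
  a <- annotation(gene_df(1000, 1999), label = "A")
  b <- annotation(gene_df(1006, 1999), label = "B", is_reference = TRUE)
  cl <- build_clusters(list(a, b))
  ea_ref <- derive_ea(cl, list(a, b))
  expect_equal(ea_ref$genes$start, 1006L)     # reference member wins
  b$is_reference <- FALSE
  ea_first <- derive_ea(cl, list(a, b))
  expect_equal(ea_first$genes$start, 1000L)   # else first-listed annotation
})

test_that("unique lists hold singleton clusters grouped by source", {
  fx <- ext_fixture()
  uq <- collect_unique(fx$clusters, fx$anns)
  expect_equal(nrow(uq$genes), 2L)
  expect_equal(uq$genes$support, c("A", "B"))
  # identical annotations leave no unique genes
  a <- generate_annotation(10, replicon_length = 40000L, seed = 81,
                           label = "A")
  b <- a; b$label <- "B"
  b$genes$uid <- sub("^A", "B", b$genes$uid)
  cl <- build_clusters(list(a, b))
  expect_equal(nrow(collect_unique(cl, list(a, b))$genes), 0L)
})

test_that("EUA is the sorted concatenation of EA and unique", {
  fx <- ext_fixture()
  ea <- derive_ea(fx$clusters, fx$anns)
  uq <- collect_unique(fx$clusters, fx$anns)
  eua <- derive_eua(ea, uq)
  expect_equal(nrow(eua$genes), nrow(ea$genes) + nrow(uq$genes))
  expect_false(is.unsorted(eua$genes$start))
  # empty unique -> EUA = EA
  a <- generate_annotation(8, replicon_length = 30000L, seed = 82,
                           label = "A")
  b <- a; b$label <- "B"
  b$genes$uid <- sub("^A", "B", b$genes$uid)
  cl <- build_clusters(list(a, b))
  ea2 <- derive_ea(cl, list(a, b))
  uq2 <- collect_unique(cl, list(a, b))
  eua2 <- derive_eua(ea2, uq2)
  expect_equal(eua2$genes$start, ea2$genes$start)
  # no common genes -> EUA holds every gene with support 1
  c1 <- annotation(gene_df(1000, 1999), label = "A")
  c2 <- annotation(gene_df(9000, 9999), label = "B")
  cl3 <- build_clusters(list(c1, c2))
  eua3 <- derive_eua(derive_ea(cl3, list(c1, c2)),
                     collect_unique(cl3, list(c1, c2)))
  expect_equal(nrow(eua3$genes), 2L)
  expect_true(all(eua3$genes$n_support == 1L))
})

test_that("the clean EUA drops pseudo and frameshifted genes, idempotently", {
  a <- annotation(gene_df(
    start = c(1000, 5000, 9000), stop = c(1999, 5999, 9999),
    is_pseudo = c(TRUE, FALSE, FALSE)), label = "A")
  b <- annotation(gene_df(
    start = c(1000, 5000, 9000), stop = c(1999, 5999, 9999),
    is_frameshifted = c(FALSE, TRUE, FALSE)), label = "B")
  cl <- build_clusters(list(a, b))
  ea <- derive_ea(cl, list(a, b))
  eua <- derive_eua(ea, collect_unique(cl, list(a, b)))
  clean <- clean_eua(eua)
  expect_equal(clean$kind, "EUA_clean")
  expect_equal(nrow(clean$genes), 1L)
  expect_equal(clean$genes$start, 9000L)
  expect_equal(clean_eua(clean)$genes, clean$genes)
})

test_that("pseudo flags propagated from another AM are cleaned too", {
  # pseudo call only in A; B's member must leave EUA_clean after propagation
  a <- annotation(gene_df(c(1000, 5000), c(1999, 5999),
                          is_pseudo = c(TRUE, FALSE)), label = "A")
  b <- annotation(gene_df(c(1006, 5000), c(1999, 5999)), label = "B")
  m <- match_genes(a, b)
  upd <- propagate_pseudo(m, a, b)
  anns <- list(upd$x, upd$z)
  cl <- build_clusters(anns)
  eua <- derive_eua(derive_ea(cl, anns), collect_unique(cl, anns))
  expect_true(eua$genes$is_pseudo[eua$genes$start == 1000])
  clean <- clean_eua(eua)
  expect_equal(nrow(clean$genes), 1L)
  expect_equal(clean$genes$start, 5000L)
})

test_that("extension statistics split orphan and functional genes", {
  fx <- ext_fixture()
  ea <- derive_ea(fx$clusters, fx$anns)
  s <- extension_stats(ea)
  expect_equal(s$total, 2L)
  expect_equal(s$orphan + s$functional, s$total)
  expect_equal(s$orphan_pct + s$functional_pct, 100.00)
  # all-functional view
  expect_equal(s$orphan, 0L)
  expect_equal(s$orphan_pct, 0.00)
  # empty view: counts 0, percentages undefined
  c1 <- annotation(gene_df(1000, 1999), label = "A")
  c2 <- annotation(gene_df(9000, 9999), label = "B")
  ea0 <- derive_ea(build_clusters(list(c1, c2)), list(c1, c2))
  s0 <- extension_stats(ea0)
  expect_equal(s0$total, 0L)
  expect_true(is.na(s0$orphan_pct))
})

test_that("EA functional count dominates any single member annotation", {
  for (seed in 1:5) {
    truth <- generate_annotation(40, replicon_length = 150000L, seed = seed,
                                 label = "T", hypothetical_fraction = 0.4)
    v <- perturb_annotation(truth, perturbation_spec(
      seed = seed, end_shift_fraction = 0.2, hypothetical_fraction = 0.4),
      label = "V")$variant
    anns <- list(truth, v)
    cl <- build_clusters(anns)
    ea <- derive_ea(cl, anns)
    in_ea <- unlist(lapply(ea$genes$member_uids, identity))
    per_member <- vapply(anns, function(a) {
      uids <- sub("^[^:]+:", "", in_ea[startsWith(in_ea, paste0(a$label, ":"))])
      sum(a$genes$product_category[match(uids, a$genes$uid)] == "functional")
    }, 1L)
    expect_gte(ea$stats$functional, max(per_member))
  }
})

test_that("complemented views relabel orphans with borrowed functions", {
  fx <- ext_fixture()
  cv <- complemented_view(fx$clusters, fx$anns, "A")
  g <- cv$genes
  # A's first gene is hypothetical but B supplies a functional description
  expect_equal(g$complemented_category[g$start == 1000], "functional")
  # A's third gene is unique, stays hypothetical
  expect_equal(g$complemented_category[g$start == 9000], "hypothetical")
  expect_equal(cv$stats$orphan + cv$stats$functional, cv$stats$total)
  expect_lte(cv$stats$orphan,
             sum(fx$anns[[1]]$genes$product_category != "functional"))
})

test_that("extension tables export one product column per label", {
  fx <- ext_fixture()
  ea <- derive_ea(fx$clusters, fx$anns)
  path <- tempfile(fileext = ".tsv")
  tab <- write_extension_table(ea, path)
  expect_true(all(c("product_A", "product_B") %in% names(tab)))
  re <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(re), 2L)
  expect_equal(re$product_B[1], "gyrase subunit B")
})
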