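cds_row <- function(start, stop, strand = "+", type = "CDS",
                    discontig = FALSE) {
  data.frame(replicon_id = "chr1", feature_type = type, strand = strand,
             start = start, stop = stop, is_discontiguous = discontig,
             stringsAsFactors = FALSE)
}

test_that("the reading frame is the mod-3 phase of the translation start", {
  expect_equal(cds_frame(cds_row(1000, 2000)), 1000L %% 3L)
  # same frame: starts congruent mod 3
  expect_equal(cds_frame(cds_row(1000, 2000)), cds_frame(cds_row(1006, 2006)))
  expect_false(cds_frame(cds_row(1000, 2000)) == cds_frame(cds_row(1001, 2001)))
  # minus strand: the stop end starts translation
  expect_equal(cds_frame(cds_row(900, 2000, strand = "-")), 2000L %% 3L)
  expect_true(is.na(cds_frame(cds_row(100, 900, discontig = TRUE))))
  expect_error(cds_frame(cds_row(100, 200, type = "tRNA")), "CDS")
})

test_that("pair classification implements the four-way status taxonomy", {
  # identical: exact coordinates, same strand and type
  r <- classify_pair(cds_row(1000, 2000), cds_row(1000, 2000))
  expect_equal(r$status, "identical")
  expect_equal(r$start_deviation, 0L)
  expect_equal(r$stop_deviation, 0L)

  # similar: deviations within offset * shorter length, same frame
  r <- classify_pair(cds_row(1000, 2000), cds_row(1006, 2000), offset = 0.02)
  expect_equal(r$status, "similar")
  expect_equal(r$start_deviation, 6L)

  # beyond the offset: unique with overlap
  r <- classify_pair(cds_row(1000, 2000), cds_row(1100, 2100), offset = 0.02)
  expect_equal(r$status, "unique_with_overlap")
  expect_false(r$relative_frameshift)

  # opposite strands: no match even with equal coordinates
  r <- classify_pair(cds_row(1000, 2000), cds_row(1000, 2000, strand = "-"))
  expect_equal(r$status, "unique_without_overlap")

  # disjoint genes
  r <- classify_pair(cds_row(100, 200), cds_row(500, 600))
  expect_equal(r$status, "unique_without_overlap")

  # in-offset overlap of CDS in different frames: relative frameshift
  r <- classify_pair(cds_row(1000, 2000), cds_row(1001, 2000), offset = 0.02)
  expect_equal(r$status, "unique_with_overlap")
  expect_true(r$relative_frameshift)
  expect_false(r$same_frame)

  # feature-type mismatch can never be identical/similar
  r <- classify_pair(cds_row(1000, 2000), cds_row(1000, 2000, type = "rRNA"))
  expect_equal(r$status, "unique_with_overlap")

  # non-CDS features skip the frame check
  r <- classify_pair(cds_row(1000, 2000, type = "rRNA"),
                     cds_row(1001, 2000, type = "rRNA"))
  expect_equal(r$status, "similar")

  # discontiguous CDS compare on the outer span, frame check skipped
  r <- classify_pair(cds_row(1000, 2000, discontig = TRUE),
                     cds_row(1001, 2000))
  expect_equal(r$status, "similar")
  expect_true(is.na(r$same_frame))

  expect_error(
    classify_pair(cds_row(1, 10),
                  within(cds_row(1, 10), replicon_id <- "chr2")),
    "replicon")
})

test_that("self-comparison matches every gene as identical", {
  a <- generate_annotation(40, replicon_length = 150000L, seed = 21,
                           label = "A")
  m <- match_genes(a, a)
  expect_equal(nrow(m$pairs), 40L)
  expect_true(all(m$pairs$status == "identical"))
  expect_true(all(m$pairs$start_deviation == 0L))
  expect_true(all(m$x_status == "identical"))
})

test_that("an extra disjoint gene is unique without overlap", {
  z <- make_ann(c(100, 5000), c(1099, 5999), label = "Z")
  x <- annotation(gene_df(c(100, 5000, 9000), c(1099, 5999, 9899)),
                  label = "X")
  m <- match_genes(x, z)
  expect_equal(sum(m$x_status == "identical"), 2L)
  expect_equal(unname(m$x_status[3]), "unique_without_overlap")
  expect_true(all(m$z_status == "identical"))
})

test_that("disjoint replicon ids raise a mapping error", {
  x <- make_ann(100, 1099, replicon = "chrA", label = "X")
  z <- make_ann(100, 1099, replicon = "chrB", label = "Z")
  expect_error(match_genes(x, z), "replicon")
})

test_that("matching agrees with the exhaustive brute-force matcher", {
  for (seed in 1:20) {
    x <- random_annotation(60, seed = seed, label = "X")
    z <- random_annotation(60, seed = seed + 1000, label = "Z")
    m <- match_genes(x, z, offset = 0.05)
    o <- oracle_match(x, z, offset = 0.05)
    expect_equal(m$x_status, o$x_status)
    expect_equal(m$z_status, o$z_status)
  }
})

test_that("pseudogene flags propagate over identical/similar pairs only", {
  z <- annotation(gene_df(c(100, 5000, 9000), c(1099, 5999, 9999),
                          is_pseudo = c(TRUE, TRUE, TRUE)), label = "Z")
  # gene 1 identical, gene 2 similar (shift 6), gene 3 only short overlap
  x <- annotation(gene_df(c(100, 5006, 9400), c(1099, 5999, 10399)),
                  label = "X")
  m <- match_genes(x, z)
  expect_equal(unname(m$x_status), c("identical", "similar",
                                     "unique_with_overlap"))
  upd <- propagate_pseudo(m, x, z)
  expect_true(upd$x$genes$is_pseudo[1])
  expect_true(upd$x$genes$is_pseudo[2])
  expect_false(upd$x$genes$is_pseudo[3])  # short overlap: out of scope
  expect_true(all(upd$z$genes$is_pseudo == z$genes$is_pseudo))

  # idempotent
  upd2 <- propagate_pseudo(m, upd$x, upd$z)
  expect_equal(upd2$x$genes$is_pseudo, upd$x$genes$is_pseudo)
  expect_equal(upd2$z$genes$is_pseudo, upd$z$genes$is_pseudo)
})

test_that("the similarity score is the symmetric matched fraction", {
  expect_equal(similarity_score(2421, 126, 3048, 3089), 83.00)
  expect_equal(similarity_score(2780, 71, 3048, 3088), 92.93)
  expect_equal(similarity_score(10, 0, 10, 10), 100.00)
  expect_equal(similarity_score(2421, 126, 3089, 3048),
               similarity_score(2421, 126, 3048, 3089))
  expect_error(similarity_score(0, 0, 0, 0), "empty")
  expect_error(similarity_score(5, 0, 4, 10), "exceed")
})

test_that("the reference report partitions both gene sets", {
  truth <- generate_annotation(40, replicon_length = 150000L, seed = 22,
                               label = "REF")
  out <- perturb_annotation(truth, perturbation_spec(
    seed = 7, end_shift_fraction = 0.2, beyond_offset_fraction = 0.1,
    drop_fraction = 0.1, insert_count = 2), label = "AM")
  m <- match_genes(out$variant, truth)
  r <- reference_report(m, out$variant, truth)

  expect_equal(r$identical + r$similar + r$fn_short_overlap + r$fn_no_overlap,
               r$total_z)
  expect_equal(r$identical + r$similar + r$fp_short_overlap + r$fp_no_overlap,
               r$total_x)
  expect_equal(sum(r$identical_by_type), r$identical)
  expect_equal(sum(r$similar_by_type), r$similar)
  expect_equal(r$percent[["identical"]], percent_of(r$identical, r$total_z))

  # self-comparison: no FN/FP and an identical share of 100 %
  m0 <- match_genes(truth, truth)
  r0 <- reference_report(m0, truth, truth)
  expect_equal(r0$fn_short_overlap + r0$fn_no_overlap +
               r0$fp_short_overlap + r0$fp_no_overlap, 0L)
  expect_equal(r0$percent[["identical"]], 100.00)
  expect_equal(r0$similarity_score, 100.00)
})

test_that("comparison tables carry the canonical row labels", {
  a <- make_ann(100, 1099, label = "A")
  r <- reference_report(match_genes(a, a), a, a)
  path <- tempfile(fileext = ".tsv")
  tab <- write_comparison_table(r, path)
  expect_equal(tab[["Gene calls"]],
               c("Detected identical", "Detected similar",
                 "FN - Short overlap", "FN - No overlap",
                 "FP - Short overlap", "FP-No overlap", "Similarity score"))
  expect_true(file.exists(path))
})
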