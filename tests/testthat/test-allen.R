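test_that("classification matches the day-set oracle exhaustively and covers 13 labels", {
  g <- interval_pair_grid(6L)
  got <- allen_classify(g$xs, g$xe, g$ys, g$ye)
  expect_false(anyNA(got$label))
  expected <- mapply(oracle_label, g$xs, g$xe, g$ys, g$ye)
  expect_equal(got$label, unname(expected))
  expect_setequal(unique(got$label), allen_labels())
  expect_length(unique(got$label), 13L)
})

test_that("inverse symmetry holds for every pair; equals is self-inverse", {
  g <- interval_pair_grid(6L)
  fwd <- allen_classify(g$xs, g$xe, g$ys, g$ye)$label
  rev <- allen_classify(g$ys, g$ye, g$xs, g$xe)$label
  expect_equal(fwd, allen_inverse(rev))
  expect_identical(allen_inverse("equals"), "equals")
  expect_identical(allen_inverse("not_applicable"), "not_applicable")
})

test_that("gap_days and overlap_days appear exactly when they should", {
  g <- interval_pair_grid(6L)
  r <- allen_classify(g$xs, g$xe, g$ys, g$ye)
  expect_true(all(!is.na(r$gap_days) == (r$label %in% c("before", "after"))))
  expect_true(all(r$gap_days >= 1L, na.rm = TRUE))
  sharing <- c(
    "overlaps", "overlapped_by", "starts", "started_by",
    "finishes", "finished_by", "contains", "during", "equals"
  )
  expect_true(all(!is.na(r$overlap_days) == (r$label %in% sharing)))
  expect_true(all(r$overlap_days >= 1L, na.rm = TRUE))
})

test_that("degenerate intervals are rejected", {
  expect_error(allen_classify(0, 0, 1, 2), "degenerate")
  expect_error(allen_classify(0, 5, 3, 3), "degenerate")
})

test_that("sequence annotation chains consecutive records and marks the first", {
  one <- dispensations("p1", "methadone", start = 0, days_supply = 7)
  expect_equal(annotate_relations(one)$label, "not_applicable")

  d <- dispensations("p1", "methadone", start = c(0, 7, 20), days_supply = c(7, 7, 5))
  ann <- annotate_relations(d)
  expect_equal(ann$label, c("not_applicable", "meets", "before"))
  expect_equal(ann$gap_days, c(NA, NA, 6L))
})

test_that("same-drug scope keeps each drug's chain independent", {
  d <- dplyr::bind_rows(
    dispensations("p1", "methadone", start = c(0, 7), days_supply = 7),
    dispensations("p1", "srom", start = c(3, 12), days_supply = 7)
  )
  same <- annotate_relations(d, scope = "same_drug")
  expect_equal(sum(same$label == "not_applicable"), 2L)
  expect_equal(same$label[same$drug == "methadone"], c("not_applicable", "meets"))
  expect_equal(same$label[same$drug == "srom"], c("not_applicable", "before"))
  cross <- annotate_relations(d, scope = "cross_drug")
  expect_equal(sum(cross$label == "not_applicable"), 1L)
})

test_that("relation frequencies count per drug and sum to 100 percent", {
  d <- dispensations("p1", "methadone", start = seq(0, by = 7, length.out = 100), days_supply = 7)
  freq <- relation_frequencies(annotate_relations(d))
  expect_equal(freq$pct[freq$relation == "meets"], 99)
  expect_equal(freq$pct[freq$relation == "not_applicable"], 1)
  expect_equal(sum(freq$pct), 100)

  empty <- relation_frequencies(annotate_relations(d[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("inverse labels fold onto the base reporting categories", {
  expect_equal(allen_base(c("finished_by", "during", "after", "equals")),
    c("finishes", "contains", "before", "equals"))
  expect_error(allen_base("nonsense"), "unknown")
})
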