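test_that("impact score averages the two deleteriousness probabilities", {
  expect_equal(impact_score(0, 1), 1.0)
  expect_equal(impact_score(1, 0), 0.0)
  expect_equal(impact_score(0.2, 0.8), 0.8)
  # monotone: increasing in polyphen, decreasing in sift
  s <- seq(0, 1, by = 0.1)
  expect_true(all(diff(impact_score(rep(0.3, 11), s)) > 0))
  expect_true(all(diff(impact_score(s, rep(0.3, 11))) < 0))
  expect_error(impact_score(-0.1, 0.5), "invalid annotation")
  expect_error(impact_score(0.5, 1.2, variant_id = "1:5:A:C"), "1:5:A:C")
})

test_that("splice weight is the maximum of the four delta scores", {
  expect_equal(splice_weight(c(0.1, 0, 0, 0)), 0.1)
  expect_equal(splice_weight(c(0, 0, 0, 0)), 0)
  expect_equal(splice_weight(c(0.3, 0.6, 0.1, 0.05)), 0.6)
  expect_error(splice_weight(c(0.1, 0.2)), "invalid annotation")
  m <- rbind(c(0.1, 0, 0, 0), c(0.3, 0.6, 0.1, 0.05))
  expect_equal(splice_weight(m), c(0.1, 0.6))
})

test_that("rbp effect is alt minus ref with max-absolute weight", {
  p <- runif(8)
  eq <- rbp_effect(p, p)
  expect_equal(eq$effect, rep(0, 8))
  expect_equal(eq$weight, 0)
  p_ref <- rep(0.2, 8); p_alt <- p_ref; p_alt[3] <- 0.9
  r <- rbp_effect(p_alt, p_ref)
  expect_equal(r$effect[3], 0.7)
  expect_equal(r$weight, 0.7)
  expect_error(rbp_effect(runif(8), runif(7)), "invalid annotation")
})

test_that("build_annotations scores all categories and flags dual pLOF", {
  ann <- build_annotations(h_raw_annotations())
  expect_s3_class(ann, "variant_annotation")
  w <- setNames(ann$weight, ann$variant_id)
  expect_equal(unname(w["1:100:A:C"]), 1)          # pLOF
  expect_equal(unname(w["1:200:A:C"]), 0.9)        # missense
  expect_equal(unname(w["1:300:A:C"]), 0.75)
  expect_equal(unname(w["1:500:A:C"]), 0.1)        # splice max delta
  expect_equal(unname(w["1:700:A:C"]), 0.35)       # rbp max abs effect
  expect_equal(unname(w["1:800:A:C"]), 0.25)
  expect_true(ann$is_also_plof[ann$variant_id == "1:500:A:C"])
  expect_false(any(ann$is_also_plof[ann$category == "pLOF"]))
  expect_equal(length(ann$effect_vector[[which(ann$variant_id ==
                                                 "1:700:A:C")]]), 8L)
  # missense rows without both scores are dropped with a warning
  raw <- h_raw_annotations()
  raw$sift[2] <- NA
  expect_warning(a2 <- build_annotations(raw), "missing SIFT/PolyPhen")
  expect_false("1:200:A:C" %in% a2$variant_id)
  # duplicated (variant, gene, category) rows rejected
  expect_error(build_annotations(rbind(raw, raw[1, ])), "duplicated")
})

test_that("qualifying selection applies thresholds and the rescue rule", {
  ann <- build_annotations(h_raw_annotations())
  q <- assign_qualifying(ann)
  ids <- q$variant_id
  expect_true("1:100:A:C" %in% ids)                 # pLOF always
  expect_true("1:200:A:C" %in% ids)                 # 0.9 >= 0.8
  expect_true("1:300:A:C" %in% ids)                 # 0.75 rescued at aa 10
  expect_true("1:400:A:C" %in% ids)                 # exactly 0.8 boundary
  expect_true("1:500:A:C" %in% ids)                 # splice 0.1 boundary
  expect_false("1:600:A:C" %in% ids)                # splice 0.05 < 0.1
  expect_true(all(c("1:700:A:C", "1:800:A:C") %in% ids))  # rbp >= 0.25
  expect_true(all(q$weight[q$category == "pLOF"] == 1))
  expect_true(all(q$weight > 0))

  # lone sub-threshold missense is excluded (no rescue partner)
  raw <- h_raw_annotations()
  raw <- raw[raw$variant_id != "1:200:A:C", ]       # remove the 0.9 at aa 10
  q2 <- assign_qualifying(build_annotations(raw))
  expect_false("1:300:A:C" %in% q2$variant_id)

  # invariant to input row order
  ann_rev <- build_annotations(h_raw_annotations()[8:1, ])
  q_rev <- assign_qualifying(ann_rev)
  expect_equal(q_rev$variant_id, q$variant_id)
  expect_equal(q_rev$weight, q$weight)

  # unknown gene: warn and skip
  expect_warning(q3 <- assign_qualifying(ann, known_genes = "G1"),
                 "unknown genes")
  expect_true(all(q3$gene_id == "G1"))
  expect_equal(attr(q3, "n_skipped_unknown_gene"), 4L)
})
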