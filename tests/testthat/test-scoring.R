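found_meas <- function(key, value)
  lookup_allele(allele_source(
    data.frame(chrom = "chr1", pos = 1, ref = "G", alt = "A", value = value),
    key = key), variant_spec("chr1", 1, "G", "A", gene = "G"))

missing_meas <- function(key)
  lookup_allele(allele_source(
    data.frame(chrom = "chr9", pos = 9, ref = "C", alt = "T", value = 0),
    key = key), variant_spec("chr1", 1, "G", "A", gene = "G"))

test_that("binarize implements inclusive/exclusive operators and the unknown rule", {
  ge2 <- threshold_rule("ge", "cadd", 2.0)
  expect_equal(binarize(found_meas("cadd", 2.0), ge2), 1L)   # boundary inclusive
  expect_equal(binarize(found_meas("cadd", 1.999), ge2), 0L)
  expect_equal(binarize(found_meas("cadd", 2.0), threshold_rule("gt", "cadd", 2.0)), 0L)
  expect_equal(binarize(found_meas("cadd", 2.0), threshold_rule("le", "cadd", 2.0)), 1L)
  # unknown evidence scores 0 under any comparative rule
  expect_equal(binarize(missing_meas("cadd"), ge2), 0L)
  lt <- threshold_rule("lt", "gnomad_af", 0.01)
  expect_equal(binarize(found_meas("gnomad_af", 0.05), lt), 0L)
  expect_equal(binarize(found_meas("gnomad_af", 0.001), lt), 1L)
  # absence/presence operators read the measurement status
  abs_rule <- threshold_rule("absent", "gnomad_af")
  expect_equal(binarize(missing_meas("gnomad_af"), abs_rule), 1L)
  expect_equal(binarize(found_meas("gnomad_af", 0.5), abs_rule), 0L)
  pres <- threshold_rule("present", "remap")
  iv <- interval_source(data.frame(chrom = "chr1", start = 0, end = 5, name = "tf"))
  on_target <- overlap_intervals(iv, variant_spec("chr1", 3, "G", "A", gene = "G"))
  off_target <- overlap_intervals(iv, variant_spec("chr1", 50, "G", "A", gene = "G"))
  expect_equal(binarize(on_target, pres), 1L)
  expect_equal(binarize(off_target, pres), 0L)
  # repeated evaluation of the same measurement is stable
  m <- found_meas("cadd", 3)
  expect_identical(binarize(m, ge2), binarize(m, ge2))
  expect_error(binarize(found_meas("cadd", 1), lt), class = "rve_internal_error")
})

test_that("compute_scores matches hand enumeration, including saturation", {
  rub <- toy_rubric4()
  zeros <- compute_scores(list(), rub)
  expect_equal(c(zeros$c_score, zeros$f_score, zeros$rve_score), c(0, 0, 0))
  expect_true(all(zeros$contributions$provenance == "default_unknown"))

  ones <- compute_scores(
    evidence_from_values(c(C1 = 1, C2 = 1, F1 = 1, F2 = 1)), rub)
  ms <- max_scores(rub)
  expect_equal(ones$c_score, ms[["max_c"]])
  expect_equal(ones$f_score, ms[["max_f"]])
  expect_equal(ones$rve_score, sum(ms))

  # clinical weights {2,1}, functional {3,1}, evidence {1,0,1,1} -> (2,4,6)
  mixed <- compute_scores(
    evidence_from_values(c(C1 = 1, C2 = 0, F1 = 1, F2 = 1)), rub)
  expect_equal(c(mixed$c_score, mixed$f_score, mixed$rve_score), c(2, 4, 6))

  expect_error(compute_scores(evidence_from_values(c(Z9 = 1)), rub),
               class = "rve_validation_error")
  expect_error(evidence_value("C1", 2), class = "rve_validation_error")
})

test_that("compute_scores equals the brute-force oracle on random cases", {
  set.seed(17)
  for (i in 1:200) {
    rub <- random_toy_rubric()
    ids <- vapply(rub$criteria, `[[`, character(1), "id")
    vals <- stats::setNames(sample(0:1, length(ids), replace = TRUE), ids)
    keep <- sample(ids, sample(0:length(ids), 1))  # some criteria left unset
    res <- compute_scores(evidence_from_values(vals[keep]), rub)
    expected <- brute_component_scores(as.list(vals[keep]), rub)
    expect_equal(res$c_score, unname(expected["c"]))
    expect_equal(res$f_score, unname(expected["f"]))
    expect_equal(res$rve_score, res$c_score + res$f_score)
    expect_equal(sum(res$contributions$contribution), res$rve_score)
  }
})

test_that("flipping any evidence 0 to 1 never decreases a score", {
  set.seed(23)
  for (i in 1:30) {
    rub <- random_toy_rubric()
    ids <- vapply(rub$criteria, `[[`, character(1), "id")
    vals <- stats::setNames(sample(0:1, length(ids), replace = TRUE), ids)
    base <- compute_scores(evidence_from_values(vals), rub)
    for (id in ids[vals == 0]) {
      flipped <- vals; flipped[id] <- 1
      res <- compute_scores(evidence_from_values(flipped), rub)
      expect_gte(res$c_score, base$c_score)
      expect_gte(res$f_score, base$f_score)
      expect_gte(res$rve_score, base$rve_score)
    }
  }
})

test_that("ranking uses the <=-count ECDF and reference tertiles", {
  rub <- toy_rubric4()
  score_of <- function(vals) compute_scores(evidence_from_values(vals), rub)

  res2 <- rank_against_reference(
    score_of(c(C1 = 1)),  # rve 2
    ref_dist(c(1, 2, 3, 4)))
  expect_equal(res2$percentile, 50)

  top <- rank_against_reference(
    score_of(c(C1 = 1, C2 = 1, F1 = 1, F2 = 1)),  # rve 7 >= max(ref)
    ref_dist(c(1, 2, 3, 4)))
  expect_equal(top$percentile, 100)
  expect_equal(top$strength_label, "high")

  expect_warning(empty <- rank_against_reference(score_of(c(C1 = 1)),
                                                 ref_dist(numeric(0))))
  expect_true(is.na(empty$percentile))
  expect_true(is.na(empty$strength_label))

  # labels follow independently computed tertile cut points
  ref <- ref_dist(0:29)
  cuts <- unname(quantile(0:29, c(1, 2) / 3))
  low <- rank_against_reference(score_of(c(F2 = 1)), ref)          # rve 1
  mid <- rank_against_reference(score_of(c(C1 = 1, C2 = 1, F1 = 1, F2 = 1)), ref)  # rve 7... still below cuts[1]?
  expect_equal(low$strength_label, if (1 < cuts[1]) "low" else "intermediate")
  expect_equal(mid$strength_label,
               if (7 < cuts[1]) "low" else if (7 < cuts[2]) "intermediate" else "high")
})

test_that("percentile is non-decreasing in the score for a fixed reference", {
  set.seed(31)
  ref <- ref_dist(sample(0:40, 46, replace = TRUE))
  rub <- rubric(list(criterion("C1", "clinical", "w", 1, "manual"),
                     criterion("F1", "functional", "w", 50, "manual")),
                strict = FALSE)
  pct <- vapply(list(c(), c(C1 = 1), c(C1 = 1, F1 = 1)), function(vals) {
    rank_against_reference(compute_scores(evidence_from_values(vals), rub),
                           ref)$percentile
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("the reference distribution loader validates size and content", {
  ref <- load_reference(default_reference_path())
  expect_equal(nrow(ref), 46L)
  expect_true(all(ref$rve_score >= 0))
  expect_error(load_reference(default_reference_path(), expected_size = 45),
               class = "rve_validation_error")
  bad <- write_tsv_file(data.frame(label = "x", rve_score = -1))
  expect_error(load_reference(bad, expected_size = NULL),
               class = "rve_validation_error")
})
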