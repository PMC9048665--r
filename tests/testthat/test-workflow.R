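test_that("step ordering is enforced", {
  rub <- load_rubric(default_rubric_path())
  s <- new_session(variant_spec("chr1", 150000, "G", "A", gene = "TFX1"), rub)
  expect_error(step2_manual(s, c(C3.1 = "yes")), class = "rve_validation_error")
  expect_error(step3_override(s, list(C3.1 = list(value = 1, comment = "x"))),
               class = "rve_validation_error")
  expect_error(finalize(s), class = "rve_validation_error")
})

test_that("step 1 scores every auto criterion per the planted fixture truths", {
  for (recipe in c("all-pass", "no-coverage", "mixed")) {
    fx <- fixture_session(recipe, seed = 13)
    expected <- fx$key$expected_auto_evidence
    for (id in names(expected)) {
      ev <- fx$session$evidence[[id]]
      expect_equal(ev$value, expected[[id]],
                   label = sprintf("%s under recipe %s", id, recipe))
      expect_equal(ev$provenance, "auto")
      expect_s3_class(ev$raw, "rve_measurement")
    }
    df <- as.data.frame(fx$rubric)
    expect_setequal(names(fx$session$evidence), df$id[df$mode == "auto"])
  }
})

test_that("re-running step 1 is idempotent on the evidence and audited", {
  fx <- fixture_session("mixed", seed = 3)
  bundle <- load_bundle(file.path(fx$dir, "manifest.yaml"))
  again <- step1_auto(fx$session, bundle)
  expect_identical(again$evidence, fx$session$evidence)
  expect_equal(nrow(again$audit), 2 * nrow(fx$session$audit))
})

test_that("step 2 maps yes/no/unanswered and rejects answers for auto criteria", {
  fx <- fixture_session("no-coverage", seed = 9)
  s <- step2_manual(fx$session, c(C3.1 = "yes", C2.1 = "no"))
  expect_equal(s$evidence$C3.1$value, 1L)
  expect_equal(s$evidence$C3.1$provenance, "user_answer")
  expect_equal(s$evidence$C2.1$value, 0L)
  expect_equal(s$evidence$C2.1$provenance, "user_answer")
  # unanswered manual criteria default to 0, flagged unknown
  expect_equal(s$evidence$F3.1$value, 0L)
  expect_equal(s$evidence$F3.1$provenance, "default_unknown")
  expect_error(step2_manual(fx$session, c(C1.1 = "yes")),
               class = "rve_validation_error")
  expect_error(step2_manual(fx$session, c(C3.1 = "maybe")),
               class = "rve_validation_error")
})

test_that("step 3 overrides retain provenance, warn, and audit the change", {
  fx <- fixture_session("no-coverage", seed = 9)
  s <- step2_manual(fx$session, character(0))
  expect_warning(
    s2 <- step3_override(s, list(C1.1 = list(value = 1,
                                             comment = "functional data, PMID:1"))),
    "supporting evidence")
  expect_equal(s2$evidence$C1.1$value, 1L)
  expect_equal(s2$evidence$C1.1$provenance, "user_override")
  expect_equal(s2$evidence$C1.1$previous, 0L)
  row <- s2$audit[nrow(s2$audit), ]
  expect_equal(c(row$old_value, row$new_value), c(0, 1))
  expect_equal(row$comment, "functional data, PMID:1")

  # empty comment draws an extra warning; empty override set is the identity
  w <- capture_warnings(step3_override(s, list(C1.1 = list(value = 1))))
  expect_length(w, 2L)
  s3 <- step3_override(s, list())
  expect_identical(s3$evidence, s$evidence)
  expect_error(suppressWarnings(
    step3_override(s, list(C1.1 = list(value = 2, comment = "x")))),
    class = "rve_validation_error")
})

test_that("replaying the audit log reproduces the evidence decisions", {
  fx <- fixture_session("mixed", seed = 29)
  s <- step2_manual(fx$session, c(C3.1 = "yes", F4.1 = "yes", C2.2 = "no"))
  s <- suppressWarnings(step3_override(
    s, list(F1.2 = list(value = 1, comment = "enhancer assay"),
            C3.1 = list(value = 0, comment = "segregation retracted"))))
  replayed <- replay_audit(s)
  expect_setequal(names(replayed), names(s$evidence))
  for (id in names(s$evidence)) {
    expect_equal(replayed[[id]]$value, s$evidence[[id]]$value, label = id)
    expect_equal(replayed[[id]]$provenance, s$evidence[[id]]$provenance, label = id)
    expect_equal(replayed[[id]]$comment, s$evidence[[id]]$comment, label = id)
  }
})

test_that("finalize is pure and agrees with direct scoring", {
  fx <- fixture_session("all-pass", seed = 41)
  s <- step2_manual(fx$session, c(C5.1 = "yes"))
  ref <- load_reference(default_reference_path())
  before <- s
  r1 <- finalize(s, ref)
  r2 <- finalize(s, ref)
  expect_identical(s, before)
  expect_identical(r1, r2)
  direct <- compute_scores(s$evidence, s$rubric)
  expect_equal(r1$c_score, direct$c_score)
  expect_equal(r1$f_score, direct$f_score)
  expect_equal(r1$rve_score, direct$rve_score)
  expect_false(is.na(r1$percentile))
})

test_that("an uncovered bundle with no answers scores zero across the board", {
  fx <- fixture_session("no-coverage", seed = 8)
  s <- step2_manual(fx$session, character(0))
  res <- finalize(s, load_reference(default_reference_path()))
  expect_equal(c(res$c_score, res$f_score, res$rve_score), c(0, 0, 0))
  expect_equal(res$percentile, 0)
})

test_that("session snapshots round-trip through JSON", {
  fx <- fixture_session("mixed", seed = 55)
  s <- step2_manual(fx$session, c(C4.1 = "yes"))
  s <- suppressWarnings(step3_override(
    s, list(F2.1 = list(value = 1, comment = "EMSA shift"))))
  path <- tempfile(fileext = ".json")
  save_session(s, path)
  s2 <- load_session(path, fx$rubric)
  expect_equal(s2$steps_done, s$steps_done)
  expect_equal(s2$audit, s$audit)
  expect_setequal(names(s2$evidence), names(s$evidence))
  for (id in names(s$evidence)) {
    expect_equal(s2$evidence[[id]]$value, s$evidence[[id]]$value, label = id)
    expect_equal(s2$evidence[[id]]$provenance, s$evidence[[id]]$provenance,
                 label = id)
  }
  # scores after reload are unchanged
  expect_equal(finalize(s2)$rve_score, finalize(s)$rve_score)
  # schema guard
  snap <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  snap$schema_version <- "99"
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(snap, bad, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_session(bad, fx$rubric), class = "rve_io_error")
})

test_that("answers and overrides files parse, including YAML booleans", {
  ans_path <- tempfile(fileext = ".yaml")
  writeLines(c("C3.1: yes", "C2.1: no", "C4.1: unanswered"), ans_path)
  ans <- load_answers(ans_path)
  expect_equal(unname(ans[c("C3.1", "C2.1", "C4.1")]),
               c("yes", "no", "unanswered"))
  ov_path <- tempfile(fileext = ".yaml")
  writeLines(c("F2.1:", "  value: 1", "  comment: gel shift"), ov_path)
  ov <- load_overrides(ov_path)
  expect_equal(ov$F2.1$value, 1)
  expect_equal(ov$F2.1$comment, "gel shift")
})
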