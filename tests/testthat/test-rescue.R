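# Scripted backend returning fixed mean plDDTs per mode, for exercising
# the orchestration logic without a real (or mock-stochastic) predictor.
stub_backend <- function(values) {
  b <- structure(list(values = values), class = "stub_backend")
  registerS3method("predict_structure", "stub_backend",
                   function(backend, request, domain_span = NULL, ...) {
                     v <- backend$values[[request$mode]]
                     if (is.null(v)) stop("no scripted value for ", request$mode)
                     L <- nchar(request$sequence)
                     prediction_result(request$protein_id, request$mode,
                                       structure_model(request$protein_id,
                                                       request$sequence,
                                                       rep(v, L)),
                                       domain_span)
                   },
                   envir = asNamespace("foldrescue"))
  b
}

toy_bank <- function(n = 3, seed = 21) {
  withr::with_seed(seed, {
    results <- lapply(seq_len(n), function(i) {
      m <- structure_model(sprintf("T%d", i), random_seq(12),
                           rep(70 + i * 5, 12), ca_coords = cbind(1:12, 0, 0))
      prediction_result(m$protein_id, "no_template_msa", m)
    })
    build_template_bank(results, "FAMB")
  })
}

test_that("template banks keep exactly the confident models, best first", {
  mk <- function(id, v) prediction_result(id, "no_template_msa",
                                          toy_model(id, plddt = rep(v, 8)))
  bank <- build_template_bank(list(mk("A", 65), mk("B", 70), mk("C", 90.2)), "F")
  expect_equal(vapply(bank$templates, `[[`, "", "protein_id"), c("C", "B"))
  expect_equal(bank$template_plddts, c(90.2, 70))

  expect_warning(empty <- build_template_bank(list(mk("A", 60)), "F"),
                 "empty template bank")
  expect_length(empty$templates, 0)

  tmpl_mode <- prediction_result("Z", "template_msa", toy_model("Z"))
  expect_error(build_template_bank(list(tmpl_mode), "F"), "no_template_msa")
})

test_that("template bank equals a filter-and-sort oracle on generated members", {
  fam <- generate_family(family_spec("FB", n_members = 30, seed = 44))
  results <- lapply(fam$models, function(m)
    prediction_result(m$protein_id, "no_template_msa", m))
  bank <- build_template_bank(unname(results), "FB")
  means <- vapply(fam$models, function(m) mean(m$plddt), numeric(1))
  keep <- means[means >= 70]
  expect_equal(vapply(bank$templates, `[[`, "", "protein_id"),
               names(sort(keep, decreasing = TRUE)))
})

test_that("best pick takes the max and breaks ties toward the MSA mode", {
  expect_equal(best_pick(68, 75), list(mode = "template_single", plddt = 75))
  expect_equal(best_pick(70, 70), list(mode = "template_msa", plddt = 70))
  withr::local_seed(5)
  for (i in 1:200) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    expect_equal(best_pick(a, b)$plddt, max(a, b))
  }
})

test_that("rescue classification follows the best-pick and threshold rules", {
  bank <- toy_bank()
  run1 <- function(vals) run_rescue("Q1", random_seq(12), "FAMB", bank,
                                    stub_backend(vals), seed = 1)
  withr::local_seed(9)
  rec <- run1(list(no_template_msa = 60, template_msa = 68, template_single = 75))
  expect_equal(rec$best_pick_mode, "template_single")
  expect_equal(rec$best_pick_plddt, 75)
  expect_true(rec$rescued)

  rec2 <- run1(list(no_template_msa = 60, template_msa = 69, template_single = 64))
  expect_equal(rec2$best_pick_plddt, 69)
  expect_false(rec2$rescued)

  # confident baseline: a positive control, never counted as rescued
  rec3 <- run1(list(no_template_msa = 72, template_msa = 80, template_single = 85))
  expect_false(rec3$rescued)
  expect_equal(rec3$best_pick_plddt, 85)
})

test_that("a failing mode leaves its field missing and the rest intact", {
  bank <- toy_bank()
  vals <- list(no_template_msa = 60, template_msa = 70)  # single mode fails
  withr::local_seed(10)
  expect_warning(
    rec <- run_rescue("Q2", random_seq(12), "FAMB", bank, stub_backend(vals),
                      seed = 1),
    "backend failed")
  expect_true(is.na(rec$template_single_plddt))
  expect_equal(rec$best_pick_plddt, 70)
  expect_true(rec$rescued)
})

test_that("self-exclusion removes the query's own model from its templates", {
  bank <- toy_bank()
  self_id <- bank$templates[[1]]$protein_id
  vals <- list(no_template_msa = 60, template_msa = 70, template_single = 65)
  withr::local_seed(11)
  rec_incl <- run_rescue(self_id, bank$templates[[1]]$sequence, "FAMB", bank,
                         stub_backend(vals), seed = 1)
  expect_equal(rec_incl$closest_template_id, self_id)
  expect_equal(rec_incl$closest_template_identity_pct, 100)
  rec_excl <- run_rescue(self_id, bank$templates[[1]]$sequence, "FAMB", bank,
                         stub_backend(vals), seed = 1, exclude_self = TRUE)
  expect_false(rec_excl$closest_template_id == self_id)
})

test_that("prediction requests enforce the mode/template contract", {
  t1 <- toy_model("T1")
  expect_error(prediction_request("P", "AAA", "no_template_msa",
                                  templates = list(t1)), "must not carry")
  expect_error(prediction_request("P", "AAA", "template_single"), "template")
  req <- prediction_request("P", "AAA", "template_single", list(t1))
  expect_false(req$msa_enabled)
  expect_true(prediction_request("P", "AAA", "template_msa", list(t1))$msa_enabled)
})

test_that("the command backend exchanges files with an external predictor", {
  workdir <- withr::local_tempdir()
  prepared <- file.path(workdir, "prepared.pdb")
  out_model <- toy_model("Q9", n = 10, plddt = rep(81.25, 10), seed = 2)
  write_model(out_model, prepared)
  backend <- command_backend(paste("cp", prepared, "{out}"), workdir = workdir)
  req <- prediction_request("Q9", out_model$sequence, "template_msa",
                            list(toy_model("T5", seed = 3)))
  res <- predict_structure(backend, req)
  expect_equal(res$mean_plddt, 81.25, tolerance = 1e-6)
  expect_true(file.exists(file.path(workdir, "Q9_template_msa", "query.fasta")))
  expect_true(file.exists(file.path(workdir, "Q9_template_msa", "templates",
                                    "T5.pdb")))
  bad <- command_backend("false", workdir = workdir)
  expect_error(predict_structure(bad, req), "failed")
})
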