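test_that("family generation is a deterministic function of the spec", {
  spec <- family_spec("FD", n_members = 25, seed = 99)
  a <- generate_family(spec)
  b <- generate_family(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$models, `[[`, "plddt"),
                   lapply(b$models, `[[`, "plddt"))
  c <- generate_family(family_spec("FD", n_members = 25, seed = 100))
  expect_false(identical(a$truth$domain_plddt, c$truth$domain_plddt))
})

test_that("generated members respect bounds, spans, and the fragment rate", {
  fam <- generate_family(family_spec("FG", n_members = 40, seed = 7,
                                     fragment_fraction = 0))
  for (m in fam$models) {
    expect_true(all(m$plddt >= 0 & m$plddt <= 100))
    expect_equal(nchar(m$sequence), 120)
  }
  expect_false(any(fam$annotations$is_fragment))
  expect_true(all(fam$annotations$end <= nchar(fam$annotations$sequence)))
  # domain mean plDDT equals the drawn mixture value exactly
  dp <- vapply(fam$models, function(m) mean(m$plddt[11:110]), numeric(1))
  expect_equal(unname(dp), fam$truth$domain_plddt, tolerance = 1e-9)
})

test_that("bimodal specs are recovered as rescuable; degenerate mixtures are not", {
  hits <- 0
  for (s in 1:6) {
    fam <- generate_family(family_spec("FR", n_members = 200, seed = s))
    prof <- family_profile("FR", setNames(fam$truth$domain_plddt,
                                          fam$truth$protein_id))
    if (is_rescuable_bimodal(prof) &&
        any(abs(prof$peaks$bin_index - 40) <= 2) &&
        any(abs(prof$peaks$bin_index - 85) <= 2)) hits <- hits + 1
  }
  expect_gte(hits, 5)

  uni <- generate_family(family_spec("FU", n_members = 200, seed = 3,
                                     mixture_weights = c(1, 0)))
  prof_uni <- family_profile("FU", setNames(uni$truth$domain_plddt,
                                            uni$truth$protein_id))
  expect_false(is_rescuable_bimodal(prof_uni))
})

test_that("low-confidence members are the diverged ones", {
  fam <- generate_family(family_spec("FI", n_members = 80, seed = 13))
  low <- fam$truth$domain_plddt < 70
  expect_gt(mean(fam$truth$mutation_rate[low]),
            mean(fam$truth$mutation_rate[!low]))
  expect_true(all(fam$truth$planted_identity[!low] > 80))
})

test_that("alignment identity tracks the generator's planted identity", {
  fam <- generate_family(family_spec("FC", n_members = 60, seed = 21))
  high <- head(fam$truth$protein_id[fam$truth$domain_plddt >= 70], 4)
  low <- head(fam$truth$protein_id[fam$truth$domain_plddt < 70], 20)
  bank <- setNames(fam$annotations$sequence[match(high,
                                                  fam$annotations$protein_id)],
                   high)
  measured <- vapply(low, function(pid)
    closest_template_identity(fam$models[[pid]]$sequence, bank)$identity_pct,
    numeric(1))
  planted <- fam$truth$planted_identity[match(low, fam$truth$protein_id)]
  expect_gt(cor(measured, planted), 0.8)
})

test_that("the mock response hits its formula endpoints exactly", {
  fam <- generate_family(family_spec("FM", n_members = 40, seed = 31))
  low_id <- fam$truth$protein_id[which(fam$truth$mean_plddt < 60)][1]
  base <- fam$models[[low_id]]

  noiseless <- mock_response_spec(gain_at_full_identity = 20,
                                  sd_single = 0, sd_msa = 0)
  backend <- mock_backend(fam$models, noiseless)

  # identity 100: the query's own model as template
  req <- prediction_request(low_id, base$sequence, "template_single",
                            list(base), seed = 5)
  res <- predict_structure(backend, req)
  expect_equal(res$mean_plddt, mean(base$plddt) + 20, tolerance = 1e-9)

  # MSA mode retains only the attenuated gain
  req_msa <- prediction_request(low_id, base$sequence, "template_msa",
                                list(base), seed = 5)
  expect_equal(predict_structure(backend, req_msa)$mean_plddt,
               mean(base$plddt) + 20 * noiseless$msa_attenuation,
               tolerance = 1e-9)

  # identity exactly at the floor: zero response in both modes
  donor <- "AAACCCCCCC"   # 3/10 identical to poly-A, no gaps favoured
  q_id <- fam$truth$protein_id[2]
  q_model <- structure_model(q_id, "AAAAAAAAAA", rep(50, 10))
  backend2 <- mock_backend(setNames(list(q_model), q_id), noiseless)
  tmpl <- structure_model("D1", donor, rep(90, 10))
  for (mode in c("template_single", "template_msa")) {
    res0 <- predict_structure(backend2,
                              prediction_request(q_id, "AAAAAAAAAA", mode,
                                                 list(tmpl), seed = 1))
    expect_equal(res0$mean_plddt, 50, tolerance = 1e-9)
  }

  # below the floor, single-sequence mode degrades, MSA mode does not
  donor_far <- "CCCCCCCCCC"
  res_far_single <- predict_structure(backend2,
    prediction_request(q_id, "AAAAAAAAAA", "template_single",
                       list(structure_model("D2", donor_far, rep(90, 10))),
                       seed = 1))
  expect_lt(res_far_single$mean_plddt, 50)
  res_far_msa <- predict_structure(backend2,
    prediction_request(q_id, "AAAAAAAAAA", "template_msa",
                       list(structure_model("D2", donor_far, rep(90, 10))),
                       seed = 1))
  expect_equal(res_far_msa$mean_plddt, 50, tolerance = 1e-9)
})

test_that("mock noise is deterministic per seed, protein and mode", {
  fam <- generate_family(family_spec("FN", n_members = 10, seed = 41))
  backend <- mock_backend(fam$models, mock_response_spec())
  pid <- fam$truth$protein_id[1]
  req <- function(seed) prediction_request(pid, fam$models[[pid]]$sequence,
                                           "template_single",
                                           list(fam$models[[2]]), seed = seed)
  a <- predict_structure(backend, req(3))
  b <- predict_structure(backend, req(3))
  expect_identical(a$mean_plddt, b$mean_plddt)
  c <- predict_structure(backend, req(4))
  expect_false(identical(a$mean_plddt, c$mean_plddt))
})

test_that("families round-trip through the on-disk layout", {
  fam <- generate_family(family_spec("FW", n_members = 6, seed = 51))
  dir <- withr::local_tempdir()
  write_family(fam, dir)
  models <- read_models(file.path(dir, "models"))
  expect_length(models, 6)
  back <- models[[fam$truth$protein_id[1]]]
  expect_identical(back$sequence, fam$models[[fam$truth$protein_id[1]]]$sequence)
  expect_equal(back$plddt, fam$models[[fam$truth$protein_id[1]]]$plddt,
               tolerance = 0.011)
  tab <- read_domain_table(file.path(dir, "domains.tsv"))
  expect_equal(nrow(tab), 6)
})
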