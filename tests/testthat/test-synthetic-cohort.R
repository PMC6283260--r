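test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(n_subjects = 0), "positive")
  expect_error(cohort_spec(block_loading = 1.2), "\\[0,1\\]")
  expect_error(cohort_spec(block_sizes = c(3, 3)), "length mismatch")
  expect_error(cohort_spec(reversion_rate = -0.1), "\\[0,1\\]")
  expect_error(cohort_spec(n_noise_analytes = -1), "non-negative")
  sp <- cohort_spec()
  expect_s3_class(sp, "cohort_spec")
  # panel width identity: blocks + noise analytes
  expect_identical(sum(sp$block_sizes) + sp$n_noise_analytes, 200L)
})

test_that("zero loading produces uncorrelated analytes within blocks", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 400, n_plasma_blocks = 2, block_sizes = c(6, 6),
    block_loading = 0, n_noise_analytes = 0, n_roi_pairs = 2, seed = 14))
  b1 <- ft_data(ft_select(co$features, features = sprintf("plasma_b01_%02d", 1:6)))
  r <- cor(b1)[upper.tri(diag(6))]
  expect_lt(mean(abs(r)), 3 / sqrt(400))
})

test_that("shared-factor blocks reach the closed-form pairwise correlation", {
  # loading L on a shared latent implies pairwise correlation L^2
  co <- generate_cohort(cohort_spec(
    n_subjects = 2000, n_plasma_blocks = 1, block_sizes = 8,
    block_loading = 0.95, n_noise_analytes = 0, n_roi_pairs = 2, seed = 15))
  b <- ft_data(ft_select(co$features, tags = "plasma"))
  r <- cor(b)[upper.tri(diag(8))]
  expect_equal(mean(r), 0.95^2, tolerance = 0.05)
})

test_that("without a planted effect, progression is independent of the latent", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 800, hallmark_effect = 0, reversion_rate = 0, seed = 16))
  prog <- as.numeric(co$truth$progressed)
  expect_lt(abs(cor(prog, co$truth$z_hallmark)), 3 / sqrt(800))
})

test_that("generation is bit-reproducible given the seed", {
  sp <- cohort_spec(n_subjects = 120, n_plasma_blocks = 2, block_sizes = c(4, 4),
                    n_noise_analytes = 2, n_roi_pairs = 2, seed = 17)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(ft_data(a$features), ft_data(b$features))
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(as.data.frame(a$diagnoses), as.data.frame(b$diagnoses))
})

test_that("every feature carries one tag; block membership partitions analytes", {
  co <- generate_cohort(cohort_spec(n_subjects = 100, seed = 18))
  tags <- ft_classes(co$features)
  expect_identical(names(tags), colnames(ft_data(co$features)))
  expect_false(anyNA(tags))
  bm <- co$truth$block_membership
  plasma <- names(tags)[tags == "plasma"]
  non_noise <- plasma[!grepl("noise", plasma)]
  expect_setequal(names(bm), non_noise)
  expect_identical(anyDuplicated(names(bm)), 0L)
})

test_that("hallmark-driven structure has the expected signs", {
  co <- generate_cohort(cohort_spec(n_subjects = 800, hallmark_effect = 0.5,
                                    seed = 19))
  comp <- cohort_composite(co)
  ct <- cor.test(comp$delta, co$truth$z_hallmark)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  prog <- co$truth$progressed | co$truth$baseline_dx == "AD"
  expect_lt(mean(co$outcomes$tbm_temporal[prog]), 0)    # tissue loss
  expect_gt(mean(co$outcomes$tbm_ventricle[prog]), 0)   # expansion
  expect_lt(mean(co$outcomes$tbm_temporal[prog]),
            mean(co$outcomes$tbm_temporal[!prog]))
  # APOE-like allele count roughly matches the planted 70/25/5 thresholds
  apoe <- ft_data(co$features)[, "apoe4"]
  expect_equal(as.numeric(prop.table(table(apoe))), c(0.7, 0.25, 0.05),
               tolerance = 0.15)
})

test_that("left/right region pairs share a strong lateral correlation", {
  co <- generate_cohort(cohort_spec(n_subjects = 1000, n_roi_pairs = 4, seed = 20))
  m <- ft_data(co$features)
  lr <- sapply(1:4, function(r) {
    cor(m[, sprintf("roi%02d_L_volume", r)], m[, sprintf("roi%02d_R_volume", r)])
  })
  expect_true(all(lr >= 0.4))  # planted lateral latent, attenuated by noise
})

test_that("cohorts round-trip bit-identically through write/read", {
  co <- generate_cohort(cohort_spec(
    n_subjects = 60, n_plasma_blocks = 3, block_sizes = c(4, 4, 4),
    block_loading = 0.8, n_noise_analytes = 3, n_roi_pairs = 2, seed = 5))
  dir <- withr::local_tempdir()
  target <- file.path(dir, "cohort")      # created by write_cohort
  write_cohort(co, target)
  co2 <- read_cohort(target)
  expect_identical(ft_data(co$features), ft_data(co2$features))
  expect_identical(ft_classes(co$features), ft_classes(co2$features))
  expect_identical(as.data.frame(co$diagnoses), as.data.frame(co2$diagnoses))
  expect_equal(co$outcomes, co2$outcomes, tolerance = 0)
  expect_equal(unname(co$truth$z_hallmark), unname(co2$truth$z_hallmark),
               tolerance = 0)
  # refuses to overwrite without force, then accepts with it
  expect_error(write_cohort(co, target), "force")
  expect_silent(write_cohort(co, target, force = TRUE))
})

test_that("optional MCAR missingness hits roughly the requested rate", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, missing_rate = 0.1, seed = 21))
  expect_lt(abs(mean(is.na(ft_data(co$features))) - 0.1), 0.01)
})
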