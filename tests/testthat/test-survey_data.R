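test_that("constructor validates dimensions, modes and missingness", {
  y <- matrix(c(1, 0, NA, 1), 2, 2)
  d <- make_binary_data(y, site_covs = data.frame(MST = c(10, 20)))
  expect_s3_class(d, "survey_data")
  expect_identical(sum(is.na(d$y)), 1L)

  expect_error(make_binary_data(matrix(c(0, 2), 1, 2)), "binary")
  expect_error(make_count_data(matrix(c(0, 1.5), 1, 2)), "integer")
  expect_error(make_count_data(matrix(c(0, -1), 1, 2)), "integer|nonneg")
  expect_error(survey_data(y, site_covs = data.frame(MST = 1:3)),
               "one row per site")
  expect_error(survey_data(y, visit_covs = list(TOD = matrix(0, 3, 2))),
               "n_sites x n_visits")
  # optional inputs absent -> still valid
  expect_s3_class(make_binary_data(y), "survey_data")
})

test_that("read_survey reads the CSV layout and preserves blanks as missing", {
  dir <- withr::local_tempdir()
  writeLines(c("site_id,v1,v2,v3,v4",
               "s1,1,0,,1",
               "s2,0,0,0,0",
               "s3,1,1,0,0"), file.path(dir, "det.csv"))
  writeLines(c("site_id,MST,CAN",
               "s1,14,26", "s2,11,20", "s3,17,28"),
             file.path(dir, "site.csv"))
  writeLines(c("site_id,v1,v2,v3,v4",
               "s1,3,1,4,2", "s2,5,2,3,3", "s3,1,0,2,6"),
             file.path(dir, "cwd.csv"))
  d <- read_survey(file.path(dir, "det.csv"), file.path(dir, "site.csv"),
                   c(CWD = file.path(dir, "cwd.csv")), mode = "binary")
  expect_equal(nrow(d$y), 3)
  expect_equal(ncol(d$y), 4)
  expect_true(is.na(d$y["s1", "v3"]))
  expect_equal(d$site_covs["s2", "MST"], 11)
  expect_equal(d$visit_covs$CWD[3, 4], 6)

  # unknown site id in covariate file
  writeLines(c("site_id,MST", "s1,14", "s2,11", "s9,17"),
             file.path(dir, "bad.csv"))
  expect_error(read_survey(file.path(dir, "det.csv"),
                           file.path(dir, "bad.csv"), mode = "binary"),
               "unknown site ids")
})

test_that("write_survey / read_survey round-trips the numeric payload", {
  covs <- simulate_covariates(12, 4, seed = 11)
  sim <- simulate_occupancy_data(c(`(Intercept)` = 0.5),
                                 c(`(Intercept)` = -0.3), covs, seed = 12)
  d <- sim$dataset
  d$y[2, 3] <- NA
  dir <- withr::local_tempdir()
  paths <- write_survey(d, dir)
  d2 <- read_survey(paths[["detections"]], paths[["site_covs"]],
                    paths[names(d$visit_covs)], mode = "binary")
  expect_identical(unname(d2$y), unname(d$y))
  expect_equal(as.matrix(d2$site_covs), as.matrix(d$site_covs))
  for (nm in names(d$visit_covs))
    expect_equal(unname(d2$visit_covs[[nm]]), unname(d$visit_covs[[nm]]))
  # and a second write is byte-identical
  dir2 <- withr::local_tempdir()
  write_survey(d2, dir2)
  expect_identical(readLines(file.path(dir2, "detections.csv")),
                   readLines(file.path(dir, "detections.csv")))
})

test_that("standardization yields exact z-scores and is affine-invariant", {
  y <- matrix(0, 3, 2)
  d <- make_binary_data(y, site_covs = data.frame(MST = c(11, 14, 17)))
  out <- standardize_covariates(d, "MST")
  z <- out$data$site_covs$MST
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::var(z), 1, tolerance = 1e-12)
  expect_equal(z, (c(11, 14, 17) - 14) / 3, tolerance = 1e-12)
  expect_equal(out$record$mean, 14)
  expect_equal(out$record$sd, 3)

  # idempotence on z-scores
  out2 <- standardize_covariates(out$data, "MST")
  expect_equal(out2$data$site_covs$MST, z, tolerance = 1e-12)

  # affine invariance of the z-scores
  d_scaled <- make_binary_data(y, site_covs = data.frame(MST = 5 + 2 * c(11, 14, 17)))
  z2 <- standardize_covariates(d_scaled, "MST")$data$site_covs$MST
  expect_equal(z2, z, tolerance = 1e-10)

  # constant covariate errors by name
  d_const <- make_binary_data(y, site_covs = data.frame(ELV = c(7, 7, 7)))
  expect_error(standardize_covariates(d_const, "ELV"), "ELV")

  # visit covariates standardized over all site-visits
  d_v <- make_binary_data(y, visit_covs = list(TOD = matrix(1:6, 3, 2)))
  zv <- standardize_covariates(d_v, "TOD")$data$visit_covs$TOD
  expect_equal(mean(zv), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(zv)), 1, tolerance = 1e-12)
})

test_that("naive POA counts sites with any detection and ignores visit order", {
  set.seed(42)
  y <- matrix(0, 40, 4)
  rows <- sample(40, 25)
  for (i in rows) y[i, sample(4, 1)] <- 1
  d <- make_binary_data(y)
  expect_equal(naive_poa(d), 25 / 40)
  expect_equal(round_half_up(naive_poa(d), 2), 0.63)

  y[setdiff(seq_len(40), rows)[1], 2] <- 1
  expect_equal(naive_poa(make_binary_data(y)), 26 / 40)

  expect_equal(naive_poa(make_binary_data(matrix(0, 5, 3))), 0)

  # invariant under column permutation
  perm <- make_binary_data(y[, c(3, 1, 4, 2)])
  expect_equal(naive_poa(perm), naive_poa(make_binary_data(y)))

  # missing visits don't create detections
  y2 <- matrix(NA, 2, 3); y2[1, 1] <- 1; y2[2, 2] <- 0
  expect_equal(naive_poa(make_binary_data(y2)), 0.5)

  expect_error(naive_poa(make_count_data(matrix(2, 1, 2))), "binarize")
})

test_that("Beers aspect hits the published endpoints and wraps out-of-range", {
  expect_equal(beers_aspect(45), 2)
  expect_equal(beers_aspect(225), 0)
  expect_equal(beers_aspect(135), 1)
  expect_true(all(beers_aspect(seq(0, 359.9, by = 0.1)) >= 0))
  expect_true(all(beers_aspect(seq(0, 359.9, by = 0.1)) <= 2))
  expect_warning(w <- beers_aspect(405), "wrapped")
  expect_equal(w, beers_aspect(45))
})

test_that("TPI scale selection maximizes |r| with smallest-scale tie-break", {
  counts <- c(2, 5, 1, 7, 4, 3)
  # single candidate
  expect_equal(select_tpi_scale(list(`50` = rnorm(6)), counts)$scale, "50")

  # constructed winner: exact linear function of counts at scale 150
  set.seed(7)
  tab <- list(`50` = rnorm(6), `100` = rnorm(6),
              `150` = 3 * counts - 1, `200` = rnorm(6))
  sel <- select_tpi_scale(tab, counts)
  expect_equal(sel$scale, "150")
  expect_equal(sel$r, 1, tolerance = 1e-12)
  # full correlation table matches a brute-force loop
  brute <- vapply(tab, function(v) cor(v, counts), numeric(1))
  expect_equal(sel$correlations$r, unname(brute), tolerance = 1e-12)

  # tie on |r| -> smaller scale (negative r counts via magnitude)
  tie <- list(`300` = counts, `100` = -counts)
  expect_equal(select_tpi_scale(tie, counts)$scale, "100")

  # constant vector excluded with warning
  expect_warning(sel2 <- select_tpi_scale(
    list(`50` = rep(1, 6), `100` = counts), counts), "excluded")
  expect_equal(sel2$scale, "100")
})
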