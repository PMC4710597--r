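# Synthetic cohort generator: determinism, structural invariants,
# calibration of the stratified medians, and CSV round-trips.

test_that("generation is deterministic given the seed", {
  a <- quick_cohort(n = 150, seed = 42)
  b <- quick_cohort(n = 150, seed = 42)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$survival, b$survival)
  c2 <- quick_cohort(n = 150, seed = 43)
  expect_false(identical(a$methylation, c2$methylation))
})

test_that("cohort tables satisfy their structural invariants", {
  cc <- quick_cohort(n = 1200, seed = 7)
  d <- cc$cohort
  s <- cc$survival
  m <- cc$methylation

  nev <- !is.na(d$smoking_status) & d$smoking_status == "never"
  cur <- !is.na(d$smoking_status) & d$smoking_status == "current"
  expect_true(all(d$pack_years[nev] == 0, na.rm = TRUE))
  expect_true(all(is.na(d$years_since_cessation[nev | cur])))
  expect_true(all(d$age >= 50 & d$age <= 75))
  expect_true(all(d$cigarettes_per_day[cur] > 0, na.rm = TRUE))

  bmat <- as.matrix(m[, methrisk_cpgs])
  expect_true(all(bmat >= 0 & bmat <= 1, na.rm = TRUE))
  expect_true(all(colSums(is.na(bmat)) <= 4)) # per-CpG missing cap

  expect_true(all(s$time > 0))
  expect_true(all(s$time <= 11.3))
  expect_true(all(s$cause[s$event == 0] == "none"))
  expect_true(all(is.na(s$cause[s$event == 1 & !s$cause_known])))
  expect_true(all(s$cause[s$event == 1 & s$cause_known] %in%
    c("cvd", "cancer", "other")))
})

test_that("stratified medians reproduce the calibration targets", {
  cc <- quick_cohort(n = 10000, seed = 11)
  d <- cc$cohort
  m <- cc$methylation
  med <- function(cg, st) {
    i <- !is.na(d$smoking_status) & d$smoking_status == st
    median(m[[cg]][i], na.rm = TRUE)
  }
  expect_equal(med("cg05575921", "never"), 0.88, tolerance = 0.011)
  expect_equal(med("cg05575921", "current"), 0.63, tolerance = 0.016)
  expect_equal(med("cg06126421", "never"), 0.70, tolerance = 0.011)
  expect_equal(med("cg06126421", "current"), 0.57, tolerance = 0.016)
  # former smokers sit between the two
  expect_true(med("cg05575921", "former") < med("cg05575921", "never"))
  expect_true(med("cg05575921", "former") > med("cg05575921", "current"))
})

test_that("zero smoking effects and zero correlation give independent CpGs", {
  prof <- default_cpg_profiles()
  prof$current_offset[] <- 0
  prof$former_offset[] <- 0
  cc <- generate_cohort(sim_config(
    n_participants = 5000, seed = 5, cpg_profiles = prof,
    inter_cpg_correlation = diag(9)
  ))
  sp <- spearman_matrix(cc$methylation)
  off <- sp[upper.tri(sp)]
  expect_true(all(abs(off) < 0.05))
})

test_that("generator mean declines monotonically with smoked dose", {
  cfg <- sim_config()
  mu0 <- generator_mean_beta(cfg, "never")
  mu10 <- generator_mean_beta(cfg, "current",
    cigarettes_per_day = 10, pack_years = 20
  )
  mu30 <- generator_mean_beta(cfg, "current",
    cigarettes_per_day = 30, pack_years = 60
  )
  nz <- cfg$cpg_profiles$current_offset < 0
  expect_true(all(mu30[, nz] < mu10[, nz]))
  expect_true(all(mu10[, nz] < mu0[, nz]))
  # cessation recovery: mean rises with years since quitting
  mu_f2 <- generator_mean_beta(cfg, "former",
    pack_years = 29, years_since_cessation = 2
  )
  mu_f20 <- generator_mean_beta(cfg, "former",
    pack_years = 29, years_since_cessation = 20
  )
  expect_true(all(mu_f20[, nz] > mu_f2[, nz]))
})

test_that("death fraction is near the 14.3% target", {
  cc <- quick_cohort(n = 10000, seed = 19)
  expect_gt(mean(cc$survival$event), 0.143 - 0.03)
  expect_lt(mean(cc$survival$event), 0.143 + 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(
    sim_config(smoking_prevalence = c(0.5, 0.3, 0.1)),
    "sum to 1"
  )
  expect_error(sim_config(cause_mix = c(0.5, 0.5, 0.5)), "sum to 1")
  bad <- default_cpg_correlation()
  bad[1, 2] <- bad[2, 1] <- -0.99 # breaks PSD with the other 0.55 entries
  expect_error(sim_config(inter_cpg_correlation = bad), "positive semi")
  asym <- default_cpg_correlation()
  asym[1, 2] <- 0.9
  expect_error(sim_config(inter_cpg_correlation = asym), "symmetric")
  prof <- default_cpg_profiles()
  prof$never_mean[1] <- 1.2
  expect_error(sim_config(cpg_profiles = prof), "in \\(0, 1\\)")
})

test_that("cohort CSV round-trip is lossless", {
  cc <- quick_cohort(n = 80, seed = 3)
  dir <- tempfile("io_")
  write_cohort(cc, dir)
  back <- read_cohort(dir)
  expect_identical(back$cohort, cc$cohort)
  expect_identical(back$methylation, cc$methylation)
  expect_identical(back$survival, cc$survival)
})

test_that("reading invalid or empty cohorts behaves as specified", {
  cc <- quick_cohort(n = 20, seed = 3)
  dir <- tempfile("io_")
  write_cohort(cc, dir)
  # corrupt a beta-value beyond 1
  m <- read.csv(file.path(dir, "methylation.csv"), check.names = FALSE)
  m$cg05575921[1] <- 1.2
  write.csv(m, file.path(dir, "methylation.csv"), row.names = FALSE, na = "")
  expect_error(read_cohort(dir), "outside")

  # key mismatch
  dir2 <- tempfile("io_")
  write_cohort(cc, dir2)
  s <- read.csv(file.path(dir2, "survival.csv"), check.names = FALSE)
  s$participant_id[1] <- 999L
  write.csv(s, file.path(dir2, "survival.csv"), row.names = FALSE, na = "")
  expect_error(read_cohort(dir2), "keys differ")

  # empty cohort round-trips to empty valid files
  e <- generate_cohort(sim_config(n_participants = 0))
  dir3 <- tempfile("io_")
  write_cohort(e, dir3)
  back <- read_cohort(dir3)
  expect_equal(nrow(back$cohort), 0)
  expect_equal(names(back$methylation), names(e$methylation))
})
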