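test_that("the generator is deterministic in the seed and schema-stable", {
  a <- simulateCohort(cohortConfig(seed = 5), seed = 5)
  b <- simulateCohort(cohortConfig(seed = 5), seed = 5)
  expect_identical(measureTable(a), measureTable(b))
  expect_identical(subjectData(a), subjectData(b))
  c2 <- simulateCohort(cohortConfig(seed = 6), seed = 6)
  expect_false(identical(measureTable(a)$value, measureTable(c2)$value))
  expect_identical(measureTable(a)[, 1:4], measureTable(c2)[, 1:4])
  expect_equal(ncol(a), 57)
  expect_equal(range(subjectData(a)$age_months) >= c(14, 14), c(TRUE, TRUE))
  expect_lte(max(subjectData(a)$age_months), 71)
  expect_equal(sum(subjectData(a)$sex == "male"), 41)
})

test_that("a symmetric generator yields near-zero mean AI per region", {
  co <- simulateCohort(clearLateralization(cohortConfig(seed = 55)),
                       seed = 55)
  ai <- computeAsymmetry(co)
  pa <- populationAverageAsymmetry(ai)
  for (i in seq_len(nrow(pa))) {
    v <- ai$ai[ai$region == pa$region[i] & ai$measure == pa$measure[i]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(pa$mean_ai[i]), 4 * se + 1e-9)
  }
})

test_that("noiseless linear generation is recovered exactly", {
  cfg <- volOnlyConfig(66)
  cfg$region_specs$sd <- 0
  cfg$etiv_sd <- 0
  co <- simulateCohort(cfg, seed = 66)
  s <- subjectData(co)
  m <- measureTable(co)
  d <- m[m$region == "thalamus" & m$hemisphere == "left", ]
  i <- match(d$subject_id, s$subject_id)
  fit <- fitTrajectory(s$age_months[i], d$value, s$sex[i])
  expect_lt(abs(fit$edf - 1), 0.05)
  cv <- fit$fitted_curve
  slope <- (cv$fit[nrow(cv)] - cv$fit[1]) /
    (cv$age_months[nrow(cv)] - cv$age_months[1])
  expect_equal(slope, 9, tolerance = 1e-6)  # generator slope for thalamus
  # and the symmetric noiseless cohort has AI identically zero
  ai <- computeAsymmetry(co, measures = "volume")
  expect_equal(max(abs(ai$ai)), 0)
})

test_that("window-mean AI matches the closed-form lateralization ramp", {
  T0 <- 36; delta <- 0.15
  set.seed(101)
  diffs <- replicate(30, {
    seed <- sample.int(1e6, 1)
    cfg <- plantLateralization(volOnlyConfig(seed), "superiortemporal",
                               "volume", T0, delta)
    co <- simulateCohort(cfg, seed = seed)
    ai <- computeAsymmetry(co, measures = "volume")
    ai <- ai[ai$region == "superiortemporal", ]
    s <- subjectData(co)
    w <- buildWindows(s$age_months, ids = s$subject_id)
    gt <- groundTruth(co)
    mid <- nrow(w) %/% 2
    sapply(c(2, mid, nrow(w) - 1), function(j) {
      ids <- w$members[[j]]
      obs <- mean(ai$ai[ai$subject_id %in% ids])
      expct <- mean(truthAsymmetry(gt, "superiortemporal", "volume",
                                   s$age_months[match(ids, s$subject_id)]))
      obs - expct
    })
  })
  # per-window noise is ~0.04/sqrt(12); averaging 30 cohorts shrinks it
  expect_lt(max(abs(rowMeans(diffs))), 0.01)
})

test_that("stratified sampling reproduces the configured group sizes", {
  set.seed(1)
  cfg <- cohortConfig(age_sampling = "stratified", seed = 77)
  co <- simulateCohort(cfg, seed = 77)
  expect_equal(as.integer(table(subjectData(co)$age_group)),
               c(7L, 15L, 14L, 11L, 10L))
})

test_that("the marginal age distribution matches the configured uniform", {
  rs <- defaultRegionSpecs()
  cfg <- cohortConfig(n_subjects = 1500,
                      region_specs = rs[rs$region == "thalamus" &
                                          rs$measure == "volume", ],
                      seed = 88)
  co <- simulateCohort(clearLateralization(cfg), seed = 88)
  ks <- suppressWarnings(
    ks.test(subjectData(co)$age_months, "punif", 14, 71))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid generator configs are rejected before sampling", {
  expect_error(cohortConfig(n_subjects = 0), "n_subjects")
  expect_error(cohortConfig(age_min = 40, age_max = 30), "age_min")
  expect_error(cohortConfig(male_fraction = 1.2), "male_fraction")
  expect_error(cohortConfig(etiv_sd = -1), "SD")
  cfg <- cohortConfig()
  expect_error(plantLateralization(cfg, "thalamus", "volume", 30, 1.5),
               "delta")
  expect_error(plantLateralization(cfg, "nonexistent", "volume", 30, 0.1),
               "no generator spec")
  expect_error(cohortConfig(age_sampling = "stratified", n_subjects = 40),
               "sum")
})

test_that("fixture trees are byte-stable and sized to the cohort", {
  co <- tinyCohort(seed = 3, n = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFixture(co, d1, "freesurfer_stats_tree")
  writeFixture(tinyCohort(seed = 3, n = 3), d2, "freesurfer_stats_tree")
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # one directory per subject plus participants.tsv
  expect_length(list.dirs(d1, recursive = FALSE), 3)
})
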