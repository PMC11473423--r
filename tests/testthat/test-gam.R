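ages57 <- function(seed = 2) {
  set.seed(seed)
  list(age = runif(57, 14, 71),
       sex = sample(c("male", "female"), 57, replace = TRUE))
}

test_that("noiseless linear data collapse to a line (edf 1, linear by BIC)", {
  d <- ages57()
  fit <- fitTrajectory(d$age, 2 + 0.05 * d$age, d$sex)
  expect_lt(abs(fit$edf - 1), 0.05)
  expect_lt(abs(fit$sex_coefficient), 1e-6)
  expect_equal(fit$selected_model, "linear")
  # recovered slope from the fitted curve
  slope <- diff(fit$fitted_curve$fit[c(1, nrow(fit$fitted_curve))]) /
    diff(fit$fitted_curve$age_months[c(1, nrow(fit$fitted_curve))])
  expect_equal(slope, 0.05, tolerance = 1e-6)
})

test_that("noiseless quadratic with an interior peak is localized", {
  d <- ages57()
  y <- 5 - 0.002 * (d$age - 40)^2
  fit <- fitTrajectory(d$age, y, d$sex)
  expect_gt(fit$edf, 1)
  peak <- fit$fitted_curve$age_months[which.max(fit$fitted_curve$fit)]
  expect_lte(abs(peak - 40), 1)
  expect_equal(fit$selected_model, "smooth")
})

test_that("edf stays within [1, k - 1] across noisy fits", {
  d <- ages57(seed = 9)
  for (i in 1:10) {
    set.seed(100 + i)
    y <- 3 + 0.02 * d$age + rnorm(57, 0, 0.5)
    fit <- fitTrajectory(d$age, y, d$sex)
    expect_gte(fit$edf, 1 - 1e-6)
    expect_lte(fit$edf, fit$spec$k - 1 + 1e-6)
    expect_gt(fit$p_value, 0)
    expect_lte(fit$p_value, 1)
  }
})

test_that("BIC selection recovers the generating model class", {
  d <- ages57(seed = 4)
  set.seed(1)
  y_lin <- 10 + 0.1 * d$age + rnorm(57, 0, 0.3)
  expect_equal(fitTrajectory(d$age, y_lin, d$sex)$selected_model, "linear")
  set.seed(2)
  y_smooth <- 5 * sin(d$age / 8) + rnorm(57, 0, 0.3)
  expect_equal(fitTrajectory(d$age, y_smooth, d$sex)$selected_model,
               "smooth")
  # exact ties break toward the simpler model
  expect_equal(selectByBIC(c(intercept = 1, linear = 1, smooth = 1)),
               "intercept")
  expect_equal(selectByBIC(c(smooth = 0.5, linear = 0.5, intercept = 1)),
               "linear")
})

test_that("sex adjustment absorbs a constant between-sex offset", {
  d <- ages57(seed = 6)
  set.seed(3)
  y <- 2 + 0.03 * d$age + rnorm(57, 0, 0.2)
  f0 <- fitTrajectory(d$age, y, d$sex)
  y2 <- y + ifelse(d$sex == "male", 5, 0)
  f1 <- fitTrajectory(d$age, y2, d$sex)
  expect_equal(f1$sex_coefficient - f0$sex_coefficient, 5,
               tolerance = 1e-6)
  # the age trajectory itself is unchanged up to the sex-mean shift
  expect_equal(f1$fitted_curve$fit - f0$fitted_curve$fit,
               rep(2.5, nrow(f0$fitted_curve)), tolerance = 1e-6)
  expect_equal(f1$edf, f0$edf, tolerance = 1e-3)
})

test_that("trajectory fitting rejects unusable inputs", {
  expect_error(fitTrajectory(1:5, 1:5, rep("male", 5)), "at least 10")
  expect_error(fitTrajectory(rep(20, 12), rnorm(12),
                             rep(c("male", "female"), 6)), "not all")
  expect_error(fitTrajectory(c(1:11, NA), rnorm(12),
                             rep(c("male", "female"), 6)), "missing")
})

test_that("BH adjustment matches brute-force step-up", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdrAdjust(c(0.5, 0)), "0, 1")
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(3:8, 1))
    q <- fdrAdjust(p)
    expect_equal(q, bruteBH(p))
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
})

test_that("regional fit tables have the family bookkeeping", {
  co <- simulateCohort(volOnlyConfig(23), seed = 23)
  tv <- fitAllRegions(co, "volume")
  expect_equal(nrow(tv), 22)  # 11 regions x 2 hemispheres
  expect_setequal(unique(tv$region), frontolimbicRegions())
  for (h in c("left", "right")) {
    p <- tv$p_value[tv$hemisphere == h]
    expect_equal(tv$q_value[tv$hemisphere == h], bruteBH(p))
  }
  expect_true(all(tv$q_value >= tv$p_value))
  curves <- attr(tv, "curves")
  expect_length(curves, 22)
})

test_that("a planted strongly age-dependent region attains the smallest q", {
  cfg <- volOnlyConfig(29)
  rs <- cfg$region_specs
  rs$form <- "constant"; rs$p2 <- 0                 # flat null regions
  i <- rs$region == "superiortemporal"
  rs$form[i] <- "linear"; rs$p1[i] <- 4500; rs$p2[i] <- 60  # strong trend
  cfg$region_specs <- rs
  co <- simulateCohort(cfg, seed = 29)
  tv <- fitAllRegions(co, "volume")
  for (h in c("left", "right")) {
    sub <- tv[tv$hemisphere == h, ]
    expect_equal(sub$region[which.min(sub$q_value)], "superiortemporal")
    expect_lt(min(sub$q_value), 0.05)
  }
})

test_that("ANOVA with Fisher's LSD matches its textbook special cases", {
  set.seed(7)
  x <- c(rnorm(10, 0), rnorm(10, 10))
  g <- rep(c("a", "b"), each = 10)
  res <- groupAnovaLSD(x, g)
  expect_lt(res$p_value, 0.001)
  # two groups: LSD pairwise p equals the pooled-variance t-test p
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(unname(res$pairwise["b", "a"]), tt$p.value,
               tolerance = 1e-12)
  expect_error(groupAnovaLSD(rnorm(3), c("a", "a", "b")), ">= 2 members")
  expect_error(groupAnovaLSD(rnorm(4), rep("a", 4)), "2 groups")
})
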