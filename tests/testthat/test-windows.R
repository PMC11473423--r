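test_that("window construction follows the stated conventions", {
  ages <- 14:71
  w <- buildWindows(ages, width = 12, stride = 1)
  expect_equal(w$start[1], 14)
  expect_equal(w$end[1], 26)
  expect_equal(w$midpoint[1], 20)
  expect_equal(w$members[[1]], which(ages >= 14 & ages < 26))
  expect_equal(diff(w$start), rep(1, nrow(w) - 1))
  wi <- buildWindows(ages, width = 12, stride = 1,
                     convention = "integer-inclusive")
  expect_equal(wi$end[1], 25)
  expect_equal(wi$midpoint[1], 19.5)
  expect_equal(wi$members[[1]], w$members[[1]])  # membership unchanged

  # width beyond the whole span: a single all-subject window
  w1 <- buildWindows(ages, width = 100)
  expect_equal(nrow(w1), 1)
  expect_length(w1$members[[1]], length(ages))

  expect_error(buildWindows(numeric(0)), "empty")
})

test_that("every subject is covered by at least one window", {
  set.seed(33)
  for (i in 1:20) {
    ages <- runif(sample(5:60, 1), 10, 80)
    ids <- seq_along(ages)
    w <- buildWindows(ages, ids = ids, width = sample(6:18, 1),
                      stride = sample(c(1, 2, 3, 6), 1))
    expect_setequal(unique(unlist(w$members)), ids)
  }
  # contiguous coverage requires stride <= width; wider strides warn
  expect_warning(buildWindows(runif(20, 10, 80), width = 6, stride = 12),
                 "gaps")
})

test_that("signed-rank p-values are exact for small samples", {
  r <- wilcoxonSignedRank(c(1, 2, 3))
  expect_equal(r$p.value, 0.25)   # 2/2^3, smallest attainable two-sided p
  expect_equal(r$statistic, 6)
  # antisymmetric input: p identical, W reflected to n(n+1)/2 - W
  x <- c(0.3, -1.2, 2.1, 0.7, -0.4)
  a <- wilcoxonSignedRank(x); b <- wilcoxonSignedRank(-x)
  expect_equal(a$p.value, b$p.value)
  expect_equal(b$statistic, length(x) * (length(x) + 1) / 2 - a$statistic)
  # total ties still get an exact enumeration
  const <- wilcoxonSignedRank(rep(0.2, 10))
  expect_equal(const$p.value, 2 / 2^10)
  expect_equal(const$method, "exact-enumeration")
  # zeros are dropped; all-zero input is untestable
  expect_warning(z <- wilcoxonSignedRank(rep(0, 4)), "undefined")
  expect_true(is.na(z$p.value))
  expect_equal(wilcoxonSignedRank(c(0, 0, 1, 2, 3))$p.value, 0.25)
})

test_that("exact p equals brute-force sign-pattern enumeration", {
  set.seed(44)
  for (i in 1:80) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n, 0.3), if (i %% 3 == 0) 1 else 6)  # some with ties
    x <- x[x != 0]
    if (length(x) < 1) next
    r <- wilcoxonSignedRank(x)
    expect_equal(r$p.value, bruteWilcoxonP(x), tolerance = 1e-12)
  }
})

test_that("window tests bookkeeping, families and directions are coherent", {
  co <- simulateCohort(volOnlyConfig(3), seed = 3)
  ai <- computeAsymmetry(co, measures = "volume")
  s <- subjectData(co)
  w <- buildWindows(s$age_months, ids = s$subject_id)
  wt <- testWindows(ai, w)
  expect_equal(nrow(wt), nrow(w) * 11)
  # BH family: across regions within each (window, measure)
  one <- wt[wt$window_id == wt$window_id[which(!is.na(wt$p_value))[1]], ]
  expect_equal(one$q_value[!is.na(one$p_value)],
               bruteBH(one$p_value[!is.na(one$p_value)]))
  # untestable windows carry NA
  expect_true(all(is.na(wt$p_value[wt$n < 5])))
  expect_true(all(is.na(wt$direction[wt$n < 5])))
  sig <- !is.na(wt$q_value) & wt$q_value < 0.05
  expect_true(all(wt$direction[sig & wt$mean_ai > 0] == "left"))
  expect_true(all(wt$direction[sig & wt$mean_ai < 0] == "right"))
  expect_true(all(wt$q_value >= wt$p_value, na.rm = TRUE))
})

test_that("constant positive AI in a window attains the exact minimum p", {
  ai <- data.frame(subject_id = sprintf("s%d", 1:10), region = "fusiform",
                   measure = "volume", ai = 0.2)
  w <- buildWindows(rep(20, 10), ids = ai$subject_id, width = 12)
  wt <- testWindows(ai, w)
  expect_equal(wt$p_value, 2 / 2^10)
  expect_equal(wt$direction, "left")
})

test_that("emergence is the earliest significant window midpoint", {
  wr <- data.frame(region = "fusiform", measure = "volume",
                   window_id = 1:5, start = 1:5, end = 13:17,
                   midpoint = 7:11, n = 10, mean_ai = 0.1,
                   w_statistic = 50,
                   p_value = c(NA, 0.2, 0.01, 0.5, 0.001),
                   q_value = c(NA, 0.2, 0.01, 0.5, 0.001),
                   direction = c(NA, "none", "left", "none", "left"))
  em <- detectEmergence(wr)
  expect_equal(em$initial_point_months, 9)
  expect_equal(em$asymmetry_direction, "left")
  expect_equal(em$q_at_initial_point, 0.01)
  # nothing significant -> NA row
  wr$q_value <- c(NA, 0.9, 0.8, 0.9, 0.7)
  em2 <- detectEmergence(wr)
  expect_true(is.na(em2$initial_point_months))
  expect_true(is.na(em2$asymmetry_direction))
})

test_that("raising alpha never delays the initial point", {
  co <- simulateCohort(cohortConfig(seed = 15), seed = 15)
  ai <- computeAsymmetry(co)
  s <- subjectData(co)
  w <- buildWindows(s$age_months, ids = s$subject_id)
  wt <- testWindows(ai, w)
  em_lo <- detectEmergence(wt, alpha = 0.01)
  em_hi <- detectEmergence(wt, alpha = 0.10)
  k <- paste(em_lo$region, em_lo$measure)
  em_hi <- em_hi[match(k, paste(em_hi$region, em_hi$measure)), ]
  both <- !is.na(em_lo$initial_point_months)
  expect_true(all(em_hi$initial_point_months[both] <=
                    em_lo$initial_point_months[both]))
  expect_true(all(!is.na(em_hi$initial_point_months[both])))
})

test_that("population averages agree with direct recomputation", {
  ai <- data.frame(subject_id = c("a", "b"), region = "thalamus",
                   measure = "volume", ai = c(0.1, -0.1))
  pa <- populationAverageAsymmetry(ai)
  expect_equal(pa$mean_ai, 0)
  expect_equal(pa$direction, "none")

  co <- tinyCohort(seed = 2, n = 6)
  ai2 <- computeAsymmetry(co, measures = "volume")
  pa2 <- populationAverageAsymmetry(ai2)
  for (i in seq_len(nrow(pa2))) {
    v <- ai2$ai[ai2$region == pa2$region[i]]
    expect_equal(pa2$mean_ai[i], mean(v))
    expect_equal(pa2$direction[i],
                 if (mean(v) > 0) "left" else if (mean(v) < 0) "right"
                 else "none")
  }
  expect_true(all(pa2$direction[pa2$mean_ai > 0] == "left"))
})

test_that("a whole-range window reduces to the whole-cohort test", {
  co <- simulateCohort(volOnlyConfig(71), seed = 71)
  ai <- computeAsymmetry(co, measures = "volume")
  s <- subjectData(co)
  w <- buildWindows(s$age_months, ids = s$subject_id, width = 1000)
  wt <- testWindows(ai, w)
  expect_equal(nrow(wt), 11)
  for (i in seq_len(nrow(wt))) {
    ref <- wilcoxonSignedRank(ai$ai[ai$region == wt$region[i]])
    expect_equal(wt$p_value[i], ref$p.value)
    expect_equal(wt$w_statistic[i], ref$statistic)
  }
})

test_that("mirroring the hemispheres negates AI and preserves p and q", {
  co <- simulateCohort(cohortConfig(seed = 99), seed = 99)
  m <- measureTable(co)
  m$hemisphere <- ifelse(m$hemisphere == "left", "right", "left")
  co_m <- MorphoCohort(subjectData(co), m)
  ai <- computeAsymmetry(co)
  ai_m <- computeAsymmetry(co_m)
  k <- function(d) paste(d$subject_id, d$region, d$measure)
  ai_m <- ai_m[match(k(ai), k(ai_m)), ]
  expect_equal(ai_m$ai, -ai$ai, tolerance = 1e-12)
  s <- subjectData(co)
  w <- buildWindows(s$age_months, ids = s$subject_id)
  wt <- testWindows(ai, w); wt_m <- testWindows(ai_m, w)
  kk <- function(d) paste(d$region, d$measure, d$window_id)
  wt_m <- wt_m[match(kk(wt), kk(wt_m)), ]
  expect_equal(wt_m$p_value, wt$p_value, tolerance = 1e-12)
  expect_equal(wt_m$q_value, wt$q_value, tolerance = 1e-12)
  expect_equal(wt_m$mean_ai, -wt$mean_ai, tolerance = 1e-12)
  flip <- c(left = "right", right = "left", none = "none")
  ok <- !is.na(wt$direction)
  expect_equal(unname(flip[wt$direction[ok]]), wt_m$direction[ok])
})
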