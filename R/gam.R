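## Sex-adjusted penalized-spline developmental trajectories.
##
## Each (region, hemisphere, measure) series is modelled as
##   value = b0 + b_sex * 1[male] + s(age) + e
## with s() a penalized regression spline (mgcv). The effective degrees
## of freedom (edf) of the age smooth summarize trajectory complexity:
## edf = 1 is a straight line, edf > 1 curvature. Candidate models
## {intercept + sex, linear age + sex, smooth age + sex} are compared by
## BIC (edf-based parameter count for the smooth) and the most
## parsimonious (minimum-BIC, ties to the simpler model) is selected.

#' Smooth-term specification
#'
#' @param basis spline basis: `"cr"` (cubic regression spline, default)
#'   or `"tp"` (thin plate).
#' @param k basis dimension (>= 4; default 6, suiting cohorts of a few
#'   dozen subjects over a ~5-year age span). The maximum admissible
#'   edf is `k - 1`.
#' @param penalty smoothing-parameter selection criterion: `"REML"`
#'   (default) or `"GCV.Cp"`.
#' @return a `SmoothSpec` list.
#' @export
smoothSpec <- function(basis = c("cr", "tp"), k = 6L,
                       penalty = c("REML", "GCV.Cp")) {
  basis <- match.arg(basis)
  penalty <- match.arg(penalty)
  k <- as.integer(k)
  if (k < 4L) stopf("basis dimension k must be >= 4")
  structure(list(basis = basis, k = k, penalty = penalty),
            class = "SmoothSpec")
}

# Gaussian BIC with an explicit variance floor, used only when a
# candidate interpolates the data (residual variance ~ 0) and
# likelihood-based BIC diverges; the floor preserves the limit ordering
# (fewest parameters among interpolating candidates wins).
.flooredBIC <- function(rss, n, n_par, floor) {
  n * log(pmax(rss / n, floor)) + (n_par + 1) * log(n)
}

#' Fit one developmental trajectory
#'
#' Fits `value ~ sex + s(age)` by penalized least squares and reports
#' the smooth's effective degrees of freedom, the approximate F test of
#' the smooth term, BIC for the three candidate models and the
#' BIC-selected model, the sex coefficient (male minus female), and the
#' fitted sex-averaged curve with pointwise +/- 2 SE intervals on an
#' integer-month grid spanning the observed ages.
#'
#' When the linear (or intercept) model already interpolates the data
#' (relative residual sum of squares below 1e-10), penalized smoothing
#' parameter selection is ill-posed; the fit then returns the
#' infinite-penalty limit — the linear fit, edf = 1 — and BIC is
#' evaluated with a variance floor under which the simplest
#' interpolating candidate is selected.
#'
#' @param ages numeric vector, months.
#' @param values numeric response, same length.
#' @param sex character/factor `"male"`/`"female"`, same length.
#' @param spec a [smoothSpec()].
#' @return object of class `TrajectoryFit`: list with `edf`, `f_stat`,
#'   `p_value`, `bic_by_model`, `selected_model`, `sex_coefficient`,
#'   `fitted_curve` (data.frame `age_months`, `fit`, `lower`, `upper`),
#'   `n`, `spec`.
#' @export
fitTrajectory <- function(ages, values, sex, spec = smoothSpec()) {
  if (length(ages) != length(values) || length(ages) != length(sex))
    stopf("ages, values and sex must have equal length")
  if (anyNA(ages) || anyNA(values) || anyNA(sex))
    stopf("missing values must be filtered before fitting")
  n <- length(ages)
  if (n < 10L) stopf("at least 10 observations required (got %d)", n)
  if (length(unique(ages)) < 2L) stopf("ages must not all be equal")
  sex <- factor(as.character(sex), levels = c("female", "male"))
  if (anyNA(sex)) stopf("sex must be 'male' or 'female'")
  dat <- data.frame(y = values, age = ages, sex = sex)
  grid_age <- seq(floor(min(ages)), ceiling(max(ages)), by = 1)

  k <- spec$k
  n_distinct <- length(unique(ages))
  if (k >= n_distinct) {
    k <- max(4L, n_distinct - 1L)
    warnf("basis dimension reduced to %d (< %d distinct ages)", k,
          n_distinct)
  }

  lm1 <- lm(y ~ sex + age, data = dat)
  tss <- sum((values - mean(values))^2)
  rss1 <- sum(lm1$residuals^2)
  scale0 <- tss + .Machine$double.eps

  if (rss1 <= 1e-10 * scale0) {         # degenerate: (near-)exact fit
    floor_v <- tss / n * 1e-15 + 1e-300
    bics <- c(intercept = .flooredBIC(tss, n, 2, floor_v),
              linear = .flooredBIC(rss1, n, 3, floor_v),
              smooth = .flooredBIC(rss1, n, 3 + (k - 2), floor_v))
    sel <- selectByBIC(bics)
    cf <- coef(lm1)
    # summary.lm warns on interpolating fits; that is this branch's premise
    slope_t <- suppressWarnings(summary(lm1))$coefficients["age", ]
    f_stat <- unname(slope_t["t value"]^2)
    p <- unname(slope_t["Pr(>|t|)"])
    if (!is.finite(f_stat)) f_stat <- Inf
    if (!is.finite(p) || p <= 0) p <- .Machine$double.xmin
    pred <- cf["(Intercept)"] + cf["sexmale"] * 0.5 + cf["age"] * grid_age
    curve <- data.frame(age_months = grid_age, fit = unname(pred),
                        lower = unname(pred), upper = unname(pred))
    fit <- list(edf = 1, f_stat = f_stat, p_value = p,
                bic_by_model = bics, selected_model = sel,
                sex_coefficient = unname(cf["sexmale"]),
                fitted_curve = curve, n = n, spec = spec,
                degenerate = TRUE)
    class(fit) <- "TrajectoryFit"
    return(fit)
  }

  sfml <- stats::as.formula(sprintf("y ~ sex + s(age, bs = \"%s\", k = %d)",
                                    spec$basis, k))
  ms <- try(mgcv::gam(sfml, data = dat, method = spec$penalty), silent = TRUE)
  if (inherits(ms, "try-error")) {
    warnf("smooth fit failed (%s); falling back to the linear model",
          attr(ms, "condition")$message)
    ms <- NULL
  }
  m0 <- mgcv::gam(y ~ sex, data = dat, method = spec$penalty)
  m1 <- mgcv::gam(y ~ sex + age, data = dat, method = spec$penalty)
  bics <- c(intercept = BIC(m0), linear = BIC(m1),
            smooth = if (is.null(ms)) Inf else BIC(ms))
  sel <- selectByBIC(bics)

  if (is.null(ms)) {
    sm <- summary(m1)$p.table["age", , drop = FALSE]
    edf <- 1
    f_stat <- unname(sm[1, "t value"]^2)
    p <- unname(sm[1, "Pr(>|t|)"])
    use <- m1
  } else {
    sm <- summary(ms)
    edf <- unname(sm$edf[1])
    f_stat <- unname(sm$s.table[1, "F"])
    p <- unname(sm$s.table[1, "p-value"])
    use <- ms
  }
  p <- min(max(p, .Machine$double.xmin), 1)

  nd_f <- data.frame(age = grid_age, sex = factor("female",
                                                  levels = levels(sex)))
  nd_m <- data.frame(age = grid_age, sex = factor("male",
                                                  levels = levels(sex)))
  pf <- predict(use, nd_f, se.fit = TRUE)
  pm <- predict(use, nd_m, se.fit = TRUE)
  fitv <- (as.numeric(pf$fit) + as.numeric(pm$fit)) / 2
  sev <- sqrt(as.numeric(pf$se.fit)^2 + as.numeric(pm$se.fit)^2) / 2
  curve <- data.frame(age_months = grid_age, fit = fitv,
                      lower = fitv - 2 * sev, upper = fitv + 2 * sev)

  fit <- list(edf = edf, f_stat = f_stat, p_value = p,
              bic_by_model = bics, selected_model = sel,
              sex_coefficient = unname(coef(use)["sexmale"]),
              fitted_curve = curve, n = n, spec = spec,
              degenerate = FALSE)
  class(fit) <- "TrajectoryFit"
  fit
}

#' @export
print.TrajectoryFit <- function(x, ...) {
  cat(sprintf(
    "TrajectoryFit (n = %d): edf = %.3f, F = %.3f, p = %.3g\n", x$n,
    x$edf, x$f_stat, x$p_value))
  cat("  BIC:", paste(sprintf("%s %.1f", names(x$bic_by_model),
                              x$bic_by_model), collapse = ", "),
      "-> selected:", x$selected_model, "\n")
  invisible(x)
}

#' Most parsimonious model by BIC
#'
#' Returns the candidate with minimum BIC; exact ties break toward the
#' simpler model in the order intercept < linear < smooth.
#'
#' @param bics named numeric vector with names among `"intercept"`,
#'   `"linear"`, `"smooth"`.
#' @return the selected model name.
#' @export
selectByBIC <- function(bics) {
  ord <- c("intercept", "linear", "smooth")
  stopifnot(all(names(bics) %in% ord), length(bics) >= 1)
  bics <- bics[order(match(names(bics), ord))]
  names(bics)[which.min(bics)]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), monotone and capped at 1.
#' Applied separately per test family by the callers (8 cortical
#' fronto-limbic pairs for thickness, 11 pairs for volume).
#'
#' @param p_values numeric vector of p-values in (0, 1]; `NA` entries
#'   are passed through.
#' @return q-values, same length.
#' @export
fdrAdjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1))
    stopf("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Fit trajectories for all fronto-limbic regions
#'
#' One [fitTrajectory()] per (fronto-limbic region, hemisphere) for the
#' chosen measure — 11 region pairs for volume, the 8 cortical pairs
#' for thickness — on eTIV-relative volumes / hemisphere-relative
#' thickness by default. q-values are Benjamini-Hochberg within the
#' measure's family: by default separately per hemisphere (families of
#' 11 or 8 tests); `fdrFamily = "pooled"` corrects across both
#' hemispheres at once.
#'
#' @param cohort a [MorphoCohort-class].
#' @param measure `"volume"` or `"thickness"`.
#' @param spec a [smoothSpec()].
#' @param normalization `"relative"` (default) or `"absolute"`.
#' @param fdrFamily `"per-hemisphere"` (default) or `"pooled"`.
#' @return data.frame with one row per (region, hemisphere): `region`,
#'   `hemisphere`, `measure`, `n`, `edf`, `f_stat`, `p_value`,
#'   `q_value`, `selected_model`, `bic_intercept`, `bic_linear`,
#'   `bic_smooth`, `sex_coefficient`. Fitted curves are attached as
#'   `attr(, "curves")`, a named list of data.frames.
#' @export
fitAllRegions <- function(cohort, measure = c("volume", "thickness"),
                          spec = smoothSpec(),
                          normalization = c("relative", "absolute"),
                          fdrFamily = c("per-hemisphere", "pooled")) {
  measure <- match.arg(measure)
  normalization <- match.arg(normalization)
  fdrFamily <- match.arg(fdrFamily)
  regions <- if (measure == "thickness") frontolimbicRegions("cortical")
             else frontolimbicRegions("all")
  nm <- normalizeCohort(cohort, mode = normalization)
  nm <- nm[nm$measure == measure & nm$region %in% regions, , drop = FALSE]
  s <- subjectData(cohort)
  grid <- expand.grid(region = regions, hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  curves <- list()
  for (i in seq_len(nrow(grid))) {
    rg <- grid$region[i]; hm <- grid$hemisphere[i]
    d <- nm[nm$region == rg & nm$hemisphere == hm, , drop = FALSE]
    si <- match(d$subject_id, s$subject_id)
    fit <- try(fitTrajectory(s$age_months[si], d$value, s$sex[si],
                             spec = spec), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warnf("fit failed for %s/%s (%s); row recorded as NA", rg, hm,
            trimws(attr(fit, "condition")$message))
      rows[[i]] <- data.frame(region = rg, hemisphere = hm,
                              measure = measure, n = nrow(d), edf = NA_real_,
                              f_stat = NA_real_, p_value = NA_real_,
                              selected_model = NA_character_,
                              bic_intercept = NA_real_,
                              bic_linear = NA_real_, bic_smooth = NA_real_,
                              sex_coefficient = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(region = rg, hemisphere = hm,
                              measure = measure, n = fit$n, edf = fit$edf,
                              f_stat = fit$f_stat, p_value = fit$p_value,
                              selected_model = fit$selected_model,
                              bic_intercept = fit$bic_by_model["intercept"],
                              bic_linear = fit$bic_by_model["linear"],
                              bic_smooth = fit$bic_by_model["smooth"],
                              sex_coefficient = fit$sex_coefficient,
                              stringsAsFactors = FALSE)
      curves[[paste(rg, hm, sep = "|")]] <- fit$fitted_curve
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (fdrFamily == "per-hemisphere") {
    out$q_value <- NA_real_
    for (hm in c("left", "right")) {
      j <- out$hemisphere == hm
      out$q_value[j] <- fdrAdjust(out$p_value[j])
    }
  } else {
    out$q_value <- fdrAdjust(out$p_value)
  }
  out <- out[, c("region", "hemisphere", "measure", "n", "edf", "f_stat",
                 "p_value", "q_value", "selected_model", "bic_intercept",
                 "bic_linear", "bic_smooth", "sex_coefficient")]
  attr(out, "curves") <- curves
  out
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Omnibus one-way ANOVA plus unadjusted pairwise t-tests using the
#' pooled within-group variance (Fisher's least significant
#' difference), as used for comparing eTIV and demographics across age
#' groups.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; >= 2 groups with >= 2
#'   members each.
#' @return list with `f_statistic`, `p_value`, `pairwise` (lower
#'   triangular matrix of LSD p-values), `group_means`, `group_n`.
#' @export
groupAnovaLSD <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs >= 2 members")
  if (length(values) != length(groups))
    stopf("values and groups must have equal length")
  fit <- aov(values ~ groups)
  at <- anova(fit)
  pw <- pairwise.t.test(values, groups, p.adjust.method = "none",
                        pool.sd = TRUE)$p.value
  list(f_statistic = at[["F value"]][1], p_value = at[["Pr(>F)"]][1],
       pairwise = pw,
       group_means = tapply(values, groups, mean),
       group_n = as.integer(table(groups)))
}
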