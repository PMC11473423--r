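## Synthetic pediatric morphometry cohorts with known ground truth.
##
## The generator emulates the value-level structure of a preschool
## cross-sectional morphometry study: n subjects with ages over a
## 14-71 month span (uniform or stratified into yearly groups), eTIV
## increasing linearly with age, per-region bilateral mean trajectories
## that are constant/linear/logarithmic/quadratic in age, and
## hemisphere lateralization that switches on at a configurable onset
## age through a smoothstep ramp:
##   left  = m(age) * (1 + a(age)),  right = m(age) * (1 - a(age)),
##   a(age) = delta * smoothstep((age - T) / ramp_width),
## so the noise-free asymmetry index equals a(age) exactly. Additive
## Gaussian noise (or log-normal, optionally) is applied per
## hemisphere. Defaults are chosen for testability at a realistic
## order of magnitude, not as biological claims.

.trajValue <- function(form, p1, p2, p3, age) {
  switch(form,
         constant = rep(p1, length(age)),
         linear = p1 + p2 * age,
         logarithmic = p1 + p2 * log(age),
         quadratic = p1 + p2 * (age - p3)^2,
         stopf("unknown trajectory form: %s", form))
}

.spec_row <- function(region, measure, form, p1, p2 = 0, p3 = NA, sd = 0,
                      lat_onset = NA, lat_delta = 0, lat_width = 12) {
  data.frame(region = region, measure = measure, form = form, p1 = p1,
             p2 = p2, p3 = p3, sd = sd, lat_onset = lat_onset,
             lat_delta = lat_delta, lat_width = lat_width,
             stringsAsFactors = FALSE)
}

#' Default per-region generator specifications
#'
#' One row per (region, measure): trajectory form and parameters for
#' the bilateral mean in native units, per-hemisphere residual SD, and
#' the lateralization triple (onset month, plateau AI effect delta,
#' ramp width). Fronto-limbic defaults carry mixed trajectory shapes
#' (linear subcortical growth, logarithmic cortical volume growth,
#' declining thickness) and a lateralization pattern of the kind seen
#' in preschool cohorts (e.g. left-ward superior temporal and fusiform
#' volume, right-ward inferior parietal volume, no lateral
#' orbitofrontal asymmetry); non-fronto-limbic regions get generic
#' shapes and no asymmetry.
#'
#' @return data.frame of generator specs (see Details).
#' @export
defaultRegionSpecs <- function() {
  reg <- regionRegistry()
  rows <- list(
    # subcortical volumes, mm^3 per hemisphere
    .spec_row("thalamus", "volume", "linear", 6200, 9, sd = 280,
              lat_onset = 18, lat_delta = 0.05),
    .spec_row("amygdala", "volume", "linear", 1050, 5, sd = 70),
    .spec_row("hippocampus", "volume", "linear", 2700, 7, sd = 150),
    .spec_row("caudate", "volume", "linear", 3300, 3, sd = 200),
    .spec_row("putamen", "volume", "linear", 4500, 4, sd = 250),
    .spec_row("pallidum", "volume", "linear", 1500, 1.5, sd = 100),
    .spec_row("accumbens", "volume", "linear", 500, 0.8, sd = 50),
    # fronto-limbic cortical volumes, mm^3
    .spec_row("rostralanteriorcingulate", "volume", "logarithmic", 900, 350,
              sd = 120, lat_onset = 14, lat_delta = 0.06),
    .spec_row("caudalanteriorcingulate", "volume", "logarithmic", 800, 300,
              sd = 110, lat_onset = 20, lat_delta = -0.06),
    .spec_row("posteriorcingulate", "volume", "logarithmic", 1400, 450,
              sd = 160, lat_onset = 27, lat_delta = -0.05),
    .spec_row("medialorbitofrontal", "volume", "logarithmic", 2000, 500,
              sd = 200, lat_onset = 28, lat_delta = -0.05),
    .spec_row("lateralorbitofrontal", "volume", "logarithmic", 3000, 700,
              sd = 280),
    .spec_row("superiortemporal", "volume", "logarithmic", 4500, 1000,
              sd = 380, lat_onset = 20, lat_delta = 0.05),
    .spec_row("inferiorparietal", "volume", "logarithmic", 5500, 1300,
              sd = 480, lat_onset = 14, lat_delta = -0.06),
    .spec_row("fusiform", "volume", "logarithmic", 3500, 900, sd = 330,
              lat_onset = 23, lat_delta = 0.05),
    # fronto-limbic cortical thickness, mm
    .spec_row("medialorbitofrontal", "thickness", "logarithmic", 3.8, -0.28,
              sd = 0.09),
    .spec_row("rostralanteriorcingulate", "thickness", "linear", 3.3,
              -0.006, sd = 0.09),
    .spec_row("superiortemporal", "thickness", "logarithmic", 2.4, 0.12,
              sd = 0.09),
    .spec_row("posteriorcingulate", "thickness", "quadratic", 2.9, -2e-4,
              p3 = 45, sd = 0.08, lat_onset = 35, lat_delta = 0.025),
    .spec_row("inferiorparietal", "thickness", "linear", 3.0, -0.004,
              sd = 0.08, lat_onset = 16, lat_delta = 0.03),
    .spec_row("fusiform", "thickness", "linear", 2.9, -0.003, sd = 0.08,
              lat_onset = 22, lat_delta = 0.03),
    .spec_row("caudalanteriorcingulate", "thickness", "linear", 3.1,
              -0.004, sd = 0.09),
    .spec_row("lateralorbitofrontal", "thickness", "linear", 3.0, -0.004,
              sd = 0.09))
  # generic non-fronto-limbic cortex: both measures, no lateralization
  other <- reg[reg$tissue_class == "cortical" & !reg$frontolimbic, ]
  for (i in seq_len(nrow(other))) {
    aw <- other$area_weight[i]
    rows[[length(rows) + 1L]] <-
      .spec_row(other$region[i], "volume", "logarithmic", 1.2 * aw,
                0.3 * aw, sd = 0.08 * aw)
    rows[[length(rows) + 1L]] <-
      .spec_row(other$region[i], "thickness", "constant", 2.7, sd = 0.08)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generator configuration
#'
#' @param n_subjects cohort size (default 57).
#' @param age_min,age_max age range in months (defaults 14 and 71).
#' @param male_fraction expected fraction of males (default 41/57).
#' @param age_sampling `"uniform"` (default) or `"stratified"` into
#'   yearly groups with `group_counts`.
#' @param group_counts per-year-group subject counts used when
#'   stratified (default `c(7, 15, 14, 11, 10)`; must sum to
#'   `n_subjects`).
#' @param etiv_baseline,etiv_slope,etiv_sd eTIV model, mm^3:
#'   `etiv = baseline + slope * age + N(0, sd)` (defaults 1.05e6, 5000,
#'   7e4 — a plausible preschool scale).
#' @param region_specs per-region trajectory/lateralization table
#'   (default [defaultRegionSpecs()]).
#' @param noise_model `"gaussian"` (additive, default) or
#'   `"lognormal"` (multiplicative, for strictly positive volumes).
#' @param seed default RNG seed used by [simulateCohort()] (default 1).
#' @return a `GeneratorConfig` list.
#' @export
cohortConfig <- function(n_subjects = 57L, age_min = 14, age_max = 71,
                         male_fraction = 41 / 57,
                         age_sampling = c("uniform", "stratified"),
                         group_counts = c(7L, 15L, 14L, 11L, 10L),
                         etiv_baseline = 1.05e6, etiv_slope = 5000,
                         etiv_sd = 7e4,
                         region_specs = defaultRegionSpecs(),
                         noise_model = c("gaussian", "lognormal"),
                         seed = 1L) {
  age_sampling <- match.arg(age_sampling)
  noise_model <- match.arg(noise_model)
  cfg <- list(n_subjects = as.integer(n_subjects), age_min = age_min,
              age_max = age_max, male_fraction = male_fraction,
              age_sampling = age_sampling,
              group_counts = as.integer(group_counts),
              etiv_baseline = etiv_baseline, etiv_slope = etiv_slope,
              etiv_sd = etiv_sd, region_specs = region_specs,
              noise_model = noise_model, seed = as.integer(seed))
  validateConfig(cfg)
  structure(cfg, class = "GeneratorConfig")
}

#' @rdname cohortConfig
#' @param config a `GeneratorConfig` to validate.
#' @export
validateConfig <- function(config) {
  rs <- config$region_specs
  if (config$n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (config$age_min <= 0 || config$age_max <= config$age_min)
    stopf("need 0 < age_min < age_max")
  if (config$male_fraction < 0 || config$male_fraction > 1)
    stopf("male_fraction must lie in [0, 1]")
  if (config$age_sampling == "stratified" &&
      sum(config$group_counts) != config$n_subjects)
    stopf("group_counts must sum to n_subjects")
  if (config$etiv_sd < 0 || any(rs$sd < 0)) stopf("all SDs must be >= 0")
  if (any(abs(rs$lat_delta) >= 1))
    stopf("lateralization effect delta must lie in (-1, 1)")
  if (any(rs$lat_width <= 0)) stopf("lat_width must be positive")
  quad <- rs$form == "quadratic"
  if (any(quad & (rs$p3 < config$age_min - 24 | rs$p3 > config$age_max + 24)))
    stopf("quadratic peak parameter must lie within or near the age range")
  unknown <- setdiff(rs$region, regionRegistry()$region)
  if (length(unknown))
    stopf("region_specs contain unknown region(s): %s",
          paste(unknown, collapse = ", "))
  invisible(config)
}

#' Plant or clear lateralization effects
#'
#' `plantLateralization` sets the (onset, delta, ramp width) triple for
#' one (region, measure); `clearLateralization` zeroes every effect,
#' giving a fully symmetric generator.
#'
#' @param config a [cohortConfig()].
#' @param region,measure target of the planted effect.
#' @param onset onset age T in months.
#' @param delta plateau AI effect in (-1, 1); positive = left-ward.
#' @param width ramp width in months (default 12).
#' @return the modified config.
#' @export
plantLateralization <- function(config, region, measure, onset, delta,
                                width = 12) {
  rs <- config$region_specs
  i <- which(rs$region == region & rs$measure == measure)
  if (!length(i)) stopf("no generator spec for %s/%s", region, measure)
  rs$lat_onset[i] <- onset
  rs$lat_delta[i] <- delta
  rs$lat_width[i] <- width
  config$region_specs <- rs
  validateConfig(config)
}

#' @rdname plantLateralization
#' @export
clearLateralization <- function(config) {
  config$region_specs$lat_delta <- 0
  config$region_specs$lat_onset <- NA
  config
}

# closed-form AI ramp a(age) for one spec row
.latProfile <- function(delta, onset, width, age) {
  if (is.na(onset) || delta == 0) return(rep(0, length(age)))
  delta * smoothstep((age - onset) / width)
}

#' Ground-truth curves of a simulated cohort
#'
#' `truthAsymmetry` evaluates the generator's noise-free AI profile
#' `a(age)`; `truthTrajectory` the bilateral mean trajectory `m(age)`.
#'
#' @param gt ground truth from [groundTruth()] (or a `GeneratorConfig`).
#' @param region,measure the targeted series.
#' @param ages numeric vector of ages in months.
#' @return numeric vector of the requested curve at `ages`.
#' @export
truthAsymmetry <- function(gt, region, measure, ages) {
  rs <- gt$region_specs
  i <- which(rs$region == region & rs$measure == measure)
  if (!length(i)) stopf("no ground truth for %s/%s", region, measure)
  .latProfile(rs$lat_delta[i], rs$lat_onset[i], rs$lat_width[i], ages)
}

#' @rdname truthAsymmetry
#' @export
truthTrajectory <- function(gt, region, measure, ages) {
  rs <- gt$region_specs
  i <- which(rs$region == region & rs$measure == measure)
  if (!length(i)) stopf("no ground truth for %s/%s", region, measure)
  .trajValue(rs$form[i], rs$p1[i], rs$p2[i], rs$p3[i], ages)
}

#' Simulate a morphometry cohort
#'
#' Draws a cohort under a [cohortConfig()] and returns a
#' [MorphoCohort-class] whose `metadata()` carries the generator
#' ground truth (`groundTruth(x)`): the region spec table, the seed,
#' and per-series linearity flags for recovery scoring. Identical
#' seeds yield identical cohorts.
#'
#' @param config a [cohortConfig()].
#' @param seed RNG seed (default `config$seed`).
#' @return a [MorphoCohort-class].
#' @export
simulateCohort <- function(config = cohortConfig(), seed = config$seed) {
  validateConfig(config)
  set.seed(seed)
  n <- config$n_subjects
  ages <- if (config$age_sampling == "uniform") {
    runif(n, config$age_min, config$age_max)
  } else {
    unlist(lapply(seq_along(config$group_counts), function(g) {
      lo <- max(config$age_min, 12 * g)
      hi <- min(config$age_max, 12 * g + 12 - 1e-9)
      runif(config$group_counts[g], lo, hi)
    }))
  }
  n_male <- round(n * config$male_fraction)
  sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
  etiv <- config$etiv_baseline + config$etiv_slope * ages +
    rnorm(n, 0, config$etiv_sd)
  etiv <- pmax(etiv, 0.5 * config$etiv_baseline)
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- data.frame(subject_id = ids, age_months = ages, sex = sex,
                         etiv = etiv, stringsAsFactors = FALSE)

  rs <- config$region_specs
  meas <- vector("list", nrow(rs))
  for (i in seq_len(nrow(rs))) {
    m <- .trajValue(rs$form[i], rs$p1[i], rs$p2[i], rs$p3[i], ages)
    a <- .latProfile(rs$lat_delta[i], rs$lat_onset[i], rs$lat_width[i],
                     ages)
    mu_l <- m * (1 + a)
    mu_r <- m * (1 - a)
    if (config$noise_model == "gaussian") {
      left <- pmax(mu_l + rnorm(n, 0, rs$sd[i]), 0)
      right <- pmax(mu_r + rnorm(n, 0, rs$sd[i]), 0)
    } else {
      rel <- rs$sd[i] / max(mean(m), .Machine$double.eps)
      left <- mu_l * exp(rnorm(n, 0, rel))
      right <- mu_r * exp(rnorm(n, 0, rel))
    }
    meas[[i]] <- data.frame(
      subject_id = rep(ids, 2L), region = rs$region[i],
      hemisphere = rep(c("left", "right"), each = n),
      measure = rs$measure[i], value = c(left, right),
      stringsAsFactors = FALSE)
  }
  gt <- list(region_specs = rs, seed = seed,
             linear = setNames(rs$form %in% c("constant", "linear"),
                               paste(rs$region, rs$measure, sep = "|")),
             config = config)
  MorphoCohort(subjects, do.call(rbind, meas),
               provenance = sprintf("synthetic cohort (seed %d)", seed),
               groundTruth = gt)
}

## ---- fixture writer ----------------------------------------------------

.fsLabelFor <- function(region, hemisphere) {
  ali <- .aliasTable()
  i <- which(ali$region == region & ali$hemisphere == hemisphere)
  if (length(i)) ali$fs_label[i[1]] else region
}

#' Write a cohort as an on-disk fixture
#'
#' Emits either a single long-format CSV (readable with
#' [readCohortTable()]) or a per-subject FreeSurfer-style stats tree
#' (`participants.tsv` plus `<subject>/stats/aseg.stats`,
#' `lh.aparc.stats`, `rh.aparc.stats`, readable with
#' [readCohortTree()]). Values are printed at full double precision so
#' reading the fixture back reproduces the cohort exactly, and output
#' is byte-stable for a fixed seed. The stats-tree writer requires
#' every cortical region to carry both volume and thickness (the aparc
#' dialect has both columns in each row).
#'
#' @param cohort a [MorphoCohort-class].
#' @param dir output directory (created if needed).
#' @param format `"long_csv"` or `"freesurfer_stats_tree"`.
#' @return the paths written, invisibly.
#' @export
writeFixture <- function(cohort, dir,
                         format = c("long_csv", "freesurfer_stats_tree")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "long_csv") {
    return(invisible(writeCohortTable(cohort,
                                      file.path(dir, "cohort.csv"))))
  }
  s <- subjectData(cohort)
  m <- measureTable(cohort)
  reg <- regionRegistry()
  paths <- file.path(dir, "participants.tsv")
  part <- data.frame(subject_id = s$subject_id,
                     age_months = sprintf("%.17g", s$age_months),
                     sex = s$sex, stringsAsFactors = FALSE)
  write.table(part, paths, sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_len(nrow(s))) {
    sid <- s$subject_id[i]
    sdir <- file.path(dir, sid, "stats")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    ms <- m[m$subject_id == sid, , drop = FALSE]
    tc <- reg$tissue_class[match(ms$region, reg$region)]

    sub <- ms[tc == "subcortical", , drop = FALSE]
    aseg <- file.path(sdir, "aseg.stats")
    lines <- c("# Title Segmentation Statistics",
               sprintf(paste0("# Measure EstimatedTotalIntraCranialVol,",
                              " eTIV, Estimated Total Intracranial Volume,",
                              " %.17g, mm^3"), s$etiv[i]),
               "# ColHeaders Index SegId NVoxels Volume_mm3 StructName")
    if (nrow(sub)) {
      sub <- sub[order(sub$region, sub$hemisphere), , drop = FALSE]
      lines <- c(lines, sprintf(
        "%3d %4d %7d %.17g %s", seq_len(nrow(sub)),
        9L + seq_len(nrow(sub)), as.integer(round(sub$value)), sub$value,
        mapply(.fsLabelFor, sub$region, sub$hemisphere)))
    }
    writeLines(lines, aseg)
    paths <- c(paths, aseg)

    for (h in c("left", "right")) {
      ct <- ms[tc == "cortical" & ms$hemisphere == h, , drop = FALSE]
      vol <- ct[ct$measure == "volume", , drop = FALSE]
      th <- ct[ct$measure == "thickness", , drop = FALSE]
      only <- union(setdiff(vol$region, th$region),
                    setdiff(th$region, vol$region))
      if (length(only))
        stopf(paste0("stats-tree fixture needs both volume and thickness",
                     " for cortical region(s): %s"),
              paste(head(only, 3), collapse = ", "))
      vol <- vol[order(vol$region), , drop = FALSE]
      th <- th[match(vol$region, th$region), , drop = FALSE]
      f <- file.path(sdir, sprintf("%s.aparc.stats",
                                   if (h == "left") "lh" else "rh"))
      aw <- reg$area_weight[match(vol$region, reg$region)]
      lines <- c("# Table of FreeSurfer cortical parcellation anatomical statistics",
                 sprintf("# hemi %s", if (h == "left") "lh" else "rh"),
                 "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg")
      if (nrow(vol))
        lines <- c(lines, sprintf("%s %d %d %.17g %.17g", vol$region,
                                  as.integer(aw * 2), as.integer(aw),
                                  vol$value, th$value))
      writeLines(lines, f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
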