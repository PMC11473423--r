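## End-to-end orchestration: ingest -> QC -> normalize -> trajectories
## -> asymmetry emergence -> report tables, with reproducibility
## metadata written next to the outputs.

#' Pipeline configuration
#'
#' Exactly one of `input` (a long-format cohort table, or a directory
#' holding a FreeSurfer-style stats tree) or `generator` (a
#' [cohortConfig()], simulated at run time) must be given.
#'
#' @param input path to a cohort CSV/TSV or stats-tree directory.
#' @param generator a [cohortConfig()] for a simulated run.
#' @param outdir output directory (`NULL` for an in-memory run only).
#' @param seed RNG seed for the run (default 1).
#' @param normalization `"relative"` or `"absolute"`.
#' @param aiScale AI input scale, `"absolute"` (default; the eTIV
#'   denominator cancels exactly for volumes) or `"relative"`.
#' @param smooth a [smoothSpec()].
#' @param windowWidth,stride,minN,windowConvention sliding-window
#'   settings, see [buildWindows()].
#' @param alpha significance level (default 0.05).
#' @param fdrFamily window FDR family, see [testWindows()].
#' @param trajFdrFamily trajectory FDR family, see [fitAllRegions()].
#' @param qcZ z-score threshold for QC flags (default 3).
#' @param qcAction `"report"` (default, advisory flags) or `"exclude"`
#'   (flagged values are removed before analysis).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(input = NULL, generator = NULL, outdir = NULL,
                           seed = 1L,
                           normalization = c("relative", "absolute"),
                           aiScale = c("absolute", "relative"),
                           smooth = smoothSpec(), windowWidth = 12,
                           stride = 1, minN = 5,
                           windowConvention = c("half-open",
                                                "integer-inclusive"),
                           alpha = 0.05,
                           fdrFamily = c("per-window", "per-region"),
                           trajFdrFamily = c("per-hemisphere", "pooled"),
                           qcZ = 3, qcAction = c("report", "exclude")) {
  if (is.null(input) == is.null(generator))
    stopf("give exactly one of 'input' or 'generator'")
  if (!is.null(generator)) validateConfig(generator)
  stopifnot(windowWidth > 0, stride > 0, minN >= 1, alpha > 0, alpha <= 1,
            qcZ > 0)
  structure(list(input = input, generator = generator, outdir = outdir,
                 seed = as.integer(seed),
                 normalization = match.arg(normalization),
                 aiScale = match.arg(aiScale), smooth = smooth,
                 windowWidth = windowWidth, stride = stride, minN = minN,
                 windowConvention = match.arg(windowConvention),
                 alpha = alpha, fdrFamily = match.arg(fdrFamily),
                 trajFdrFamily = match.arg(trajFdrFamily), qcZ = qcZ,
                 qcAction = match.arg(qcAction)),
            class = "PipelineConfig")
}

.writeTsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  df <- as.data.frame(df)
  df$members <- NULL
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> QC -> normalization -> per-region trajectory GAMs
#' (volume and, when thickness data are present, thickness) -> sliding
#' -window asymmetry emergence -> demographics, writing every stage
#' table plus the resolved configuration to `outdir` (when given).
#' Per-region fit failures are recorded and the run continues. Fixed
#' (inputs, config, seed) give byte-identical output tables.
#'
#' @param config a [pipelineConfig()].
#' @return a `RunReport` list: `cohort`, `qc_flags`, `normalized`,
#'   `trajectories` (list by measure), `asymmetry` (AI records),
#'   `windows`, `window_tests`, `emergence`, `population_asymmetry`,
#'   `demographics`, `config`, `fingerprint`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$generator)) {
    simulateCohort(config$generator, seed = config$seed)
  } else if (dir.exists(config$input)) {
    readCohortTree(config$input)
  } else {
    readCohortTable(config$input)
  }

  flags <- withCallingHandlers(qcOutlierFlags(cohort, config$qcZ),
                               warning = function(w) invokeRestart("muffleWarning"))
  if (config$qcAction == "exclude" && nrow(flags)) {
    message(sprintf("QC: excluding %d flagged measurement(s)", nrow(flags)))
    cohort <- applyQcExclusions(cohort, flags)
  }

  normalized <- normalizeCohort(cohort, mode = config$normalization)

  meas_present <- unique(measureTable(cohort)$measure)
  traj <- list()
  for (ms in intersect(c("volume", "thickness"), meas_present)) {
    traj[[ms]] <- fitAllRegions(cohort, measure = ms,
                                spec = config$smooth,
                                normalization = config$normalization,
                                fdrFamily = config$trajFdrFamily)
  }

  ai <- suppressWarnings(
    computeAsymmetry(cohort, measures = intersect(c("volume", "thickness"),
                                                  meas_present),
                     scale = config$aiScale))
  s <- subjectData(cohort)
  windows <- buildWindows(s$age_months, ids = s$subject_id,
                          width = config$windowWidth,
                          stride = config$stride, minN = config$minN,
                          convention = config$windowConvention)
  wtests <- testWindows(ai, windows, alpha = config$alpha,
                        minN = config$minN, fdrFamily = config$fdrFamily)
  emergence <- detectEmergence(wtests, alpha = config$alpha)
  popasym <- populationAverageAsymmetry(ai)
  demo <- makeDemographics(cohort)

  fingerprint <- list(package = "MorphoDev",
                      version = as.character(packageVersion("MorphoDev")),
                      seed = config$seed,
                      n_subjects = ncol(cohort),
                      provenance = cohortProvenance(cohort))

  if (!is.null(config$outdir)) {
    writeCohortTable(cohort, file.path(config$outdir, "cohort.csv"))
    .writeTsv(flags, config$outdir, "qc_flags.tsv")
    .writeTsv(normalized, config$outdir, "normalized.tsv")
    for (ms in names(traj))
      .writeTsv(traj[[ms]], config$outdir,
                sprintf("trajectories_%s.tsv", ms))
    .writeTsv(wtests, config$outdir, "window_tests.tsv")
    .writeTsv(emergence, config$outdir, "emergence.tsv")
    .writeTsv(popasym, config$outdir, "population_asymmetry.tsv")
    .writeTsv(demo$table, config$outdir, "demographics.tsv")
    cfg <- config
    cfg$outdir <- NULL   # volatile; the file's own location records it
    json <- jsonlite::toJSON(list(config = cfg, fingerprint = fingerprint),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             dataframe = "rows", force = TRUE)
    writeLines(json, file.path(config$outdir, "config.json"))
  }

  structure(list(cohort = cohort, qc_flags = flags, normalized = normalized,
                 trajectories = traj, asymmetry = ai, windows = windows,
                 window_tests = wtests, emergence = emergence,
                 population_asymmetry = popasym, demographics = demo,
                 config = config, fingerprint = fingerprint),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("MorphoDev RunReport\n")
  cat("  subjects:", x$fingerprint$n_subjects, "| seed:",
      x$fingerprint$seed, "\n")
  cat("  provenance:", x$fingerprint$provenance, "\n")
  cat("  QC flags:", nrow(x$qc_flags), "\n")
  for (ms in names(x$trajectories)) {
    t <- x$trajectories[[ms]]
    cat(sprintf("  %s trajectories: %d fits, %d with q < 0.05\n", ms,
                nrow(t), sum(t$q_value < 0.05, na.rm = TRUE)))
  }
  em <- x$emergence
  sig <- !is.na(em$initial_point_months)
  cat("  emergence: ", sum(sig), " of ", nrow(em),
      " region/measure series lateralized\n", sep = "")
  invisible(x)
}

#' Demographics table with group comparisons
#'
#' Per age group: n, mean and SD of scan age and eTIV, male count and
#' percentage; one-way ANOVA with Fisher's LSD pairwise comparisons
#' ([groupAnovaLSD()]) for age and eTIV across groups. When every
#' adjacent pair of groups differs significantly (LSD p < 0.05) and
#' the group means are monotone increasing, an ordering string such as
#' `"1 < 2 < 3 < 4 < 5"` is reported. With a single group only the
#' descriptives are returned and tests are suppressed with a note.
#'
#' @param cohort a [MorphoCohort-class].
#' @param alpha significance level for the ordering string (0.05).
#' @return list with `table` (per-group descriptives), `tests` (named
#'   list for `age_months` and `etiv`: `f_statistic`, `p_value`,
#'   `pairwise`, `ordering`), and `note`.
#' @export
makeDemographics <- function(cohort, alpha = 0.05) {
  s <- subjectData(cohort)
  g <- factor(s$age_group)
  tab <- do.call(rbind, lapply(levels(g), function(lv) {
    d <- s[g == lv, , drop = FALSE]
    data.frame(age_group = lv, n = nrow(d),
               age_mean = mean(d$age_months), age_sd = sd(d$age_months),
               male_n = sum(d$sex == "male"),
               male_pct = 100 * mean(d$sex == "male"),
               etiv_mean = mean(d$etiv), etiv_sd = sd(d$etiv),
               stringsAsFactors = FALSE)
  }))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    return(list(table = tab, tests = NULL,
                note = "group tests suppressed: need >= 2 groups with >= 2 members"))
  }
  tests <- lapply(c(age_months = "age_months", etiv = "etiv"),
                  function(v) {
    res <- groupAnovaLSD(s[[v]], g)
    res$ordering <- .lsdOrdering(res, levels(g), alpha)
    res
  })
  list(table = tab, tests = tests, note = NULL)
}

# "1 < 2 < ... < k" when all adjacent LSD comparisons are significant
# and the group means increase in label order
.lsdOrdering <- function(res, lv, alpha) {
  mu <- res$group_means[lv]
  if (any(diff(mu) <= 0)) return("")
  for (i in seq_len(length(lv) - 1)) {
    a <- lv[i + 1]; b <- lv[i]
    p <- res$pairwise[a, b]
    if (is.na(p)) p <- res$pairwise[b, a]
    if (is.na(p) || p >= alpha) return("")
  }
  paste(lv, collapse = " < ")
}
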