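#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' MorphoCohort: a regional-morphometry cohort container
#'
#' An S4 container for a cross-sectional morphometry cohort, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are morphometric
#' features — one per (region, hemisphere, measure) triple, where
#' `measure` is `"volume"` (mm\eqn{^3}) or `"thickness"` (mm) — and
#' columns are subjects. The single `"value"` assay holds native-unit
#' measurements with `NA` where a subject lacks a feature. Subject
#' metadata (`subject_id`, `age_months`, `sex`, `etiv`, `age_group`)
#' live in `colData`; feature metadata (`region`, `hemisphere`,
#' `measure`, `tissue_class`, `frontolimbic`) in `rowData`; free-text
#' provenance and, for simulated cohorts, the generator ground truth in
#' `metadata()`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @name MorphoCohort-class
#' @aliases MorphoCohort-class
#' @exportClass MorphoCohort
setClass("MorphoCohort", contains = "SummarizedExperiment")

setValidity("MorphoCohort", function(object) {
  cd <- colData(object)
  rd <- rowData(object)
  msgs <- character()
  need_cd <- c("subject_id", "age_months", "sex", "etiv", "age_group")
  if (!all(need_cd %in% names(cd)))
    msgs <- c(msgs, paste("colData must contain:",
                          paste(setdiff(need_cd, names(cd)), collapse = ", ")))
  need_rd <- c("region", "hemisphere", "measure")
  if (!all(need_rd %in% names(rd)))
    msgs <- c(msgs, paste("rowData must contain:",
                          paste(setdiff(need_rd, names(rd)), collapse = ", ")))
  if (!length(msgs)) {
    if (any(cd$age_months <= 0)) msgs <- c(msgs, "age_months must be > 0")
    if (any(cd$etiv <= 0)) msgs <- c(msgs, "etiv must be > 0")
    if (!all(cd$sex %in% c("male", "female")))
      msgs <- c(msgs, "sex must be 'male' or 'female'")
    if (anyDuplicated(cd$subject_id))
      msgs <- c(msgs, "duplicated subject_id in colData")
    if (!all(rd$hemisphere %in% c("left", "right")))
      msgs <- c(msgs, "hemisphere must be 'left' or 'right'")
    if (!all(rd$measure %in% c("volume", "thickness")))
      msgs <- c(msgs, "measure must be 'volume' or 'thickness'")
    reg <- regionRegistry()
    cort <- reg$region[reg$tissue_class == "cortical"]
    bad_th <- rd$measure == "thickness" & !(rd$region %in% cort)
    if (any(bad_th))
      msgs <- c(msgs, "thickness features are only valid for cortical regions")
    v <- assay(object, "value")
    if (any(v < 0, na.rm = TRUE))
      msgs <- c(msgs, "measurement values must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MorphoCohort from subject and measurement tables
#'
#' @param subjects data.frame with columns `subject_id`, `age_months`
#'   (months, > 0), `sex` (`"male"`/`"female"`), `etiv` (mm^3, > 0) and
#'   optionally `age_group` (defaults to [ageGroup()] of `age_months`).
#' @param measures long data.frame with columns `subject_id`, `region`
#'   (canonical registry name), `hemisphere` (`"left"`/`"right"`),
#'   `measure` (`"volume"`/`"thickness"`) and `value` (native units,
#'   non-negative). The key (subject, region, hemisphere, measure) must
#'   be unique, and every `subject_id` must appear in `subjects`.
#' @param provenance free-text description of the data source.
#' @param groundTruth optional generator ground truth (list), attached
#'   for simulated cohorts.
#' @return a [MorphoCohort-class] object.
#' @export
#' @examples
#' subj <- data.frame(subject_id = "s1", age_months = 24,
#'                    sex = "male", etiv = 1.2e6)
#' meas <- data.frame(subject_id = "s1", region = "thalamus",
#'                    hemisphere = c("left", "right"),
#'                    measure = "volume", value = c(7100, 6900))
#' MorphoCohort(subj, meas)
MorphoCohort <- function(subjects, measures, provenance = "",
                         groundTruth = NULL) {
  subjects <- as.data.frame(subjects)
  measures <- as.data.frame(measures)
  assertColumns(subjects, c("subject_id", "age_months", "sex", "etiv"),
                "subjects")
  assertColumns(measures,
                c("subject_id", "region", "hemisphere", "measure", "value"),
                "measures")
  if (is.null(subjects$age_group))
    subjects$age_group <- ageGroup(subjects$age_months)
  if (anyDuplicated(subjects$subject_id))
    stopf("duplicated subject_id in subjects table")
  orphan <- setdiff(measures$subject_id, subjects$subject_id)
  if (length(orphan))
    stopf("measures reference unknown subject(s): %s",
          paste(head(orphan, 5), collapse = ", "))
  key <- paste(measures$subject_id, measures$region, measures$hemisphere,
               measures$measure, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicated (subject, region, hemisphere, measure) key, e.g. %s",
          gsub("\r", "/", key[duplicated(key)][1]))
  if (any(measures$value < 0, na.rm = TRUE))
    stopf("negative measurement value(s); raw morphometry must be >= 0")

  reg <- regionRegistry()
  unknown <- setdiff(measures$region, reg$region)
  if (length(unknown))
    stopf("measures contain region(s) absent from the registry: %s",
          paste(head(unknown, 5), collapse = ", "))

  # feature space ordered by registry, then measure, then hemisphere
  feat <- unique(measures[, c("region", "hemisphere", "measure")])
  feat <- feat[order(match(feat$region, reg$region),
                     feat$measure, feat$hemisphere), , drop = FALSE]
  fid <- paste(feat$region, feat$hemisphere, feat$measure, sep = "|")
  sid <- subjects$subject_id
  mat <- matrix(NA_real_, nrow = length(fid), ncol = length(sid),
                dimnames = list(fid, sid))
  mi <- match(paste(measures$region, measures$hemisphere, measures$measure,
                    sep = "|"), fid)
  mat[cbind(mi, match(measures$subject_id, sid))] <- measures$value

  ri <- match(feat$region, reg$region)
  rd <- DataFrame(region = feat$region, hemisphere = feat$hemisphere,
                  measure = feat$measure,
                  tissue_class = reg$tissue_class[ri],
                  frontolimbic = reg$frontolimbic[ri],
                  row.names = fid)
  cd <- DataFrame(subjects, row.names = sid)
  se <- SummarizedExperiment(assays = SimpleList(value = mat),
                             rowData = rd, colData = cd)
  metadata(se)$provenance <- provenance
  if (!is.null(groundTruth)) metadata(se)$groundTruth <- groundTruth
  new("MorphoCohort", se)
}

#' @describeIn MorphoCohort-class subject metadata as a plain data.frame.
#' @param x a `MorphoCohort`.
#' @export
subjectData <- function(x) {
  stopifnot(is(x, "MorphoCohort"))
  as.data.frame(colData(x))
}

#' @describeIn MorphoCohort-class long-format measurement table
#'   (`subject_id`, `region`, `hemisphere`, `measure`, `value`), one row
#'   per observed value.
#' @export
measureTable <- function(x) {
  stopifnot(is(x, "MorphoCohort"))
  v <- assay(x, "value")
  rd <- as.data.frame(rowData(x))
  idx <- which(!is.na(v), arr.ind = TRUE)
  out <- data.frame(subject_id = colnames(v)[idx[, 2]],
                    region = rd$region[idx[, 1]],
                    hemisphere = rd$hemisphere[idx[, 1]],
                    measure = rd$measure[idx[, 1]],
                    value = v[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$subject_id, colnames(v)),
                   match(paste(out$region, out$hemisphere, out$measure,
                               sep = "|"), rownames(v))), ]
  rownames(out) <- NULL
  out
}

#' @describeIn MorphoCohort-class free-text provenance string.
#' @export
cohortProvenance <- function(x) {
  stopifnot(is(x, "MorphoCohort"))
  metadata(x)$provenance %||% ""
}

#' @describeIn MorphoCohort-class generator ground truth for simulated
#'   cohorts (`NULL` for real data).
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "MorphoCohort"))
  metadata(x)$groundTruth
}

#' @describeIn MorphoCohort-class subjects lacking one hemisphere of a
#'   (region, measure) pair; these are excluded per-region from
#'   asymmetry computation but retained for unilateral trajectory fits.
#' @export
incompletePairs <- function(x) {
  m <- measureTable(x)
  k <- paste(m$subject_id, m$region, m$measure, sep = "|")
  tab <- table(k)
  inc <- names(tab)[tab == 1L]
  if (!length(inc))
    return(data.frame(subject_id = character(), region = character(),
                      measure = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(inc, "|", fixed = TRUE))
  data.frame(subject_id = parts[, 1], region = parts[, 2],
             measure = parts[, 3], stringsAsFactors = FALSE)
}

setMethod("show", "MorphoCohort", function(object) {
  cd <- colData(object)
  rd <- rowData(object)
  cat("MorphoCohort:", ncol(object), "subjects,", nrow(object),
      "morphometric features\n")
  cat("  age range (months):",
      sprintf("%.1f-%.1f", min(cd$age_months), max(cd$age_months)),
      "| sex:", sum(cd$sex == "male"), "male /",
      sum(cd$sex == "female"), "female\n")
  cat("  measures:", paste(sort(unique(rd$measure)), collapse = ", "),
      "| fronto-limbic features:", sum(rd$frontolimbic), "\n")
  prov <- cohortProvenance(object)
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  invisible(NULL)
})
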