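## Head-size normalization and the left-right asymmetry index.
##
## Two normalizations are supported: regional volume relative to the
## estimated total intracranial volume (dimensionless, x 1000), and
## regional cortical thickness relative to the subject's hemisphere
## mean thickness. The asymmetry index AI = (L - R)/(L + R) is scale
## free: any common positive rescaling of both hemispheres (eTIV
## division included) cancels.

#' eTIV-relative regional volume
#'
#' `roi_volume / etiv * 1000`: regional volume as a per-mille fraction
#' of estimated total intracranial volume, removing inter-individual
#' skull-size variation.
#'
#' @param roi_volume regional volume(s), mm^3, non-negative.
#' @param etiv estimated total intracranial volume(s), mm^3, positive.
#' @return dimensionless relative volume.
#' @export
#' @examples
#' relativeVolume(5000, 1e6)  # 5
relativeVolume <- function(roi_volume, etiv) {
  if (any(etiv <= 0)) stopf("etiv must be positive")
  if (any(roi_volume < 0)) stopf("roi_volume must be non-negative")
  roi_volume / etiv * 1000
}

#' Hemisphere-relative cortical thickness
#'
#' `roi_thickness / hemisphere_mean_thickness`: regional thickness as a
#' fraction of the subject's mean cortical thickness in the same
#' hemisphere.
#'
#' @param roi_thickness regional mean thickness, mm.
#' @param hemisphere_mean_thickness subject's hemisphere mean cortical
#'   thickness, mm, positive (see [hemisphereMeanThickness()]).
#' @return dimensionless relative thickness.
#' @export
relativeThickness <- function(roi_thickness, hemisphere_mean_thickness) {
  if (any(hemisphere_mean_thickness <= 0))
    stopf("hemisphere mean thickness must be positive")
  roi_thickness / hemisphere_mean_thickness
}

#' Per-subject hemisphere mean cortical thickness
#'
#' The denominator of [relativeThickness()]. By default the mean over
#' the hemisphere's Desikan-Killiany cortical regions is weighted by
#' the registry's typical regional surface areas (the convention of
#' FreeSurfer's whole-hemisphere MeanThickness, which is area
#' weighted); `weighting = "unweighted"` gives the plain mean of the
#' available regional values.
#'
#' @param cohort a [MorphoCohort-class].
#' @param weighting `"area"` (default) or `"unweighted"`.
#' @return data.frame `subject_id`, `hemisphere`, `mean_thickness`.
#' @export
hemisphereMeanThickness <- function(cohort,
                                    weighting = c("area", "unweighted")) {
  weighting <- match.arg(weighting)
  m <- measureTable(cohort)
  m <- m[m$measure == "thickness", , drop = FALSE]
  if (!nrow(m)) stopf("cohort has no thickness measurements")
  reg <- regionRegistry()
  w <- if (weighting == "area") {
    reg$area_weight[match(m$region, reg$region)]
  } else rep(1, nrow(m))
  key <- paste(m$subject_id, m$hemisphere, sep = "|")
  num <- tapply(m$value * w, key, sum)
  den <- tapply(w, key, sum)
  parts <- do.call(rbind, strsplit(names(num), "|", fixed = TRUE))
  out <- data.frame(subject_id = parts[, 1], hemisphere = parts[, 2],
                    mean_thickness = as.numeric(num / den),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Left-right asymmetry index
#'
#' `AI = (left - right) / (left + right)`. Positive values indicate
#' left-ward lateralization, negative right-ward. AI is bounded in
#' \eqn{[-1, 1]} for non-negative inputs and is invariant under common
#' positive rescaling of both hemispheres.
#'
#' @param left,right non-negative hemisphere measures with
#'   `left + right > 0`.
#' @return AI in \eqn{[-1, 1]}.
#' @export
#' @examples
#' asymmetryIndex(3, 1)  # 0.5, left-ward
asymmetryIndex <- function(left, right) {
  if (any(left < 0) || any(right < 0))
    stopf("hemisphere measures must be non-negative")
  if (any(left + right == 0))
    stopf("undefined AI: left + right is zero")
  (left - right) / (left + right)
}

#' Normalize a cohort's measurements
#'
#' Applies the selected normalization to every applicable measurement:
#' volumes via [relativeVolume()], cortical thickness via
#' [relativeThickness()] with the subject's hemisphere mean.
#' `mode = "absolute"` passes values through unchanged (with
#' `measure_kind` `"absolute_volume"`/`"absolute_thickness"`).
#'
#' @param cohort a [MorphoCohort-class].
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param thicknessWeighting passed to [hemisphereMeanThickness()].
#' @return data.frame `subject_id`, `region`, `hemisphere`, `measure`,
#'   `measure_kind`, `value`.
#' @export
normalizeCohort <- function(cohort, mode = c("relative", "absolute"),
                            thicknessWeighting = c("area", "unweighted")) {
  mode <- match.arg(mode)
  m <- measureTable(cohort)
  if (mode == "absolute") {
    m$measure_kind <- paste0("absolute_", m$measure)
    return(m[, c("subject_id", "region", "hemisphere", "measure",
                 "measure_kind", "value")])
  }
  s <- subjectData(cohort)
  out <- m
  out$measure_kind <- NA_character_
  isv <- m$measure == "volume"
  if (any(isv)) {
    etiv <- s$etiv[match(m$subject_id[isv], s$subject_id)]
    out$value[isv] <- relativeVolume(m$value[isv], etiv)
    out$measure_kind[isv] <- "relative_volume"
  }
  ist <- m$measure == "thickness"
  if (any(ist)) {
    hm <- hemisphereMeanThickness(cohort, weighting = thicknessWeighting)
    i <- match(paste(m$subject_id[ist], m$hemisphere[ist]),
               paste(hm$subject_id, hm$hemisphere))
    out$value[ist] <- relativeThickness(m$value[ist], hm$mean_thickness[i])
    out$measure_kind[ist] <- "relative_thickness"
  }
  out[, c("subject_id", "region", "hemisphere", "measure", "measure_kind",
          "value")]
}

#' Per-subject, per-region asymmetry records
#'
#' Computes AI for every fronto-limbic (region, measure) pair with both
#' hemispheres present. By default AI is computed on the raw (absolute)
#' scale: for volumes the eTIV denominator cancels exactly, so raw and
#' eTIV-relative AI are identical; for thickness the hemisphere-mean
#' denominators differ slightly between sides, and `scale = "relative"`
#' selects normalized inputs instead. Subjects missing one hemisphere
#' of a pair are dropped for that region; left+right = 0 rows are
#' dropped with a warning.
#'
#' @param cohort a [MorphoCohort-class].
#' @param measures subset of `c("volume", "thickness")`.
#' @param scale `"absolute"` (default) or `"relative"`.
#' @param frontolimbicOnly restrict to the 11-pair fronto-limbic set
#'   (default `TRUE`).
#' @return data.frame `subject_id`, `region`, `measure`, `left_value`,
#'   `right_value`, `ai`.
#' @export
computeAsymmetry <- function(cohort, measures = c("volume", "thickness"),
                             scale = c("absolute", "relative"),
                             frontolimbicOnly = TRUE) {
  scale <- match.arg(scale)
  measures <- match.arg(measures, several.ok = TRUE)
  m <- if (scale == "absolute") {
    x <- measureTable(cohort)
    x$measure_kind <- x$measure
    x
  } else normalizeCohort(cohort, mode = "relative")
  m <- m[m$measure %in% measures, , drop = FALSE]
  if (frontolimbicOnly) {
    reg <- regionRegistry()
    m <- m[reg$frontolimbic[match(m$region, reg$region)], , drop = FALSE]
  }
  L <- m[m$hemisphere == "left", , drop = FALSE]
  R <- m[m$hemisphere == "right", , drop = FALSE]
  key <- function(d) paste(d$subject_id, d$region, d$measure, sep = "|")
  i <- match(key(L), key(R))
  ok <- !is.na(i)
  ndrop <- sum(!ok) + sum(!(key(R) %in% key(L)))
  if (ndrop)
    warnf("%d unpaired hemisphere value(s) excluded from AI", ndrop)
  L <- L[ok, , drop = FALSE]
  Rv <- R$value[i[ok]]
  zero <- L$value + Rv == 0
  if (any(zero)) {
    warnf("%d record(s) with left + right = 0 dropped (undefined AI)",
          sum(zero))
    L <- L[!zero, , drop = FALSE]
    Rv <- Rv[!zero]
  }
  out <- data.frame(subject_id = L$subject_id, region = L$region,
                    measure = L$measure, left_value = L$value,
                    right_value = Rv,
                    ai = asymmetryIndex(L$value, Rv),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
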