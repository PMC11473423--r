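#' @importFrom stats aov anova coef fitted lm p.adjust pairwise.t.test
#'   predict pnorm rnorm runif sd setNames var wilcox.test BIC psignrank
#'   complete.cases
#' @importFrom utils read.delim read.table write.table head packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Default age-group binning
#'
#' Maps scan age in months to a yearly age group, `clamp(floor(age/12), 1, 5)`.
#' Children younger than 12 months fall into group 1 and older than 71 months
#' into group 5, matching a five-group preschool design.
#'
#' @param age_months numeric vector of ages in months (> 0).
#' @return integer vector of group labels in 1..5.
#' @export
#' @examples
#' ageGroup(c(14, 30, 71))
ageGroup <- function(age_months) {
  stopifnot(is.numeric(age_months), all(age_months > 0))
  as.integer(pmin(pmax(floor(age_months / 12), 1L), 5L))
}

# cubic smoothstep on [0,1]; 0 below, 1 above
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assertColumns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}
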