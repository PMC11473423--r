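## Sliding-window localization of emerging hemispheric asymmetry.
##
## Subjects are binned into fixed-width age windows (default 12 months,
## advanced by a 1-month stride). In each window the region's AI values
## are tested against a zero-asymmetry null with the Wilcoxon
## signed-rank test, p-values are Benjamini-Hochberg corrected across
## regions within each (window, measure) family, and a region's
## "initial point" of lateralization is the midpoint of the earliest
## window with q below alpha.

#' Build sliding age windows
#'
#' Windows start at the youngest age and advance by `stride` while
#' `start + width <= max(age) + stride`; membership is the half-open
#' interval `[start, start + width)`. With
#' `convention = "integer-inclusive"` starts are floored to integer
#' months and a window is reported as the inclusive integer range
#' `[start, start + width - 1]`, so midpoints fall on half months
#' (e.g. a 12-month window starting at 14 has midpoint 19.5);
#' membership is unchanged. A window narrower than the configured
#' minimum size is still emitted but flagged untestable. If `width`
#' exceeds the whole age span a single window containing every subject
#' is returned.
#'
#' @param ages numeric vector of ages in months.
#' @param ids subject identifiers parallel to `ages` (default
#'   `seq_along(ages)`).
#' @param width window width in months (default 12).
#' @param stride window advance in months (default 1; `stride = width`
#'   gives non-overlapping windows).
#' @param minN minimum window size considered testable (default 5; note
#'   two-sided exact signed-rank significance at alpha = 0.05 is
#'   unattainable below n = 6).
#' @param convention `"half-open"` (default) or `"integer-inclusive"`.
#' @return data.frame `window_id`, `start`, `end`, `midpoint`, `n`,
#'   `testable`, plus a `members` list-column of subject ids.
#' @export
buildWindows <- function(ages, ids = seq_along(ages), width = 12,
                         stride = 1, minN = 5,
                         convention = c("half-open", "integer-inclusive")) {
  convention <- match.arg(convention)
  if (!length(ages)) stopf("empty cohort: no ages to window")
  stopifnot(width > 0, stride > 0, length(ids) == length(ages))
  if (stride > width)
    warnf("stride (%g) exceeds width (%g): windows leave age gaps", stride,
          width)
  amin <- if (convention == "integer-inclusive") floor(min(ages))
          else min(ages)
  amax <- max(ages)
  n_win <- max(1L, floor((amax + stride - width - amin) / stride) + 1L)
  starts <- amin + stride * (seq_len(n_win) - 1L)
  members <- lapply(starts, function(s) ids[ages >= s & ages < s + width])
  n <- lengths(members)
  end <- if (convention == "integer-inclusive") starts + width - 1
         else starts + width
  out <- data.frame(window_id = seq_along(starts), start = starts,
                    end = end, midpoint = (starts + end) / 2, n = n,
                    testable = n >= minN)
  out$members <- members
  out
}

#' Wilcoxon signed-rank test against a location null
#'
#' One-sample two-sided signed-rank test of `values` against `mu0`.
#' Zeros (values equal to `mu0`) are dropped (the classic Wilcoxon
#' convention) and tied absolute values receive midranks. The null
#' distribution is exact — from the signed-rank distribution when there
#' are no ties and n <= 25, and by full enumeration of all 2^n sign
#' assignments of the midranks when ties are present and n <= 14 —
#' otherwise a normal approximation with tie and continuity corrections
#' is used. Two-sided p doubles the smaller tail, capped at 1.
#'
#' @param values numeric vector.
#' @param mu0 null location (default 0).
#' @return list with `statistic` (W, the positive-rank sum), `p.value`,
#'   `n` (after zero removal) and `method`. All-zero input yields `NA`
#'   with a warning.
#' @export
wilcoxonSignedRank <- function(values, mu0 = 0) {
  x <- values - mu0
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    warnf("all values equal the null location; test undefined")
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                method = "untestable"))
  }
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  ties <- anyDuplicated(abs(x)) > 0L
  if (!ties && n <= 25L) {
    ht <- wilcox.test(x, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                n = n, method = "exact"))
  }
  if (ties && n <= 14L) {
    seq0 <- 0:(2^n - 1)
    B <- vapply(seq_len(n) - 1L,
                function(b) bitwAnd(seq0, bitwShiftL(1L, b)) > 0L,
                logical(length(seq0)))
    W_dist <- as.numeric(B %*% r)
    p <- min(1, 2 * min(mean(W_dist <= W), mean(W_dist >= W)))
    return(list(statistic = W, p.value = p, n = n,
                method = "exact-enumeration"))
  }
  ht <- suppressWarnings(wilcox.test(x, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value, n = n,
       method = "normal-approximation")
}

#' Window-level asymmetry tests
#'
#' For every (region, measure, window): the window members' AI values
#' are averaged and tested against zero with
#' [wilcoxonSignedRank()]; q-values are Benjamini-Hochberg within each
#' (window, measure) family across regions (the 8- or 11-region family
#' sizes; `fdrFamily = "per-region"` corrects across windows within a
#' region instead, an experimental alternative). Windows with fewer
#' than `minN` AI values for a region are reported untestable (`NA`
#' test fields).
#'
#' @param ai asymmetry records from [computeAsymmetry()].
#' @param windows windows from [buildWindows()] (built with subject
#'   ids as `ids`).
#' @param alpha significance level for direction calls (default 0.05).
#' @param minN minimum testable per-region window size (default 5).
#' @param fdrFamily `"per-window"` (default) or `"per-region"`.
#' @return data.frame `region`, `measure`, `window_id`, `start`, `end`,
#'   `midpoint`, `n`, `mean_ai`, `w_statistic`, `p_value`, `q_value`,
#'   `direction`.
#' @export
testWindows <- function(ai, windows, alpha = 0.05, minN = 5,
                        fdrFamily = c("per-window", "per-region")) {
  fdrFamily <- match.arg(fdrFamily)
  assertColumns(ai, c("subject_id", "region", "measure", "ai"),
                "asymmetry records")
  combos <- unique(ai[, c("region", "measure")])
  rows <- vector("list", nrow(combos) * nrow(windows))
  k <- 0L
  for (i in seq_len(nrow(combos))) {
    rg <- combos$region[i]; ms <- combos$measure[i]
    sub <- ai[ai$region == rg & ai$measure == ms, , drop = FALSE]
    for (w in seq_len(nrow(windows))) {
      vals <- sub$ai[sub$subject_id %in% windows$members[[w]]]
      k <- k + 1L
      base <- data.frame(region = rg, measure = ms,
                         window_id = windows$window_id[w],
                         start = windows$start[w], end = windows$end[w],
                         midpoint = windows$midpoint[w], n = length(vals),
                         stringsAsFactors = FALSE)
      if (length(vals) < minN) {
        rows[[k]] <- cbind(base, mean_ai = if (length(vals)) mean(vals)
                                           else NA_real_,
                           w_statistic = NA_real_, p_value = NA_real_)
      } else {
        wt <- suppressWarnings(wilcoxonSignedRank(vals))
        rows[[k]] <- cbind(base, mean_ai = mean(vals),
                           w_statistic = wt$statistic,
                           p_value = wt$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  fam <- if (fdrFamily == "per-window") {
    paste(out$window_id, out$measure)
  } else {
    paste(out$region, out$measure)
  }
  for (f in unique(fam)) {
    j <- fam == f
    out$q_value[j] <- fdrAdjust(out$p_value[j])
  }
  out$direction <- "none"
  sig <- !is.na(out$q_value) & out$q_value < alpha
  out$direction[sig & out$mean_ai > 0] <- "left"
  out$direction[sig & out$mean_ai < 0] <- "right"
  out$direction[is.na(out$p_value)] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Initial point of significant lateralization
#'
#' Scans each region's window results in increasing midpoint order; the
#' first window with `q_value < alpha` defines the initial point (its
#' midpoint, months) and the asymmetry direction (sign of that window's
#' mean AI). Regions with no significant window report `NA`.
#'
#' @param window_results output of [testWindows()].
#' @param alpha significance level (default 0.05).
#' @return data.frame `region`, `measure`, `asymmetry_direction`,
#'   `initial_point_months`, `q_at_initial_point`.
#' @export
detectEmergence <- function(window_results, alpha = 0.05) {
  combos <- unique(window_results[, c("region", "measure")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- window_results[window_results$region == combos$region[i] &
                          window_results$measure == combos$measure[i], ,
                          drop = FALSE]
    sub <- sub[order(sub$midpoint), , drop = FALSE]
    hit <- which(!is.na(sub$q_value) & sub$q_value < alpha)
    if (!length(hit)) {
      data.frame(region = combos$region[i], measure = combos$measure[i],
                 asymmetry_direction = NA_character_,
                 initial_point_months = NA_real_,
                 q_at_initial_point = NA_real_, stringsAsFactors = FALSE)
    } else {
      h <- hit[1]
      data.frame(region = combos$region[i], measure = combos$measure[i],
                 asymmetry_direction = if (sub$mean_ai[h] > 0) "left"
                                       else if (sub$mean_ai[h] < 0) "right"
                                       else "none",
                 initial_point_months = sub$midpoint[h],
                 q_at_initial_point = sub$q_value[h],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-average regional asymmetry
#'
#' Cohort-mean AI per (region, measure) with a direction label, the
#' whole-cohort summary behind population asymmetry maps.
#'
#' @param ai asymmetry records from [computeAsymmetry()].
#' @return data.frame `region`, `measure`, `n`, `mean_ai`, `direction`.
#' @export
populationAverageAsymmetry <- function(ai) {
  assertColumns(ai, c("region", "measure", "ai"), "asymmetry records")
  key <- paste(ai$region, ai$measure, sep = "|")
  agg <- lapply(split(ai, key), function(d) {
    m <- mean(d$ai)
    data.frame(region = d$region[1], measure = d$measure[1], n = nrow(d),
               mean_ai = m,
               direction = if (m > 0) "left" else if (m < 0) "right"
                           else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$measure, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
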