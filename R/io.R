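## Readers and writers: FreeSurfer stats dialect (aseg/aparc style) and
## long-format delimited cohort tables.

.parseStatsLines <- function(lines, path) {
  comments <- grep("^#", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  # eTIV header, e.g.
  # Measure EstimatedTotalIntraCranialVol, eTIV, ..., 1234567.000000, mm^3
  etiv <- NA_real_
  et <- grep("Measure EstimatedTotalIntraCranialVol", comments, value = TRUE)
  if (length(et)) {
    parts <- strsplit(et[1], ",")[[1]]
    num <- suppressWarnings(as.numeric(trimws(parts)))
    num <- num[!is.na(num)]
    if (length(num)) etiv <- num[1]
  }
  hemi <- NA_character_
  hl <- grep("^#\\s*hemi\\s+", comments, value = TRUE)
  if (length(hl)) {
    h <- trimws(sub("^#\\s*hemi\\s+", "", hl[1]))
    hemi <- switch(h, lh = "left", rh = "right", NA_character_)
  }
  ch <- grep("^#\\s*ColHeaders\\s+", comments, value = TRUE)
  if (!length(ch))
    stopf("no '# ColHeaders' line in stats file: %s", path)
  headers <- strsplit(trimws(sub("^#\\s*ColHeaders\\s+", "", ch[1])),
                      "\\s+")[[1]]
  if (!length(data_lines))
    return(list(table = NULL, headers = headers, etiv = etiv, hemi = hemi))
  tab <- read.table(text = data_lines, header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) != length(headers))
    stopf("stats file %s: %d data columns but %d ColHeaders", path,
          ncol(tab), length(headers))
  names(tab) <- headers
  list(table = tab, headers = headers, etiv = etiv, hemi = hemi)
}

#' Read a FreeSurfer-style regional statistics file
#'
#' Parses the FreeSurfer stats text dialect: comment lines starting
#' `#`, whitespace-delimited data rows, column names on a
#' `# ColHeaders` line. Two flavours are recognised automatically:
#' aseg-like files (a `Volume_mm3` column; subcortical volumes; eTIV in
#' a `# Measure EstimatedTotalIntraCranialVol` header) and aparc-like
#' per-hemisphere files (`GrayVol` and `ThickAvg` columns; the
#' hemisphere is taken from a `# hemi lh|rh` line or the `hemisphere`
#' argument). Region labels are mapped to canonical registry names via
#' the packaged alias table; rows whose label has no alias are skipped
#' with a warning.
#'
#' @param path path to the stats file.
#' @param subject_id subject identifier attached to every measure.
#' @param hemisphere optional `"left"`/`"right"` override for
#'   aparc-like files lacking a `# hemi` header.
#' @return list with elements `measures` (data.frame `subject_id`,
#'   `region`, `hemisphere`, `measure`, `value`), `etiv` (numeric or
#'   `NA`) and `unmapped` (character vector of skipped labels).
#' @export
readFreesurferStats <- function(path, subject_id, hemisphere = NULL) {
  if (!file.exists(path)) stopf("cannot read stats file: %s", path)
  p <- .parseStatsLines(readLines(path, warn = FALSE), path)
  tab <- p$table
  empty <- data.frame(subject_id = character(), region = character(),
                      hemisphere = character(), measure = character(),
                      value = numeric(), stringsAsFactors = FALSE)
  if (is.null(tab))
    return(list(measures = empty, etiv = p$etiv, unmapped = character()))
  if (!"StructName" %in% names(tab))
    stopf("stats file %s has no StructName column", path)
  mapped <- mapRegionLabel(tab$StructName)
  unmapped <- mapped$fs_label[is.na(mapped$region)]
  if (length(unmapped))
    warnf("%s: %d row(s) with unmapped region label(s) skipped: %s", path,
          length(unmapped), paste(unique(unmapped), collapse = ", "))
  keep <- !is.na(mapped$region)
  tab <- tab[keep, , drop = FALSE]
  mapped <- mapped[keep, , drop = FALSE]

  out <- list()
  if ("Volume_mm3" %in% names(tab)) {           # aseg-like
    .checkNonNegative(tab$Volume_mm3, tab$StructName, path, "Volume_mm3")
    out$vol <- data.frame(subject_id = subject_id, region = mapped$region,
                          hemisphere = mapped$hemisphere, measure = "volume",
                          value = tab$Volume_mm3, stringsAsFactors = FALSE)
  }
  if (any(c("GrayVol", "ThickAvg") %in% names(tab))) {  # aparc-like
    hemi <- p$hemi %||% NA_character_
    if (!is.na(hemi) && !is.null(hemisphere) && hemisphere != hemi)
      warnf("%s: hemisphere argument '%s' overrides '# hemi' header '%s'",
            path, hemisphere, hemi)
    if (!is.null(hemisphere)) hemi <- hemisphere
    if (is.na(hemi))
      stopf("aparc-like file %s: hemisphere unknown (no '# hemi' header; %s",
            path, "pass hemisphere = 'left' or 'right')")
    fill <- is.na(mapped$hemisphere)
    mapped$hemisphere[fill] <- hemi
    if ("GrayVol" %in% names(tab)) {
      .checkNonNegative(tab$GrayVol, tab$StructName, path, "GrayVol")
      out$gv <- data.frame(subject_id = subject_id, region = mapped$region,
                           hemisphere = mapped$hemisphere,
                           measure = "volume", value = tab$GrayVol,
                           stringsAsFactors = FALSE)
    }
    if ("ThickAvg" %in% names(tab)) {
      .checkNonNegative(tab$ThickAvg, tab$StructName, path, "ThickAvg")
      out$th <- data.frame(subject_id = subject_id, region = mapped$region,
                           hemisphere = mapped$hemisphere,
                           measure = "thickness", value = tab$ThickAvg,
                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stopf("stats file %s has neither Volume_mm3 nor GrayVol/ThickAvg columns",
          path)
  measures <- do.call(rbind, out)
  rownames(measures) <- NULL
  list(measures = measures, etiv = p$etiv, unmapped = unique(unmapped))
}

.checkNonNegative <- function(v, labels, path, col) {
  bad <- which(v < 0)
  if (length(bad))
    stopf("%s: negative %s for row '%s'", path, col, labels[bad[1]])
}

#' Read a per-subject FreeSurfer stats tree into a cohort
#'
#' Expects `dir/participants.tsv` (columns `subject_id`, `age_months`,
#' `sex`) and, for each subject, `dir/<subject_id>/stats/aseg.stats`,
#' `lh.aparc.stats`, `rh.aparc.stats`. eTIV is taken from the aseg
#' header.
#'
#' @param dir root directory of the tree.
#' @return a [MorphoCohort-class].
#' @export
readCohortTree <- function(dir) {
  pfile <- file.path(dir, "participants.tsv")
  if (!file.exists(pfile)) stopf("missing participants table: %s", pfile)
  part <- read.delim(pfile, stringsAsFactors = FALSE)
  assertColumns(part, c("subject_id", "age_months", "sex"),
                "participants.tsv")
  meas <- vector("list", nrow(part))
  etiv <- numeric(nrow(part))
  for (i in seq_len(nrow(part))) {
    sid <- part$subject_id[i]
    sdir <- file.path(dir, sid, "stats")
    aseg <- readFreesurferStats(file.path(sdir, "aseg.stats"), sid)
    lh <- readFreesurferStats(file.path(sdir, "lh.aparc.stats"), sid)
    rh <- readFreesurferStats(file.path(sdir, "rh.aparc.stats"), sid)
    meas[[i]] <- rbind(aseg$measures, lh$measures, rh$measures)
    if (is.na(aseg$etiv)) stopf("subject %s: no eTIV in aseg.stats", sid)
    etiv[i] <- aseg$etiv
  }
  subjects <- data.frame(subject_id = part$subject_id,
                         age_months = part$age_months, sex = part$sex,
                         etiv = etiv, stringsAsFactors = FALSE)
  MorphoCohort(subjects, do.call(rbind, meas),
               provenance = paste("FreeSurfer stats tree:", dir))
}

.cohortColumns <- c("subject_id", "age_months", "sex", "etiv", "region",
                    "hemisphere", "measure", "value")

#' Read a long-format cohort table
#'
#' Reads a delimited (CSV or TSV, by file extension) long-format table
#' with columns `subject_id`, `age_months`, `sex`, `etiv`, `region`,
#' `hemisphere`, `measure`, `value` — one row per measurement, subject
#' metadata repeated — and validates it into a [MorphoCohort-class].
#' Missing columns raise a schema error naming them; duplicate
#' (subject, region, hemisphere, measure) keys are rejected.
#'
#' @param path file path.
#' @return a [MorphoCohort-class].
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stopf("cannot read cohort table: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  assertColumns(tab, .cohortColumns, sprintf("cohort table %s", path))
  subjects <- unique(tab[, c("subject_id", "age_months", "sex", "etiv")])
  if (anyDuplicated(subjects$subject_id))
    stopf("inconsistent subject metadata for duplicated subject_id")
  MorphoCohort(subjects,
               tab[, c("subject_id", "region", "hemisphere", "measure",
                       "value")],
               provenance = paste("long-format table:", path))
}

#' Write a cohort as a long-format table
#'
#' Inverse of [readCohortTable()]: one row per measurement with subject
#' metadata repeated. Values are written at full double precision
#' (`%.17g`) so a write/read round trip reproduces the in-memory cohort
#' field-for-field, and output is byte-stable for identical input.
#'
#' @param cohort a [MorphoCohort-class].
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  m <- measureTable(cohort)
  s <- subjectData(cohort)
  i <- match(m$subject_id, s$subject_id)
  out <- data.frame(subject_id = m$subject_id,
                    age_months = sprintf("%.17g", s$age_months[i]),
                    sex = s$sex[i],
                    etiv = sprintf("%.17g", s$etiv[i]),
                    region = m$region, hemisphere = m$hemisphere,
                    measure = m$measure,
                    value = sprintf("%.17g", m$value),
                    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Population-level outlier flags
#'
#' Flags measurements whose absolute z-score within their
#' (region, hemisphere, measure) cohort cell exceeds `z_threshold`.
#' This is a simple population-level quality-control screen; flags are
#' advisory — nothing is removed unless [applyQcExclusions()] is called.
#' Cells with zero standard deviation yield no flags (with a warning),
#' and cells with fewer than 3 subjects are skipped with a warning.
#'
#' @param cohort a [MorphoCohort-class].
#' @param z_threshold positive z-score cutoff (default 3).
#' @return data.frame `subject_id`, `region`, `hemisphere`, `measure`,
#'   `value`, `z_score`.
#' @export
qcOutlierFlags <- function(cohort, z_threshold = 3) {
  stopifnot(z_threshold > 0)
  m <- measureTable(cohort)
  cell <- paste(m$region, m$hemisphere, m$measure, sep = "|")
  flags <- lapply(split(seq_len(nrow(m)), cell), function(idx) {
    v <- m$value[idx]
    if (length(v) < 3) {
      warnf("QC cell %s has %d subject(s) (< 3); skipped", cell[idx[1]],
            length(v))
      return(NULL)
    }
    s <- sd(v)
    if (s == 0) {
      warnf("QC cell %s has zero variance; no flags", cell[idx[1]])
      return(NULL)
    }
    z <- (v - mean(v)) / s
    hit <- abs(z) > z_threshold
    if (!any(hit)) return(NULL)
    cbind(m[idx[hit], , drop = FALSE], z_score = z[hit])
  })
  out <- do.call(rbind, flags)
  if (is.null(out))
    out <- cbind(m[0, , drop = FALSE], z_score = numeric())
  rownames(out) <- NULL
  out[order(match(out$subject_id, subjectData(cohort)$subject_id),
            out$region, out$hemisphere, out$measure), , drop = FALSE]
}

#' Remove QC-flagged measurements from a cohort
#'
#' @param cohort a [MorphoCohort-class].
#' @param flags output of [qcOutlierFlags()].
#' @return a new [MorphoCohort-class] without the flagged values.
#' @export
applyQcExclusions <- function(cohort, flags) {
  if (!nrow(flags)) return(cohort)
  m <- measureTable(cohort)
  key <- function(d) paste(d$subject_id, d$region, d$hemisphere, d$measure,
                           sep = "|")
  keep <- !(key(m) %in% key(flags))
  MorphoCohort(subjectData(cohort), m[keep, , drop = FALSE],
               provenance = paste0(cohortProvenance(cohort),
                                   " [", sum(!keep), " QC exclusion(s)]"),
               groundTruth = groundTruth(cohort))
}
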