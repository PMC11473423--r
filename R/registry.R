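## Desikan-Killiany region registry and FreeSurfer label aliasing.
##
## The registry is shipped as a versioned TSV resource
## (inst/extdata/dk_registry.tsv): 34 bilateral cortical parcels of the
## Desikan-Killiany atlas plus the common aseg subcortical structures.
## Eleven paired regions form the fronto-limbic analysis set: thalamus,
## amygdala, hippocampus (subcortical) and rostral/caudal anterior
## cingulate, posterior cingulate, medial/lateral orbitofrontal,
## superior temporal, inferior parietal and fusiform cortex (8 cortical
## pairs, the thickness multiple-testing family).

.registry_env <- new.env(parent = emptyenv())

#' Region registry
#'
#' Returns the packaged Desikan-Killiany region registry: one row per
#' paired region name, with tissue class (`cortical`/`subcortical`), a
#' fronto-limbic membership flag, and a typical surface-area weight
#' (mm\eqn{^2}, cortical only) used for area-weighted hemisphere mean
#' thickness.
#'
#' @return data.frame with columns `region`, `tissue_class`,
#'   `frontolimbic`, `area_weight`.
#' @export
#' @examples
#' r <- regionRegistry()
#' sum(r$tissue_class == "cortical")  # 34 pairs, 68 labels
regionRegistry <- function() {
  if (is.null(.registry_env$registry)) {
    path <- system.file("extdata", "dk_registry.tsv", package = "MorphoDev",
                        mustWork = TRUE)
    reg <- read.delim(path, stringsAsFactors = FALSE)
    reg$frontolimbic <- as.logical(reg$frontolimbic)
    .registry_env$registry <- reg
  }
  .registry_env$registry
}

.aliasTable <- function() {
  if (is.null(.registry_env$aliases)) {
    path <- system.file("extdata", "fs_aliases.tsv", package = "MorphoDev",
                        mustWork = TRUE)
    .registry_env$aliases <- read.delim(path, stringsAsFactors = FALSE)
  }
  .registry_env$aliases
}

#' Fronto-limbic region names
#'
#' @param tissue restrict to `"cortical"` or `"subcortical"` regions, or
#'   `"all"` (default) for the full 11-pair set.
#' @return character vector of canonical region names.
#' @export
frontolimbicRegions <- function(tissue = c("all", "cortical", "subcortical")) {
  tissue <- match.arg(tissue)
  reg <- regionRegistry()
  reg <- reg[reg$frontolimbic, , drop = FALSE]
  if (tissue != "all") reg <- reg[reg$tissue_class == tissue, , drop = FALSE]
  reg$region
}

#' Map FreeSurfer labels to canonical registry regions
#'
#' Resolves FreeSurfer stats-file labels (e.g. `"Left-Thalamus-Proper"`,
#' `"rostralanteriorcingulate"`) to canonical region names. Cortical
#' aparc base labels map to themselves with hemisphere `NA` (the
#' hemisphere comes from the per-hemisphere file); aseg labels carry
#' their hemisphere. Unmapped labels yield `NA` rows.
#'
#' @param labels character vector of FreeSurfer labels.
#' @return data.frame with columns `fs_label`, `region`, `hemisphere`.
#' @export
mapRegionLabel <- function(labels) {
  reg <- regionRegistry()
  ali <- .aliasTable()
  region <- rep(NA_character_, length(labels))
  hemisphere <- rep(NA_character_, length(labels))
  i <- match(labels, ali$fs_label)
  hit <- !is.na(i)
  region[hit] <- ali$region[i[hit]]
  hemisphere[hit] <- ali$hemisphere[i[hit]]
  cort <- !hit & labels %in% reg$region[reg$tissue_class == "cortical"]
  region[cort] <- labels[cort]
  data.frame(fs_label = labels, region = region, hemisphere = hemisphere,
             stringsAsFactors = FALSE)
}

.corticalRegions <- function() {
  reg <- regionRegistry()
  reg$region[reg$tissue_class == "cortical"]
}
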