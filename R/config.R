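#' Pipeline configuration
#'
#' Collects every numeric threshold used by the filtering pipeline in one
#' list. Defaults are the published values of the method; any override is
#' recorded in the `overrides` attribute so a run can report how it deviated
#' from the defaults.
#'
#' @param coverage_class `"30x"` or `"15x"`. Sets the depth and VAF thresholds
#'   of the pre-filter and the excess-coverage breakend rule.
#' @param seed Integer seed used by stochastic steps (random-forest training,
#'   subsampling).
#' @param ... Named overrides of any default listed below.
#'
#' @details Defaults:
#' * `min_qual = 100` — site quality (QUAL), inclusive.
#' * `min_depth_30x = 10`, `min_depth_15x = 5` — minimum base coverage in the
#'   test and each control sample.
#' * `min_mq = 55` — mapping quality, strict (`> 55` passes).
#' * `min_gq_het = 99`, `min_gq_hom = 10` — genotype-quality minima for
#'   heterozygous and homozygous-alt base substitutions (inclusive).
#' * `min_vaf_snv_30x = 0.3`, `min_vaf_snv_15x = 0.2`, `min_vaf_indel = 0.25`
#'   — VAF minima (inclusive).
#' * `ai_window = 2e5`, `ai_min_hets = 10`, `ai_loess_degree = 2`,
#'   `ai_baf_clamp = 0.001` — allelic-imbalance model.
#' * `linkage_error_rate = 0.005`, `linkage_phred_cap = 3000`,
#'   `linkage_low = 100`, `linkage_high = 1000` — read-backed phasing score.
#' * `rf_ntree = 500`, `rf_mtry = 4`, `distance_cap = 1e7` — random forest.
#' * `pr_best_min = 0.7`, `cosine_grid = seq(0.1, 0.8, by = 0.025)`,
#'   `pr_grid = seq(0, 1, by = 0.01)`, `min_spectrum_mutations = 30` —
#'   cutoff calibration.
#' * `indel_min_vaf_exclusion = 0.15`, `homopolymer_min_run = 5` — indel
#'   filter.
#' * `sv_gamma = 100`, `sv_bin = 1000`, `sv_coarse_bin = 1e5`,
#'   `pon_outlier_quantile = 0.01`, `centromere_margin = 1e6`,
#'   `sample_p_max = 0.05`, `pon_p_max = 0.2`, `daf_loh = 0.45`,
#'   `mode_tol = 0.12`, `mode_density_min = 0.1`, `min_hets_per_segment = 20`,
#'   `daf_snap_window = 2e5`, `daf_snap_tol = 0.1` — CNV/cnLOH calling.
#' * `bnd_pon_window = 2000`, `dup_min_daf = 0.18`, `dup_min_cn = 2.5`,
#'   `del_min_daf = 0.4`, `del_max_cn = 1.5`, `inv_min_size = 1000`,
#'   `ctx_rescue_dist = 1e5`, `max_bin_coverage_15x = 100` — breakend filter.
#'
#' @return A list of class `ptascrub_config`.
#' @export
#' @examples
#' cfg <- ptascrub_config("15x", min_qual = 50)
#' attr(cfg, "overrides")
ptascrub_config <- function(coverage_class = c("30x", "15x"), seed = 1L, ...) {
  coverage_class <- match.arg(coverage_class)
  cfg <- list(
    coverage_class = coverage_class,
    seed = as.integer(seed),
    # prefilter
    min_qual = 100,
    min_depth_30x = 10,
    min_depth_15x = 5,
    min_mq = 55,
    min_gq_het = 99,
    min_gq_hom = 10,
    min_vaf_snv_30x = 0.3,
    min_vaf_snv_15x = 0.2,
    min_vaf_indel = 0.25,
    # allelic imbalance
    ai_window = 2e5,
    ai_min_hets = 10,
    ai_loess_degree = 2,
    ai_baf_clamp = 0.001,
    # linked reads
    linkage_error_rate = 0.005,
    linkage_phred_cap = 3000,
    linkage_low = 100,
    linkage_high = 1000,
    # random forest
    rf_ntree = 500,
    rf_mtry = 4,
    distance_cap = 1e7,
    # cutoff calibration
    pr_grid = seq(0, 1, by = 0.01),
    pr_best_min = 0.7,
    cosine_grid = seq(0.1, 0.8, by = 0.025),
    min_spectrum_mutations = 30,
    # indels
    indel_min_vaf_exclusion = 0.15,
    homopolymer_min_run = 5,
    # SV: coverage + DAF
    sv_gamma = 100,
    sv_bin = 1000,
    sv_coarse_bin = 1e5,
    pon_outlier_quantile = 0.01,
    centromere_margin = 1e6,
    sample_p_max = 0.05,
    pon_p_max = 0.2,
    daf_loh = 0.45,
    mode_tol = 0.12,
    mode_density_min = 0.1,
    min_hets_per_segment = 20,
    daf_snap_window = 2e5,
    daf_snap_tol = 0.1,
    # SV: breakends
    bnd_pon_window = 2000,
    dup_min_daf = 0.18,
    dup_min_cn = 2.5,
    del_min_daf = 0.4,
    del_max_cn = 1.5,
    inv_min_size = 1000,
    ctx_rescue_dist = 1e5,
    max_bin_coverage_15x = 100
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "ptascrub_config", overrides = names(dots))
}

#' @export
print.ptascrub_config <- function(x, ...) {
  cat("<ptascrub_config> coverage class", x$coverage_class, "\n")
  ov <- attr(x, "overrides")
  if (length(ov)) {
    cat("overridden:", paste(ov, collapse = ", "), "\n")
  } else {
    cat("all thresholds at defaults\n")
  }
  invisible(x)
}

# depth / VAF thresholds resolved for the configured coverage class
cfg_min_depth <- function(cfg) {
  if (cfg$coverage_class == "30x") cfg$min_depth_30x else cfg$min_depth_15x
}
cfg_min_vaf_snv <- function(cfg) {
  if (cfg$coverage_class == "30x") cfg$min_vaf_snv_30x else cfg$min_vaf_snv_15x
}

#' Read or write a key-value configuration file
#'
#' The file format is one `key = value` pair per line; `#` starts a comment.
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path File path.
#' @param coverage_class,seed Passed to [ptascrub_config()] unless present in
#'   the file.
#' @return A `ptascrub_config`.
#' @export
read_config <- function(path, coverage_class = "30x", seed = 1L) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- lapply(kv, function(p) {
    v <- p[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  if (!is.null(vals$coverage_class)) {
    coverage_class <- vals$coverage_class
    vals$coverage_class <- NULL
  }
  if (!is.null(vals$seed)) {
    seed <- as.integer(vals$seed)
    vals$seed <- NULL
  }
  if (!is.null(vals$pr_grid) || !is.null(vals$cosine_grid)) {
    abort("grids cannot be set from a config file")
  }
  do.call(ptascrub_config,
          c(list(coverage_class = coverage_class, seed = seed), vals))
}

#' @rdname read_config
#' @param cfg A `ptascrub_config` to serialize.
#' @export
write_config <- function(cfg, path) {
  scalar <- vapply(cfg, function(v) is.atomic(v) && length(v) == 1L, TRUE)
  lines <- paste(names(cfg)[scalar], unlist(cfg[scalar]), sep = " = ")
  writeLines(lines, path)
  invisible(path)
}
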