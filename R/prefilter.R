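#' Apply quality, depth, VAF, control and panel-of-normals pre-filters
#'
#' Implements the candidate-somatic definition: a variant is candidate somatic
#' iff its flag set is empty after this step. All failures are recorded
#' cumulatively, not first-hit. The rules, with the inequality directions
#' locked by boundary tests:
#'
#' * `FAIL_QUAL` — site QUAL below 100 (`>= 100` passes), or a non-PASS
#'   `FILTER` value already present in the input VCF (the upstream hard
#'   filters are honored, not recomputed).
#' * `FAIL_DEPTH` — base coverage (AD sum, falling back to DP when AD is
#'   missing) below 10 (30x class) or 5 (15x class) in the test sample or any
#'   control.
#' * `FAIL_MQ` — mapping quality not strictly greater than 55.
#' * `FAIL_GQ` — base substitutions: GQ < 99 for heterozygous, GQ < 10 for
#'   homozygous-alt calls. Indels: GQ < 99 in the test sample or any control.
#' * `FAIL_VAF` — base substitutions with VAF < 0.2 (15x) or < 0.3 (30x);
#'   indels with VAF < 0.25.
#' * `FAIL_CONTROL_EVIDENCE` — any control sample shows the variant
#'   (`alt_depth > 0` or a non-hom-ref genotype). With no dedicated control
#'   (`shared_counts` supplied), a variant seen in two or more samples of the
#'   individual is flagged instead: only private variants survive.
#' * `FAIL_PON` — exact `chrom, pos, ref, alt` match in the panel of normals.
#'
#' Missing fields never pass silently: an `NA` quality/depth/VAF fails its
#' check (strictest reading), except `mq`, which is skipped when absent from
#' the input.
#'
#' @param variants Variant tibble from [read_variants()] (or the simulator).
#' @param pon_sites Optional tibble `chrom, pos, ref, alt` from
#'   [read_pon_sites()].
#' @param config A [ptascrub_config()]; `coverage_class` must be set.
#' @param shared_counts Optional tibble `chrom, pos, ref, alt, n_samples`
#'   giving, for the no-control mode, the number of samples of the same
#'   individual carrying each variant.
#' @return `variants` with the `flags` list-column populated.
#' @export
apply_prefilters <- function(variants, pon_sites = NULL, config = ptascrub_config(),
                             shared_counts = NULL) {
  if (is.null(config$coverage_class)) abort("coverage_class unset in config")
  min_depth <- cfg_min_depth(config)
  min_vaf_snv <- cfg_min_vaf_snv(config)
  n <- nrow(variants)
  if (n == 0L) return(variants)
  flags <- variants$flags
  add <- function(flags, idx, flag) {
    flags[idx] <- lapply(flags[idx], function(f) union(f, flag))
    flags
  }
  is_snv <- variants$var_type == "SNV"

  # QUAL and pre-existing FILTER
  fail_qual <- is.na(variants$qual) | variants$qual < config$min_qual
  if ("filter_input" %in% names(variants)) {
    fail_qual <- fail_qual |
      !(variants$filter_input %in% c("PASS", ".", NA))
  }
  flags <- add(flags, which(fail_qual), "FAIL_QUAL")

  # depth in test and every control
  depth_of <- function(ref_d, alt_d, dp) {
    ad_sum <- ref_d + alt_d
    ifelse(is.na(ad_sum), dp, ad_sum)
  }
  test_depth <- depth_of(variants$ref_depth, variants$alt_depth, variants$depth)
  ctrl_min_depth <- vapply(variants$controls, function(df) {
    if (!nrow(df)) return(Inf)
    d <- depth_of(df$ref_depth, df$alt_depth, df$depth)
    if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
  }, 1)
  fail_depth <- is.na(test_depth) | test_depth < min_depth |
    is.na(ctrl_min_depth) | ctrl_min_depth < min_depth
  flags <- add(flags, which(fail_depth), "FAIL_DEPTH")

  # mapping quality, strict inequality; skipped when the input lacks MQ
  if ("mq" %in% names(variants) && any(!is.na(variants$mq))) {
    fail_mq <- is.na(variants$mq) | variants$mq <= config$min_mq
    flags <- add(flags, which(fail_mq), "FAIL_MQ")
  }

  # genotype quality
  gq <- variants$gq
  fail_gq_snv <- is_snv & (
    (variants$genotype == "het" & (is.na(gq) | gq < config$min_gq_het)) |
    (variants$genotype == "hom_alt" & (is.na(gq) | gq < config$min_gq_hom)))
  ctrl_min_gq <- vapply(variants$controls, function(df) {
    if (!nrow(df) || all(is.na(df$gq))) Inf else min(df$gq, na.rm = TRUE)
  }, 1)
  fail_gq_indel <- !is_snv & ((is.na(gq) | gq < config$min_gq_het) |
                                ctrl_min_gq < config$min_gq_het)
  flags <- add(flags, which(fail_gq_snv | fail_gq_indel), "FAIL_GQ")

  # VAF
  fail_vaf <- ifelse(is_snv,
                     is.na(variants$vaf) | variants$vaf < min_vaf_snv,
                     is.na(variants$vaf) | variants$vaf < config$min_vaf_indel)
  flags <- add(flags, which(fail_vaf), "FAIL_VAF")

  # control evidence / private-variant mode
  has_controls <- any(vapply(variants$controls, nrow, 1L) > 0L)
  if (has_controls) {
    ctrl_evidence <- vapply(variants$controls, function(df) {
      if (!nrow(df)) return(FALSE)
      any((!is.na(df$alt_depth) & df$alt_depth > 0) |
            !df$genotype %in% c("hom_ref", "missing"))
    }, TRUE)
    flags <- add(flags, which(ctrl_evidence), "FAIL_CONTROL_EVIDENCE")
  } else if (!is.null(shared_counts)) {
    key <- paste(norm_chrom(variants$chrom), variants$pos,
                 variants$ref, variants$alt)
    skey <- paste(norm_chrom(shared_counts$chrom), shared_counts$pos,
                  shared_counts$ref, shared_counts$alt)
    n_shared <- shared_counts$n_samples[match(key, skey)]
    flags <- add(flags, which(!is.na(n_shared) & n_shared >= 2L),
                 "FAIL_CONTROL_EVIDENCE")
  }

  # panel of normals
  if (!is.null(pon_sites) && nrow(pon_sites)) {
    key <- paste(norm_chrom(variants$chrom), variants$pos,
                 variants$ref, variants$alt)
    pkey <- paste(norm_chrom(pon_sites$chrom), pon_sites$pos,
                  pon_sites$ref, pon_sites$alt)
    flags <- add(flags, which(key %in% pkey), "FAIL_PON")
  }

  variants$flags <- flags
  variants
}

#' Is a variant currently PASS?
#'
#' @param variants Variant tibble with a `flags` list-column.
#' @return Logical vector, `TRUE` where the flag set is empty.
#' @export
is_pass <- function(variants) lengths(variants$flags) == 0L
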