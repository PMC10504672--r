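#' Classify candidate base substitutions end to end
#'
#' Given prefiltered candidates with phasing scores and feature rows, scores
#' every candidate with the model bundle, calibrates the sample-specific
#' cutoff (precision-recall against the confidently phased variants, cosine
#' similarity over the 96-channel spectra of nested probability groups, and
#' the published merge rule), and flags variants above the final cutoff.
#'
#' @param variants Candidate tibble with `link_phred` (from
#'   [linkage_analysis()]), `flags`, and either `up`/`dn` context columns or
#'   coordinates resolvable in `genome`.
#' @param features Feature tibble aligned with `variants` rows.
#' @param bundle A [train_rf()] bundle.
#' @param genome Optional [ref_genome()] for spectrum context.
#' @param config A [ptascrub_config()].
#' @param oob Use out-of-bag probabilities ([oob_probability()]) — set this
#'   when `variants` are the rows the bundle was trained on.
#' @return List: `variants` (with `p_artifact`, `model_used`, updated flags),
#'   `cutoff` (a `cutoff_result`).
#' @export
classify_candidates <- function(variants, features, bundle, genome = NULL,
                                config = ptascrub_config(), oob = FALSE) {
  stopifnot(nrow(variants) == nrow(features))
  scored <- if (oob) oob_probability(bundle, features)
    else artifact_probability(bundle, features)
  variants$p_artifact <- scored$p_artifact
  variants$model_used <- scored$model_used
  pr <- pr_based_cutoff(variants$link_phred, variants$p_artifact,
                        grid = config$pr_grid, high = config$linkage_high)
  snv <- variants[variants$var_type == "SNV", , drop = FALSE]
  cosine <- cosine_based_cutoff(snv, genome = genome,
                                grid = config$cosine_grid,
                                min_mutations = config$min_spectrum_mutations)
  cut <- final_cutoff(pr, cosine, pr_best_min = config$pr_best_min)
  list(variants = apply_cutoff(variants, cut), cutoff = cut)
}

#' Run the full base-substitution pipeline on simulated data
#'
#' Convenience wrapper chaining the stages on one sample: pre-filters, the
#' allelic-imbalance test, the read-backed phasing analysis, random-forest
#' scoring and cutoff calibration. Mainly used by the end-to-end tests and
#' as executable documentation of the stage order.
#'
#' @param sim Output of [simulate_candidates()].
#' @param hets Phased het series tibble (as [simulate_phased_hets()]).
#' @param evidence Read evidence (as [simulate_read_evidence()]).
#' @param bundle A trained [train_rf()] bundle.
#' @param config A [ptascrub_config()].
#' @param oob Passed to [classify_candidates()].
#' @return List `variants`, `cutoff`.
#' @export
run_snv_pipeline <- function(sim, hets, evidence, bundle,
                             config = ptascrub_config(), oob = FALSE) {
  v <- apply_prefilters(sim$variants, config = config)
  series <- orient_hets(hets)
  v <- ai_test(v, series, config = config)
  v <- linkage_analysis(v, evidence, config = config)
  classify_candidates(v, sim$features, bundle, config = config, oob = oob)
}

#' Plot a coverage/DAF profile along a chromosome
#'
#' @param profile A [normalize_coverage()] result.
#' @param daf Optional [daf_profile()].
#' @param chrom Chromosome to plot.
#' @return A ggplot.
#' @export
plot_coverage_daf <- function(profile, daf = NULL, chrom = NULL) {
  p <- filter(profile, !.data$excluded)
  if (!is.null(chrom)) p <- p[norm_chrom(p$chrom) == norm_chrom(chrom), ]
  df <- tibble(pos = (p$start + p$end) / 2, value = p$ratio,
               track = "normalized coverage ratio")
  if (!is.null(daf)) {
    b <- daf$bins
    if (!is.null(chrom)) b <- b[norm_chrom(b$chrom) == norm_chrom(chrom), ]
    df <- bind_rows(df, tibble(pos = (b$start + b$end) / 2, value = b$value,
                               track = "mean DAF (100 kb)"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~track, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (bp)", y = NULL)
}

#' Plot segment tables
#'
#' Draws segment means as horizontal steps per chromosome; works for both
#' coverage-ratio and DAF segments, and colours by `state` when present
#' (output of [call_cn_segments()]).
#'
#' @param segments A segment tibble from [segment_values()] or
#'   [call_cn_segments()].
#' @return A ggplot.
#' @export
plot_segments <- function(segments) {
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)))
  ycol <- if ("mean" %in% names(segments)) "mean" else "mean_ratio"
  gg <- ggplot2::ggplot(segments,
                        ggplot2::aes(x = .data$start, xend = .data$end,
                                     y = .data[[ycol]], yend = .data[[ycol]]))
  gg <- if ("state" %in% names(segments)) {
    gg + ggplot2::geom_segment(ggplot2::aes(colour = .data$state),
                               linewidth = 1.2)
  } else {
    gg + ggplot2::geom_segment(linewidth = 1.2, colour = "steelblue")
  }
  gg + ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (bp)", y = ycol)
}

#' @rdname plot_coverage_daf
#' @param object A `coverage_profile` or `daf_profile`.
#' @param ... Unused.
#' @export
autoplot.coverage_profile <- function(object, ...) plot_coverage_daf(object)

#' @export
autoplot.daf_profile <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(tibble(pos = (b$start + b$end) / 2, daf = b$value),
                  ggplot2::aes(x = .data$pos, y = .data$daf)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.45, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (bp)", y = "mean DAF (100 kb)")
}

#' Plot precision-recall curves of the cutoff calibration
#'
#' @param pr Result of [pr_based_cutoff()] (with a `curve`).
#' @return A ggplot.
#' @export
plot_pr_curve <- function(pr) {
  stopifnot(!is.null(pr$curve))
  df <- tidyr::pivot_longer(pr$curve, c("precision", "recall"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = pr$pr_cutoff, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "artifact-probability cutoff", y = NULL)
}
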