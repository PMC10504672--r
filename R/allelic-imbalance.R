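#' Orient phased germline heterozygous sites
#'
#' Builds the haplotype-oriented B-allele-frequency series used to model local
#' allelic imbalance. Sites are kept only if they are heterozygous in the bulk
#' control, carry a dbSNP-style identifier, and have a haplotype assignment;
#' the allele depths of sites whose alternate allele is phased to the second
#' haplotype are swapped, so the oriented BAF always measures the same
#' physical haplotype.
#'
#' @param phased_hets Tibble from [read_phased_hets()] (columns `chrom, pos,
#'   id, hap, ref_depth, alt_depth, control_genotype`).
#' @param require_id Keep only sites with a non-`"."` identifier (default
#'   `TRUE`).
#' @return Tibble `chrom, pos, hap, oriented_baf, weight` (weight = total
#'   depth), sorted by position within chromosome. The number of sites dropped
#'   for a missing haplotype label is kept in attribute `n_unphased`, with a
#'   warning when positive.
#' @export
orient_hets <- function(phased_hets, require_id = TRUE) {
  h <- phased_hets
  h <- filter(h, .data$control_genotype == "het")
  if (require_id) h <- filter(h, !is.na(.data$id) & .data$id != ".")
  n_unphased <- sum(is.na(h$hap))
  if (n_unphased > 0L) {
    warn(paste0(n_unphased, " site(s) without haplotype label dropped"))
  }
  h <- filter(h, !is.na(.data$hap))
  total <- h$ref_depth + h$alt_depth
  raw_baf <- ifelse(total > 0, h$alt_depth / total, NA_real_)
  oriented <- ifelse(h$hap == "hap2", 1 - raw_baf, raw_baf)
  out <- tibble(chrom = h$chrom, pos = h$pos, hap = h$hap,
                oriented_baf = oriented, weight = total)
  out <- arrange(filter(out, !is.na(.data$oriented_baf) & .data$weight > 0),
                 .data$chrom, .data$pos)
  attr(out, "n_unphased") <- n_unphased
  out
}

#' Predict the local B-allele frequency at a position
#'
#' Fits a locally weighted least-squares regression (degree 2, tricube kernel
#' with span covering all points in the window, observations weighted by total
#' allele depth) to the oriented BAFs of the phased germline hets within
#' `window` bp of the candidate, and evaluates it at the candidate position.
#' The prediction is clamped to `[clamp, 1 - clamp]` so the downstream
#' binomial test stays defined.
#'
#' @param series Oriented het series from [orient_hets()] (one chromosome, or
#'   filtered by `chrom`).
#' @param candidate_pos 1-based position of the candidate variant.
#' @param chrom Chromosome of the candidate (used to subset `series`).
#' @param window Half-width of the selection window in bp (default 200,000).
#' @param min_hets Minimum informative sites; below it the prediction is
#'   undefined and the classifier falls back to the model without the
#'   allelic-imbalance feature.
#' @param degree Polynomial degree of the local fit.
#' @param clamp Clamp bound away from 0 and 1.
#' @return List with `predicted_baf` (or `NA`), `n_hets`, `defined`.
#' @export
predict_baf <- function(series, candidate_pos, chrom = NULL, window = 2e5,
                        min_hets = 10, degree = 2, clamp = 0.001) {
  s <- series
  if (!is.null(chrom)) s <- s[norm_chrom(s$chrom) == norm_chrom(chrom), ]
  s <- s[abs(s$pos - candidate_pos) <= window, ]
  if (nrow(s) < min_hets) {
    return(list(predicted_baf = NA_real_, n_hets = nrow(s), defined = FALSE))
  }
  fit <- stats::loess(oriented_baf ~ pos, data = s, weights = s$weight,
                      degree = degree, span = 1,
                      control = stats::loess.control(surface = "direct"))
  pred <- unname(predict(fit, newdata = data.frame(pos = candidate_pos)))
  pred <- min(max(pred, clamp), 1 - clamp)
  list(predicted_baf = pred, n_hets = nrow(s), defined = TRUE)
}

#' Log p-value of the allelic-imbalance binomial test
#'
#' Two-sided exact binomial test of the observed alternate-allele count
#' against the predicted local B-allele frequency: the p-value is the sum of
#' the probabilities of all outcomes no more probable than the observed one
#' (the standard exact-binomial convention), returned as a natural logarithm.
#'
#' @param alt_depth Observed alternate-allele count.
#' @param total_depth Total allele depth at the candidate.
#' @param predicted_baf Predicted BAF in (0, 1).
#' @return Natural log of the p-value (`<= 0`); `NA` when `total_depth` is 0.
#' @export
ai_log_p <- function(alt_depth, total_depth, predicted_baf) {
  stopifnot(length(alt_depth) == 1L, length(total_depth) == 1L)
  if (is.na(total_depth) || total_depth == 0) return(NA_real_)
  stopifnot(alt_depth >= 0, alt_depth <= total_depth,
            predicted_baf > 0, predicted_baf < 1)
  d <- dbinom(0:total_depth, total_depth, predicted_baf)
  # relative tolerance guards against ties lost to floating point, as in the
  # standard exact test
  p <- sum(d[d <= d[alt_depth + 1L] * (1 + 1e-7)])
  log(min(p, 1))
}

#' Allelic-imbalance test for a set of candidates
#'
#' Convenience wrapper: for every candidate, selects the phased germline hets
#' within the window, predicts the local BAF and runs the binomial test.
#'
#' @param variants Candidate tibble (columns `chrom, pos, ref_depth,
#'   alt_depth`).
#' @param series Oriented het series from [orient_hets()].
#' @param config A [ptascrub_config()].
#' @return `variants` with columns `predicted_baf`, `ai_log_p`, `ai_defined`.
#' @export
ai_test <- function(variants, series, config = ptascrub_config()) {
  res <- purrr::pmap(
    list(variants$chrom, variants$pos, variants$ref_depth,
         variants$alt_depth),
    function(chrom, pos, rd, ad) {
      pb <- predict_baf(series, pos, chrom = chrom,
                        window = config$ai_window,
                        min_hets = config$ai_min_hets,
                        degree = config$ai_loess_degree,
                        clamp = config$ai_baf_clamp)
      if (!pb$defined || is.na(rd) || is.na(ad) || rd + ad == 0) {
        return(list(predicted_baf = pb$predicted_baf, ai_log_p = NA_real_,
                    ai_defined = FALSE))
      }
      list(predicted_baf = pb$predicted_baf,
           ai_log_p = ai_log_p(ad, rd + ad, pb$predicted_baf),
           ai_defined = TRUE)
    })
  variants$predicted_baf <- vapply(res, `[[`, 1, "predicted_baf")
  variants$ai_log_p <- vapply(res, `[[`, 1, "ai_log_p")
  variants$ai_defined <- vapply(res, `[[`, TRUE, "ai_defined")
  variants
}
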