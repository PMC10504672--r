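#' Count cis and trans reads for a (somatic, germline) site pair
#'
#' A read spanning both sites is *cis* when it carries the alternate alleles
#' of both the somatic candidate and the germline het, or the reference
#' alleles of both; every other spanning read is *trans*. Reads not observing
#' both sites are ignored.
#'
#' @param evidence Tibble with columns `somatic_allele` and `germline_allele`,
#'   each `"ref"`, `"alt"` or `"none"`, one row per read (pair).
#' @return Named list `n_cis`, `n_trans`.
#' @export
count_phase_support <- function(evidence) {
  spanning <- evidence$somatic_allele %in% c("ref", "alt") &
    evidence$germline_allele %in% c("ref", "alt")
  s <- evidence$somatic_allele[spanning]
  g <- evidence$germline_allele[spanning]
  n_cis <- sum(s == g)
  list(n_cis = n_cis, n_trans = sum(spanning) - n_cis)
}

#' Phred-scaled read-backed phasing score
#'
#' Bayesian comparison of three hypotheses about how a candidate's alternate
#' allele relates to the surrounding germline haplotypes: *cis* (expected
#' cis-read fraction `1 - error_rate`), *trans* (`error_rate`) and *mixed*
#' (`0.5`, the signature of a chimeric amplification artifact). Per germline
#' site, the cis-read count is binomial under each hypothesis; likelihoods
#' are multiplied across sites under uniform priors and the score is
#' `-10 * log10(1 - max(P(cis), P(trans)))`, capped. A candidate whose reads
#' phase consistently (all cis or all trans) scores high; mixed support keeps
#' the score low.
#'
#' @param counts Tibble with one row per informative germline site, columns
#'   `n_cis`, `n_trans`.
#' @param error_rate Per-read allele-observation error (default 0.005).
#' @param cap Upper bound for the Phred score.
#' @return List `phred`, `p_cis`, `p_trans`, `p_mixed`, `informative`
#'   (`FALSE` with `phred = NA` when there are no spanning reads).
#' @export
linkage_quality <- function(counts, error_rate = 0.005, cap = 3000) {
  counts <- counts[counts$n_cis + counts$n_trans > 0, , drop = FALSE]
  if (!nrow(counts)) {
    return(list(phred = NA_real_, p_cis = NA_real_, p_trans = NA_real_,
                p_mixed = NA_real_, informative = FALSE))
  }
  n <- counts$n_cis + counts$n_trans
  loglik <- function(p) sum(dbinom(counts$n_cis, n, p, log = TRUE))
  ll <- c(cis = loglik(1 - error_rate), trans = loglik(error_rate),
          mixed = loglik(0.5))
  ll <- ll - max(ll)
  post <- exp(ll) / sum(exp(ll))
  p_err <- 1 - max(post[["cis"]], post[["trans"]])
  phred <- if (p_err <= 0) cap else min(-10 * log10(p_err), cap)
  list(phred = phred, p_cis = post[["cis"]], p_trans = post[["trans"]],
       p_mixed = post[["mixed"]], informative = TRUE)
}

#' Classify a phasing score
#'
#' Scores below 100 mark likely false positives, 100-1000 is uncertain, and
#' above 1000 likely true variants (both boundaries fall in the uncertain
#' band). A missing score (no spanning reads) is uninformative.
#'
#' @param phred_score Numeric vector of Phred scores (may contain `NA`).
#' @param low,high Category boundaries.
#' @return Character vector: `"false_positive"`, `"uncertain"`,
#'   `"true_variant"` or `"uninformative"`.
#' @export
classify_linkage <- function(phred_score, low = 100, high = 1000) {
  dplyr::case_when(
    is.na(phred_score) ~ "uninformative",
    phred_score < low ~ "false_positive",
    phred_score > high ~ "true_variant",
    TRUE ~ "uncertain"
  )
}

#' Read-backed phasing analysis for a set of candidates
#'
#' Consumes pre-extracted read evidence (one row per read and site pair, the
#' BAM-free interchange format) and returns the per-candidate score and
#' category. Germline sites not heterozygous in the control are skipped.
#'
#' @param variants Candidate tibble with `chrom`, `pos`.
#' @param evidence Tibble with columns `chrom`, `somatic_pos`, `germline_pos`,
#'   `read_id`, `somatic_allele`, `germline_allele` (alleles `"ref"`, `"alt"`
#'   or `"none"`).
#' @param config A [ptascrub_config()].
#' @return `variants` with `link_phred`, `link_category`, `n_cis`, `n_trans`.
#' @export
linkage_analysis <- function(variants, evidence, config = ptascrub_config()) {
  key_v <- paste(norm_chrom(variants$chrom), variants$pos)
  ev_key <- paste(norm_chrom(evidence$chrom), evidence$somatic_pos)
  res <- purrr::map(key_v, function(k) {
    ev <- evidence[ev_key == k, , drop = FALSE]
    if (!nrow(ev)) {
      return(list(phred = NA_real_, n_cis = 0L, n_trans = 0L))
    }
    counts <- ev |>
      group_by(.data$germline_pos) |>
      summarise(
        n_cis = count_phase_support(dplyr::pick(dplyr::everything()))$n_cis,
        n_trans = count_phase_support(dplyr::pick(dplyr::everything()))$n_trans,
        .groups = "drop")
    q <- linkage_quality(counts, error_rate = config$linkage_error_rate,
                         cap = config$linkage_phred_cap)
    list(phred = q$phred, n_cis = sum(counts$n_cis),
         n_trans = sum(counts$n_trans))
  })
  variants$link_phred <- vapply(res, `[[`, 1, "phred")
  variants$n_cis <- vapply(res, function(x) as.integer(x$n_cis), 1L)
  variants$n_trans <- vapply(res, function(x) as.integer(x$n_trans), 1L)
  variants$link_category <- classify_linkage(
    variants$link_phred, low = config$linkage_low, high = config$linkage_high)
  variants
}
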