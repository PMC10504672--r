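#' Optimal penalized piecewise-constant segmentation
#'
#' Finds the segmentation minimizing the sum of within-segment squared
#' residuals plus `penalty` per breakpoint, exactly, by dynamic programming
#' with PELT-style pruning (pruning never discards an optimal candidate for
#' this cost, so the result equals exhaustive search over all breakpoint
#' placements).
#'
#' @param values Numeric vector ordered along a chromosome.
#' @param penalty Non-negative penalty per breakpoint (absolute scale).
#' @return Tibble `start_idx, end_idx, mean, n` (1-based indices into
#'   `values`); zero rows for empty input.
#' @export
segment_piecewise <- function(values, penalty) {
  n <- length(values)
  if (n == 0L) {
    return(tibble(start_idx = integer(), end_idx = integer(),
                  mean = double(), n = integer()))
  }
  stopifnot(penalty >= 0)
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  segcost <- function(s, t) {
    # within-segment sum of squares for values[s..t], vectorized over s
    len <- t - s + 1
    cs2[t + 1L] - cs2[s] - (cs[t + 1L] - cs[s])^2 / len
  }
  f <- c(-penalty, rep(Inf, n))      # f[t+1] = optimal cost of values[1..t]
  cp <- integer(n)                   # cp[t] = last changepoint before t
  cand <- 1L                         # candidate segment starts (1-based)
  for (t in seq_len(n)) {
    tot <- f[cand] + segcost(cand, t) + penalty
    best <- which.min(tot)
    f[t + 1L] <- tot[best]
    cp[t] <- cand[best] - 1L
    keep <- tot <= f[t + 1L] + penalty
    cand <- c(cand[keep], t + 1L)
  }
  ends <- integer(0)
  t <- n
  while (t > 0L) {
    ends <- c(t, ends)
    t <- cp[t]
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(start_idx = starts, end_idx = ends,
         mean = (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L),
         n = ends - starts + 1L)
}

# difference-based robust noise variance; floored so that noiseless data
# still get a strictly positive penalty (which makes the minimal-breakpoint
# optimum unique)
noise_variance <- function(values) {
  if (length(values) < 3L) return(1e-12)
  s <- stats::mad(diff(values)) / sqrt(2)
  max(s^2, 1e-12)
}

#' Segment per-bin values with the standard penalty scale
#'
#' Applies [segment_piecewise()] per chromosome with penalty
#' `gamma * sigma2`, where `sigma2` is a difference-based estimate of the
#' local noise variance. `gamma = 100` is the default of the method; the
#' noise normalization makes the penalty scale-free.
#'
#' @param bins Tibble `chrom, start, end, value` (0-based half-open bins,
#'   `NA` values are dropped).
#' @param gamma Penalty multiplier.
#' @return Tibble `chrom, start, end, mean, n_bins` of segments.
#' @export
segment_values <- function(bins, gamma = 100) {
  bins <- filter(bins, !is.na(.data$value))
  if (!nrow(bins)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  mean = double(), n_bins = integer()))
  }
  bind_rows(lapply(split(bins, norm_chrom(bins$chrom)), function(b) {
    b <- arrange(b, .data$start)
    seg <- segment_piecewise(b$value, gamma * noise_variance(b$value))
    tibble(chrom = b$chrom[1L],
           start = b$start[seg$start_idx], end = b$end[seg$end_idx],
           mean = seg$mean, n_bins = seg$n)
  }))
}

#' Fine-map coarse segment boundaries
#'
#' Snaps the start/end of 100-kb-resolution segments to the boundaries of the
#' overlapping 1-kb-resolution segments.
#'
#' @param coarse,fine Segment tibbles from [segment_values()].
#' @return `coarse` with adjusted `start`/`end`.
#' @export
fine_map_segments <- function(coarse, fine) {
  out <- coarse
  for (i in seq_len(nrow(coarse))) {
    f <- fine[norm_chrom(fine$chrom) == norm_chrom(coarse$chrom[i]), ]
    if (!nrow(f)) next
    ov <- f[f$end > coarse$start[i] & f$start < coarse$end[i], ]
    if (!nrow(ov)) next
    out$start[i] <- ov$start[which.min(abs(ov$start - coarse$start[i]))]
    out$end[i] <- ov$end[which.min(abs(ov$end - coarse$end[i]))]
  }
  out
}

#' Build a coverage panel of normals
#'
#' Normalizes each normal sample to a common total read count, averages per
#' bin, and flags the bottom and top 1% of bins as outliers.
#'
#' @param count_tables List (>= 2) of tibbles `chrom, start, end, count` on an
#'   identical bin grid.
#' @param outlier_quantile Fraction flagged at each tail.
#' @return Tibble `chrom, start, end, mean_count, outlier` (class
#'   `coverage_pon`).
#' @export
build_coverage_pon <- function(count_tables, outlier_quantile = 0.01) {
  stopifnot(length(count_tables) >= 2L)
  grid <- count_tables[[1L]][, c("chrom", "start", "end")]
  gkey <- paste(norm_chrom(grid$chrom), grid$start)
  mat <- vapply(count_tables, function(df) {
    if (!identical(paste(norm_chrom(df$chrom), df$start), gkey)) {
      abort("panel samples are not on the same bin grid")
    }
    df$count * (sum(count_tables[[1L]]$count) / sum(df$count))
  }, numeric(nrow(grid)))
  m <- rowMeans(mat)
  lo <- quantile(m, outlier_quantile)
  hi <- quantile(m, 1 - outlier_quantile)
  out <- mutate(grid, mean_count = m, outlier = m <= lo | m >= hi)
  class(out) <- c("coverage_pon", class(out))
  out
}

#' Normalize a coverage profile against the panel of normals
#'
#' Scales the test sample to the panel's total read count and divides each
#' 1-kb bin by the panel's mean count in that bin, removing shared coverage
#' waves. Panel outlier bins (bottom/top 1%) and bins within the configured
#' margin of centromeres/telomeres are excluded with a reason and carry no
#' ratio.
#'
#' @param sample_counts Tibble `chrom, start, end, count` (1-kb bins).
#' @param pon A [build_coverage_pon()] result on the same grid.
#' @param centromeres Optional tibble `chrom, start, end` of
#'   centromere/telomere intervals.
#' @param margin Exclusion margin around those intervals in bp.
#' @return Tibble `chrom, start, end, count, ratio, excluded, reason` (class
#'   `coverage_profile`).
#' @export
normalize_coverage <- function(sample_counts, pon, centromeres = NULL,
                               margin = 1e6) {
  skey <- paste(norm_chrom(sample_counts$chrom), sample_counts$start)
  pkey <- paste(norm_chrom(pon$chrom), pon$start)
  if (!identical(skey, pkey)) abort("sample and PON bin grids differ")
  scaled <- sample_counts$count * (sum(pon$mean_count) / sum(sample_counts$count))
  out <- mutate(sample_counts,
                ratio = ifelse(pon$mean_count > 0, scaled / pon$mean_count,
                               NA_real_),
                excluded = FALSE, reason = NA_character_)
  mark <- function(out, idx, why) {
    out$excluded[idx] <- TRUE
    out$reason[idx] <- ifelse(is.na(out$reason[idx]), why,
                              paste(out$reason[idx], why, sep = ";"))
    out$ratio[idx] <- NA_real_
    out
  }
  out <- mark(out, which(pon$outlier), "pon_outlier")
  out <- mark(out, which(pon$mean_count == 0), "pon_zero")
  if (!is.null(centromeres) && nrow(centromeres)) {
    grown <- mutate(centromeres, start = pmax(0, .data$start - margin),
                    end = .data$end + margin)
    q <- GenomicRanges::GRanges(norm_chrom(out$chrom),
                                IRanges::IRanges(out$start + 1L, out$end))
    hit <- IRanges::overlapsAny(q, intervals_to_granges(grown))
    out <- mark(out, which(hit), "centromere_margin")
  }
  class(out) <- c("coverage_profile", class(out))
  out
}

#' Aggregate a 1-kb profile into coarse bins
#'
#' @param profile A [normalize_coverage()] result.
#' @param bin_size Coarse bin width in bp.
#' @return Tibble `chrom, start, end, value` of per-bin median ratios.
#' @export
coarse_bins <- function(profile, bin_size = 1e5) {
  p <- filter(profile, !.data$excluded & !is.na(.data$ratio))
  p |>
    mutate(bin = floor(.data$start / bin_size)) |>
    group_by(chrom_n = norm_chrom(.data$chrom), .data$bin) |>
    summarise(chrom = dplyr::first(.data$chrom),
              start = .data$bin[1L] * bin_size,
              end = (.data$bin[1L] + 1) * bin_size,
              value = median(.data$ratio), .groups = "drop") |>
    select("chrom", "start", "end", "value") |>
    arrange(norm_chrom(.data$chrom), .data$start)
}

#' Coverage-segment significance tests
#'
#' For each segment, the per-1-kb ratios are compared against a within-sample
#' diploid reference — the pooled 1-kb ratios of the top 25% of segments whose
#' mean is closest to the diploid level (ratio 1) — via a Z score and a
#' one-sided normal p-value whose direction follows the sign of the
#' difference (`sample_p`). The same construction against the panel's per-bin
#' expectation gives `pon_p`. A segment is a copy-number candidate when
#' `sample_p < 0.05` and `pon_p < 0.2`.
#'
#' @param segments Segment tibble (`chrom, start, end, mean`).
#' @param profile A [normalize_coverage()] result.
#' @param pon The [build_coverage_pon()] used for `profile`.
#' @param sample_p_max,pon_p_max Candidate thresholds.
#' @return `segments` with `sample_p`, `pon_p`, `direction`, `cn_candidate`.
#' @export
coverage_segment_tests <- function(segments, profile, pon,
                                   sample_p_max = 0.05, pon_p_max = 0.2) {
  prof <- filter(profile, !.data$excluded & !is.na(.data$ratio))
  pon_ratio <- pon$mean_count / mean(pon$mean_count[!pon$outlier])
  pon_use <- tibble(chrom = pon$chrom, start = pon$start,
                    ratio = pon_ratio)[!pon$outlier, ]
  seg_bins <- function(df, seg) {
    df[norm_chrom(df$chrom) == norm_chrom(seg$chrom) &
         df$start >= seg$start & df$start < seg$end, ]
  }
  n_seg <- nrow(segments)
  if (n_seg < 4L) {
    warn("fewer than 4 segments; no diploid reference set, tests undefined")
  }
  ord <- order(abs(segments$mean - 1))
  ref_idx <- ord[seq_len(max(1L, ceiling(n_seg * 0.25)))]
  ref_ratios <- unlist(lapply(ref_idx, function(i) {
    seg_bins(prof, segments[i, ])$ratio
  }))
  ref_mean <- mean(ref_ratios)
  ref_sd <- sd(ref_ratios)

  one_sided <- function(z) {
    if (is.na(z)) NA_real_ else if (z < 0) pnorm(z) else pnorm(z, lower.tail = FALSE)
  }
  res <- purrr::map(seq_len(n_seg), function(i) {
    seg <- segments[i, ]
    rs <- seg_bins(prof, seg)$ratio
    if (!length(rs) || is.na(ref_sd) || ref_sd == 0) {
      return(list(sample_p = NA_real_, pon_p = NA_real_, dir = "undetermined"))
    }
    z_s <- (mean(rs) - ref_mean) / ref_sd
    pr <- seg_bins(pon_use, seg)$ratio
    z_p <- if (length(pr) >= 2L && sd(pr) > 0) {
      (mean(rs) - mean(pr)) / sd(pr)
    } else NA_real_
    list(sample_p = one_sided(z_s), pon_p = one_sided(z_p),
         dir = if (z_s < 0) "loss" else "gain")
  })
  segments$sample_p <- vapply(res, `[[`, 1, "sample_p")
  segments$pon_p <- vapply(res, `[[`, 1, "pon_p")
  segments$direction <- vapply(res, `[[`, "", "dir")
  segments$cn_candidate <- !is.na(segments$sample_p) & !is.na(segments$pon_p) &
    segments$sample_p < sample_p_max & segments$pon_p < pon_p_max
  segments
}
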