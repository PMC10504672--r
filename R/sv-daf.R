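#' Deviation-of-allele-frequency profile of germline hets
#'
#' The DAF of a variant is `|VAF - 0.5|`: 0 for a perfectly balanced het, 0.5
#' for a homozygous-appearing one. Per-het DAFs are averaged in 100-kb bins
#' and segmented twice with the same engine: once on all hets (for losses and
#' copy-neutral LOH) and once after excluding hets with DAF > 0.45 (for gains,
#' which artificial allelic-dropout LOH would otherwise mask). Crude segment
#' boundaries are snapped to the nearest germline het with a similar DAF
#' within 200 kb.
#'
#' @param hets Tibble `chrom, pos, ref_depth, alt_depth` of germline
#'   heterozygous sites in the test sample.
#' @param gamma Segmentation penalty multiplier.
#' @param bin_size DAF bin width in bp.
#' @param loh_daf DAF above which a het is treated as LOH-like and excluded
#'   from the gain-oriented segmentation.
#' @param snap_window,snap_tol Boundary-snapping window (bp) and DAF
#'   similarity tolerance.
#' @return List of class `daf_profile`: `hets` (with `vaf`, `daf`), `bins`,
#'   `bins_noloh`, `segments_all`, `segments_noloh`, `mean_daf` (sample-wide).
#' @export
daf_profile <- function(hets, gamma = 100, bin_size = 1e5, loh_daf = 0.45,
                        snap_window = 2e5, snap_tol = 0.1) {
  total <- hets$ref_depth + hets$alt_depth
  h <- mutate(hets, vaf = ifelse(total > 0, .data$alt_depth / total, NA_real_),
              daf = abs(.data$vaf - 0.5)) |>
    filter(!is.na(.data$daf)) |>
    arrange(norm_chrom(.data$chrom), .data$pos)

  bin_daf <- function(hh) {
    hh |>
      mutate(bin = floor((.data$pos - 1) / bin_size)) |>
      group_by(chrom_n = norm_chrom(.data$chrom), .data$bin) |>
      summarise(chrom = dplyr::first(.data$chrom),
                start = .data$bin[1L] * bin_size,
                end = (.data$bin[1L] + 1) * bin_size,
                value = mean(.data$daf), n_hets = dplyr::n(),
                .groups = "drop") |>
      select("chrom", "start", "end", "value", "n_hets") |>
      arrange(norm_chrom(.data$chrom), .data$start)
  }
  bins_all <- bin_daf(h)
  bins_noloh <- bin_daf(filter(h, .data$daf <= loh_daf))

  snap <- function(segs) {
    for (i in seq_len(nrow(segs))) {
      hh <- h[norm_chrom(h$chrom) == norm_chrom(segs$chrom[i]), ]
      near_s <- hh[abs(hh$pos - segs$start[i]) <= snap_window &
                     abs(hh$daf - segs$mean[i]) <= snap_tol, ]
      if (nrow(near_s)) {
        segs$start[i] <- near_s$pos[which.min(abs(near_s$pos - segs$start[i]))] - 1L
      }
      near_e <- hh[abs(hh$pos - segs$end[i]) <= snap_window &
                     abs(hh$daf - segs$mean[i]) <= snap_tol, ]
      if (nrow(near_e)) {
        segs$end[i] <- near_e$pos[which.min(abs(near_e$pos - segs$end[i]))]
      }
    }
    segs
  }
  out <- list(hets = h,
              bins = bins_all, bins_noloh = bins_noloh,
              segments_all = snap(segment_values(bins_all, gamma = gamma)),
              segments_noloh = snap(segment_values(bins_noloh, gamma = gamma)),
              mean_daf = mean(h$daf))
  class(out) <- "daf_profile"
  out
}

#' @export
print.daf_profile <- function(x, ...) {
  cat("<daf_profile>", nrow(x$hets), "hets, sample mean DAF",
      round(x$mean_daf, 3), ";", nrow(x$segments_all), "segment(s)\n")
  invisible(x)
}

#' Modes of a VAF distribution
#'
#' Kernel-density mode finding: local maxima of a Gaussian KDE (Silverman
#' bandwidth), with minor modes below 10% of the peak density suppressed. A
#' diploid segment yields a single mode near 0.5; a copy-number-3 segment
#' yields modes near 1/3 and 2/3; a loss yields modes near 0 and 1.
#'
#' @param vafs Numeric VAFs in a segment.
#' @param min_n Minimum number of VAFs; below it the result is empty
#'   (segment undetermined).
#' @param density_min Suppression threshold as a fraction of the peak density.
#' @return Numeric vector of mode locations (possibly empty).
#' @export
vaf_modes <- function(vafs, min_n = 20, density_min = 0.1) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_n) return(numeric(0))
  if (sd(vafs) == 0) return(vafs[1L])
  d <- density(vafs, bw = "nrd0")
  y <- d$y
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              FALSE)
  modes <- d$x[is_max & y >= density_min * max(y)]
  modes
}

#' Mean segment DAF
#'
#' @param profile A [daf_profile()].
#' @param chrom,start,end Interval (0-based half-open).
#' @return Mean DAF of the hets inside the interval (`NA` when none).
#' @export
segment_mean_daf <- function(profile, chrom, start, end) {
  hh <- profile$hets
  sel <- norm_chrom(hh$chrom) == norm_chrom(chrom) &
    hh$pos > start & hh$pos <= end
  if (!any(sel)) return(NA_real_)
  mean(hh$daf[sel])
}
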