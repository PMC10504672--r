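#' Call copy-number segment states from coverage and allele-frequency evidence
#'
#' Integrates the two evidence tracks:
#' * **loss** — a coverage candidate in the loss direction overlapping a DAF
#'   segment (all-het segmentation) with mean DAF above the LOH threshold
#'   (0.45); called on the intersection of the two intervals.
#' * **gain** — a coverage candidate in the gain direction overlapping a
#'   segment of the LOH-excluded DAF segmentation whose mean DAF exceeds the
#'   sample average, and whose VAF distribution has more than one mode with
#'   one near 1/3 and one near 2/3 (each within the tolerance).
#' * **cnLOH** — a DAF segment above the LOH threshold with no overlapping
#'   coverage candidate: diploid coverage, homozygous-appearing hets.
#'
#' Copy-number variants therefore require both coverage and DAF support;
#' cnLOH requires DAF support and the absence of a coverage change.
#'
#' @param cov_segments Output of [coverage_segment_tests()].
#' @param daf A [daf_profile()].
#' @param config A [ptascrub_config()].
#' @return Tibble `chrom, start, end, state, mean_ratio, mean_daf, sample_p,
#'   pon_p, evidence` with `state` in loss/gain/cnLOH.
#' @export
call_cn_segments <- function(cov_segments, daf, config = ptascrub_config()) {
  calls <- list()
  loh <- config$daf_loh
  tol <- config$mode_tol

  overlap <- function(a_start, a_end, b_start, b_end) {
    pmax(a_start, b_start) < pmin(a_end, b_end)
  }

  cand <- filter(cov_segments, .data$cn_candidate)
  for (i in seq_len(nrow(cand))) {
    seg <- cand[i, ]
    if (seg$direction == "loss") {
      d <- filter(daf$segments_all,
                  norm_chrom(.data$chrom) == norm_chrom(seg$chrom),
                  .data$mean > loh,
                  overlap(.data$start, .data$end, seg$start, seg$end))
    } else {
      d <- filter(daf$segments_noloh,
                  norm_chrom(.data$chrom) == norm_chrom(seg$chrom),
                  .data$mean > daf$mean_daf,
                  overlap(.data$start, .data$end, seg$start, seg$end))
    }
    for (j in seq_len(nrow(d))) {
      s0 <- max(seg$start, d$start[j]); e0 <- min(seg$end, d$end[j])
      md <- segment_mean_daf(daf, seg$chrom, s0, e0)
      if (seg$direction == "gain") {
        hh <- daf$hets
        v <- hh$vaf[norm_chrom(hh$chrom) == norm_chrom(seg$chrom) &
                      hh$pos > s0 & hh$pos <= e0]
        modes <- vaf_modes(v, min_n = config$min_hets_per_segment,
                           density_min = config$mode_density_min)
        mode_ok <- length(modes) > 1L &&
          any(abs(modes - 1 / 3) <= tol) && any(abs(modes - 2 / 3) <= tol)
        if (!mode_ok) next
      }
      calls[[length(calls) + 1L]] <- tibble(
        chrom = seg$chrom, start = s0, end = e0, state = seg$direction,
        mean_ratio = seg$mean, mean_daf = md,
        sample_p = seg$sample_p, pon_p = seg$pon_p,
        evidence = "coverage;daf")
    }
  }

  # cnLOH: high-DAF segments not overlapping any coverage candidate
  loh_segs <- filter(daf$segments_all, .data$mean > loh)
  for (i in seq_len(nrow(loh_segs))) {
    seg <- loh_segs[i, ]
    hit <- cand[norm_chrom(cand$chrom) == norm_chrom(seg$chrom) &
                  overlap(cand$start, cand$end, seg$start, seg$end), ]
    if (nrow(hit)) next
    cov_mean <- cov_segments |>
      filter(norm_chrom(.data$chrom) == norm_chrom(seg$chrom),
             overlap(.data$start, .data$end, seg$start, seg$end)) |>
      pull(.data$mean)
    calls[[length(calls) + 1L]] <- tibble(
      chrom = seg$chrom, start = seg$start, end = seg$end, state = "cnLOH",
      mean_ratio = if (length(cov_mean)) mean(cov_mean) else NA_real_,
      mean_daf = seg$mean, sample_p = NA_real_, pon_p = NA_real_,
      evidence = "daf")
  }
  if (!length(calls)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  state = character(), mean_ratio = double(),
                  mean_daf = double(), sample_p = double(), pon_p = double(),
                  evidence = character()))
  }
  arrange(bind_rows(calls), norm_chrom(.data$chrom), .data$start)
}

# --- breakends -------------------------------------------------------------

#' Read a breakend (BND) VCF
#'
#' Parses GRIDSS-style breakend records: bracketed ALT alleles plus `MATEID`
#' INFO keys. Records whose mate is missing or malformed are kept with
#' `mate_found = FALSE`, not dropped.
#'
#' @param path VCF path.
#' @return Tibble `id, chrom, pos, ref, alt, mate_id, orientation,
#'   mate_chrom, mate_pos, mate_orientation, mate_found`. Orientation is `"+"`
#'   when the retained segment is to the left of the break.
#' @export
read_breakend_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  alt <- fix[, "ALT"]
  m <- stringr::str_match(alt, "^(?:([ACGTN]+)([\\[\\]])([^\\[\\]]+)[\\[\\]]|([\\[\\]])([^\\[\\]]+)[\\[\\]]([ACGTN]+))$")
  base_first <- !is.na(m[, 2L])
  orientation <- ifelse(base_first, "+", "-")
  mate_loc <- ifelse(base_first, m[, 4L], m[, 6L])
  bracket <- ifelse(base_first, m[, 3L], m[, 5L])
  mate_orientation <- ifelse(bracket == "]", "+", "-")
  loc <- stringr::str_match(mate_loc, "^(.+):([0-9]+)$")
  mate_id <- stringr::str_match(fix[, "INFO"], "(?:^|;)MATEID=([^;]+)")[, 2L]
  tibble(
    id = fix[, "ID"], chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt, mate_id = mate_id,
    orientation = orientation,
    mate_chrom = loc[, 2L], mate_pos = as.integer(loc[, 3L]),
    mate_orientation = mate_orientation,
    mate_found = !is.na(mate_loc)
  )
}

#' Pair breakends into junctions and classify them
#'
#' Joins mate records and classifies each junction by orientation: on one
#' chromosome, `+/-` (lower/higher position) is a deletion-type junction,
#' `-/+` a duplication-type, `++` or `--` inversion-type; different
#' chromosomes give an inter-chromosomal junction (CTX). Malformed mate
#' references flag the record instead of failing.
#'
#' @param breakends From [read_breakend_vcf()].
#' @return Tibble, one row per junction: `chrom1, pos1, chrom2, pos2,
#'   sv_class, size, flags` (list-column).
#' @export
pair_breakends <- function(breakends) {
  b <- breakends
  seen <- character(0)
  rows <- list()
  for (i in seq_len(nrow(b))) {
    if (b$id[i] %in% seen) next
    flags <- character(0)
    mate <- if (!is.na(b$mate_id[i])) which(b$id == b$mate_id[i]) else integer(0)
    if (length(mate) == 1L) {
      seen <- c(seen, b$id[i], b$id[mate])
      o1 <- b$orientation[i]; o2 <- b$orientation[mate]
      c1 <- b$chrom[i]; c2 <- b$chrom[mate]
      p1 <- b$pos[i]; p2 <- b$pos[mate]
    } else {
      seen <- c(seen, b$id[i])
      if (!b$mate_found[i] || is.na(b$mate_chrom[i])) {
        flags <- c(flags, "MALFORMED_MATE")
      }
      o1 <- b$orientation[i]; o2 <- b$mate_orientation[i]
      c1 <- b$chrom[i]; c2 <- b$mate_chrom[i]
      p1 <- b$pos[i]; p2 <- b$mate_pos[i]
    }
    if (is.na(c2)) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom1 = c1, pos1 = p1, chrom2 = NA_character_, pos2 = NA_integer_,
        sv_class = "UNKNOWN", size = NA_real_, flags = list(flags))
      next
    }
    if (norm_chrom(c1) != norm_chrom(c2)) {
      cls <- "CTX"; size <- NA_real_
    } else {
      if (p1 > p2) {
        tmp <- p1; p1 <- p2; p2 <- tmp
        tmpo <- o1; o1 <- o2; o2 <- tmpo
      }
      size <- p2 - p1
      cls <- if (o1 == "+" && o2 == "-") "DEL"
        else if (o1 == "-" && o2 == "+") "DUP"
        else "INV"
    }
    rows[[length(rows) + 1L]] <- tibble(
      chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2,
      sv_class = cls, size = size, flags = list(flags))
  }
  bind_rows(rows)
}

#' Build a breakend panel of normals
#'
#' Clusters breakend positions across individuals by single-linkage within a
#' window; clusters seen in two or more distinct individuals form the panel.
#'
#' @param breakends_by_individual Named list of tibbles `chrom, pos`.
#' @param window Linking distance in bp.
#' @return Tibble `chrom, pos, individual_count` of panel positions (class
#'   `breakend_pon`).
#' @export
build_breakend_pon <- function(breakends_by_individual, window = 2000) {
  if (is.null(names(breakends_by_individual))) {
    names(breakends_by_individual) <-
      paste0("I", seq_along(breakends_by_individual))
  }
  all <- bind_rows(lapply(names(breakends_by_individual), function(ind) {
    mutate(breakends_by_individual[[ind]], individual = ind)
  }))
  out <- bind_rows(lapply(split(all, norm_chrom(all$chrom)), function(df) {
    df <- arrange(df, .data$pos)
    df$cluster <- cumsum(c(1L, diff(df$pos) > window))
    df |>
      group_by(.data$cluster) |>
      mutate(individual_count = dplyr::n_distinct(.data$individual)) |>
      ungroup() |>
      filter(.data$individual_count >= 2L) |>
      select("chrom", "pos", "individual_count")
  }))
  class(out) <- c("breakend_pon", class(out))
  out
}

#' Filter structural-variant junctions
#'
#' Applies the published breakend filters:
#' * panel of normals — a junction with either end within the window of a
#'   panel position is flagged `BND_PON`;
#' * duplication-type — flagged when the mean DAF between the breakpoints is
#'   below 0.18 (`DUP_LOW_DAF`) and/or the copy-number level between them
#'   (2 x normalized ratio) is below 2.5 (`DUP_LOW_CN`);
#' * deletion-type — flagged when the DAF is below 0.4 (`DEL_LOW_DAF`) and/or
#'   the copy number is above 1.5 (`DEL_HIGH_CN`);
#' * excess coverage — for 15x samples, a breakend in a 1-kb bin with more
#'   than 100 reads is flagged `EXCESS_COVERAGE`;
#' * inversions — flagged when only one of the two reciprocal junctions is
#'   present (`INV_SINGLE_JUNCTION`) or smaller than 1 kb (`INV_SHORT`);
#' * inter-chromosomal — single-junction events are flagged
#'   (`CTX_SINGLE_JUNCTION`) unless within 100 kb of a called copy-number
#'   variant, which rescues unbalanced translocations.
#'
#' Filtering is idempotent; flags are cumulative. Surviving junctions carry
#' `junction_count` and local evidence summaries.
#'
#' @param junctions From [pair_breakends()].
#' @param bnd_pon Optional [build_breakend_pon()].
#' @param profile A [normalize_coverage()] result.
#' @param daf A [daf_profile()].
#' @param cn_calls Optional [call_cn_segments()] output (for the CTX rescue).
#' @param config A [ptascrub_config()].
#' @return `junctions` with `junction_count`, `local_cn`, `local_daf`,
#'   updated `flags`, and `pass`.
#' @export
filter_breakends <- function(junctions, bnd_pon = NULL, profile, daf,
                             cn_calls = NULL, config = ptascrub_config()) {
  j <- junctions
  n <- nrow(j)
  if (!n) {
    j$junction_count <- integer(); j$local_cn <- double()
    j$local_daf <- double(); j$pass <- logical()
    return(j)
  }
  add <- function(i, flag) {
    j$flags[[i]] <<- union(j$flags[[i]], flag)
  }

  local_stats <- function(chrom, s, e) {
    p <- profile[norm_chrom(profile$chrom) == norm_chrom(chrom) &
                   !profile$excluded & !is.na(profile$ratio) &
                   profile$start >= s & profile$start < e, ]
    cn <- if (nrow(p)) 2 * mean(p$ratio) else NA_real_
    list(cn = cn, daf = segment_mean_daf(daf, chrom, s, e))
  }

  # junction multiplicity for INV / CTX: a reciprocal partner has both ends
  # within the PON window and is of the same class
  partner_count <- function(i) {
    same <- which(j$sv_class == j$sv_class[i])
    cnt <- 0L
    for (k in setdiff(same, i)) {
      if (norm_chrom(j$chrom1[k]) == norm_chrom(j$chrom1[i]) &&
          norm_chrom(j$chrom2[k]) == norm_chrom(j$chrom2[i]) &&
          abs(j$pos1[k] - j$pos1[i]) <= config$bnd_pon_window &&
          abs(j$pos2[k] - j$pos2[i]) <= config$bnd_pon_window) {
        cnt <- cnt + 1L
      }
    }
    cnt + 1L
  }

  j$junction_count <- vapply(seq_len(n), partner_count, 1L)
  j$local_cn <- NA_real_
  j$local_daf <- NA_real_

  for (i in seq_len(n)) {
    cls <- j$sv_class[i]
    # panel of normals
    if (!is.null(bnd_pon) && nrow(bnd_pon)) {
      near <- function(chrom, pos) {
        !is.na(pos) && any(norm_chrom(bnd_pon$chrom) == norm_chrom(chrom) &
                             abs(bnd_pon$pos - pos) <= config$bnd_pon_window)
      }
      if (near(j$chrom1[i], j$pos1[i]) || near(j$chrom2[i], j$pos2[i])) {
        add(i, "BND_PON")
      }
    }
    if (cls %in% c("DEL", "DUP") && !is.na(j$pos2[i])) {
      st <- local_stats(j$chrom1[i], j$pos1[i], j$pos2[i])
      j$local_cn[i] <- st$cn
      j$local_daf[i] <- st$daf
      if (cls == "DUP") {
        if (!is.na(st$daf) && st$daf < config$dup_min_daf) add(i, "DUP_LOW_DAF")
        if (!is.na(st$cn) && st$cn < config$dup_min_cn) add(i, "DUP_LOW_CN")
      } else {
        if (!is.na(st$daf) && st$daf < config$del_min_daf) add(i, "DEL_LOW_DAF")
        if (!is.na(st$cn) && st$cn > config$del_max_cn) add(i, "DEL_HIGH_CN")
      }
    }
    # excess coverage at either breakend bin (15x class only)
    if (config$coverage_class == "15x") {
      bin_count <- function(chrom, pos) {
        if (is.na(pos)) return(NA_real_)
        p <- profile[norm_chrom(profile$chrom) == norm_chrom(chrom) &
                       profile$start <= pos - 1 & profile$end >= pos, ]
        if (nrow(p)) p$count[1L] else NA_real_
      }
      cnt <- c(bin_count(j$chrom1[i], j$pos1[i]),
               bin_count(j$chrom2[i], j$pos2[i]))
      if (any(!is.na(cnt) & cnt > config$max_bin_coverage_15x)) {
        add(i, "EXCESS_COVERAGE")
      }
    }
    if (cls == "INV") {
      if (j$junction_count[i] < 2L) add(i, "INV_SINGLE_JUNCTION")
      if (!is.na(j$size[i]) && j$size[i] < config$inv_min_size) {
        add(i, "INV_SHORT")
      }
    }
    if (cls == "CTX" && j$junction_count[i] < 2L) {
      rescued <- FALSE
      if (!is.null(cn_calls) && nrow(cn_calls)) {
        near_cnv <- function(chrom, pos) {
          !is.na(pos) &&
            any(norm_chrom(cn_calls$chrom) == norm_chrom(chrom) &
                  cn_calls$state %in% c("loss", "gain") &
                  pos >= cn_calls$start - config$ctx_rescue_dist &
                  pos <= cn_calls$end + config$ctx_rescue_dist)
        }
        rescued <- near_cnv(j$chrom1[i], j$pos1[i]) ||
          near_cnv(j$chrom2[i], j$pos2[i])
      }
      if (!rescued) add(i, "CTX_SINGLE_JUNCTION")
    }
    if (cls == "UNKNOWN") add(i, "MALFORMED_MATE")
  }
  j$pass <- lengths(j$flags) == 0L
  j
}

#' Integrate copy-number segments and breakend junctions
#'
#' Copy-number variants are emitted on coverage+DAF evidence regardless of
#' breakend support; breakend-only events that survived filtering (balanced
#' SVs) are emitted on their own; a junction matching a called CNV of the same
#' type is merged into that call, which then lists both evidence types.
#'
#' @param cn_calls From [call_cn_segments()].
#' @param junctions From [filter_breakends()].
#' @param match_dist Maximum breakpoint distance for merging a junction into a
#'   CNV call.
#' @return Tibble `chrom, start, end, chrom2, pos2, type, evidence`.
#' @export
integrate_svs <- function(cn_calls, junctions, match_dist = 1e5) {
  out <- list()
  used <- rep(FALSE, nrow(junctions))
  for (i in seq_len(nrow(cn_calls))) {
    seg <- cn_calls[i, ]
    ev <- seg$evidence
    want <- if (seg$state == "loss") "DEL" else if (seg$state == "gain") "DUP"
      else NA_character_
    if (!is.na(want) && nrow(junctions)) {
      hit <- which(!used & junctions$pass & junctions$sv_class == want &
                     norm_chrom(junctions$chrom1) == norm_chrom(seg$chrom) &
                     abs(junctions$pos1 - seg$start) <= match_dist &
                     abs(junctions$pos2 - seg$end) <= match_dist)
      if (length(hit)) {
        used[hit] <- TRUE
        ev <- paste(ev, "breakend", sep = ";")
      }
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = seg$chrom, start = seg$start, end = seg$end,
      chrom2 = NA_character_, pos2 = NA_integer_,
      type = seg$state, evidence = ev)
  }
  surv <- which(!used & junctions$pass)
  for (k in surv) {
    out[[length(out) + 1L]] <- tibble(
      chrom = junctions$chrom1[k], start = junctions$pos1[k],
      end = ifelse(is.na(junctions$pos2[k]), junctions$pos1[k],
                   junctions$pos2[k]),
      chrom2 = junctions$chrom2[k], pos2 = junctions$pos2[k],
      type = junctions$sv_class[k], evidence = "breakend")
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  chrom2 = character(), pos2 = integer(), type = character(),
                  evidence = character()))
  }
  arrange(bind_rows(out), norm_chrom(.data$chrom), .data$start)
}
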