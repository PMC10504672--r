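test_that("DP segmentation equals exhaustive search on small instances", {
  set.seed(41)
  for (i in 1:15) {
    n <- sample(4:11, 1)
    v <- rnorm(n) + rep(c(0, 3), length.out = n, each = sample(2:4, 1))
    for (pen in c(0.01, 0.5, 2, 10)) {
      expect_equal(dp_cost(v, pen), brute_segment_cost(v, pen),
                   tolerance = 1e-9)
    }
  }
})

test_that("constant series yields one segment, a noiseless step exactly two", {
  const <- tibble::tibble(chrom = "1", start = 0:99 * 1000,
                          end = 1:100 * 1000, value = 1)
  expect_equal(nrow(segment_values(const, gamma = 100)), 1L)
  step <- tibble::tibble(chrom = "1", start = 0:399 * 1000,
                         end = 1:400 * 1000,
                         value = rep(c(1, 0.5), each = 200))
  seg <- segment_values(step, gamma = 100)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$end[1], 200 * 1000)
  expect_equal(seg$mean, c(1, 0.5))
  expect_equal(nrow(segment_piecewise(numeric(0), 1)), 0L)
})

test_that("fine mapping snaps coarse boundaries to 1-kb segment boundaries", {
  coarse <- tibble::tibble(chrom = "1", start = c(0, 5e5), end = c(5e5, 1e6),
                           mean = c(1, 0.5), n_bins = c(5L, 5L))
  fine <- tibble::tibble(chrom = "1", start = c(0, 483000),
                         end = c(483000, 1e6), mean = c(1, 0.5),
                         n_bins = c(483L, 517L))
  out <- fine_map_segments(coarse, fine)
  expect_equal(out$end[1], 483000)
  expect_equal(out$start[2], 483000)
})

test_that("PON normalization removes shared waves and flags exclusions", {
  set.seed(42)
  n_bin <- 3000
  starts <- (0:(n_bin - 1)) * 1000
  wave <- exp(0.3 * sin(starts / 2e5))
  pon_tables <- lapply(1:4, function(k) {
    tibble::tibble(chrom = "1", start = starts, end = starts + 1000,
                   count = rpois(n_bin, 100 * wave))
  })
  pon <- build_coverage_pon(pon_tables)
  expect_equal(sum(pon$outlier), 2 * ceiling(0.01 * n_bin), tolerance = 2)
  sample_counts <- tibble::tibble(chrom = "1", start = starts,
                                  end = starts + 1000,
                                  count = rpois(n_bin, 100 * wave))
  prof <- normalize_coverage(sample_counts, pon)
  ok <- !prof$excluded
  expect_equal(mean(prof$ratio[ok]), 1, tolerance = 0.01)
  # the wave is gone: ratios uncorrelated with the wave
  expect_lt(abs(cor(prof$ratio[ok], wave[ok])), 0.1)
  expect_true(all(is.na(prof$ratio[prof$excluded])))
  # a sample exactly proportional to the PON mean gives ratio 1 everywhere
  prop <- tibble::tibble(chrom = "1", start = starts, end = starts + 1000,
                         count = pon$mean_count * 3)
  prof2 <- normalize_coverage(prop, pon)
  expect_equal(prof2$ratio[!prof2$excluded],
               rep(1, sum(!prof2$excluded)), tolerance = 1e-12)
  # centromere margin exclusion
  centro <- tibble::tibble(chrom = "1", start = 1.5e6, end = 1.6e6)
  prof3 <- normalize_coverage(sample_counts, pon, centromeres = centro,
                              margin = 1e6)
  in_margin <- prof3$start >= 0.5e6 & prof3$end <= 2.6e6
  expect_true(all(prof3$excluded[in_margin]))
  expect_error(normalize_coverage(sample_counts[-1, ], pon), "grid")
})

test_that("segment tests give null p-values for diploid segments and call CNVs", {
  set.seed(43)
  segs <- tibble::tribble(~chrom, ~start, ~end, ~state,
                          "1", 0e6, 4e6, "neutral",
                          "1", 4e6, 6e6, "loss",
                          "1", 6e6, 10e6, "neutral")
  sim <- simulate_coverage_daf(segs, seed = 43)
  pon <- build_coverage_pon(sim$pon_counts)
  prof <- normalize_coverage(sim$sample_counts, pon)
  seg <- segment_values(coarse_bins(prof), gamma = 100)
  tests <- suppressWarnings(coverage_segment_tests(seg, prof, pon))
  loss_row <- which(tests$mean < 0.75)
  expect_length(loss_row, 1L)
  expect_lt(tests$sample_p[loss_row], 0.05)
  expect_lt(tests$pon_p[loss_row], 0.2)
  expect_equal(tests$direction[loss_row], "loss")
  expect_true(all(tests$sample_p[-loss_row] > 0.05))
  expect_false(any(tests$cn_candidate[-loss_row]))
  # both thresholds are required
  expect_equal(tests$cn_candidate,
               tests$sample_p < 0.05 & tests$pon_p < 0.2)
})

test_that("DAF transformation maps VAFs onto [0, 0.5]", {
  hets <- tibble::tibble(chrom = "1", pos = c(1e5, 2e5, 3e5),
                         ref_depth = c(15L, 0L, 21L),
                         alt_depth = c(15L, 30L, 9L))
  prof <- daf_profile(hets)
  expect_equal(prof$hets$vaf, c(0.5, 1.0, 0.3))
  expect_equal(prof$hets$daf, c(0.0, 0.5, 0.2))
})

test_that("scaling VAFs toward 0.5 never increases a segment's mean DAF", {
  set.seed(44)
  pos <- sort(sample(1:2e6, 400))
  alt <- rbinom(400, 30, 0.5)
  hets <- tibble::tibble(chrom = "1", pos = pos, ref_depth = 30L - alt,
                         alt_depth = alt)
  p1 <- daf_profile(hets)
  # shrink: move depths halfway toward 15/15
  hets2 <- dplyr::mutate(hets,
                         alt_depth = as.integer(round((alt_depth + 15) / 2)),
                         ref_depth = 30L - alt_depth)
  p2 <- daf_profile(hets2)
  expect_lte(p2$mean_daf, p1$mean_daf)
  expect_true(all(p2$bins$value <= p1$bins$value + 1e-9))
})

test_that("VAF mode finding recovers the expected distribution shapes", {
  set.seed(45)
  # diploid: unimodal near 0.5
  m1 <- vaf_modes(rbinom(500, 30, 0.5) / 30)
  expect_length(m1, 1L)
  expect_lt(abs(m1 - 0.5), 0.05)
  # trisomic: two modes within +/- 0.12 of 1/3 and 2/3
  v3 <- c(rbinom(250, 30, 1 / 3), rbinom(250, 30, 2 / 3)) / 30
  m2 <- vaf_modes(v3)
  expect_gte(length(m2), 2L)
  expect_true(any(abs(m2 - 1 / 3) <= 0.12))
  expect_true(any(abs(m2 - 2 / 3) <= 0.12))
  # degenerate inputs
  expect_equal(vaf_modes(rep(0.4, 100)), 0.4)
  expect_length(vaf_modes(c(0.5, 0.5)), 0L)   # below min_n
})

test_that("CN states integrate coverage and allele-frequency evidence", {
  segs <- tibble::tribble(~chrom, ~start, ~end, ~state,
                          "1", 0e6, 5e6, "neutral",
                          "1", 5e6, 7e6, "loss",
                          "1", 7e6, 10e6, "neutral",
                          "1", 10e6, 12e6, "gain",
                          "1", 12e6, 15e6, "neutral",
                          "1", 15e6, 17e6, "cnLOH",
                          "1", 17e6, 20e6, "neutral")
  sim <- simulate_coverage_daf(segs, seed = 46)
  pon <- build_coverage_pon(sim$pon_counts)
  prof <- normalize_coverage(sim$sample_counts, pon)
  tests <- coverage_segment_tests(segment_values(coarse_bins(prof), 100),
                                  prof, pon)
  daf <- daf_profile(sim$hets)
  calls <- call_cn_segments(tests, daf)
  expect_setequal(calls$state, c("loss", "gain", "cnLOH"))
  states <- function(st) calls[calls$state == st, ]
  expect_lt(abs(states("loss")$start - 5e6), 1e5)
  expect_lt(abs(states("gain")$end - 12e6), 1e5)
  expect_gt(states("loss")$mean_daf, 0.45)
  expect_gt(states("cnLOH")$mean_daf, 0.45)
  expect_true(abs(states("cnLOH")$mean_ratio - 1) < 0.1)
})

test_that("breakend ALT parsing, mate pairing and junction classification", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "1\t1000\tbnd1\tA\tA[1:5000[\t60\tPASS\tMATEID=bnd2",
    "1\t5000\tbnd2\tT\t]1:1000]T\t60\tPASS\tMATEID=bnd1",
    "1\t20000\tbnd3\tC\t]1:26000]C\t60\tPASS\tMATEID=bnd4",
    "1\t26000\tbnd4\tG\tG[1:20000[\t60\tPASS\tMATEID=bnd3",
    "1\t40000\tbnd5\tA\tA]1:47000]\t60\tPASS\tMATEID=bnd6",
    "1\t47000\tbnd6\tT\tT]1:40000]\t60\tPASS\tMATEID=bnd5",
    "2\t1000\tbnd7\tG\tG[3:9000[\t60\tPASS\tMATEID=bnd8",
    "3\t9000\tbnd8\tA\t]2:1000]A\t60\tPASS\tMATEID=bnd7",
    "1\t90000\tbnd9\tC\tC[1:95000[\t60\tPASS\tMATEID=missing"
  ), vcf)
  b <- read_breakend_vcf(vcf)
  expect_equal(nrow(b), 9L)
  expect_equal(b$orientation[1:2], c("+", "-"))
  j <- pair_breakends(b)
  expect_equal(nrow(j), 5L)
  expect_equal(j$sv_class[1:4], c("DEL", "DUP", "INV", "CTX"))
  expect_equal(j$size[1], 4000)
  expect_equal(j$sv_class[5], "DEL")   # classified from its own ALT
})

test_that("breakend PON includes only multi-individual clusters", {
  pon <- build_breakend_pon(list(
    I1 = tibble::tibble(chrom = "1", pos = c(1000L, 50000L)),
    I2 = tibble::tibble(chrom = "1", pos = c(2500L, 90000L)),
    I3 = tibble::tibble(chrom = "1", pos = 300000L)))
  # 1000 and 2500 are within 2000 bp across two individuals; the rest are not
  expect_setequal(pon$pos, c(1000L, 2500L))
  expect_true(all(pon$individual_count >= 2))
})

test_that("duplication and deletion junctions honor DAF and CN thresholds", {
  segs <- tibble::tribble(~chrom, ~start, ~end, ~state,
                          "1", 0e6, 3e6, "neutral",
                          "1", 3e6, 5e6, "loss",
                          "1", 5e6, 8e6, "neutral",
                          "1", 8e6, 10e6, "gain",
                          "1", 10e6, 12e6, "neutral")
  sim <- simulate_coverage_daf(segs, seed = 47)
  pon <- build_coverage_pon(sim$pon_counts)
  prof <- normalize_coverage(sim$sample_counts, pon)
  daf <- daf_profile(sim$hets)
  flag <- function(j) {
    out <- filter_breakends(j, NULL, prof, daf)
    out$flags[[1]]
  }
  jn <- function(cls, p1, p2) {
    tibble::tibble(chrom1 = "1", pos1 = p1, chrom2 = "1", pos2 = p2,
                   sv_class = cls, size = p2 - p1, flags = list(character()))
  }
  # a real deletion: CN ~1, DAF ~0.48 -> passes
  expect_length(flag(jn("DEL", 3e6 + 1, 5e6)), 0L)
  # a deletion junction over diploid sequence: CN ~2 (> 1.5), DAF ~0 -> both
  expect_setequal(flag(jn("DEL", 5.2e6, 6.8e6)),
                  c("DEL_LOW_DAF", "DEL_HIGH_CN"))
  # a real duplication: CN ~3, bimodal VAF -> DAF ~0.17 just below 0.18
  # boundary exercised both ways through the local evidence
  f_dup_neutral <- flag(jn("DUP", 5.2e6, 6.8e6))
  expect_true("DUP_LOW_DAF" %in% f_dup_neutral)
  expect_true("DUP_LOW_CN" %in% f_dup_neutral)
  f_dup_real <- flag(jn("DUP", 8e6 + 1, 1e7))
  expect_false("DUP_LOW_CN" %in% f_dup_real)
})

test_that("inversion and translocation junction-count rules with CNV rescue", {
  segs <- tibble::tribble(~chrom, ~start, ~end, ~state,
                          "1", 0e6, 2e6, "neutral")
  sim <- simulate_coverage_daf(segs, seed = 48)
  pon <- build_coverage_pon(sim$pon_counts)
  prof <- normalize_coverage(sim$sample_counts, pon)
  daf <- daf_profile(sim$hets)
  inv1 <- tibble::tibble(chrom1 = "1", pos1 = 1e5, chrom2 = "1",
                         pos2 = 1e5 + 800, sv_class = "INV", size = 800,
                         flags = list(character()))
  inv_pair <- dplyr::bind_rows(
    tibble::tibble(chrom1 = "1", pos1 = 2e5, chrom2 = "1", pos2 = 2e5 + 5e4,
                   sv_class = "INV", size = 5e4, flags = list(character())),
    tibble::tibble(chrom1 = "1", pos1 = 2e5 + 30, chrom2 = "1",
                   pos2 = 2e5 + 5e4 + 30, sv_class = "INV", size = 5e4,
                   flags = list(character())))
  out1 <- filter_breakends(inv1, NULL, prof, daf)
  expect_setequal(out1$flags[[1]], c("INV_SINGLE_JUNCTION", "INV_SHORT"))
  out2 <- filter_breakends(inv_pair, NULL, prof, daf)
  expect_true(all(out2$pass))
  ctx <- tibble::tibble(chrom1 = "1", pos1 = 5e5, chrom2 = "2", pos2 = 7e5,
                        sv_class = "CTX", size = NA_real_,
                        flags = list(character()))
  out3 <- filter_breakends(ctx, NULL, prof, daf)
  expect_equal(out3$flags[[1]], "CTX_SINGLE_JUNCTION")
  cn_calls <- tibble::tibble(chrom = "1", start = 4.5e5, end = 4.8e5,
                             state = "loss", evidence = "coverage;daf")
  out4 <- filter_breakends(ctx, NULL, prof, daf, cn_calls = cn_calls)
  expect_length(out4$flags[[1]], 0L)   # rescued: within 100 kb of a CNV
  # idempotence
  again <- filter_breakends(out1, NULL, prof, daf)
  expect_identical(again$flags, out1$flags)
})

test_that("breakend PON proximity and 15x excess coverage are flagged", {
  segs <- tibble::tribble(~chrom, ~start, ~end, ~state, "1", 0e6, 2e6, "neutral")
  sim <- simulate_coverage_daf(segs, seed = 49, reads_per_kb = 200)
  pon <- build_coverage_pon(sim$pon_counts)
  prof <- normalize_coverage(sim$sample_counts, pon)
  daf <- daf_profile(sim$hets)
  bnd_pon <- tibble::tibble(chrom = "1", pos = 5e5, individual_count = 3L)
  jn <- tibble::tibble(chrom1 = "1", pos1 = 5e5 + 1500, chrom2 = "1",
                       pos2 = 9e5, sv_class = "DEL", size = 4e5 - 1500,
                       flags = list(character()))
  out <- filter_breakends(jn, bnd_pon, prof, daf)
  expect_true("BND_PON" %in% out$flags[[1]])
  cfg15 <- ptascrub_config("15x")
  out15 <- filter_breakends(jn, NULL, prof, daf, config = cfg15)
  expect_true("EXCESS_COVERAGE" %in% out15$flags[[1]])   # 200 reads > 100
  out30 <- filter_breakends(jn, NULL, prof, daf,
                            config = ptascrub_config("30x"))
  expect_false("EXCESS_COVERAGE" %in% out30$flags[[1]])
})

test_that("integration keeps CNVs without breakends and merges duplicates", {
  cn <- tibble::tibble(chrom = "1", start = c(1e6, 8e6), end = c(3e6, 9e6),
                       state = c("loss", "cnLOH"),
                       mean_ratio = c(0.5, 1), mean_daf = c(0.48, 0.47),
                       sample_p = c(1e-4, NA), pon_p = c(0.01, NA),
                       evidence = c("coverage;daf", "daf"))
  jn <- dplyr::bind_rows(
    tibble::tibble(chrom1 = "1", pos1 = 1e6 + 200, chrom2 = "1",
                   pos2 = 3e6 - 300, sv_class = "DEL", size = 2e6,
                   flags = list(character()), junction_count = 1L,
                   local_cn = 1, local_daf = 0.48, pass = TRUE),
    tibble::tibble(chrom1 = "2", pos1 = 5e5, chrom2 = "3", pos2 = 6e5,
                   sv_class = "CTX", size = NA_real_,
                   flags = list(character()), junction_count = 2L,
                   local_cn = NA_real_, local_daf = NA_real_, pass = TRUE),
    tibble::tibble(chrom1 = "2", pos1 = 8e5, chrom2 = "2", pos2 = 9e5,
                   sv_class = "DUP", size = 1e5, flags = list("DUP_LOW_CN"),
                   junction_count = 1L, local_cn = 2, local_daf = 0.1,
                   pass = FALSE))
  out <- integrate_svs(cn, jn)
  expect_equal(nrow(out), 3L)   # loss (merged), cnLOH, balanced CTX
  loss <- out[out$type == "loss", ]
  expect_equal(loss$evidence, "coverage;daf;breakend")
  expect_true("cnLOH" %in% out$type)
  ctx <- out[out$type == "CTX", ]
  expect_equal(ctx$evidence, "breakend")
  expect_false("DUP" %in% out$type)   # filtered junction stays out
})
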