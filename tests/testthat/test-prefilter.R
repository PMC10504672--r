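cfg15 <- ptascrub_config("15x")
cfg30 <- ptascrub_config("30x")

test_that("QUAL threshold is inclusive at 100", {
  v <- dplyr::bind_rows(make_variant(qual = 99), make_variant(qual = 100))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_QUAL" %in% out$flags[[1]])
  expect_false("FAIL_QUAL" %in% out$flags[[2]])
})

test_that("VAF thresholds follow the coverage class, boundary inclusive", {
  # 15x: VAF < 0.2 fails, exactly 0.2 passes that check
  v <- dplyr::bind_rows(
    make_variant(ref_depth = 81L, alt_depth = 19L),
    make_variant(ref_depth = 80L, alt_depth = 20L),
    make_variant(ref_depth = 70L, alt_depth = 30L))
  out15 <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_VAF" %in% out15$flags[[1]])
  expect_false("FAIL_VAF" %in% out15$flags[[2]])
  # 30x: 0.29 fails, 0.30 passes
  out30 <- apply_prefilters(v, config = cfg30)
  expect_true("FAIL_VAF" %in% out30$flags[[2]])
  expect_false("FAIL_VAF" %in% out30$flags[[3]])
})

test_that("genotype-quality rule: het < 99, hom-alt < 10", {
  v <- dplyr::bind_rows(
    make_variant(gq = 98, genotype = "het"),
    make_variant(gq = 99, genotype = "het"),
    make_variant(gq = 10, genotype = "hom_alt", ref_depth = 0L,
                 alt_depth = 30L),
    make_variant(gq = 9, genotype = "hom_alt", ref_depth = 0L,
                 alt_depth = 30L))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_GQ" %in% out$flags[[1]])
  expect_false("FAIL_GQ" %in% out$flags[[2]])
  expect_false("FAIL_GQ" %in% out$flags[[3]])
  expect_true("FAIL_GQ" %in% out$flags[[4]])
})

test_that("indel GQ rule uses the 99 threshold in test and control", {
  v <- dplyr::bind_rows(
    make_variant(ref = "A", alt = "AT", gq = 98, ref_depth = 15L,
                 alt_depth = 15L),
    make_variant(ref = "A", alt = "AT", gq = 99, ctrl_gq = 98),
    make_variant(ref = "A", alt = "AT", gq = 99, ctrl_gq = 99))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_GQ" %in% out$flags[[1]])
  expect_true("FAIL_GQ" %in% out$flags[[2]])
  expect_false("FAIL_GQ" %in% out$flags[[3]])
})

test_that("indel VAF minimum is 0.25", {
  v <- dplyr::bind_rows(
    make_variant(ref = "A", alt = "AT", ref_depth = 76L, alt_depth = 24L),
    make_variant(ref = "A", alt = "AT", ref_depth = 75L, alt_depth = 25L))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_VAF" %in% out$flags[[1]])
  expect_false("FAIL_VAF" %in% out$flags[[2]])
})

test_that("mapping quality is strict: exactly 55 fails, above passes", {
  v <- dplyr::bind_rows(make_variant(mq = 55), make_variant(mq = 55.01))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_MQ" %in% out$flags[[1]])
  expect_false("FAIL_MQ" %in% out$flags[[2]])
})

test_that("depth thresholds depend on coverage class and check controls", {
  v <- dplyr::bind_rows(
    make_variant(ref_depth = 2L, alt_depth = 2L),          # depth 4
    make_variant(ref_depth = 3L, alt_depth = 2L),          # depth 5
    make_variant(ref_depth = 5L, alt_depth = 4L),          # depth 9
    make_variant(ctrl_depth = 4L))                         # control depth 4
  out15 <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_DEPTH" %in% out15$flags[[1]])
  expect_false("FAIL_DEPTH" %in% out15$flags[[2]])
  expect_true("FAIL_DEPTH" %in% out15$flags[[4]])
  out30 <- apply_prefilters(v, config = cfg30)
  expect_true("FAIL_DEPTH" %in% out30$flags[[3]])
})

test_that("any control evidence fails the variant", {
  v <- dplyr::bind_rows(
    make_variant(ctrl_alt = 1L),
    make_variant(ctrl_geno = "het", ctrl_alt = 0L),
    make_variant())
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_CONTROL_EVIDENCE" %in% out$flags[[1]])
  expect_true("FAIL_CONTROL_EVIDENCE" %in% out$flags[[2]])
  expect_false("FAIL_CONTROL_EVIDENCE" %in% out$flags[[3]])
})

test_that("panel-of-normals matching is exact on chrom+pos+ref+alt", {
  pon <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  v <- dplyr::bind_rows(
    make_variant(pos = 100L),                  # matches (chr normalization)
    make_variant(pos = 100L, alt = "G"),       # different alt
    make_variant(pos = 101L))                  # different pos
  out <- apply_prefilters(v, pon_sites = pon, config = cfg15)
  expect_true("FAIL_PON" %in% out$flags[[1]])
  expect_false("FAIL_PON" %in% out$flags[[2]])
  expect_false("FAIL_PON" %in% out$flags[[3]])
})

test_that("pre-existing non-PASS FILTER values are honored", {
  v <- dplyr::bind_rows(make_variant(filter_input = "SOR3"),
                        make_variant(filter_input = "."))
  out <- apply_prefilters(v, config = cfg15)
  expect_true("FAIL_QUAL" %in% out$flags[[1]])
  expect_false("FAIL_QUAL" %in% out$flags[[2]])
})

test_that("without controls, variants shared by >= 2 samples are never PASS", {
  v <- make_variant()
  v$controls <- list(v$controls[[1]][0, ])   # no control data
  shared <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "T",
                           n_samples = 2L)
  out <- apply_prefilters(v, config = cfg15, shared_counts = shared)
  expect_true("FAIL_CONTROL_EVIDENCE" %in% out$flags[[1]])
  shared$n_samples <- 1L
  out2 <- apply_prefilters(v, config = cfg15, shared_counts = shared)
  expect_false("FAIL_CONTROL_EVIDENCE" %in% out2$flags[[1]])
})

test_that("flags accumulate instead of stopping at the first failure", {
  v <- make_variant(qual = 10, mq = 10, ref_depth = 3L, alt_depth = 0L,
                    gq = 5)
  out <- apply_prefilters(v, config = cfg15)
  expect_setequal(out$flags[[1]],
                  c("FAIL_QUAL", "FAIL_MQ", "FAIL_DEPTH", "FAIL_GQ",
                    "FAIL_VAF"))
})

test_that("filtering is idempotent on its own PASS output", {
  set.seed(5)
  v <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_variant(pos = i, qual = sample(c(50, 500), 1),
                 mq = sample(c(40, 60), 1),
                 ref_depth = sample(3:30, 1), alt_depth = sample(1:30, 1))
  }))
  once <- apply_prefilters(v, config = cfg30)
  pass <- once[is_pass(once), ]
  twice <- apply_prefilters(pass, config = cfg30)
  expect_true(all(is_pass(twice)))
  expect_identical(twice$flags, pass$flags)
})

test_that("raising thresholds never increases the PASS count", {
  set.seed(6)
  v <- dplyr::bind_rows(lapply(1:50, function(i) {
    make_variant(pos = i, qual = runif(1, 50, 200), mq = runif(1, 50, 70),
                 ref_depth = sample(3:30, 1), alt_depth = sample(1:20, 1))
  }))
  base_pass <- sum(is_pass(apply_prefilters(v, config = cfg15)))
  for (override in list(list(min_qual = 150), list(min_mq = 60),
                        list(min_vaf_snv_15x = 0.35),
                        list(min_depth_15x = 12))) {
    cfg <- do.call(ptascrub_config, c(list("15x"), override))
    expect_lte(sum(is_pass(apply_prefilters(v, config = cfg))), base_pass)
  }
})
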