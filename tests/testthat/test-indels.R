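indel_genome <- function() {
  # chr1: ...G TTTTTT G... at 201-206 (6xT) and CAAAAC at 220-225 (4xA)
  fixture_genome()
}

test_that("exclusion list keeps indels seen in two or more individuals", {
  g <- indel_genome()
  call1 <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "AT",
                          vaf = 0.4, sample = "s1")
  calls <- list(
    I1 = dplyr::bind_rows(call1, call1 |> dplyr::mutate(sample = "s2"),
                          call1 |> dplyr::mutate(sample = "s3")),
    I2 = call1 |> dplyr::mutate(sample = "s4"),
    I3 = tibble::tibble(chrom = "1", pos = 150L, ref = "GA", alt = "G",
                        vaf = 0.5, sample = "s5"))
  xl <- build_indel_exclusion_list(calls, g)
  expect_equal(nrow(xl), 1L)
  expect_equal(xl$pos, 100L)
  expect_equal(xl$individual_count, 2L)
  expect_equal(xl$sample_count, 4L)
  # an indel private to one individual is never listed, however many samples
  calls_one <- list(I1 = calls$I1,
                    I2 = tibble::tibble(chrom = "1", pos = 150L, ref = "GA",
                                        alt = "G", vaf = 0.5, sample = "x"))
  expect_equal(nrow(build_indel_exclusion_list(calls_one, g)), 0L)
})

test_that("only calls with VAF above 0.15 are collected", {
  g <- indel_genome()
  low <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "AT",
                        vaf = 0.10)
  at_th <- dplyr::mutate(low, vaf = 0.15)
  above <- dplyr::mutate(low, vaf = 0.16)
  expect_equal(nrow(build_indel_exclusion_list(list(I1 = low, I2 = low), g)),
               0L)
  expect_equal(nrow(build_indel_exclusion_list(list(I1 = at_th, I2 = at_th),
                                               g)), 0L)   # strict >
  expect_equal(nrow(build_indel_exclusion_list(list(I1 = above, I2 = above),
                                               g)), 1L)
  expect_warning(build_indel_exclusion_list(list(I1 = above), g), "two")
})

test_that("construction is symmetric in the order individuals are supplied", {
  g <- indel_genome()
  a <- tibble::tibble(chrom = "1", pos = c(100L, 150L), ref = c("A", "GA"),
                      alt = c("AT", "G"), vaf = c(0.3, 0.4))
  b <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "AT",
                      vaf = 0.25)
  x1 <- build_indel_exclusion_list(list(I1 = a, I2 = b), g)
  x2 <- build_indel_exclusion_list(list(I2 = b, I1 = a), g)
  expect_equal(x1[, c("chrom", "pos", "ref", "alt", "individual_count")],
               x2[, c("chrom", "pos", "ref", "alt", "individual_count")])
})

test_that("left-alignment canonicalizes equivalent indel representations", {
  g <- ref_genome(c("1" = "GGACCCCTGG"))
  # insertion of C in the C run, written at two different anchors
  r1 <- left_align_indels("1", 7L, "C", "CC", g)
  r2 <- left_align_indels("1", 5L, "C", "CC", g)
  expect_equal(r1$pos, r2$pos)
  expect_equal(r1$ref, r2$ref)
  expect_equal(r1$alt, r2$alt)
  expect_equal(r1$pos, 3L)   # anchored at the A before the run
  # deletion of one C likewise
  d1 <- left_align_indels("1", 6L, "CC", "C", g)
  d2 <- left_align_indels("1", 4L, "CC", "C", g)
  expect_equal(d1, d2)
  # SNVs pass through untouched
  s <- left_align_indels("1", 5L, "C", "T", g)
  expect_equal(s$pos, 5L)
})

test_that("exclusion matching flags exact (left-aligned) keys only", {
  g <- ref_genome(c("1" = "GGACCCCTGGAAAAAAAAAA"))
  xl <- build_indel_exclusion_list(list(
    I1 = tibble::tibble(chrom = "1", pos = 7L, ref = "C", alt = "CC", vaf = 0.3),
    I2 = tibble::tibble(chrom = "1", pos = 5L, ref = "C", alt = "CC", vaf = 0.3)),
    g)
  expect_equal(nrow(xl), 1L)
  v <- dplyr::bind_rows(
    make_variant(pos = 6L, ref = "C", alt = "CC"),    # same event, 3rd anchor
    make_variant(pos = 6L, ref = "C", alt = "CT"))
  out <- filter_indels(v, xl, g)
  expect_true("FAIL_EXCLUSION" %in% out$flags[[1]])
  expect_false("FAIL_EXCLUSION" %in% out$flags[[2]])
})

test_that("homopolymer rule: 1-bp insertions in 5bp+ runs fail, 4bp runs pass", {
  g <- indel_genome()   # 6xT at 201-206, 4xA at 221-224
  v <- dplyr::bind_rows(
    make_variant(pos = 203L, ref = "T", alt = "TT"),   # inside the 6T run
    make_variant(pos = 200L, ref = "G", alt = "GT"),   # adjacent, left edge
    make_variant(pos = 222L, ref = "A", alt = "AA"),   # 4A run only
    make_variant(pos = 203L, ref = "TT", alt = "T"),   # deletion in the run
    make_variant(pos = 203L, ref = "T", alt = "TAG"))  # multi-base insertion
  out <- filter_indels(v, NULL, g)
  hp <- vapply(out$flags, function(f) "FAIL_HOMOPOLYMER" %in% f, TRUE)
  expect_equal(hp, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("indel filtering is idempotent and order-independent", {
  g <- indel_genome()
  v <- dplyr::bind_rows(
    make_variant(pos = 203L, ref = "T", alt = "TT"),
    make_variant(pos = 100L, ref = "A", alt = "AT"),
    make_variant(pos = 222L, ref = "A", alt = "AA"))
  once <- filter_indels(v, NULL, g)
  twice <- filter_indels(once, NULL, g)
  expect_identical(once$flags, twice$flags)
  rev_in <- v[3:1, ]
  rev_out <- filter_indels(rev_in, NULL, g)
  expect_identical(rev_out$flags, once$flags[3:1])
})

test_that("exclusion list round-trips through VCF and TSV", {
  g <- indel_genome()
  call <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "AT",
                         vaf = 0.3)
  xl <- build_indel_exclusion_list(list(I1 = call, I2 = call, I3 = call), g)
  for (ext in c(".vcf", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_indel_exclusion_list(xl, path)
    back <- read_indel_exclusion_list(path)
    expect_equal(back$pos, xl$pos)
    expect_equal(back$individual_count, xl$individual_count)
    expect_equal(back$individual_frequency, xl$individual_frequency)
  }
})

test_that("homopolymer-artifact simulation is filtered with high precision", {
  set.seed(31)
  L <- 20000L
  g <- simulate_genome(c("1" = L), seed = 31)
  # find homopolymer runs >= 5 in the random genome
  seq1 <- ref_window(g, "1", 1, L)
  runs <- gregexpr("A{5,}|C{5,}|G{5,}|T{5,}", seq1)[[1]]
  expect_gt(length(runs), 20)
  art_pos <- as.integer(runs) + 1L
  art_base <- substring(seq1, art_pos, art_pos)
  artifacts <- dplyr::bind_rows(lapply(seq_along(art_pos), function(i) {
    make_variant(pos = art_pos[i], ref = art_base[i],
                 alt = paste0(art_base[i], art_base[i]))
  }))
  # true indels placed away from any long run
  true_pos <- setdiff(seq(50L, L - 50L, by = 997L),
                      unlist(lapply(seq_along(runs), function(i) {
                        (as.integer(runs)[i] - 8L):(as.integer(runs)[i] +
                          attr(runs, "match.length")[i] + 8L)
                      })))
  trues <- dplyr::bind_rows(lapply(true_pos, function(p) {
    b <- substr(seq1, p, p)
    make_variant(pos = p, ref = b, alt = paste0(b, "CGA"))
  }))
  out <- filter_indels(dplyr::bind_rows(artifacts, trues), NULL, g)
  flagged <- vapply(out$flags, function(f) "FAIL_HOMOPOLYMER" %in% f, TRUE)
  truth_artifact <- c(rep(TRUE, nrow(artifacts)), rep(FALSE, nrow(trues)))
  # precision of the PASS set against truth
  pass <- !flagged
  precision <- sum(pass & !truth_artifact) / sum(pass)
  expect_gt(precision, 0.9)
  expect_true(all(flagged[truth_artifact]))
})
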