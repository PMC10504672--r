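#' Read candidate variants from a multi-sample VCF
#'
#' Parses a GATK-style multi-sample VCF into one row per candidate variant and
#' alternate allele. Multi-allelic rows are split; each alternate allele is
#' filtered independently downstream. Non-variant rows (`ALT` of `"."`) are
#' dropped. Missing per-sample fields stay `NA` — they are never zero-filled.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param test_sample Name of the PTA sample to be filtered.
#' @param control_samples Character vector of germline control sample names
#'   (may be empty for the leave-one-out private-variant mode).
#' @return A tibble with one row per (site, alt allele): `chrom`, `pos`
#'   (1-based), `id`, `ref`, `alt`, `var_type`, `qual`, `mq`, `filter_input`,
#'   test-sample `ref_depth`, `alt_depth`, `depth`, `gq`, `genotype`, `vaf`,
#'   a `controls` list-column of per-control tibbles, and an empty `flags`
#'   list-column. The test sample name is kept in attribute `test_sample`.
#' @export
read_variants <- function(vcf_path, test_sample, control_samples = character()) {
  if (!file.exists(vcf_path)) abort(paste0("no such file: ", vcf_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(c(test_sample, control_samples), samples)
  if (length(missing)) {
    abort(paste0("sample(s) not in VCF header: ",
                 paste(missing, collapse = ", ")))
  }
  fix <- vcf@fix
  keep <- !is.na(fix[, "ALT"]) & fix[, "ALT"] != "." & fix[, "ALT"] != ""
  fix <- fix[keep, , drop = FALSE]
  gt <- vcf@gt[keep, , drop = FALSE]
  if (nrow(fix) == 0L) {
    return(empty_variants(test_sample))
  }

  mq <- suppressWarnings(as.numeric(
    stringr::str_match(fix[, "INFO"], "(?:^|;)MQ=([^;]+)")[, 2L]))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_i <- rep(seq_len(nrow(fix)), n_alt)
  alt_i <- unlist(lapply(n_alt, seq_len))

  parse_sample <- function(sample) {
    fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
    val <- strsplit(gt[, sample], ":", fixed = TRUE)
    field <- function(key, row) {
      k <- match(key, fmt[[row]])
      if (is.na(k) || k > length(val[[row]])) NA_character_ else val[[row]][k]
    }
    out <- lapply(seq_along(row_i), function(j) {
      r <- row_i[j]; ai <- alt_i[j]
      gt_s <- field("GT", r)
      ad_s <- field("AD", r)
      dp_s <- field("DP", r)
      gq_s <- field("GQ", r)
      ad <- if (is.na(ad_s) || ad_s == ".") NA_integer_ else
        suppressWarnings(as.integer(strsplit(ad_s, ",", fixed = TRUE)[[1L]]))
      ref_d <- if (all(is.na(ad))) NA_integer_ else ad[1L]
      alt_d <- if (all(is.na(ad)) || length(ad) < ai + 1L) NA_integer_ else ad[ai + 1L]
      alleles <- if (is.na(gt_s)) character() else
        strsplit(gt_s, "[/|]")[[1L]]
      geno <- if (!length(alleles) || any(alleles == ".")) "missing"
        else if (all(alleles == as.character(ai))) "hom_alt"
        else if (any(alleles == as.character(ai))) "het"
        else if (all(alleles == "0")) "hom_ref"
        else "hom_ref"   # homozygous / het for a different alt allele
      list(ref_depth = ref_d, alt_depth = alt_d,
           depth = suppressWarnings(as.integer(dp_s)),
           gq = suppressWarnings(as.numeric(gq_s)), genotype = geno,
           phased = !is.na(gt_s) && grepl("|", gt_s, fixed = TRUE),
           gt_raw = gt_s)
    })
    tibble(
      ref_depth = vapply(out, function(x) x$ref_depth %||% NA_integer_, 1L),
      alt_depth = vapply(out, function(x) x$alt_depth %||% NA_integer_, 1L),
      depth = vapply(out, function(x) x$depth %||% NA_integer_, 1L),
      gq = vapply(out, function(x) x$gq %||% NA_real_, 1),
      genotype = vapply(out, function(x) x$genotype, ""),
      phased = vapply(out, function(x) x$phased, TRUE),
      gt_raw = vapply(out, function(x) x$gt_raw %||% NA_character_, "")
    )
  }

  test <- parse_sample(test_sample)
  ctrl <- lapply(control_samples, parse_sample)
  controls <- lapply(seq_along(row_i), function(j) {
    if (!length(control_samples)) {
      return(tibble(sample = character(), ref_depth = integer(),
                    alt_depth = integer(), depth = integer(), gq = double(),
                    genotype = character()))
    }
    bind_rows(lapply(seq_along(control_samples), function(k) {
      tibble(sample = control_samples[k],
             ref_depth = ctrl[[k]]$ref_depth[j],
             alt_depth = ctrl[[k]]$alt_depth[j],
             depth = ctrl[[k]]$depth[j],
             gq = ctrl[[k]]$gq[j],
             genotype = ctrl[[k]]$genotype[j])
    }))
  })

  ref <- fix[row_i, "REF"]
  alt <- vapply(seq_along(row_i), function(j) alts[[row_i[j]]][alt_i[j]], "")
  total <- test$ref_depth + test$alt_depth
  out <- tibble(
    chrom = fix[row_i, "CHROM"],
    pos = as.integer(fix[row_i, "POS"]),
    id = ifelse(is.na(fix[row_i, "ID"]), ".", fix[row_i, "ID"]),
    ref = ref,
    alt = alt,
    var_type = variant_type(ref, alt),
    qual = suppressWarnings(as.numeric(fix[row_i, "QUAL"])),
    mq = mq[row_i],
    filter_input = ifelse(is.na(fix[row_i, "FILTER"]), ".",
                          fix[row_i, "FILTER"]),
    ref_depth = test$ref_depth,
    alt_depth = test$alt_depth,
    depth = test$depth,
    gq = test$gq,
    genotype = test$genotype,
    phased_gt = test$gt_raw,
    vaf = ifelse(!is.na(total) & total > 0, test$alt_depth / total, NA_real_),
    controls = controls,
    flags = lapply(seq_along(row_i), function(i) character())
  )
  attr(out, "test_sample") <- test_sample
  out
}

empty_variants <- function(test_sample) {
  out <- tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alt = character(), var_type = character(), qual = double(), mq = double(),
    filter_input = character(), ref_depth = integer(), alt_depth = integer(),
    depth = integer(), gq = double(), genotype = character(),
    phased_gt = character(), vaf = double(), controls = list(), flags = list()
  )
  attr(out, "test_sample") <- test_sample
  out
}

#' Read phased germline heterozygous sites
#'
#' Reads a phased VCF (pipe-separated genotypes) and returns per-site allele
#' depths of the test sample together with the haplotype carrying the
#' alternate allele, plus the control genotype needed to keep only sites
#' heterozygous in the bulk control.
#'
#' @param vcf_path Phased VCF path.
#' @param test_sample Sample whose allele depths are modeled.
#' @param control_sample Bulk control whose genotype defines heterozygosity
#'   (defaults to the test sample when no control is available).
#' @return Tibble `chrom, pos, id, ref, alt, hap, ref_depth, alt_depth,
#'   control_genotype`; `hap` is `"hap1"`/`"hap2"` for the haplotype carrying
#'   the alternate allele, `NA` for unphased genotypes.
#' @export
read_phased_hets <- function(vcf_path, test_sample,
                             control_sample = test_sample) {
  v <- read_variants(vcf_path, test_sample, unique(control_sample))
  ctrl_geno <- vapply(v$controls, function(df) {
    if (nrow(df)) df$genotype[df$sample == control_sample][1L] else NA_character_
  }, "")
  hap <- dplyr::case_when(
    v$phased_gt == "1|0" ~ "hap1",
    v$phased_gt == "0|1" ~ "hap2",
    TRUE ~ NA_character_
  )
  tibble(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref, alt = v$alt,
         hap = hap, ref_depth = v$ref_depth, alt_depth = v$alt_depth,
         test_genotype = v$genotype, control_genotype = ctrl_geno)
}

#' Read a panel-of-normals site list
#'
#' Accepts a VCF or a 4-column TSV (`chrom, pos, ref, alt`). Matching
#' downstream is exact on all four keys with the `"chr"` prefix normalized.
#'
#' @param path File path.
#' @return Tibble `chrom, pos, ref, alt`.
#' @export
read_pon_sites <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    alts <- strsplit(vcf@fix[, "ALT"], ",", fixed = TRUE)
    n <- lengths(alts)
    i <- rep(seq_len(nrow(vcf@fix)), n)
    tibble(chrom = vcf@fix[i, "CHROM"],
           pos = as.integer(vcf@fix[i, "POS"]),
           ref = vcf@fix[i, "REF"], alt = unlist(alts))
  } else {
    df <- readr::read_tsv(path, col_names = c("chrom", "pos", "ref", "alt"),
                          comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    mutate(df, chrom = as.character(.data$chrom), pos = as.integer(.data$pos))
  }
}

known_filter_flags <- c(
  FAIL_CONTROL_EVIDENCE = "evidence for the variant in a paired control sample",
  FAIL_QUAL = "site quality below threshold or non-PASS input FILTER",
  FAIL_DEPTH = "insufficient base coverage in test or control sample",
  FAIL_MQ = "mapping quality at or below threshold",
  FAIL_PON = "site present in the panel of normals",
  FAIL_GQ = "genotype quality below threshold",
  FAIL_VAF = "variant allele frequency below threshold",
  FAIL_RF = "random-forest artifact probability above the calibrated cutoff",
  FAIL_EXCLUSION = "indel recurrent across individuals (exclusion list)",
  FAIL_HOMOPOLYMER = "insertion extending a 5bp+ reference homopolymer"
)

#' Write classified variants as a VCF
#'
#' Emits a VCF 4.2 with the cumulative filter flags in `FILTER` (`PASS` when
#' the flag set is empty) and, when present in the input tibble, INFO keys
#' `PTAPROB` (random-forest artifact probability), `AILOGP` (natural log of
#' the allelic-imbalance binomial p value) and `LINKPHRED` (read-backed
#' phasing Phred score), each rounded to 6 decimals. A write-then-read
#' round-trip reproduces flag sets and probabilities.
#'
#' @param variants Variant tibble (as from [read_variants()]), with a `flags`
#'   list-column and optional `p_artifact`, `ai_log_p`, `link_phred` columns.
#' @param destination Output path (plain text).
#' @param sample Sample name for the genotype column; defaults to the
#'   `test_sample` attribute.
#' @return `destination`, invisibly.
#' @export
write_classified_vcf <- function(variants, destination,
                                 sample = attr(variants, "test_sample")) {
  if (is.null(sample)) sample <- "SAMPLE"
  dir <- dirname(destination)
  if (!dir.exists(dir)) abort(paste0("directory does not exist: ", dir))
  if (!is.list(variants$flags)) abort("variants must carry a flags list-column")

  num6 <- function(x) ifelse(is.na(x), NA, sprintf("%.6f", x))
  info <- rep("", nrow(variants))
  add_info <- function(info, key, vals) {
    piece <- ifelse(is.na(vals), "", paste0(key, "=", vals))
    joined <- ifelse(piece == "", info,
                     ifelse(info == "", piece, paste(info, piece, sep = ";")))
    joined
  }
  if ("p_artifact" %in% names(variants)) {
    info <- add_info(info, "PTAPROB", num6(variants$p_artifact))
  }
  if ("ai_log_p" %in% names(variants)) {
    info <- add_info(info, "AILOGP", num6(variants$ai_log_p))
  }
  if ("link_phred" %in% names(variants)) {
    info <- add_info(info, "LINKPHRED", num6(variants$link_phred))
  }
  info[info == ""] <- "."

  filt <- vapply(variants$flags, function(f) {
    if (length(f) == 0L) "PASS" else paste(sort(unique(f)), collapse = ";")
  }, "")

  gt <- paste0(
    ifelse(is.na(variants$genotype), "./.",
           c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0",
             missing = "./.")[variants$genotype]),
    ":", ifelse(is.na(variants$ref_depth), ".", variants$ref_depth), ",",
    ifelse(is.na(variants$alt_depth), ".", variants$alt_depth),
    ":", ifelse(is.na(variants$depth),
                variants$ref_depth + variants$alt_depth, variants$depth),
    ":", ifelse(is.na(variants$gq), ".", variants$gq)
  )

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##FILTER=<ID=", names(known_filter_flags), ",Description=\"",
           known_filter_flags, "\">"),
    "##INFO=<ID=PTAPROB,Number=1,Type=Float,Description=\"Random-forest artifact probability\">",
    "##INFO=<ID=AILOGP,Number=1,Type=Float,Description=\"Natural log of allelic-imbalance binomial p value\">",
    "##INFO=<ID=LINKPHRED,Number=1,Type=Float,Description=\"Read-backed phasing Phred score\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  mq_piece <- if ("mq" %in% names(variants)) {
    ifelse(is.na(variants$mq), "", paste0("MQ=", variants$mq))
  } else ""
  info <- ifelse(mq_piece == "", info,
                 ifelse(info == ".", mq_piece, paste(info, mq_piece, sep = ";")))
  rows <- paste(variants$chrom, variants$pos,
                if ("id" %in% names(variants)) variants$id else ".",
                variants$ref, variants$alt,
                ifelse(is.na(variants$qual), ".", variants$qual),
                filt, info, "GT:AD:DP:GQ", gt, sep = "\t")
  ok <- tryCatch({
    writeLines(c(header, rows), destination)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write: ", destination))
  invisible(destination)
}
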