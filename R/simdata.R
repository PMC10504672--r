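#' Simulate a random reference genome
#'
#' Uniform ACGT sequence per chromosome; used to give simulated variants a
#' real sequence context and the indel filter a reference to interrogate.
#'
#' @param chrom_lengths Named integer vector.
#' @param seed Integer seed.
#' @return A [ref_genome()].
#' @export
simulate_genome <- function(chrom_lengths, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  ref_genome(setNames(seqs, names(chrom_lengths)))
}

#' Simulate phased germline heterozygous sites
#'
#' Het sites are placed with exponential (Poisson-process) spacing along the
#' region; haplotype labels alternate randomly; per-site depth is Poisson
#' around the configured mean, and the alternate-allele depth is binomial with
#' a success probability following `imbalance_profile` after haplotype
#' orientation (a site whose alternate allele sits on haplotype 2 uses one
#' minus the profile value). The constant-0.5 profile is a balanced region.
#'
#' @param region_length Region length in bp.
#' @param het_density Expected hets per bp (e.g. `1/1000`).
#' @param mean_depth Mean sequencing depth.
#' @param imbalance_profile Function of position returning the
#'   haplotype-1-oriented B-allele fraction in `[0, 1]`; default constant 0.5.
#' @param seed Integer seed. A fixed seed fixes the output exactly.
#' @param chrom Chromosome name for the emitted records.
#' @return Tibble compatible with [read_phased_hets()]: `chrom, pos, id, ref,
#'   alt, hap, ref_depth, alt_depth, test_genotype, control_genotype`.
#' @export
simulate_phased_hets <- function(region_length, het_density = 1 / 1000,
                                 mean_depth = 30,
                                 imbalance_profile = function(pos) rep(0.5, length(pos)),
                                 seed = 1L, chrom = "1") {
  stopifnot(het_density > 0, mean_depth >= 1)
  set.seed(seed)
  n_max <- stats::qpois(1 - 1e-9, region_length * het_density) + 10L
  pos <- cumsum(ceiling(rexp(n_max, rate = het_density)))
  pos <- pos[pos <= region_length]
  n <- length(pos)
  hap <- sample(c("hap1", "hap2"), n, replace = TRUE)
  depth <- pmax(1L, rpois(n, mean_depth))
  p1 <- pmin(pmax(imbalance_profile(pos), 0), 1)
  p_alt <- ifelse(hap == "hap1", p1, 1 - p1)
  alt_depth <- rbinom(n, depth, p_alt)
  ref_alt <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 2L), collapse = "")
  }, "")
  tibble(chrom = chrom, pos = as.integer(pos),
         id = paste0("rs", seq_len(n)),
         ref = substr(ref_alt, 1, 1), alt = substr(ref_alt, 2, 2),
         hap = hap, ref_depth = depth - alt_depth, alt_depth = alt_depth,
         test_genotype = "het", control_genotype = "het")
}

#' Write simulated phased hets as a phased VCF
#'
#' Emits the dialect [read_phased_hets()] consumes: pipe-separated genotypes
#' in the test sample (`1|0` when the alternate allele is on haplotype 1),
#' allele depths, and an unphased het control genotype.
#'
#' @param hets From [simulate_phased_hets()].
#' @param path Output path.
#' @param test_sample,control_sample Sample column names.
#' @export
write_phased_vcf <- function(hets, path, test_sample = "PTA",
                             control_sample = "BULK") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", test_sample, control_sample, sep = "\t"))
  gt <- ifelse(hets$hap == "hap1", "1|0", "0|1")
  test <- paste0(gt, ":", hets$ref_depth, ",", hets$alt_depth, ":99")
  ctrl <- "0/1:15,15:99"
  rows <- paste(hets$chrom, hets$pos, hets$id, hets$ref, hets$alt, "500",
                "PASS", ".", "GT:AD:GQ", test, ctrl, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

# packaged 96-channel spectra used by the candidate simulator: a clock-like
# spectrum (CpG-context C>T enriched) for true somatic mutations and an
# artifact-like spectrum enriched in T>C (and some C>T) channels, standing in
# for the universal PTA amplification-error signature
sim_spectra <- function() {
  ch <- channels96()
  clock <- rep(1, 96)
  clock[grepl("\\[C>T\\]G", ch)] <- 20          # NpCpG C>T
  clock[grepl("\\[C>T\\]", ch) & !grepl("\\[C>T\\]G", ch)] <- 4
  clock <- clock / sum(clock)
  artifact <- rep(1, 96)
  artifact[grepl("\\[T>C\\]", ch)] <- 12
  artifact[grepl("\\[C>T\\]", ch)] <- 4
  artifact[grepl("\\[C>A\\]", ch)] <- 3
  artifact <- artifact / sum(artifact)
  list(clock = setNames(clock, ch), artifact = setNames(artifact, ch))
}

#' Simulate labeled candidate base substitutions with classifier features
#'
#' Draws true somatic variants and amplification artifacts from
#' class-conditional distributions whose divergence is scaled by
#' `feature_separation`: at separation 0 the two classes share one
#' distribution (no classifier can beat chance); at 1 they are at the full
#' stated separation. True somatics have VAF ~ Binomial(depth, 0.5)/depth,
#' trinucleotide context from a clock-like spectrum, earlier replication
#' timing and smaller gene distances; artifacts have VAF ~
#' Binomial(depth, q)/depth with q ~ Uniform(0.1, 0.4) (the sub-clonal
#' appearance of amplification errors), context from a T>C-enriched
#' artifact-like spectrum, and uniform genomic placement of the remaining
#' features. A small fraction of rows (3%) has an undefined
#' allelic-imbalance value or replication timing to exercise the fallback
#' models.
#'
#' @param n_true,n_artifact Class sizes (>= 0).
#' @param feature_separation Divergence scale in `[0, 1]`.
#' @param seed Integer seed.
#' @param mean_depth Mean sequencing depth.
#' @param chrom_length Nominal chromosome length for positions.
#' @return List: `variants` (candidate tibble with `up`/`dn` context columns),
#'   `features` (26-feature tibble), `truth` (tibble `label`), `params`.
#' @export
simulate_candidates <- function(n_true, n_artifact, feature_separation = 1,
                                seed = 1L, mean_depth = 30,
                                chrom_length = 1e8) {
  stopifnot(n_true >= 0, n_artifact >= 0,
            feature_separation >= 0, feature_separation <= 1)
  set.seed(seed)
  s <- feature_separation
  n <- n_true + n_artifact
  label <- c(rep("true_somatic", n_true), rep("artifact", n_artifact))
  sp <- sim_spectra()
  mid <- (sp$clock + sp$artifact) / 2
  p_true <- (1 - s) * mid + s * sp$clock
  p_art <- (1 - s) * mid + s * sp$artifact

  channel <- character(n)
  if (n_true) channel[1:n_true] <- sample(channels96(), n_true, TRUE, p_true)
  if (n_artifact) {
    channel[(n_true + 1):n] <- sample(channels96(), n_artifact, TRUE, p_art)
  }
  m <- stringr::str_match(channel, "^(.)\\[(.)>(.)\\](.)$")
  up <- m[, 2L]; ref <- m[, 3L]; alt <- m[, 4L]; dn <- m[, 5L]
  # randomly present half the variants on the purine strand
  flip <- runif(n) < 0.5
  ref_out <- ifelse(flip, revcomp(ref), ref)
  alt_out <- ifelse(flip, revcomp(alt), alt)
  up_out <- ifelse(flip, revcomp(dn), up)
  dn_out <- ifelse(flip, revcomp(up), dn)

  depth <- pmax(5L, rpois(n, mean_depth))
  q <- ifelse(label == "true_somatic", 0.5,
              runif(n, 0.5 - 0.4 * s, 0.5 - 0.1 * s))
  alt_depth <- rbinom(n, depth, q)
  # keep at least one supporting read so the record is a variant call
  alt_depth <- pmax(alt_depth, 1L)
  vaf <- alt_depth / depth

  ai_p <- ifelse(label == "true_somatic", runif(n),
                 rbeta(n, 1 / (1 + 6 * s), 1))
  ai_log_p <- log(pmax(ai_p, 1e-300))
  rt <- ifelse(label == "true_somatic", rnorm(n, 0.5 * s, 1),
               rnorm(n, -0.5 * s, 1))
  gene_d <- pmin(pmax(ifelse(label == "true_somatic",
                             rnorm(n, 3.5 - s, 1), rnorm(n, 3.5 + s, 1)),
                      0), 7)
  rep_d <- pmin(pmax(ifelse(label == "true_somatic",
                            rnorm(n, 3 + 0.5 * s, 1), rnorm(n, 3 - 0.5 * s, 1)),
                     0), 7)
  strand_true <- c(0.55, 0.2, 0.2, 0.05)
  strand_art <- c(0.55 - 0.1 * s, 0.2 + 0.05 * s, 0.2 + 0.05 * s, 0.05)
  strand <- vapply(seq_len(n), function(i) {
    p <- if (label[i] == "true_somatic") strand_true else strand_art
    sample(strand_levels, 1L, prob = p)
  }, "")
  undef_ai <- runif(n) < 0.03
  undef_rt <- runif(n) < 0.03
  ai_log_p[undef_ai] <- NA_real_
  rt[undef_rt] <- NA_real_

  features <- tibble(
    ai_log_p = ai_log_p,
    mutation_type = factor(paste0(ref, ">", alt),
                           levels = mutation_type_levels))
  ctx_names <- c(paste0("ctx_m", 10:1), paste0("ctx_p", 1:10))
  for (nm in ctx_names) {
    features[[nm]] <- factor(sample(c("A", "C", "G", "T"), n, TRUE),
                             levels = base_levels)
  }
  features$ctx_m1 <- factor(up, levels = base_levels)
  features$ctx_p1 <- factor(dn, levels = base_levels)
  features$gene_distance <- gene_d
  features$repeat_distance <- rep_d
  features$transcriptional_strand <- factor(strand, levels = strand_levels)
  features$replication_timing <- rt
  features <- features[, feature_names()]

  pos <- sort(sample.int(chrom_length, n))
  variants <- tibble(
    chrom = "1", pos = pos, id = ".",
    ref = ref_out, alt = alt_out, var_type = "SNV",
    qual = round(runif(n, 200, 2000), 1), mq = 60,
    filter_input = "PASS",
    ref_depth = depth - alt_depth, alt_depth = alt_depth, depth = depth,
    gq = 99, genotype = "het", phased_gt = NA_character_, vaf = vaf,
    up = up_out, dn = dn_out,
    controls = lapply(seq_len(n), function(i) {
      tibble(sample = "BULK", ref_depth = 30L, alt_depth = 0L, depth = 30L,
             gq = 99, genotype = "hom_ref")
    }),
    flags = lapply(seq_len(n), function(i) character())
  )
  attr(variants, "test_sample") <- "PTA"
  list(variants = variants, features = features,
       truth = tibble(label = label),
       params = list(n_true = n_true, n_artifact = n_artifact,
                     feature_separation = s, seed = seed,
                     mean_depth = mean_depth))
}

#' Simulate read evidence for the phasing analysis
#'
#' For each candidate, generates spanning read pairs over a few nearby
#' germline het sites. Reads from a true somatic variant phase consistently:
#' the somatic allele rides one haplotype, so each read shows either both
#' alternate or both reference alleles (up to the allele-observation error).
#' Reads from a chimeric artifact carry the somatic allele on a random
#' haplotype, producing mixed cis/trans support.
#'
#' @param variants Candidate tibble (`chrom`, `pos`).
#' @param labels `"true_somatic"`/`"artifact"` per candidate.
#' @param n_germline_sites Informative germline sites per candidate.
#' @param reads_per_site Spanning reads per site.
#' @param error_rate Per-allele observation error.
#' @param seed Integer seed.
#' @return Evidence tibble for [linkage_analysis()].
#' @export
simulate_read_evidence <- function(variants, labels, n_germline_sites = 3,
                                   reads_per_site = 10, error_rate = 0.005,
                                   seed = 1L) {
  set.seed(seed)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    true_var <- labels[i] == "true_somatic"
    som_hap <- sample(1:2, 1L)
    rows <- lapply(seq_len(n_germline_sites), function(g) {
      gpos <- variants$pos[i] + sample(c(-1, 1), 1L) * sample(50:400, 1L)
      read_hap <- sample(1:2, reads_per_site, replace = TRUE)
      # germline alt arbitrarily on haplotype 1
      germ <- ifelse(read_hap == 1L, "alt", "ref")
      som <- if (true_var) {
        ifelse(read_hap == som_hap, "alt", "ref")
      } else {
        ifelse(sample(1:2, reads_per_site, TRUE) == 1L, "alt", "ref")
      }
      flip <- function(a) ifelse(runif(length(a)) < error_rate,
                                 ifelse(a == "alt", "ref", "alt"), a)
      tibble(chrom = variants$chrom[i], somatic_pos = variants$pos[i],
             germline_pos = as.integer(gpos),
             read_id = paste0("r", i, "_", g, "_", seq_len(reads_per_site)),
             somatic_allele = flip(som), germline_allele = flip(germ))
    })
    out[[i]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Simulate per-bin coverage, a panel of normals, and germline-het VAFs
#'
#' Per-1-kb read counts are drawn around a shared smooth "wavy" baseline
#' (random sinusoids emulating amplification waves) scaled by the local copy
#' number, so dividing by the panel of normals removes the waves. Germline
#' het allele depths are binomial with success probability 0.5 in diploid
#' segments, 1/3 or 2/3 (equal mixture) in copy-number-3 segments, and
#' 0.02/0.98 in loss and copy-neutral LOH segments (allelic dropout).
#'
#' @param cn_segments Tibble `chrom, start, end, state` (0-based half-open,
#'   tiling each simulated chromosome; `state` in
#'   `"loss"/"neutral"/"gain"/"cnLOH"`).
#' @param n_pon_samples Number of panel samples (>= 2).
#' @param reads_per_kb Baseline reads per 1-kb bin at copy number 2.
#' @param het_density Germline hets per bp.
#' @param mean_depth Mean depth at het sites (copy number 2).
#' @param noise_sd Extra log-normal bin noise.
#' @param seed Integer seed.
#' @return List: `sample_counts`, `pon_counts` (list of tibbles), `hets`
#'   (`chrom, pos, ref_depth, alt_depth`), `truth` (the input segments),
#'   `params`.
#' @export
simulate_coverage_daf <- function(cn_segments, n_pon_samples = 5,
                                  reads_per_kb = 100, het_density = 1 / 1500,
                                  mean_depth = 30, noise_sd = 0.05,
                                  seed = 1L) {
  stopifnot(n_pon_samples >= 2)
  set.seed(seed)
  cn_of <- c(loss = 1, neutral = 2, gain = 3, cnLOH = 2)
  stopifnot(all(cn_segments$state %in% names(cn_of)))
  bin <- 1000L
  out_counts <- list(); out_pon <- list(); out_hets <- list()
  for (ch in unique(cn_segments$chrom)) {
    segs <- arrange(filter(cn_segments, .data$chrom == ch), .data$start)
    L <- max(segs$end)
    starts <- seq(0L, L - bin, by = bin)
    mids <- starts + bin / 2
    seg_idx <- findInterval(mids, segs$start)
    cn <- cn_of[segs$state[seg_idx]]
    # shared wavy baseline with random phases/periods
    p1 <- runif(1, 2e5, 6e5); p2 <- runif(1, 2e6, 6e6)
    wave <- exp(0.2 * sin(2 * pi * mids / p1 + runif(1, 0, 2 * pi)) +
                  0.15 * sin(2 * pi * mids / p2 + runif(1, 0, 2 * pi)))
    lam_base <- reads_per_kb * wave
    sample_lam <- lam_base * (cn / 2) * exp(rnorm(length(mids), 0, noise_sd))
    out_counts[[ch]] <- tibble(chrom = ch, start = starts, end = starts + bin,
                               count = rpois(length(mids), sample_lam))
    out_pon[[ch]] <- lapply(seq_len(n_pon_samples), function(k) {
      tibble(chrom = ch, start = starts, end = starts + bin,
             count = rpois(length(mids),
                           lam_base * exp(rnorm(length(mids), 0, noise_sd))))
    })
    # germline hets
    n_max <- stats::qpois(1 - 1e-9, L * het_density) + 10L
    pos <- cumsum(ceiling(rexp(n_max, rate = het_density)))
    pos <- pos[pos <= L]
    hseg <- findInterval(pos - 0.5, segs$start)
    hstate <- segs$state[hseg]
    hcn <- cn_of[hstate]
    hdepth <- pmax(1L, rpois(length(pos), mean_depth * hcn / 2))
    p_alt <- vapply(hstate, function(st) {
      switch(st,
             neutral = 0.5,
             gain = sample(c(1 / 3, 2 / 3), 1L),
             loss = sample(c(0.02, 0.98), 1L),
             cnLOH = sample(c(0.02, 0.98), 1L))
    }, 1)
    alt_d <- rbinom(length(pos), hdepth, p_alt)
    out_hets[[ch]] <- tibble(chrom = ch, pos = as.integer(pos),
                             ref_depth = hdepth - alt_d, alt_depth = alt_d)
  }
  pon_counts <- lapply(seq_len(n_pon_samples), function(k) {
    bind_rows(lapply(out_pon, `[[`, k))
  })
  list(sample_counts = bind_rows(out_counts), pon_counts = pon_counts,
       hets = bind_rows(out_hets), truth = cn_segments,
       params = list(n_pon_samples = n_pon_samples,
                     reads_per_kb = reads_per_kb, het_density = het_density,
                     mean_depth = mean_depth, noise_sd = noise_sd,
                     seed = seed))
}

#' Read / write per-bin count tables
#'
#' TSV with columns `chrom, start, end, count` (0-based half-open 1-kb bins).
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mutate(df, chrom = as.character(.data$chrom))
}

#' @rdname read_counts_tsv
#' @param counts Count tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Write simulated candidates as a multi-sample VCF
#'
#' Emits the dialect [read_variants()] consumes, with the test and a bulk
#' control sample.
#'
#' @param variants Candidate tibble from [simulate_candidates()].
#' @param path Output path.
#' @param test_sample,control_sample Sample column names.
#' @export
write_candidate_vcf <- function(variants, path, test_sample = "PTA",
                                control_sample = "BULK") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", test_sample, control_sample, sep = "\t"))
  gt_of <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0", missing = "./.")
  test <- paste0(gt_of[variants$genotype], ":", variants$ref_depth, ",",
                 variants$alt_depth, ":", variants$depth, ":", variants$gq)
  ctrl <- vapply(variants$controls, function(df) {
    paste0(gt_of[df$genotype[1L]], ":", df$ref_depth[1L], ",",
           df$alt_depth[1L], ":", df$depth[1L], ":", df$gq[1L])
  }, "")
  rows <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, variants$qual, variants$filter_input,
                paste0("MQ=", variants$mq), "GT:AD:DP:GQ", test, ctrl,
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a simulation truth table
#'
#' @param truth Truth tibble from a simulator.
#' @param path TSV destination.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
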