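# shared in-code fixtures: a small deterministic genome, annotation tracks,
# and writers for miniature VCFs

fixture_genome <- function() {
  # chr "1": fixed 300-bp sequence with known motifs at known positions
  set.seed(4242)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  # plant contexts used by feature/spectrum tests:
  #   pos 101 = C with A at 100 and G at 102
  #   pos 111 = G with C at 110 and T at 112
  substr(base, 100, 102) <- "ACG"
  substr(base, 110, 112) <- "CGT"
  # homopolymer runs: 6 T starting at 201; 4 A starting at 221
  substr(base, 201, 206) <- "TTTTTT"
  substr(base, 200, 200) <- "G"
  substr(base, 207, 207) <- "G"
  substr(base, 221, 224) <- "AAAA"
  substr(base, 220, 220) <- "C"
  substr(base, 225, 225) <- "C"
  ref_genome(c("1" = base))
}

fixture_annotations <- function(genome = fixture_genome()) {
  annotation_set(
    genes = tibble::tibble(chrom = "1", start = c(90L, 95L),
                           end = c(120L, 115L), strand = c("+", "-")),
    simple_repeats = tibble::tibble(chrom = "1", start = 200L, end = 210L),
    replication_timing = tibble::tibble(chrom = "1", start = c(0L, 100L),
                                        end = c(150L, 130L),
                                        value = c(2, 6)),
    centromeres = tibble::tibble(chrom = "1", start = 0L, end = 0L),
    genome = genome
  )
}

write_mini_vcf <- function(path, rows,
                           samples = c("PTA", "BULK"),
                           format = "GT:AD:DP:GQ") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

# a minimal candidate tibble accepted by the filters
make_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                         qual = 500, mq = 60, gq = 99, genotype = "het",
                         ref_depth = 15L, alt_depth = 15L,
                         filter_input = "PASS",
                         ctrl_alt = 0L, ctrl_geno = "hom_ref",
                         ctrl_gq = 99, ctrl_depth = 30L) {
  total <- ref_depth + alt_depth
  tibble::tibble(
    chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
    var_type = variant_type(ref, alt), qual = qual, mq = mq,
    filter_input = filter_input,
    ref_depth = ref_depth, alt_depth = alt_depth, depth = total,
    gq = gq, genotype = genotype, phased_gt = NA_character_,
    vaf = alt_depth / total,
    controls = list(tibble::tibble(
      sample = "BULK", ref_depth = ctrl_depth - ctrl_alt,
      alt_depth = ctrl_alt, depth = ctrl_depth, gq = ctrl_gq,
      genotype = ctrl_geno)),
    flags = list(character())
  )
}

flags_of <- function(variants, i = 1L) sort(variants$flags[[i]])

# exhaustive segmentation oracle: plain recursion over every placement of the
# first-segment end enumerates all 2^(n-1) breakpoint subsets
brute_segment_cost <- function(v, penalty) {
  n <- length(v)
  rec <- function(start) {
    if (start > n) return(0)
    vals <- vapply(start:n, function(e) {
      seg <- v[start:e]
      sum((seg - mean(seg))^2) + (if (e < n) penalty else 0) + rec(e + 1)
    }, 1)
    min(vals)
  }
  rec(1)
}

# objective value of the DP solution, for comparison against the oracle
dp_cost <- function(v, penalty) {
  seg <- segment_piecewise(v, penalty)
  sse <- sum(vapply(seq_len(nrow(seg)), function(j) {
    s <- v[seg$start_idx[j]:seg$end_idx[j]]
    sum((s - mean(s))^2)
  }, 1))
  sse + penalty * (nrow(seg) - 1)
}
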