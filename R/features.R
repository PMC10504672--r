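#' Feature names of the base-substitution classifier
#'
#' The 26 features: the allelic-imbalance log p-value, the pyrimidine-strand
#' mutation type (6 classes), 20 positional context bases (10 up- and 10
#' downstream of the variant, positions -10..-1 and +1..+10 on the
#' pyrimidine strand), distance to the nearest gene, distance to the nearest
#' simple repeat, transcriptional strand, and replication timing.
#'
#' @return Character vector of 26 feature names.
#' @export
feature_names <- function() {
  c("ai_log_p", "mutation_type",
    paste0("ctx_m", 10:1), paste0("ctx_p", 1:10),
    "gene_distance", "repeat_distance", "transcriptional_strand",
    "replication_timing")
}

base_levels <- c("A", "C", "G", "T", "N")
mutation_type_levels <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
strand_levels <- c("untranscribed", "plus", "minus", "both")

#' Extract classifier features for candidate base substitutions
#'
#' Builds the 26-feature representation of each candidate: mutation type and
#' the 10-bp flanking context on each side, both computed on the pyrimidine
#' strand (purine-reference variants are reverse-complemented, which also
#' reverses the context), distances to the nearest gene and simple repeat
#' (0 when inside), the transcriptional strand of overlapping genes (distinct
#' union, so plus+minus collapses to `both`), and the median replication
#' timing of overlapping intervals. Context windows running off a chromosome
#' end are padded with `N`. Distances are capped and log-transformed
#' (`log10(1 + d)`) for split stability.
#'
#' @param variants Tibble with `chrom, pos, ref, alt` (SNVs only) and
#'   optionally `ai_log_p`.
#' @param annotations An [annotation_set()].
#' @param distance_cap Cap for gene/repeat distances in bp.
#' @return Tibble of the 26 features (factor columns for the categorical
#'   ones), one row per variant. `ai_log_p` and `replication_timing` may be
#'   `NA` (undefined); the model router handles them.
#' @export
extract_features <- function(variants, annotations, distance_cap = 1e7) {
  stopifnot(all(variants$var_type %in% "SNV" | variants$ref %in% base_levels))
  n <- nrow(variants)
  genome <- annotations$genome

  ctx <- vapply(seq_len(n), function(i) {
    ref_window(genome, variants$chrom[i], variants$pos[i] - 10L,
               variants$pos[i] + 10L)
  }, "")
  up10 <- substr(ctx, 1L, 10L)
  dn10 <- substr(ctx, 12L, 21L)
  purine <- variants$ref %in% c("A", "G")
  # pyrimidine-strand conversion: reverse-complement alleles and swap/flip
  # the flanks
  ref_p <- ifelse(purine, revcomp(variants$ref), variants$ref)
  alt_p <- ifelse(purine, revcomp(variants$alt), variants$alt)
  up_p <- ifelse(purine, revcomp(dn10), up10)
  dn_p <- ifelse(purine, revcomp(up10), dn10)
  mutation_type <- paste0(ref_p, ">", alt_p)

  ctx_cols <- matrix(NA_character_, n, 20L)
  for (k in 1:10) {
    ctx_cols[, k] <- substr(up_p, k, k)               # positions -10..-1
    ctx_cols[, 10L + k] <- substr(dn_p, k, k)         # positions +1..+10
  }
  ctx_cols[!ctx_cols %in% c("A", "C", "G", "T")] <- "N"

  gene_d <- nearest_interval_distance(variants$chrom, variants$pos,
                                      annotations$genes)
  rep_d <- nearest_interval_distance(variants$chrom, variants$pos,
                                     annotations$simple_repeats)
  gene_d <- pmin(ifelse(is.na(gene_d), distance_cap, gene_d), distance_cap)
  rep_d <- pmin(ifelse(is.na(rep_d), distance_cap, rep_d), distance_cap)

  # transcriptional strand: distinct union of overlapping gene strands
  q <- GenomicRanges::GRanges(norm_chrom(variants$chrom),
                              IRanges::IRanges(variants$pos, variants$pos))
  g <- intervals_to_granges(annotations$genes)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, g))
  strand <- rep("untranscribed", n)
  if (length(ov)) {
    hits <- split(annotations$genes$strand[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    for (qi in names(hits)) {
      u <- unique(hits[[qi]])
      strand[as.integer(qi)] <-
        if (length(u) > 1L) "both" else if (u == "+") "plus" else "minus"
    }
  }

  # replication timing: median over overlapping intervals, NA when none
  rt <- rep(NA_real_, n)
  r <- intervals_to_granges(annotations$replication_timing)
  ovr <- suppressWarnings(GenomicRanges::findOverlaps(q, r))
  if (length(ovr)) {
    vals <- split(annotations$replication_timing$value[S4Vectors::subjectHits(ovr)],
                  S4Vectors::queryHits(ovr))
    for (qi in names(vals)) rt[as.integer(qi)] <- median(vals[[qi]])
  }

  out <- tibble(
    ai_log_p = if ("ai_log_p" %in% names(variants)) variants$ai_log_p
               else rep(NA_real_, n),
    mutation_type = factor(mutation_type, levels = mutation_type_levels)
  )
  ctx_names <- c(paste0("ctx_m", 10:1), paste0("ctx_p", 1:10))
  for (k in seq_len(20L)) {
    out[[ctx_names[k]]] <- factor(ctx_cols[, k], levels = base_levels)
  }
  out$gene_distance <- log10(1 + gene_d)
  out$repeat_distance <- log10(1 + rep_d)
  out$transcriptional_strand <- factor(strand, levels = strand_levels)
  out$replication_timing <- rt
  out[, feature_names()]
}
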