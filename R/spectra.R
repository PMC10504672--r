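#' The 96 trinucleotide substitution channels
#'
#' COSMIC ordering: six pyrimidine-strand substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G), within each the 16 flanking-base combinations ordered by 5'
#' base then 3' base (A, C, G, T).
#'
#' @return Character vector of 96 channel names like `"A[C>A]A"`.
#' @export
channels96 <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(classes, function(cl) {
    as.vector(t(outer(bases, bases, function(up, dn) {
      paste0(up, "[", cl, "]", dn)
    })))
  }))
}

#' Channel of one base substitution
#'
#' Substitutions with a purine reference are reverse-complemented to the
#' pyrimidine strand (context bases swap and complement accordingly).
#'
#' @param ref,alt Single-base alleles.
#' @param up,dn 5' and 3' flanking reference bases (on the reference strand).
#' @return Channel name, or `NA` when the context contains a base outside
#'   `ACGT`.
#' @export
mut_channel <- function(ref, alt, up, dn) {
  stopifnot(length(ref) == length(alt), length(up) == length(ref),
            length(dn) == length(ref))
  ref <- toupper(ref); alt <- toupper(alt)
  up <- toupper(up); dn <- toupper(dn)
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, revcomp(ref), ref)
  alt2 <- ifelse(purine, revcomp(alt), alt)
  up2 <- ifelse(purine, revcomp(dn), up)
  dn2 <- ifelse(purine, revcomp(up), dn)
  ok <- ref2 %in% c("C", "T") & alt2 %in% c("A", "C", "G", "T") &
    up2 %in% c("A", "C", "G", "T") & dn2 %in% c("A", "C", "G", "T") &
    ref2 != alt2
  ifelse(ok, paste0(up2, "[", ref2, ">", alt2, "]", dn2), NA_character_)
}

#' 96-channel mutational spectrum
#'
#' Counts base substitutions in the 96 trinucleotide-context channels. The
#' flanking bases are taken from the supplied reference genome unless the
#' input already carries `up`/`dn` columns. Substitutions whose context
#' contains `N` are skipped; the skipped count is reported in attribute
#' `n_skipped`.
#'
#' @param substitutions Tibble with `chrom, pos, ref, alt` (SNVs only) and
#'   optionally `up`, `dn`.
#' @param genome A [ref_genome()], required when `up`/`dn` are absent.
#' @return Named numeric vector of length 96 (class `spectrum96`); the sum
#'   equals the number of contributing substitutions.
#' @export
spectrum96 <- function(substitutions, genome = NULL) {
  stopifnot(all(substitutions$ref %in% c("A", "C", "G", "T")),
            all(substitutions$alt %in% c("A", "C", "G", "T")))
  if (!all(c("up", "dn") %in% names(substitutions))) {
    if (is.null(genome)) abort("genome required when up/dn columns absent")
    ctx <- purrr::map2_chr(substitutions$chrom, substitutions$pos,
                           function(ch, p) ref_window(genome, ch, p - 1, p + 1))
    substitutions$up <- substr(ctx, 1, 1)
    substitutions$dn <- substr(ctx, 3, 3)
  }
  ch <- if (nrow(substitutions)) {
    mut_channel(substitutions$ref, substitutions$alt,
                substitutions$up, substitutions$dn)
  } else character()
  counts <- table(factor(ch[!is.na(ch)], levels = channels96()))
  out <- setNames(as.numeric(counts), channels96())
  class(out) <- c("spectrum96", "numeric")
  attr(out, "n_skipped") <- sum(is.na(ch))
  out
}

#' Cosine similarity of two spectra
#'
#' @param spec_a,spec_b Non-negative numeric vectors of equal length (at least
#'   one positive entry each).
#' @return Cosine of the angle between the vectors, in `[0, 1]` for
#'   non-negative inputs.
#' @export
cosine_similarity <- function(spec_a, spec_b) {
  a <- as.numeric(spec_a); b <- as.numeric(spec_b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Small-indel context classification
#'
#' Minimal type/length/homopolymer-context classification of indels:
#' `"ins"`/`"del"`, indel length (capped at 5+), and the length of the
#' reference homopolymer run of the relevant base adjacent to the event
#' (capped at 6+). This is the context the recurrence/homopolymer filter
#' needs.
#'
#' @param indels Tibble `chrom, pos, ref, alt` (VCF-style, anchored).
#' @param genome A [ref_genome()].
#' @return Tibble with `indel_type`, `indel_len`, `hp_base`, `hp_len`,
#'   `channel`.
#' @export
classify_indels <- function(indels, genome) {
  n <- nrow(indels)
  out <- tibble(
    indel_type = ifelse(nchar(indels$alt) > nchar(indels$ref), "ins", "del"),
    indel_len = abs(nchar(indels$alt) - nchar(indels$ref)),
    hp_base = NA_character_, hp_len = 0L
  )
  for (i in seq_len(n)) {
    seq_i <- if (out$indel_type[i] == "ins") {
      substr(indels$alt[i], nchar(indels$ref[i]) + 1L, nchar(indels$alt[i]))
    } else {
      substr(indels$ref[i], nchar(indels$alt[i]) + 1L, nchar(indels$ref[i]))
    }
    base <- substr(seq_i, 1L, 1L)
    out$hp_base[i] <- base
    out$hp_len[i] <- homopolymer_run(genome, indels$chrom[i], indels$pos[i],
                                     base)
  }
  out$channel <- paste0(out$indel_type, "_",
                        pmin(out$indel_len, 5L),
                        ifelse(out$indel_len >= 5L, "+", ""),
                        "_hp", pmin(out$hp_len, 6L),
                        ifelse(out$hp_len >= 6L, "+", ""))
  out
}

# length of the reference homopolymer run of `base` adjacent to the position
# right of the VCF anchor (where an insertion lands); looks both directions
homopolymer_run <- function(genome, chrom, anchor_pos, base) {
  win <- 30L
  right <- ref_window(genome, chrom, anchor_pos + 1L, anchor_pos + win)
  left <- ref_window(genome, chrom, anchor_pos - win + 1L, anchor_pos)
  run_right <- nchar(sub(paste0("^(", base, "*).*$"), "\\1", right))
  left_rev <- paste(rev(strsplit(left, "")[[1L]]), collapse = "")
  run_left <- nchar(sub(paste0("^(", base, "*).*$"), "\\1", left_rev))
  max(run_right, run_left)
}

#' Extrapolate a mutation burden by callable fraction
#'
#' Counts PASS autosomal substitutions that fall inside the callable regions
#' and divides by the fraction of the autosomal genome the callable regions
#' cover.
#'
#' @param variants Variant tibble with `chrom`, `pos` and a `flags`
#'   list-column (only PASS rows are counted).
#' @param callable Tibble `chrom, start, end` (0-based half-open) of callable
#'   regions.
#' @param autosome_lengths Named vector of autosomal chromosome lengths.
#' @return List `n_in_callable`, `callable_fraction`, `burden`.
#' @export
extrapolate_burden <- function(variants, callable, autosome_lengths) {
  autosomes <- norm_chrom(names(autosome_lengths))
  v <- variants[is_pass(variants) &
                  norm_chrom(variants$chrom) %in% autosomes, , drop = FALSE]
  cal <- callable[norm_chrom(callable$chrom) %in% autosomes, , drop = FALSE]
  frac <- sum(cal$end - cal$start) / sum(autosome_lengths)
  if (frac <= 0 || frac > 1) abort("callable fraction must be in (0, 1]")
  inside <- rep(FALSE, nrow(v))
  if (nrow(v) && nrow(cal)) {
    q <- GenomicRanges::GRanges(norm_chrom(v$chrom),
                                IRanges::IRanges(v$pos, v$pos))
    s <- intervals_to_granges(cal)
    inside <- IRanges::overlapsAny(q, s)
  }
  n <- sum(inside)
  list(n_in_callable = n, callable_fraction = frac, burden = n / frac)
}

#' Plot a 96-channel spectrum
#'
#' @param spectrum A [spectrum96()] vector.
#' @return A ggplot.
#' @export
plot_spectrum96 <- function(spectrum) {
  df <- tibble(channel = factor(names(spectrum), levels = channels96()),
               count = as.numeric(spectrum),
               class = sub("^.\\[(.>.)\\].$", "\\1", names(spectrum)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~class, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4)) +
    ggplot2::labs(x = NULL, y = "count")
}
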