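#' Left-align an indel against the reference
#'
#' Shifts a VCF-style indel (anchored, `ref`/`alt` sharing the first base) as
#' far left as the reference allows, producing the canonical representation
#' used for exclusion-list matching. SNVs and non-anchored records are
#' returned unchanged.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing indels (VCF 1-based).
#' @param genome A [ref_genome()].
#' @return Tibble `chrom, pos, ref, alt` left-aligned.
#' @export
left_align_indels <- function(chrom, pos, ref, alt, genome) {
  n <- length(pos)
  out_pos <- as.integer(pos)
  out_ref <- ref
  out_alt <- alt
  last_ch <- function(x) substr(x, nchar(x), nchar(x))
  drop_last <- function(x) substr(x, 1L, nchar(x) - 1L)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- as.integer(pos[i])
    if (nchar(r) == nchar(a)) next
    # canonical left-alignment: truncate a shared terminal base; when one
    # allele would empty, extend both to the left from the reference instead
    repeat {
      if (nchar(r) >= 1L && nchar(a) >= 1L && last_ch(r) == last_ch(a)) {
        if (nchar(r) > 1L && nchar(a) > 1L) {
          r <- drop_last(r); a <- drop_last(a)
        } else {
          if (p <= 1L) break
          prev <- ref_window(genome, chrom[i], p - 1L, p - 1L)
          if (prev == "N") break
          r <- paste0(prev, drop_last(r))
          a <- paste0(prev, drop_last(a))
          p <- p - 1L
        }
      } else break
    }
    # trim a shared leading base beyond the single anchor
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    out_pos[i] <- p; out_ref[i] <- r; out_alt[i] <- a
  }
  tibble(chrom = chrom, pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Build the recurrent-indel exclusion list
#'
#' Collects somatic indel calls across individuals (VAF > 0.15 only, germline
#' matches already removed upstream), left-aligns them, and keeps every
#' `chrom, pos, ref, alt` key observed in at least two distinct individuals,
#' with sample/individual counts and frequencies.
#'
#' @param calls_by_individual Named list (one element per individual) of
#'   tibbles with `chrom, pos, ref, alt, vaf` and optionally `sample`.
#' @param genome A [ref_genome()] for left-alignment.
#' @param min_vaf Collection threshold (exclusive).
#' @return Tibble `chrom, pos, ref, alt, individual_count, sample_count,
#'   individual_frequency, sample_frequency` (class `indel_exclusion_list`).
#' @export
build_indel_exclusion_list <- function(calls_by_individual, genome,
                                       min_vaf = 0.15) {
  if (is.null(names(calls_by_individual))) {
    names(calls_by_individual) <- paste0("I", seq_along(calls_by_individual))
  }
  n_ind <- length(calls_by_individual)
  if (n_ind < 2L) {
    warn("fewer than two individuals supplied; exclusion list is empty")
  }
  n_samples_total <- sum(vapply(calls_by_individual, function(df) {
    if ("sample" %in% names(df)) length(unique(df$sample)) else 1L
  }, 1L))
  all <- bind_rows(lapply(names(calls_by_individual), function(ind) {
    df <- calls_by_individual[[ind]]
    df <- filter(df, !is.na(.data$vaf) & .data$vaf > min_vaf)
    if (!nrow(df)) return(NULL)
    la <- left_align_indels(df$chrom, df$pos, df$ref, df$alt, genome)
    la$individual <- ind
    la$sample <- if ("sample" %in% names(df)) df$sample else ind
    la
  }))
  if (is.null(all) || !nrow(all)) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), individual_count = integer(),
                  sample_count = integer(), individual_frequency = double(),
                  sample_frequency = double())
    class(out) <- c("indel_exclusion_list", class(out))
    return(out)
  }
  out <- all |>
    mutate(chrom_n = norm_chrom(.data$chrom)) |>
    group_by(.data$chrom_n, .data$pos, .data$ref, .data$alt) |>
    summarise(chrom = dplyr::first(.data$chrom),
              individual_count = dplyr::n_distinct(.data$individual),
              sample_count = dplyr::n_distinct(paste(.data$individual,
                                                     .data$sample)),
              .groups = "drop") |>
    filter(.data$individual_count >= 2L) |>
    mutate(individual_frequency = .data$individual_count / n_ind,
           sample_frequency = .data$sample_count / n_samples_total) |>
    select("chrom", "pos", "ref", "alt", "individual_count", "sample_count",
           "individual_frequency", "sample_frequency") |>
    arrange(norm_chrom(.data$chrom), .data$pos)
  class(out) <- c("indel_exclusion_list", class(out))
  out
}

#' Filter candidate indels
#'
#' Flags candidates that match the exclusion list exactly (after
#' left-alignment) with `FAIL_EXCLUSION`, and insertions of one or two copies
#' of a single base that extend a reference homopolymer run of five or more of
#' that base adjacent to the insertion point with `FAIL_HOMOPOLYMER`. The
#' homopolymer rule names insertions only; deletions in homopolymers pass it.
#' Flags are cumulative.
#'
#' @param candidates Variant tibble with indel rows (`var_type` of
#'   `"insertion"`/`"deletion"`) and a `flags` list-column.
#' @param exclusion_list From [build_indel_exclusion_list()] (or
#'   [read_indel_exclusion_list()]).
#' @param genome A [ref_genome()].
#' @param min_run Homopolymer run length threshold.
#' @return `candidates` with updated flags.
#' @export
filter_indels <- function(candidates, exclusion_list, genome, min_run = 5L) {
  is_indel <- candidates$var_type %in% c("insertion", "deletion")
  idx <- which(is_indel)
  if (!length(idx)) return(candidates)
  la <- left_align_indels(candidates$chrom[idx], candidates$pos[idx],
                          candidates$ref[idx], candidates$alt[idx], genome)
  key <- paste(norm_chrom(la$chrom), la$pos, la$ref, la$alt)
  if (!is.null(exclusion_list) && nrow(exclusion_list)) {
    ekey <- paste(norm_chrom(exclusion_list$chrom), exclusion_list$pos,
                  exclusion_list$ref, exclusion_list$alt)
    hit <- idx[key %in% ekey]
    candidates$flags[hit] <- lapply(candidates$flags[hit],
                                    function(f) union(f, "FAIL_EXCLUSION"))
  }
  ins <- idx[candidates$var_type[idx] == "insertion"]
  for (i in ins) {
    j <- match(i, idx)
    inserted <- substr(la$alt[j], nchar(la$ref[j]) + 1L, nchar(la$alt[j]))
    b <- unique(strsplit(inserted, "")[[1L]])
    if (length(b) != 1L || nchar(inserted) > 2L) next   # multi-base exempt
    run <- homopolymer_run(genome, la$chrom[j], la$pos[j], b)
    if (run >= min_run) {
      candidates$flags[[i]] <- union(candidates$flags[[i]], "FAIL_HOMOPOLYMER")
    }
  }
  candidates
}

#' Read / write an indel exclusion list
#'
#' The list travels as a VCF whose INFO field carries the counts and
#' frequencies (`IC`, `SC`, `IF`, `SF`), or as a TSV with those columns.
#'
#' @param path File path.
#' @return An `indel_exclusion_list` tibble.
#' @export
read_indel_exclusion_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    info <- vcf@fix[, "INFO"]
    grab <- function(key) {
      as.numeric(stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2L])
    }
    out <- tibble(chrom = vcf@fix[, "CHROM"],
                  pos = as.integer(vcf@fix[, "POS"]),
                  ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
                  individual_count = as.integer(grab("IC")),
                  sample_count = as.integer(grab("SC")),
                  individual_frequency = grab("IF"),
                  sample_frequency = grab("SF"))
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    out$chrom <- as.character(out$chrom)
  }
  class(out) <- c("indel_exclusion_list", class(out))
  out
}

#' @rdname read_indel_exclusion_list
#' @param x An `indel_exclusion_list`.
#' @export
write_indel_exclusion_list <- function(x, path) {
  if (grepl("\\.vcf$", path)) {
    header <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=IC,Number=1,Type=Integer,Description=\"Individual count\">",
      "##INFO=<ID=SC,Number=1,Type=Integer,Description=\"Sample count\">",
      "##INFO=<ID=IF,Number=1,Type=Float,Description=\"Individual frequency\">",
      "##INFO=<ID=SF,Number=1,Type=Float,Description=\"Sample frequency\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t"))
    rows <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS",
                  paste0("IC=", x$individual_count, ";SC=", x$sample_count,
                         ";IF=", x$individual_frequency,
                         ";SF=", x$sample_frequency),
                  sep = "\t")
    writeLines(c(header, rows), path)
  } else {
    readr::write_tsv(as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}
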