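#' Coordinate conventions
#'
#' Internally every interval is 0-based half-open (BED convention); VCF
#' positions are 1-based and converted at the boundary. These helpers are the
#' only place the conversion happens.
#'
#' @param pos1 1-based position(s).
#' @name coordinates
#' @return `vcf_to_internal()` returns 0-based start(s); `internal_to_vcf()`
#'   the inverse.
#' @export
vcf_to_internal <- function(pos1) as.integer(pos1) - 1L

#' @rdname coordinates
#' @param pos0 0-based position(s).
#' @export
internal_to_vcf <- function(pos0) as.integer(pos0) + 1L

#' Normalize chromosome names for matching
#'
#' Strips a leading `"chr"` so `"chr1"` and `"1"` compare equal; original
#' spellings are preserved on output by the writers.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @export
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Classify a variant from its alleles
#'
#' @param ref,alt Allele strings.
#' @return `"SNV"`, `"insertion"` or `"deletion"`.
#' @export
variant_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) > nchar(ref) ~ "insertion",
    TRUE ~ "deletion"
  )
}

#' Reference sequence accessor
#'
#' Wraps a [Biostrings::DNAStringSet] (or a named character vector, or a FASTA
#' path) so any window of reference sequence can be fetched by chromosome and
#' 1-based coordinates. Windows running off a chromosome end are padded with
#' `"N"`.
#'
#' @param x A `DNAStringSet`, a named character vector of sequences, or a path
#'   to a FASTA file.
#' @return An object of class `ref_genome`.
#' @export
ref_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    x <- Biostrings::readDNAStringSet(x)
    names(x) <- sub("\\s.*$", "", names(x))
  } else if (is.character(x)) {
    x <- Biostrings::DNAStringSet(x)
  }
  stopifnot(methods::is(x, "DNAStringSet"), !is.null(names(x)))
  names(x) <- norm_chrom(names(x))
  structure(list(seq = x), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome>", length(x$seq), "sequence(s):",
      paste(utils::head(names(x$seq), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch reference sequence
#'
#' @param genome A [ref_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return Character string of length `end - start + 1`, padded with `N`
#'   outside the chromosome.
#' @export
ref_window <- function(genome, chrom, start, end) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% names(genome$seq)) {
    abort(paste0("chromosome not in reference: ", chrom))
  }
  len <- Biostrings::width(genome$seq[chrom])
  s <- max(1L, start)
  e <- min(len, end)
  core <- if (s > e) "" else
    as.character(Biostrings::subseq(genome$seq[[chrom]], s, e))
  paste0(strrep("N", max(0L, s - start)), core, strrep("N", max(0L, end - e)))
}

#' Chromosome lengths of a reference
#'
#' @param genome A [ref_genome()].
#' @return Named integer vector.
#' @export
ref_lengths <- function(genome) {
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Reverse complement of a base string
#'
#' @param x Character vector of DNA strings (may contain `N`).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# intervals tibble (chrom, start, end [, ...]) in internal 0-based half-open
# coordinates -> GRanges (1-based closed, as GenomicRanges expects)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# distance from 1-based positions to the nearest interval; 0 when inside,
# NA when the chromosome has no interval. Non-overlapping distances follow
# the bedtools-closest convention (adjacent = 1, i.e. gap + 1).
nearest_interval_distance <- function(chrom, pos1, intervals) {
  q <- GenomicRanges::GRanges(norm_chrom(chrom),
                              IRanges::IRanges(pos1, pos1))
  s <- intervals_to_granges(intervals)
  out <- rep(NA_real_, length(q))
  # chromosomes without any annotated interval legitimately yield NA
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(q, s))
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  inside <- suppressWarnings(IRanges::overlapsAny(q, s))
  ifelse(inside, 0, ifelse(is.na(out), NA, out + 1))
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open, which matches the package's internal convention,
#' so coordinates are taken as-is. A fourth column, when present, is kept as
#' `value` (numeric if possible) or `name`.
#'
#' @param path BED/TSV path.
#' @return Tibble with `chrom`, `start`, `end` and optional extra column.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) {
    extra <- df[[4L]]
    if (is.numeric(extra)) df$value <- extra else df$name <- as.character(extra)
    df <- df[, c("chrom", "start", "end",
                 if (is.numeric(extra)) "value" else "name")]
  }
  df$chrom <- as.character(df$chrom)
  as_tibble(df)
}

#' Write intervals as BED
#'
#' @param df Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally more columns, written in order.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Annotation tracks used by feature extraction
#'
#' Bundles the interval annotations the classifier features need. All interval
#' tibbles use internal 0-based half-open `start`/`end`.
#'
#' @param genes Tibble `chrom,start,end,strand` (`"+"`/`"-"`).
#' @param simple_repeats Tibble `chrom,start,end`.
#' @param replication_timing Tibble `chrom,start,end,value` (higher = earlier
#'   replication, scale free).
#' @param centromeres Tibble `chrom,start,end` (centromere/telomere margins for
#'   coverage exclusion).
#' @param genome A [ref_genome()].
#' @return List of class `annotation_set`.
#' @export
annotation_set <- function(genes, simple_repeats, replication_timing,
                           centromeres, genome) {
  for (df in list(genes, simple_repeats, replication_timing, centromeres)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(df)),
              all(df$end >= df$start))
  }
  stopifnot("strand" %in% names(genes),
            "value" %in% names(replication_timing))
  structure(list(genes = genes, simple_repeats = simple_repeats,
                 replication_timing = replication_timing,
                 centromeres = centromeres, genome = genome),
            class = "annotation_set")
}
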