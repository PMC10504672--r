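#' Precision-recall based probability cutoff
#'
#' Uses only candidates the read-backed phasing analysis labeled confidently:
#' likely true variants (score >= 1000) and likely false positives (score
#' < 1). Over a grid of probability cutoffs from 0 to 1 in steps of 0.01
#' (101 points), a variant is predicted "true" when its artifact probability
#' is below the cutoff; precision and recall of that prediction are computed
#' against the phasing labels and the cutoff where the two curves intersect
#' (smallest `|precision - recall|`, ties broken toward the lower cutoff) is
#' returned together with the precision at that point.
#'
#' @param link_phred Phred scores from [linkage_analysis()] (NA =
#'   uninformative).
#' @param p_artifact Artifact probabilities, same length.
#' @param grid Cutoff grid.
#' @param high Phasing score defining the likely-true group (`>= high`).
#' @param low_label Score defining the likely-false group (`< low_label`).
#' @return List `pr_cutoff` (NA when either labeled group is empty),
#'   `pr_best_value`, `n_true`, `n_false`, `curve` (tibble).
#' @export
pr_based_cutoff <- function(link_phred, p_artifact,
                            grid = seq(0, 1, by = 0.01),
                            high = 1000, low_label = 1) {
  lab <- ifelse(is.na(link_phred), NA_character_,
                ifelse(link_phred >= high, "true",
                       ifelse(link_phred < low_label, "false", NA_character_)))
  use <- !is.na(lab) & !is.na(p_artifact)
  p <- p_artifact[use]
  truth <- lab[use] == "true"
  n_true <- sum(truth); n_false <- sum(!truth)
  if (n_true == 0L || n_false == 0L) {
    return(list(pr_cutoff = NA_real_, pr_best_value = 0,
                n_true = n_true, n_false = n_false, curve = NULL))
  }
  curve <- tibble(cutoff = grid) |>
    mutate(
      tp = vapply(.data$cutoff, function(c) sum(p < c & truth), 1),
      fp = vapply(.data$cutoff, function(c) sum(p < c & !truth), 1),
      fn = n_true - .data$tp,
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = .data$tp / n_true
    )
  ok <- which(!is.na(curve$precision))
  if (!length(ok)) {
    return(list(pr_cutoff = NA_real_, pr_best_value = 0,
                n_true = n_true, n_false = n_false, curve = curve))
  }
  diffs <- abs(curve$precision[ok] - curve$recall[ok])
  best <- ok[which.min(diffs)]   # which.min takes the first = lowest cutoff
  list(pr_cutoff = curve$cutoff[best], pr_best_value = curve$precision[best],
       n_true = n_true, n_false = n_false, curve = curve)
}

#' Cosine-similarity based probability cutoff
#'
#' Takes probability cutoffs from 0.1 to 0.8 in steps of 0.025 (29 groups);
#' for each, the 96-channel spectrum of the substitutions with artifact
#' probability below the cutoff is computed. The 29 x 29 cosine-similarity
#' matrix of these nested spectra is clustered (hierarchical, Euclidean
#' distance between similarity rows, complete linkage) into two clusters; the
#' cluster containing the lowest cutoff holds the mostly-true-positive
#' groups, and its highest cutoff is returned.
#'
#' @param substitutions Tibble of SNVs with `p_artifact` and either `up`/`dn`
#'   context columns or coordinates resolvable in `genome`.
#' @param genome Optional [ref_genome()] for context lookup.
#' @param grid Cutoff grid.
#' @param min_mutations Minimum substitutions below the lowest cutoff for a
#'   stable spectrum; below it the cutoff is absent.
#' @return List `cosine_cutoff` (NA when absent), `cluster` assignment per
#'   grid point, `similarity` matrix.
#' @export
cosine_based_cutoff <- function(substitutions, genome = NULL,
                                grid = seq(0.1, 0.8, by = 0.025),
                                min_mutations = 30) {
  subs <- filter(substitutions, !is.na(.data$p_artifact))
  n_lowest <- sum(subs$p_artifact < grid[1L])
  if (n_lowest < min_mutations) {
    return(list(cosine_cutoff = NA_real_, cluster = NULL, similarity = NULL,
                n_lowest = n_lowest))
  }
  specs <- lapply(grid, function(c) {
    spectrum96(subs[subs$p_artifact < c, , drop = FALSE], genome = genome)
  })
  k <- length(grid)
  sim <- matrix(1, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) sim[i, j] <- cosine_similarity(specs[[i]], specs[[j]])
      if (j < i) sim[i, j] <- sim[j, i]
    }
  }
  cl <- cutree(hclust(dist(sim), method = "complete"), k = 2)
  true_cluster <- cl[1L]   # the lowest-cutoff group anchors the true cluster
  list(cosine_cutoff = max(grid[cl == true_cluster]), cluster = cl,
       similarity = sim, n_lowest = n_lowest)
}

#' Merge the two cutoffs and flag artifacts
#'
#' The final sample-specific cutoff is the mean of the precision-recall and
#' cosine-similarity cutoffs; when the best precision-recall value is below
#' 0.7 (for example because too few variants were confidently labeled by the
#' phasing analysis) or the PR cutoff is absent, the cosine cutoff is used
#' alone. Variants with artifact probability above the final cutoff are
#' flagged `FAIL_RF`.
#'
#' @param pr Result of [pr_based_cutoff()].
#' @param cosine Result of [cosine_based_cutoff()].
#' @param pr_best_min Minimum best PR value for the mean rule.
#' @return List of class `cutoff_result`: `pr_cutoff`, `pr_best_value`,
#'   `cosine_cutoff`, `final_cutoff`, `method_used`.
#' @export
final_cutoff <- function(pr, cosine, pr_best_min = 0.7) {
  pr_ok <- !is.na(pr$pr_cutoff) && pr$pr_best_value >= pr_best_min
  cos_ok <- !is.na(cosine$cosine_cutoff)
  if (!cos_ok && !pr_ok) {
    if (!is.na(pr$pr_cutoff)) {
      # PR cutoff exists but is unreliable and no cosine cutoff is available
      abort("no reliable cutoff could be calibrated; set one manually")
    }
    abort("no cutoff could be calibrated; set one manually")
  }
  out <- list(
    pr_cutoff = pr$pr_cutoff,
    pr_best_value = pr$pr_best_value,
    cosine_cutoff = cosine$cosine_cutoff,
    final_cutoff = if (pr_ok && cos_ok) {
      mean(c(pr$pr_cutoff, cosine$cosine_cutoff))
    } else if (pr_ok) pr$pr_cutoff else cosine$cosine_cutoff,
    method_used = if (pr_ok && cos_ok) "mean"
      else if (pr_ok) "pr_only" else "cosine_only"
  )
  class(out) <- "cutoff_result"
  out
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat("<cutoff_result> final cutoff", round(x$final_cutoff, 4),
      "(", x$method_used, ")\n")
  cat("  PR cutoff:", round(x$pr_cutoff, 4), "best PR value:",
      round(x$pr_best_value, 3), "\n")
  cat("  cosine cutoff:", round(x$cosine_cutoff, 4), "\n")
  invisible(x)
}

#' @export
tidy.cutoff_result <- function(x, ...) {
  tibble(pr_cutoff = x$pr_cutoff, pr_best_value = x$pr_best_value,
         cosine_cutoff = x$cosine_cutoff, final_cutoff = x$final_cutoff,
         method_used = x$method_used)
}

#' Apply a calibrated cutoff to candidates
#'
#' @param variants Variant tibble with `p_artifact` and `flags`.
#' @param cutoff A `cutoff_result` or a numeric cutoff.
#' @return `variants` with `FAIL_RF` added where `p_artifact > cutoff`.
#' @export
apply_cutoff <- function(variants, cutoff) {
  c0 <- if (inherits(cutoff, "cutoff_result")) cutoff$final_cutoff else cutoff
  fail <- which(!is.na(variants$p_artifact) & variants$p_artifact > c0)
  variants$flags[fail] <- lapply(variants$flags[fail],
                                 function(f) union(f, "FAIL_RF"))
  variants
}

#' Write the per-sample cutoff report
#'
#' @param cutoff A `cutoff_result`.
#' @param variants Variant tibble after [apply_cutoff()].
#' @param path TSV destination.
#' @export
write_cutoff_report <- function(cutoff, variants, path) {
  df <- tidy(cutoff)
  df$n_pass <- sum(is_pass(variants))
  df$n_fail <- nrow(variants) - df$n_pass
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
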