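#' Uncorrected pairwise distance between two aligned sequences
#'
#' Proportion of compared columns that differ; columns where either row
#' has a gap (`-`) or an X are skipped (pairwise deletion).
#'
#' @param a,b aligned rows (equal-length strings).
#' @return p-distance in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  comparable <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  if (!any(comparable)) stop("no comparable columns", call. = FALSE)
  mean(ca[comparable] != cb[comparable])
}

#' Pairwise-distance conservation summary for one region
#'
#' Mean and variance of the p-distance over all unordered pairs of the
#' aligned rows, plus a bootstrap standard error obtained by resampling
#' alignment columns (500 replicates, seeded). Higher mean distance
#' means higher diversity (lower conservation).
#'
#' @param aligned character vector of equal-length aligned rows (>= 2).
#' @param region region label recorded on the summary.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed bootstrap seed.
#' @return A `distance_summary`: list with `region`, `mean`, `variance`,
#'   `std_error`, `n_pairs`, `n_seqs`.
#' @export
domain_distance_summary <- function(aligned, region = NA_character_,
                                    n_boot = 500L, seed = 1L) {
  n <- length(aligned)
  if (n < 2L) stop("need at least 2 aligned sequences", call. = FALSE)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  pair_dist_from <- function(mat) {
    pairs <- utils::combn(n, 2)
    apply(pairs, 2, function(p) {
      ca <- mat[p[1], ]; cb <- mat[p[2], ]
      comparable <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
      if (!any(comparable)) return(NA_real_)
      mean(ca[comparable] != cb[comparable])
    })
  }
  d <- pair_dist_from(chars)
  if (anyNA(d)) stop("sequence pair with no comparable columns", call. = FALSE)
  boot_means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      cols <- sample.int(ncol(chars), replace = TRUE)
      mean(pair_dist_from(chars[, cols, drop = FALSE]), na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(region = region, mean = mean(d),
                 variance = if (length(d) > 1L) stats::var(d) else 0,
                 std_error = stats::sd(boot_means),
                 n_pairs = length(d), n_seqs = n),
            class = "distance_summary")
}

#' Region-wise conservation summaries of a labeled dataset
#'
#' Extracts each region's subsequences (which are equal-length, hence
#' trivially aligned, for generator output; user data must be
#' pre-aligned per region) and summarizes their pairwise distances.
#'
#' @param dataset a `labeled_dataset` with annotations.
#' @param regions regions to summarize (default the four domains).
#' @param ... passed to [domain_distance_summary()].
#' @return Named list of `distance_summary` objects.
#' @export
dataset_distance_summaries <- function(dataset,
                                       regions = region_tags(FALSE), ...) {
  out <- lapply(regions, function(region) {
    subs <- vapply(dataset$seqs$id, function(id) {
      i <- match(id, dataset$seqs$id)
      region_subsequence(dataset$seqs$residues[i],
                         dataset$annotations[[id]], region)
    }, character(1))
    subs <- subs[!is.na(subs)]
    domain_distance_summary(unname(subs), region = region, ...)
  })
  stats::setNames(out, regions)
}

#' Relate per-region diversity to per-region model accuracy
#'
#' Pairs each region's mean pairwise distance with the corresponding
#' similarity model's cross-validated accuracy and reports the Spearman
#' rank correlation between the two columns.
#'
#' @param summaries named list of `distance_summary` (keys = regions).
#' @param model_cv_accuracies named numeric (same region keys).
#' @return List with `table` (region, mean_distance, cv_accuracy) and
#'   `rank_correlation`.
#' @export
conservation_vs_accuracy <- function(summaries, model_cv_accuracies) {
  if (!setequal(names(summaries), names(model_cv_accuracies))) {
    stop("region keys of summaries and accuracies differ", call. = FALSE)
  }
  regions <- names(summaries)
  tab <- data.frame(region = regions,
                    mean_distance = vapply(summaries, `[[`, numeric(1),
                                           "mean")[regions],
                    cv_accuracy = unname(model_cv_accuracies[regions]),
                    stringsAsFactors = FALSE)
  rho <- stats::cor(tab$mean_distance, tab$cv_accuracy, method = "spearman")
  list(table = tab, rank_correlation = rho)
}
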