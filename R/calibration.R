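#' Randomize the gene-to-annotation assignment
#'
#' Applies a uniformly random bijection of gene ids to every gene set,
#' breaking any association between annotation and the ranked variable while
#' preserving every term's size, the overlap structure between terms, and
#' the universe. This is the null used for false-positive calibration.
#'
#' @param map an [annotation_map()].
#' @param seed integer seed; the permutation is deterministic given the seed
#'   and the caller's RNG state is left untouched.
#' @return The relabelled [annotation_map()].
#' @export
randomize_assignment <- function(map, seed = NULL) {
  stopifnot(inherits(map, "annotation_map"))
  if (!length(map$universe)) stop_validation("empty universe")
  perm <- with_local_seed(seed, sample(map$universe))
  relabel <- stats::setNames(perm, map$universe)
  assignments <- lapply(map$assignments, function(g) unname(relabel[g]))
  annotation_map(assignments, terms = map$terms, universe = map$universe)
}

#' False-positive scan under randomized annotation
#'
#' Reproduces the randomization experiment used to check that neither the
#' size of a functional category nor the shape of the rate distribution
#' biases the segmentation test: for each replicate the gene-to-annotation
#' assignment is randomized ([randomize_assignment()]) and the full analysis
#' ([gssa()]) rerun; any term called SH or SL at the 5% FDR tier is a false
#' positive. Proportions are accumulated per term-size bin (by default
#' lower edges 20 to 1,400 in steps of 20 genes) and overall.
#'
#' @param ranked a [ranked_list][rank_genes()].
#' @param map an [annotation_map()] filtered against the ranked universe.
#' @param n_replicates number of randomization replicates (>= 1). Full-scale
#'   reruns of the published protocol used 10,000; tests here default to a
#'   few hundred.
#' @param size_bins ordered lower bin edges for term sizes.
#' @param seed integer seed; replicate r uses substream `seed + r`.
#' @param n_partitions,alpha passed to the underlying analysis; a term is
#'   counted as a false positive when any partition reaches `q <= alpha`.
#' @return A `calibration_summary`: list with `bins` (`data.frame` of
#'   `bin_lower`, `n_pairs`, `n_fp`, `fp_proportion`), `overall` (the same
#'   over all pairs), `n_replicates`, `seed` and `variable`.
#' @export
false_positive_scan <- function(ranked, map, n_replicates,
                                size_bins = seq(20L, 1400L, by = 20L),
                                seed = 1L, n_partitions = 30L, alpha = 0.05) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(map, "annotation_map"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop_validation("n_replicates must be >= 1")
  sizes <- lengths(map$assignments)
  bin_of <- findInterval(sizes, size_bins)
  n_bins <- length(size_bins)
  # bin 0 collects terms smaller than the first edge
  pair_counts <- tabulate(bin_of + 1L, nbins = n_bins + 1L) * n_replicates
  fp_counts <- integer(n_bins + 1L)
  for (r in seq_len(n_replicates)) {
    rmap <- randomize_assignment(map, seed = seed + r)
    res <- gssa(ranked, rmap, n_partitions = n_partitions,
                alpha_tiers = c(alpha / 50, alpha))
    fp <- res$calls$verdict != "NS"
    if (any(fp)) {
      fp_bins <- bin_of[match(res$calls$term_id[fp], names(map$assignments))]
      fp_counts <- fp_counts + tabulate(fp_bins + 1L, nbins = n_bins + 1L)
    }
  }
  keep <- pair_counts > 0L
  bins <- data.frame(bin_lower = c(NA_integer_, size_bins)[keep],
                     n_pairs = pair_counts[keep], n_fp = fp_counts[keep])
  bins$fp_proportion <- bins$n_fp / bins$n_pairs
  overall <- list(n_pairs = sum(pair_counts), n_fp = sum(fp_counts),
                  fp_proportion = sum(fp_counts) / sum(pair_counts))
  structure(list(bins = bins, overall = overall, n_replicates = n_replicates,
                 seed = seed, variable = ranked$variable, alpha = alpha),
            class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat("calibration_summary: ", x$n_replicates, " replicates, variable ",
      x$variable, ", alpha ", x$alpha, "\n", sep = "")
  cat("  overall false-positive proportion: ",
      format(x$overall$fp_proportion, digits = 4), " (", x$overall$n_fp,
      " / ", x$overall$n_pairs, " term-replicate pairs)\n", sep = "")
  cat("  max per-bin proportion: ",
      format(max(x$bins$fp_proportion), digits = 4), "\n", sep = "")
  invisible(x)
}
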