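#' Evenly spaced partitions of a ranked list
#'
#' Cut indices for the segmentation test: `cut(k) = floor(k * N / (P + 1))`
#' clamped to `[1, N - 1]` for `k = 1..P`, so the P cuts divide the list into
#' P + 1 nearly equal blocks. At small N several formulas coincide; duplicate
#' cuts are collapsed, keeping the first (lowest) partition index, and the
#' de-duplicated count defines the multiple-testing family size.
#'
#' @param n_genes number of genes N in the ranked list.
#' @param n_partitions number of partitions P (default 30; between 20 and 50
#'   partitions typically give near-optimal sensitivity for genome-scale
#'   lists).
#' @return `data.frame` with columns `partition` (index k) and `cut`
#'   (genes `1..cut` form the upper side A).
#' @examples
#' make_partitions(31, 30)$cut # 1, 2, ..., 30
#' @export
make_partitions <- function(n_genes, n_partitions = 30L) {
  n_genes <- as.integer(n_genes)
  n_partitions <- as.integer(n_partitions)
  if (n_partitions < 1L) stop_config("n_partitions must be >= 1")
  if (n_genes <= n_partitions) {
    stop_validation("need n_genes > n_partitions (got N = ", n_genes,
                    ", P = ", n_partitions, "); use fewer partitions")
  }
  k <- seq_len(n_partitions)
  cuts <- pmin(pmax(floor(k * n_genes / (n_partitions + 1L)), 1L), n_genes - 1L)
  keep <- !duplicated(cuts)
  data.frame(partition = k[keep], cut = as.integer(cuts[keep]))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the minimum-likelihood (point-probability)
#' convention: the sum of hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table. This is the standard two-sided definition in mainstream statistical
#' software, so results are directly cross-checkable. The odds ratio is the
#' sample odds ratio `a*d / (b*c)`, with `0/0 -> 1` and `x/0 -> Inf`.
#'
#' @param a,b,c,d non-negative cell counts; rows are term/non-term genes,
#'   columns the two sides of a partition.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_two_tailed(3, 0, 0, 3) # p = 0.1
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) stop_validation("counts must be non-negative")
  if (sum(counts) == 0) stop_validation("at least one count must be positive")
  num <- a * d
  den <- b * c
  or <- if (den == 0) (if (num == 0) 1 else Inf) else num / den
  list(odds_ratio = or, p_value = .fisher_p(a, b, c, d))
}

# p-value only, no argument checks (hot path)
.fisher_p <- function(a, b, c, d) {
  m <- a + c # term genes
  n <- b + d # non-term genes
  k <- a + b # size of side A
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  logd <- stats::dhyper(lo:hi, m, n, k, log = TRUE)
  # relative tolerance guards ties computed in floating point
  p <- sum(exp(logd[logd <= logd[a - lo + 1L] + log1p(1e-7)]))
  min(p, 1)
}

#' Benjamini-Hochberg q-values for the full test family
#'
#' Step-up false-discovery-rate adjustment applied jointly to all C terms x
#' P partitions of one run: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at
#' 1, where m is the family size. Separate runs (per species/branch and
#' variable) form separate families.
#'
#' @param p_values numeric vector of unadjusted p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / seq(m, 1L) * p_values[o]))[ro]
  q
}

#' Segmentation test: Fisher's exact test at every partition of every term
#'
#' For each functional term and each partition cut, builds the 2x2 table
#' (term/non-term genes on side A versus side B of the cut) and computes the
#' two-tailed Fisher's exact test. Returns the full C x P table of results;
#' q-values are unset until [adjust_fdr()] is applied over the family (the
#' [gssa()] wrapper does both).
#'
#' @param ranked a [ranked_list][rank_genes()].
#' @param map an [annotation_map()] whose assignments are subsets of the
#'   ranked universe (use [filter_terms()] with the ranked universe first).
#' @param n_partitions number of partitions (default 30).
#' @return `data.frame` with columns `term_id`, `partition`, `cut`, `a`,
#'   `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
segmentation_test <- function(ranked, map, n_partitions = 30L) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(map, "annotation_map"))
  if (!length(map$assignments)) stop_validation("annotation map has no terms")
  N <- length(ranked$gene_ids)
  parts <- make_partitions(N, n_partitions)
  rank_of <- stats::setNames(seq_len(N), ranked$gene_ids)
  res <- lapply(names(map$assignments), function(term) {
    genes <- map$assignments[[term]]
    r <- rank_of[genes]
    if (anyNA(r)) {
      stop_validation("term '", term, "' has genes outside the ranked list; ",
                      "filter the map against the ranked universe first")
    }
    r <- sort(unname(r))
    K <- length(r)
    a <- findInterval(parts$cut, r)
    b <- parts$cut - a
    cc <- K - a
    dd <- N - parts$cut - cc
    p <- vapply(seq_along(a), function(i) .fisher_p(a[i], b[i], cc[i], dd[i]),
                numeric(1))
    or <- ifelse(b * cc == 0, ifelse(a * dd == 0, 1, Inf), (a * dd) / (b * cc))
    data.frame(term_id = term, partition = parts$partition, cut = parts$cut,
               a = a, b = b, c = cc, d = dd, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify terms as SH, SL or NS
#'
#' Per-term verdicts from the q-adjusted segmentation results. The best
#' partition is the one with minimal q (ties broken by lowest partition
#' index). A term is SH (significantly high values) when its best partition
#' is significant at the 5% tier and the term is over-represented on side A
#' (observed `a` above its expectation `(a+b)(a+c)/N`), SL when
#' under-represented, NS otherwise. The tier records the strictest FDR level
#' met (0.1% or 5%). The percentage of contributing genes is the fraction of
#' the term's genes lying on the enriched side of the first significant
#' partition (the lowest-index partition with q at or below the 5% tier).
#'
#' @param results `data.frame` from [segmentation_test()] with a `q_value`
#'   column (see [adjust_fdr()]).
#' @param alpha_tiers two FDR levels, strict then loose (default 0.001 and
#'   0.05).
#' @return `data.frame` with one row per term: `term_id`, `n_genes`,
#'   `verdict`, `tier`, `q_min`, `best_partition`, `first_sig_partition`,
#'   `pct_contributing`, and the best partition's counts `a`, `b`, `c`, `d`.
#' @export
classify_terms <- function(results, alpha_tiers = c(0.001, 0.05)) {
  stopifnot(is.data.frame(results), "q_value" %in% names(results))
  alpha_tiers <- sort(alpha_tiers)
  alpha_strict <- alpha_tiers[1]
  alpha_loose <- alpha_tiers[2]
  dt <- data.table::as.data.table(results)
  one_term <- function(sub) {
    N <- sub$a[1] + sub$b[1] + sub$c[1] + sub$d[1]
    n_genes <- sub$a[1] + sub$c[1]
    best <- which(sub$q_value == min(sub$q_value))
    best <- best[which.min(sub$partition[best])]
    qmin <- sub$q_value[best]
    sig <- sub$q_value <= alpha_loose
    if (!any(sig)) {
      return(list(n_genes = n_genes, verdict = "NS", tier = "none",
                  q_min = qmin, best_partition = sub$partition[best],
                  first_sig_partition = NA_integer_,
                  pct_contributing = NA_real_,
                  a = sub$a[best], b = sub$b[best],
                  c = sub$c[best], d = sub$d[best]))
    }
    expected_a <- (sub$a[best] + sub$b[best]) * n_genes / N
    verdict <- if (sub$a[best] > expected_a) "SH"
               else if (sub$a[best] < expected_a) "SL"
               else "NS"
    if (verdict == "NS") {
      # best partition exactly at expectation: no direction, report NS
      return(list(n_genes = n_genes, verdict = "NS", tier = "none",
                  q_min = qmin, best_partition = sub$partition[best],
                  first_sig_partition = NA_integer_,
                  pct_contributing = NA_real_,
                  a = sub$a[best], b = sub$b[best],
                  c = sub$c[best], d = sub$d[best]))
    }
    tier <- if (qmin <= alpha_strict) "FDR_0.1pct" else "FDR_5pct"
    first <- which(sig)[which.min(sub$partition[sig])]
    on_side <- if (verdict == "SH") sub$a[first] else sub$c[first]
    list(n_genes = n_genes, verdict = verdict, tier = tier,
         q_min = qmin, best_partition = sub$partition[best],
         first_sig_partition = sub$partition[first],
         pct_contributing = 100 * on_side / n_genes,
         a = sub$a[best], b = sub$b[best], c = sub$c[best], d = sub$d[best])
  }
  out <- dt[, one_term(.SD), by = "term_id"]
  out <- as.data.frame(out)
  rownames(out) <- NULL
  out
}

#' Run the full gene-set selection analysis
#'
#' The segmentation test end to end on one ranked list: partition the list,
#' apply the two-tailed Fisher's exact test at every (term, partition) pair,
#' correct the whole C x P family by Benjamini-Hochberg, and classify each
#' term as SH/SL/NS at the 0.1% and 5% FDR tiers.
#'
#' @inheritParams segmentation_test
#' @param alpha_tiers two FDR levels, strict then loose (default 0.001, 0.05).
#' @return A `gssa_result`: list with `partitions` (the C x P table including
#'   `q_value`), `calls` (per-term verdicts, see [classify_terms()]) and
#'   `meta` (N, C, family size, settings).
#' @examples
#' rt <- simulate_rates(500, seed = 1)
#' rl <- rank_genes(rt, "omega")
#' map <- random_annotation(rl$gene_ids, sizes = c(20, 50, 100), seed = 2)
#' res <- gssa(rl, map)
#' res$calls
#' @export
gssa <- function(ranked, map, n_partitions = 30L, alpha_tiers = c(0.001, 0.05)) {
  parts <- segmentation_test(ranked, map, n_partitions)
  parts$q_value <- adjust_fdr(parts$p_value)
  calls <- classify_terms(parts, alpha_tiers)
  nm <- map$terms$name[match(calls$term_id, map$terms$term_id)]
  calls <- cbind(calls[, "term_id", drop = FALSE],
                 name = ifelse(is.na(nm), calls$term_id, nm),
                 calls[, setdiff(names(calls), "term_id"), drop = FALSE])
  structure(
    list(partitions = parts, calls = calls,
         meta = list(n_genes = length(ranked$gene_ids),
                     n_terms = length(map$assignments),
                     family_size = nrow(parts),
                     variable = ranked$variable, branch = ranked$branch,
                     n_partitions = n_partitions, alpha_tiers = alpha_tiers)),
    class = "gssa_result"
  )
}

#' @export
print.gssa_result <- function(x, ...) {
  v <- table(factor(x$calls$verdict, levels = c("SH", "SL", "NS")))
  cat("gssa_result: ", x$meta$n_terms, " terms x ", x$meta$n_genes,
      " genes (", x$meta$variable, ", branch ", x$meta$branch, ")\n", sep = "")
  cat("  FDR family: ", x$meta$family_size, " tests (C x P)\n", sep = "")
  cat("  verdicts: SH ", v[["SH"]], ", SL ", v[["SL"]], ", NS ", v[["NS"]],
      "\n", sep = "")
  invisible(x)
}

#' Compare positively-selected-gene counts between SH and SL modules
#'
#' Welch's two-sample t-test on the number of positively selected genes
#' (PSGs) per functional module, comparing modules with significantly high
#' values (SH) against modules with significantly low values (SL). PSG flags
#' are consumed, not computed: they come from upstream branch-site tests.
#'
#' @param calls per-term verdicts (the `calls` component of a
#'   [gssa()] result).
#' @param map the [annotation_map()] the calls were computed on.
#' @param psg_flags named 0/1 vector (or logical) per gene; genes absent
#'   from it count as 0.
#' @return List with `mean_SH`, `mean_SL`, `t_statistic`, `p_value`, `df`,
#'   and `computable`. With fewer than 2 modules in either group the
#'   comparison is reported as not computable (no error).
#' @export
compare_psg_counts <- function(calls, map, psg_flags) {
  stopifnot(inherits(map, "annotation_map"))
  flags <- as.numeric(psg_flags)
  names(flags) <- names(psg_flags)
  count_psg <- function(term) {
    g <- map$assignments[[term]]
    sum(flags[g], na.rm = TRUE)
  }
  sh <- vapply(calls$term_id[calls$verdict == "SH"], count_psg, numeric(1))
  sl <- vapply(calls$term_id[calls$verdict == "SL"], count_psg, numeric(1))
  if (length(sh) < 2L || length(sl) < 2L) {
    return(list(mean_SH = if (length(sh)) mean(sh) else NA_real_,
                mean_SL = if (length(sl)) mean(sl) else NA_real_,
                t_statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                computable = FALSE))
  }
  w <- welch_t(sh, sl)
  c(list(mean_SH = mean(sh), mean_SL = mean(sl)), w, list(computable = TRUE))
}

# Welch two-sample t-test; degenerate zero-variance cases resolved by
# convention (equal means -> t = 0, p = 1; unequal -> infinite t, p = 0)
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(t_statistic = 0, p_value = 1, df = n1 + n2 - 2))
    return(list(t_statistic = sign(m1 - m2) * Inf, p_value = 0,
                df = n1 + n2 - 2))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}
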