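#' Run configuration for the full pipeline
#'
#' Defaults reproduce the published protocol: 30 partitions, a 15-gene
#' minimum per term, and 0.1% / 5% FDR tiers.
#'
#' @param rates path to the rate table TSV (see [read_rate_table()]).
#' @param sets path to a GMT file, or `NULL` if `gene2term` is given.
#' @param gene2term path to a two-column gene-to-term TSV (alternative to
#'   `sets`).
#' @param edges optional child-parent term edge TSV for DAG propagation and
#'   level assignment.
#' @param variable ranking variable: `dS`, `dN`, `omega` or `delta_omega`.
#' @param branch branch id (optional for single-branch tables).
#' @param out output TSV path, or `NULL` to skip writing.
#' @param n_partitions,min_set_size,level_window,fdr_tiers analysis settings.
#' @param filter_rule optional [clade_rules()] name (or `c(dS_max, dN_max)`)
#'   applied as a saturation filter before ranking.
#' @param min_aln_bp drop genes with alignments shorter than this many base
#'   pairs (only applied when the table carries `aln_length_bp`).
#' @param dialect column mapping passed to [read_rate_table()].
#' @param seed integer seed recorded in the config (the deterministic
#'   pipeline itself consumes no randomness).
#' @return A `gssa_config` list.
#' @export
gssa_config <- function(rates, sets = NULL, gene2term = NULL, edges = NULL,
                        variable = c("omega", "dS", "dN", "delta_omega"),
                        branch = NULL, out = NULL,
                        n_partitions = 30L, min_set_size = 15L,
                        level_window = NULL, fdr_tiers = c(0.001, 0.05),
                        filter_rule = NULL, min_aln_bp = 100L,
                        dialect = NULL, seed = 1L) {
  variable <- match.arg(variable)
  if (is.null(sets) && is.null(gene2term)) {
    stop_config("supply `sets` (GMT) or `gene2term`")
  }
  structure(list(rates = rates, sets = sets, gene2term = gene2term,
                 edges = edges, variable = variable, branch = branch,
                 out = out, n_partitions = as.integer(n_partitions),
                 min_set_size = as.integer(min_set_size),
                 level_window = level_window, fdr_tiers = fdr_tiers,
                 filter_rule = filter_rule, min_aln_bp = min_aln_bp,
                 dialect = dialect, seed = as.integer(seed)),
            class = "gssa_config")
}

#' Run the full pipeline from files to a results table
#'
#' Executes the five stages in order - rank the genes, assign annotations,
#' partition the ranked list, Fisher-test every partition, FDR-correct the
#' whole family - logging gene and term counts at every filter, and writes
#' the per-term results TSV. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [gssa_config()].
#' @param quiet suppress progress messages.
#' @return The [gssa()] result, invisibly, with the config attached.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "gssa_config"))
  say <- function(...) if (!quiet) message("gssa: ", ...)

  tab <- read_rate_table(config$rates, dialect = config$dialect)
  say("read ", nrow(tab), " rate records")
  if (!is.null(config$filter_rule)) {
    keep <- saturation_filter(tab$dS, tab$dN, config$filter_rule)
    keep[is.na(keep)] <- TRUE
    tab <- new_rate_table(as.data.frame(tab)[keep, , drop = FALSE])
    say("saturation filter kept ", nrow(tab), " records")
  }
  if (!all(is.na(tab$aln_length_bp))) {
    keep <- length_filter(tab$aln_length_bp, config$min_aln_bp)
    keep[is.na(keep)] <- TRUE
    tab <- new_rate_table(as.data.frame(tab)[keep, , drop = FALSE])
    say("alignment-length filter kept ", nrow(tab), " records")
  }

  ranked <- rank_genes(tab, config$variable, config$branch)
  say("ranked ", length(ranked$gene_ids), " genes by ", config$variable,
      " (", ranked$n_missing, " missing values excluded)")

  map <- if (!is.null(config$sets)) read_gmt(config$sets)
         else read_gene2term(config$gene2term)
  say("read ", length(map$assignments), " terms")
  if (!is.null(config$edges)) {
    edges <- read_term_edges(config$edges)
    map <- propagate_to_ancestors(map, edges)
    map <- set_term_levels(map, assign_levels(edges))
    say("propagated to ancestors: ", length(map$assignments), " terms")
  }
  map <- filter_terms(map, min_size = config$min_set_size,
                      level_window = config$level_window,
                      universe = ranked$gene_ids)
  say("after size/level filtering: ", length(map$assignments), " terms")
  if (!length(map$assignments)) {
    stop_validation("no terms left after filtering")
  }

  res <- gssa(ranked, map, n_partitions = config$n_partitions,
              alpha_tiers = config$fdr_tiers)
  say("FDR family size (C x P): ", res$meta$family_size)
  res$config <- config
  if (!is.null(config$out)) {
    write_gssa_results(res, config$out)
    say("wrote ", config$out)
  }
  invisible(res)
}

#' Write per-term results as TSV
#'
#' @param res a [gssa()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gssa_results <- function(res, path) {
  stopifnot(inherits(res, "gssa_result"))
  cols <- c("term_id", "name", "n_genes", "verdict", "tier", "q_min",
            "best_partition", "first_sig_partition", "pct_contributing",
            "a", "b", "c", "d")
  data.table::fwrite(res$calls[, cols], path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Multi-run summary matrix of verdict codes
#'
#' Collapses several runs (e.g. one per species/branch and variable) into a
#' terms-by-runs character matrix of codes `SH**`, `SH*`, `SL**`, `SL*`,
#' `NS` (`**` = 0.1% FDR tier, `*` = 5%), suitable for heatmap-style
#' rendering. Runs with differing term universes are combined by union, with
#' `NA` marking terms absent from a run.
#'
#' @param runs named list of [gssa()] results, calls data.frames, or paths
#'   to results TSVs written by [write_gssa_results()].
#' @return Character matrix (terms x runs) with a `pct_contributing`
#'   numeric matrix attached as attribute `pct`.
#' @export
summary_matrix <- function(runs) {
  if (!length(runs)) stop_validation("no runs supplied")
  if (is.null(names(runs))) names(runs) <- paste0("run", seq_along(runs))
  calls <- lapply(runs, function(r) {
    if (inherits(r, "gssa_result")) return(r$calls)
    if (is.data.frame(r)) return(r)
    if (is.character(r) && length(r) == 1L) {
      return(data.table::fread(r, sep = "\t", data.table = FALSE))
    }
    stop_validation("each run must be a gssa_result, data.frame or file path")
  })
  code_of <- function(df) {
    ifelse(df$verdict == "NS", "NS",
           paste0(df$verdict, ifelse(df$tier == "FDR_0.1pct", "**", "*")))
  }
  terms <- sort(unique(unlist(lapply(calls, `[[`, "term_id"))))
  codes <- matrix(NA_character_, length(terms), length(calls),
                  dimnames = list(terms, names(runs)))
  pct <- matrix(NA_real_, length(terms), length(calls),
                dimnames = list(terms, names(runs)))
  for (j in seq_along(calls)) {
    i <- match(calls[[j]]$term_id, terms)
    codes[i, j] <- code_of(calls[[j]])
    pct[i, j] <- calls[[j]]$pct_contributing
  }
  attr(codes, "pct") <- pct
  codes
}
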