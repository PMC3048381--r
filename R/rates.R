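#' Read a per-gene evolutionary-rate table
#'
#' Reads a tab-separated table of per-gene, per-branch substitution rates as
#' produced by a free-ratio branch codon model: synonymous (dS) and
#' nonsynonymous (dN) rates, the selective pressure omega = dN/dS, and
#' optionally the omega of the ancestral branch (from which the change in
#' selective pressure, delta_omega = omega - omega_ancestral, is derived).
#'
#' Missing values are encoded as `"NA"` or the empty string. Rows whose
#' numeric fields fail to parse are retained with those fields missing, and
#' the number of such fields is reported via [message()]. omega is derived as
#' dN/dS wherever it is absent and dS > 0; genes with dS = 0 have undefined
#' omega and are left missing (free-ratio estimates with dS = 0 are
#' numerically unstable, so they are excluded from omega and delta_omega
#' rankings rather than treated as infinite).
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @param dialect named character vector mapping canonical column names
#'   (`gene_id`, `branch_id`, `dS`, `dN`, `omega`, `omega_ancestral`,
#'   `aln_length_bp`) to the column names used in the file. Unmapped
#'   canonical names are looked up verbatim.
#' @return A `rate_table`: a `data.frame` with canonical columns and one row
#'   per (gene, branch) record.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tdS\tdN", "g1\t0.10\t0.02", "g2\t0.30\t0.30"), tf)
#' rt <- read_rate_table(tf)
#' rt$omega # derived as dN/dS
#' @seealso [rank_genes()], [saturation_filter()], [length_filter()]
#' @export
read_rate_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_format("rate table file not found: ", path)
  if (file.size(path) == 0L) stop_format("rate table file is empty: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                           na.strings = c("NA", ""), encoding = "UTF-8",
                           data.table = FALSE)
  if (nrow(raw) == 0L) stop_format("rate table has a header but no rows: ", path)

  canonical <- c("gene_id", "branch_id", "dS", "dN", "omega",
                 "omega_ancestral", "aln_length_bp")
  colmap <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), canonical)
    if (length(bad)) stop_config("unknown dialect keys: ", paste(bad, collapse = ", "))
    colmap[names(dialect)] <- dialect
  }
  pick <- function(canon) if (colmap[[canon]] %in% names(raw)) raw[[colmap[[canon]]]] else NULL

  gene_id <- pick("gene_id")
  if (is.null(gene_id)) stop_format("missing mandatory column: ", colmap[["gene_id"]])
  numeric_cols <- c("dS", "dN", "omega", "omega_ancestral", "aln_length_bp")
  present <- numeric_cols[vapply(numeric_cols, function(cn) !is.null(pick(cn)), logical(1))]
  if (!any(c("dS", "dN", "omega") %in% present)) {
    stop_format("rate table must contain at least one of the columns: ",
                paste(colmap[c("dS", "dN", "omega")], collapse = ", "))
  }

  out <- data.frame(gene_id = as.character(gene_id), stringsAsFactors = FALSE)
  out$branch_id <- if (!is.null(pick("branch_id"))) as.character(pick("branch_id")) else "unspecified"
  n_unparseable <- 0L
  for (cn in numeric_cols) {
    v <- pick(cn)
    if (is.null(v)) {
      out[[cn]] <- NA_real_
    } else {
      num <- suppressWarnings(as.numeric(v))
      n_unparseable <- n_unparseable + sum(is.na(num) & !is.na(v))
      out[[cn]] <- num
    }
  }
  if (n_unparseable > 0L) {
    message("read_rate_table: ", n_unparseable,
            " unparseable numeric field(s) recorded as missing")
  }

  dup <- duplicated(out[c("gene_id", "branch_id")])
  if (any(dup)) {
    stop_validation("duplicate (gene_id, branch_id) records, e.g. (",
                    out$gene_id[dup][1], ", ", out$branch_id[dup][1], ")")
  }
  if (any(out$dS < 0, na.rm = TRUE) || any(out$dN < 0, na.rm = TRUE)) {
    stop_validation("negative dS or dN values are not allowed")
  }

  derive <- is.na(out$omega) & !is.na(out$dS) & !is.na(out$dN) & out$dS > 0
  out$omega[derive] <- out$dN[derive] / out$dS[derive]
  zero_ds <- !is.na(out$dS) & out$dS == 0 & is.na(out$omega)
  if (any(zero_ds)) {
    message("read_rate_table: ", sum(zero_ds),
            " record(s) with dS = 0 left with omega missing")
  }
  out$delta_omega <- out$omega - out$omega_ancestral
  new_rate_table(out)
}

new_rate_table <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("rate_table", "data.frame"))
}

#' @export
print.rate_table <- function(x, ...) {
  cat("rate_table: ", nrow(x), " records, ",
      length(unique(x$gene_id)), " genes, ",
      length(unique(x$branch_id)), " branch(es)\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Change in selective pressure between ancestor and descendant
#'
#' The difference in dN/dS between a descendant branch and its ancestral
#' branch. A positive value indicates relaxation (or an increase) of selective
#' pressure relative to the ancestor; a negative value indicates increased
#' constraint.
#'
#' @param omega_descendant,omega_ancestral dN/dS ratios (vectorised).
#' @return `omega_descendant - omega_ancestral`; `NA` where either input is
#'   missing (such genes are excluded from delta-omega rankings).
#' @examples
#' compute_delta_omega(0.30, 0.10) # relaxation: +0.2
#' @export
compute_delta_omega <- function(omega_descendant, omega_ancestral) {
  ifelse(is.na(omega_descendant) | is.na(omega_ancestral),
         NA_real_, omega_descendant - omega_ancestral)
}

#' Saturation filter rule sets for ortholog comparisons
#'
#' Named exclusive upper bounds on dS and dN beyond which ortholog
#' comparisons are considered saturated and excluded. The three shipped rule
#' sets correspond to primate-only, rodent-only and primate-versus-rodent
#' comparisons; they are configuration data and users may supply their own.
#'
#' @return A named list of `c(dS_max, dN_max)` pairs (substitutions/site).
#' @export
clade_rules <- function() {
  list(
    primates          = c(dS_max = 0.064, dN_max = 0.030),
    rodents           = c(dS_max = 0.256, dN_max = 0.122),
    primates_rodents  = c(dS_max = 1.000, dN_max = 0.500)
  )
}

#' Exclude saturated rate estimates
#'
#' A record is excluded when its dS or its dN reaches the rule's bound
#' (either bound sufficing - conservative saturation screening).
#'
#' @param dS,dN numeric vectors of rates (substitutions/site).
#' @param rule a rule-set name from [clade_rules()], or a numeric vector
#'   with elements `dS_max` and `dN_max`.
#' @return Logical vector: `TRUE` = keep, `FALSE` = exclude.
#' @examples
#' saturation_filter(0.064, 0.001, "primates") # FALSE: dS at the bound
#' @export
saturation_filter <- function(dS, dN, rule) {
  if (is.character(rule)) {
    rules <- clade_rules()
    if (!rule %in% names(rules)) {
      stop_config("unknown clade rule '", rule, "'; available: ",
                  paste(names(rules), collapse = ", "))
    }
    rule <- rules[[rule]]
  }
  if (!all(c("dS_max", "dN_max") %in% names(rule))) {
    stop_config("a saturation rule needs named elements dS_max and dN_max")
  }
  !(dS >= rule[["dS_max"]] | dN >= rule[["dN_max"]])
}

#' Exclude short alignments
#'
#' @param aln_length_bp integer alignment lengths in base pairs.
#' @param min_bp minimum length retained (default 100 bp).
#' @return Logical vector: `TRUE` = keep (length >= `min_bp`).
#' @export
length_filter <- function(aln_length_bp, min_bp = 100L) {
  if (any(aln_length_bp < 0, na.rm = TRUE)) {
    stop_validation("negative alignment length")
  }
  aln_length_bp >= min_bp
}

#' Rank the genes of a genome by an evolutionary variable
#'
#' Produces the ranked list that the segmentation test operates on: genes
#' sorted by the chosen variable in decreasing order, so the "top" of the
#' list holds the highest values and an SH verdict always means enrichment at
#' the head. Genes with a missing value are excluded (their count is
#' reported); ties are broken by a stable sort on gene id so rankings are
#' reproducible across platforms.
#'
#' @param table a [rate_table][read_rate_table].
#' @param variable one of `"dS"`, `"dN"`, `"omega"`, `"delta_omega"`.
#' @param branch branch id to rank; may be omitted when the table holds a
#'   single branch.
#' @return A `ranked_list`: list with `variable`, `branch`, `gene_ids`
#'   (highest value first), `values`, `tie_policy` and `n_missing`.
#' @examples
#' rt <- simulate_rates(200, seed = 1)
#' rl <- rank_genes(rt, "omega")
#' head(rl$gene_ids)
#' @export
rank_genes <- function(table, variable = c("dS", "dN", "omega", "delta_omega"),
                       branch = NULL) {
  variable <- match.arg(variable)
  df <- as.data.frame(table)
  if (is.null(branch)) {
    branches <- unique(df$branch_id)
    if (length(branches) > 1L) {
      stop_validation("table has ", length(branches),
                      " branches; supply `branch`")
    }
    branch <- branches[1]
  }
  df <- df[df$branch_id == branch, , drop = FALSE]
  if (nrow(df) == 0L) stop_validation("no records for branch '", branch, "'")
  vals <- df[[variable]]
  ok <- !is.na(vals) & is.finite(vals)
  n_missing <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  vals <- vals[ok]
  if (nrow(df) < 2L) {
    stop_validation("fewer than 2 genes with a value for ", variable,
                    " on branch '", branch, "'")
  }
  ord <- order(-vals, df$gene_id, method = "radix")
  structure(
    list(variable = variable, branch = branch,
         gene_ids = df$gene_id[ord], values = vals[ord],
         tie_policy = "descending value, lexicographic gene_id tie-break",
         n_missing = n_missing),
    class = "ranked_list"
  )
}

#' @export
print.ranked_list <- function(x, ...) {
  n <- length(x$gene_ids)
  cat("ranked_list: ", n, " genes by ", x$variable,
      " (branch ", x$branch, "), ", x$n_missing, " missing\n", sep = "")
  cat("  top:    ", paste(utils::head(x$gene_ids, 3), collapse = ", "), "\n")
  cat("  bottom: ", paste(rev(utils::head(rev(x$gene_ids), 3)), collapse = ", "), "\n")
  invisible(x)
}
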