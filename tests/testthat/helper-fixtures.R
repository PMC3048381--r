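# Shared fixture builders: everything is generated in code at test time.

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# minimal rate table TSV: gene, dS, dN (+ extra columns pasted verbatim)
rates_fixture <- function(genes, dS, dN, extra_header = NULL, extra = NULL) {
  header <- paste(c("gene_id", "dS", "dN", extra_header), collapse = "\t")
  rows <- paste(genes, dS, dN, sep = "\t")
  if (!is.null(extra)) rows <- paste(rows, extra, sep = "\t")
  write_tsv_fixture(c(header, rows))
}

# a ranked_list built directly (bypassing file I/O) from named values
ranked_fixture <- function(values, variable = "omega", branch = "focal") {
  ord <- order(-values, names(values), method = "radix")
  structure(
    list(variable = variable, branch = branch,
         gene_ids = names(values)[ord], values = unname(values[ord]),
         tie_policy = "descending value, lexicographic gene_id tie-break",
         n_missing = 0L),
    class = "ranked_list"
  )
}

# a ranked list of n genes with distinct values, highest first
ranked_n <- function(n, variable = "omega") {
  ranked_fixture(stats::setNames(seq(n, 1) / n, sprintf("g%05d", seq_len(n))),
                 variable = variable)
}

# annotation map placing one term at given ranks of a ranked list
map_at_ranks <- function(ranked, ranks, term_id = "T1") {
  annotation_map(stats::setNames(list(ranked$gene_ids[ranks]), term_id),
                 universe = ranked$gene_ids)
}

# brute-force BH step-up: for each p_i, min over j with rank >= rank(i)
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * sp[i:m] / seq(i, m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
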