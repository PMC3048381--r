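#' Construct an annotation map
#'
#' The container tying functional terms (GO/KEGG-style gene sets) to member
#' genes. Gene sets are stored sorted and deduplicated so identical maps
#' compare identical regardless of input order.
#'
#' @param assignments named list: term_id -> character vector of gene ids.
#' @param terms optional `data.frame` with columns `term_id`, `name`,
#'   `source` (`"GO"`, `"KEGG"` or `"custom"`) and `level` (integer DAG
#'   depth, `NA` for flat sources). Missing rows are filled with defaults.
#' @param universe optional gene universe; defaults to the union of all
#'   assigned genes. Every assigned gene must belong to it.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(assignments, terms = NULL, universe = NULL) {
  if (is.null(names(assignments)) || anyNA(names(assignments)) ||
      any(names(assignments) == "")) {
    stop_validation("assignments must be a named list of gene-id vectors")
  }
  if (anyDuplicated(names(assignments))) {
    stop_validation("duplicate term_id in assignments")
  }
  assignments <- lapply(assignments, function(g) sort(unique(as.character(g))))
  all_genes <- sort(unique(unlist(assignments, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_genes
  } else {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(all_genes, universe)
    if (length(stray)) {
      stop_validation("assigned gene(s) outside the universe, e.g. ", stray[1])
    }
  }
  term_ids <- names(assignments)
  if (is.null(terms)) {
    terms <- data.frame(term_id = term_ids, name = term_ids,
                        source = "custom", level = NA_integer_,
                        stringsAsFactors = FALSE)
  } else {
    terms <- as.data.frame(terms)
    if (!"term_id" %in% names(terms)) stop_validation("terms needs a term_id column")
    if (!"name" %in% names(terms)) terms$name <- terms$term_id
    if (!"source" %in% names(terms)) terms$source <- "custom"
    if (!"level" %in% names(terms)) terms$level <- NA_integer_
    terms <- terms[match(term_ids, terms$term_id), c("term_id", "name", "source", "level")]
    terms$term_id <- term_ids
    terms$name[is.na(terms$name)] <- term_ids[is.na(terms$name)]
    terms$source[is.na(terms$source)] <- "custom"
    if (any(terms$level < 1, na.rm = TRUE)) stop_validation("term levels must be >= 1")
    rownames(terms) <- NULL
  }
  structure(list(terms = terms, assignments = assignments, universe = universe),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  sizes <- lengths(x$assignments)
  cat("annotation_map: ", length(x$assignments), " terms, ",
      length(x$universe), " genes in universe\n", sep = "")
  if (length(sizes)) {
    cat("  term sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated. Duplicate genes within a line are collapsed; the universe
#' is the union of all listed genes.
#'
#' @param path path to a GMT file.
#' @param source annotation source label recorded on every term.
#' @return An [annotation_map()].
#' @export
read_gmt <- function(path, source = "custom") {
  if (!file.exists(path)) stop_format("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_format("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop_format("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  }
  term_ids <- vapply(fields, `[[`, character(1), 1L)
  names_ <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  if (anyDuplicated(term_ids)) {
    stop_format("duplicate term id in GMT: ", term_ids[duplicated(term_ids)][1])
  }
  annotation_map(
    stats::setNames(genes, term_ids),
    terms = data.frame(term_id = term_ids, name = names_, source = source,
                       level = NA_integer_, stringsAsFactors = FALSE)
  )
}

#' Write gene sets in GMT format
#'
#' @param map an [annotation_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(map, path) {
  stopifnot(inherits(map, "annotation_map"))
  nm <- map$terms$name[match(names(map$assignments), map$terms$term_id)]
  lines <- mapply(function(id, name, genes) {
    paste(c(id, name, genes), collapse = "\t")
  }, names(map$assignments), nm, map$assignments, USE.NAMES = FALSE)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a two-column gene-to-term table
#'
#' An alternative to GMT input: a headerless (or headered) TSV whose first
#' column is a gene id and second a term id.
#'
#' @param path path to the TSV.
#' @param header does the file carry a header row?
#' @param source annotation source label.
#' @return An [annotation_map()].
#' @export
read_gene2term <- function(path, header = FALSE, source = "custom") {
  df <- data.table::fread(path, sep = "\t", header = header,
                          colClasses = "character", data.table = FALSE)
  if (ncol(df) < 2L) stop_format("gene-to-term table needs two columns")
  assignments <- split(df[[1]], df[[2]])
  annotation_map(assignments,
                 terms = data.frame(term_id = names(assignments),
                                    name = names(assignments),
                                    source = source, level = NA_integer_,
                                    stringsAsFactors = FALSE))
}

#' Read a child-to-parent term edge list
#'
#' @param path TSV whose first column is the child term id and second the
#'   parent term id.
#' @param header does the file carry a header row?
#' @return `data.frame` with columns `child`, `parent`.
#' @export
read_term_edges <- function(path, header = FALSE) {
  df <- data.table::fread(path, sep = "\t", header = header,
                          colClasses = "character", data.table = FALSE)
  if (ncol(df) < 2L) stop_format("edge table needs two columns (child, parent)")
  stats::setNames(df[1:2], c("child", "parent"))
}

# ancestors of every node of a child->parent DAG, as a named list;
# errors on a directed cycle naming one member
dag_ancestors <- function(edges) {
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  nodes <- unique(c(child, parent))
  parents_of <- split(parent, factor(child, levels = nodes))
  anc <- vector("list", length(nodes))
  names(anc) <- nodes
  state <- stats::setNames(integer(length(nodes)), nodes) # 0 new, 1 visiting, 2 done
  visit <- function(n) {
    if (state[[n]] == 2L) return(anc[[n]])
    if (state[[n]] == 1L) stop_validation("cycle detected in term DAG at '", n, "'")
    state[[n]] <<- 1L
    ps <- parents_of[[n]]
    acc <- character(0)
    for (p in ps) acc <- c(acc, p, visit(p))
    acc <- unique(acc)
    anc[[n]] <<- acc
    state[[n]] <<- 2L
    acc
  }
  for (n in nodes) visit(n)
  anc
}

#' Propagate annotations to ancestor terms
#'
#' Extends the annotation at missing parental nodes: every gene annotated to
#' a term becomes annotated to all of that term's ancestors in the
#' child-to-parent DAG. No annotation is removed, and the operation is
#' idempotent. Ancestor terms absent from the input map are created (source
#' inherited from the map's majority source).
#'
#' @param map an [annotation_map()].
#' @param edges `data.frame` of `child`, `parent` term-id pairs (see
#'   [read_term_edges()]); must be acyclic.
#' @return The propagated [annotation_map()].
#' @export
propagate_to_ancestors <- function(map, edges) {
  stopifnot(inherits(map, "annotation_map"))
  anc <- dag_ancestors(edges)
  assignments <- map$assignments
  for (t in names(map$assignments)) {
    for (p in anc[[t]] %||% character(0)) {
      assignments[[p]] <- c(assignments[[p]], map$assignments[[t]])
    }
  }
  src <- names(which.max(table(map$terms$source)))
  new_ids <- setdiff(names(assignments), map$terms$term_id)
  terms <- rbind(map$terms,
                 if (length(new_ids))
                   data.frame(term_id = new_ids, name = new_ids,
                              source = src %||% "custom", level = NA_integer_,
                              stringsAsFactors = FALSE))
  annotation_map(assignments, terms = terms, universe = map$universe)
}

#' Assign DAG levels to terms
#'
#' Depth of each term in the child-to-parent DAG under the shortest-path
#' convention: roots are level 1 and `level(t) = 1 + min(level(parents))`.
#' This matches the common GO-level convention used to apply level windows
#' such as 2-8 (mammal analyses) or 2-12 (insect analyses).
#'
#' @param edges `data.frame` of `child`, `parent` pairs.
#' @param roots root term ids; defaults to all terms without a parent.
#' @return Named integer vector of levels.
#' @export
assign_levels <- function(edges, roots = NULL) {
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  nodes <- unique(c(child, parent, roots))
  if (is.null(roots)) roots <- setdiff(nodes, child)
  if (!length(roots)) stop_validation("no root terms (every term has a parent)")
  children_of <- split(child, factor(parent, levels = nodes))
  level <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  level[roots] <- 1L
  frontier <- roots
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- nxt[is.na(level[nxt])]
    level[nxt] <- d
    frontier <- nxt
  }
  orphan <- names(level)[is.na(level)]
  if (length(orphan)) {
    stop_validation("term(s) not reaching any root, e.g. '", orphan[1], "'")
  }
  level
}

#' Filter terms by size and level window
#'
#' Removes terms with fewer than `min_size` genes and, for DAG-derived
#' sources, terms outside the level window. When `universe` is supplied
#' (normally the ranked gene universe of the current run), term sizes are
#' counted against it and assignments are restricted to it, since only genes
#' present in the ranked list can contribute to the test.
#'
#' @param map an [annotation_map()].
#' @param min_size minimum genes per term (default 15).
#' @param level_window `c(lo, hi)` inclusive window of term levels, or `NULL`
#'   for no level filtering. Terms with a missing level (flat sources such as
#'   pathway catalogues) are exempt.
#' @param universe optional gene universe to intersect with.
#' @return The filtered [annotation_map()].
#' @export
filter_terms <- function(map, min_size = 15L, level_window = NULL, universe = NULL) {
  stopifnot(inherits(map, "annotation_map"))
  if (min_size < 1L) stop_config("min_size must be >= 1")
  assignments <- map$assignments
  if (!is.null(universe)) {
    universe <- sort(unique(as.character(universe)))
    assignments <- lapply(assignments, intersect, universe)
  } else {
    universe <- map$universe
  }
  keep <- lengths(assignments) >= min_size
  if (!is.null(level_window)) {
    if (length(level_window) != 2L || level_window[1] > level_window[2]) {
      stop_config("level_window must be c(lo, hi) with lo <= hi")
    }
    lv <- map$terms$level[match(names(assignments), map$terms$term_id)]
    in_window <- is.na(lv) | (lv >= level_window[1] & lv <= level_window[2])
    keep <- keep & in_window
  }
  annotation_map(assignments[keep],
                 terms = map$terms[map$terms$term_id %in% names(assignments)[keep], ,
                                   drop = FALSE],
                 universe = universe)
}

#' Attach levels to an annotation map's terms
#'
#' @param map an [annotation_map()].
#' @param levels named integer vector as returned by [assign_levels()];
#'   terms absent from it keep a missing level.
#' @return The map with updated term levels.
#' @export
set_term_levels <- function(map, levels) {
  stopifnot(inherits(map, "annotation_map"))
  idx <- match(map$terms$term_id, names(levels))
  map$terms$level <- ifelse(is.na(idx), NA_integer_, as.integer(levels[idx]))
  map
}
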