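test_that("read_gmt parses, deduplicates and builds the universe", {
  tf <- write_tsv_fixture(c("T1\tset one\tg1\tg2\tg3", "T2\tset two\tg2\tg4"))
  map <- read_gmt(tf)
  expect_length(map$assignments, 2L)
  expect_length(map$universe, 4L)
  expect_equal(map$assignments$T1, c("g1", "g2", "g3"))

  dup <- write_tsv_fixture("T1\td\tg1\tg1")
  expect_equal(lengths(read_gmt(dup)$assignments)[["T1"]], 1L)

  short <- write_tsv_fixture(c("T1\td\tg1", "T2\tonlydesc"))
  expect_error(read_gmt(short), "line 2", class = "gssa_format_error")
})

test_that("GMT round-trip preserves a random 100-term map", {
  set.seed(42)
  universe <- sprintf("g%04d", 1:500)
  sizes <- sample(3:40, 100, replace = TRUE)
  map <- random_annotation(universe, sizes, seed = 9)
  tf <- tempfile(fileext = ".gmt")
  write_gmt(map, tf)
  back <- read_gmt(tf)
  expect_equal(back$assignments, map$assignments)
  # GMT carries only assigned genes, so the round-trip universe is their union
  expect_equal(back$universe, sort(unique(unlist(map$assignments))))
})

test_that("read_gene2term builds the same map as the equivalent GMT", {
  tf <- write_tsv_fixture(c("g1\tT1", "g2\tT1", "g2\tT2", "g4\tT2"))
  map <- read_gene2term(tf)
  expect_equal(map$assignments, list(T1 = c("g1", "g2"), T2 = c("g2", "g4")))
})

test_that("propagation covers chains and diamonds", {
  # chain c -> b -> a
  edges <- data.frame(child = c("c", "b"), parent = c("b", "a"))
  map <- annotation_map(list(c = "g1"), universe = "g1")
  out <- propagate_to_ancestors(map, edges)
  expect_setequal(names(out$assignments)[lengths(out$assignments) > 0],
                  c("a", "b", "c"))
  expect_equal(out$assignments$a, "g1")

  # diamond: d -> {b, c} -> a
  edges <- data.frame(child = c("b", "c", "d", "d"),
                      parent = c("a", "a", "b", "c"))
  map <- annotation_map(list(d = "g1"), universe = "g1")
  out <- propagate_to_ancestors(map, edges)
  expect_equal(sum(vapply(out$assignments, function(g) "g1" %in% g, logical(1))), 4L)
})

test_that("propagation matches brute-force reachability on a random DAG", {
  set.seed(13)
  n_terms <- 50L
  terms <- sprintf("t%02d", seq_len(n_terms))
  # random DAG: edges only from later to earlier index (child -> parent)
  pairs <- t(combn(n_terms, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.06, , drop = FALSE]
  edges <- data.frame(child = terms[pick[, 2]], parent = terms[pick[, 1]])
  genes <- sprintf("g%03d", 1:80)
  assignments <- split(sample(genes, 200, replace = TRUE),
                       sample(terms, 200, replace = TRUE))
  assignments <- lapply(assignments, unique)
  map <- annotation_map(assignments, universe = genes)
  out <- propagate_to_ancestors(map, edges)

  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     vertices = terms)
  for (t in terms) {
    descendants <- names(igraph::subcomponent(g, t, mode = "in")) # t + below
    expected <- sort(unique(unlist(
      map$assignments[intersect(descendants, names(map$assignments))])))
    got <- out$assignments[[t]]
    if (is.null(got)) got <- character(0)
    expect_equal(got, expected, info = t)
  }
})

test_that("propagation is idempotent and monotone, and rejects cycles", {
  edges <- data.frame(child = c("c", "b"), parent = c("b", "a"))
  map <- annotation_map(list(c = c("g1", "g2"), b = "g3"),
                        universe = c("g1", "g2", "g3"))
  once <- propagate_to_ancestors(map, edges)
  twice <- propagate_to_ancestors(once, edges)
  expect_equal(once$assignments, twice$assignments)
  for (t in names(map$assignments)) {
    expect_true(all(map$assignments[[t]] %in% once$assignments[[t]]))
  }
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(propagate_to_ancestors(map, cyc), "cycle",
               class = "gssa_validation_error")
})

test_that("assign_levels uses shortest-path depth with roots at level 1", {
  chain <- data.frame(child = c("b", "c"), parent = c("a", "b"))
  expect_equal(assign_levels(chain), c(b = 2L, c = 3L, a = 1L)[c("b", "c", "a")])

  # d has parents at levels 2 and 3 -> level(d) = 1 + min = 3
  edges <- data.frame(child = c("b", "c2", "c3", "d", "d"),
                      parent = c("a", "a", "c2", "b", "c3"))
  lv <- assign_levels(edges)
  expect_equal(lv[["a"]], 1L)
  expect_equal(lv[["b"]], 2L)
  expect_equal(lv[["c3"]], 3L)
  expect_equal(lv[["d"]], 3L)

  expect_equal(assign_levels(data.frame(child = character(0),
                                        parent = character(0)),
                             roots = "solo"),
               c(solo = 1L))

  orphan <- data.frame(child = "x", parent = "y")
  expect_error(assign_levels(orphan, roots = "a"),
               class = "gssa_validation_error")
})

test_that("filter_terms enforces the 15-gene minimum and the level window", {
  genes <- sprintf("g%03d", 1:100)
  map <- annotation_map(
    list(small = genes[1:14], exact = genes[1:15], root = genes[1:30],
         flat = genes[1:20]),
    terms = data.frame(term_id = c("small", "exact", "root", "flat"),
                       source = c("GO", "GO", "GO", "KEGG"),
                       level = c(4L, 4L, 1L, NA_integer_)),
    universe = genes
  )
  out <- filter_terms(map, min_size = 15, level_window = c(2, 8))
  expect_setequal(names(out$assignments), c("exact", "flat")) # 14-gene and
  # level-1 terms removed; flat source exempt from the level rule

  # sizes are counted against the supplied (ranked) universe
  out2 <- filter_terms(map, min_size = 15, universe = genes[1:14])
  expect_length(out2$assignments, 0L)

  expect_error(filter_terms(map, level_window = c(8, 2)),
               class = "gssa_config_error")
  expect_error(filter_terms(map, min_size = 0), class = "gssa_config_error")
})

test_that("filter_terms output is a sub-map and re-filtering is a no-op", {
  set.seed(5)
  universe <- sprintf("g%04d", 1:300)
  map <- random_annotation(universe, sample(5:40, 30, replace = TRUE), seed = 6)
  out <- filter_terms(map, min_size = 15)
  expect_true(all(names(out$assignments) %in% names(map$assignments)))
  for (t in names(out$assignments)) {
    expect_equal(out$assignments[[t]], map$assignments[[t]])
  }
  again <- filter_terms(out, min_size = 15)
  expect_equal(again$assignments, out$assignments)
})
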