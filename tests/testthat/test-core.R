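test_that("make_partitions places floor(k*N/(P+1)) cuts", {
  expect_equal(make_partitions(31, 30)$cut, 1:30)
  expect_equal(make_partitions(62, 30)$cut, seq(2L, 60L, by = 2L))
  p300 <- make_partitions(300, 30)
  expect_equal(nrow(p300), 30L)
  expect_equal(p300$cut[1], 9L)
  expect_equal(p300$cut[30], 290L)
  expect_true(all(diff(p300$cut) > 0))
  expect_error(make_partitions(30, 30), class = "gssa_validation_error")
  expect_error(make_partitions(10, 30), "fewer partitions")
})

test_that("cuts are strictly increasing within [1, N-1] whenever N > P", {
  # with N >= P+1 the floor spacing N/(P+1) >= 1, so cuts never collapse;
  # the de-duplication contract is defensive
  for (P in c(5L, 20L, 30L, 50L)) {
    for (N in c(P + 1L, P + 2L, 2L * P + 1L, 997L)) {
      p <- make_partitions(N, P)
      expect_equal(p$cut, unique(pmax(1, pmin(floor(1:P * N / (P + 1)), N - 1))))
      expect_true(all(diff(p$cut) > 0))
      expect_gte(p$cut[1], 1L)
      expect_lte(p$cut[nrow(p)], N - 1L)
      expect_equal(p$partition, seq_len(nrow(p)))
    }
  }
})

test_that("fisher_two_tailed matches hand-enumerated tables", {
  r <- fisher_two_tailed(5, 5, 5, 5)
  expect_equal(r$p_value, 1)
  expect_equal(r$odds_ratio, 1)

  # margins (3,3|3,3): P(a=0)=P(a=3)=1/20, two-sided sum = 0.1
  r <- fisher_two_tailed(3, 0, 0, 3)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$odds_ratio, Inf)

  expect_equal(fisher_two_tailed(0, 0, 0, 10)$p_value, 1) # degenerate margin
  expect_equal(fisher_two_tailed(0, 0, 0, 10)$odds_ratio, 1)
  expect_error(fisher_two_tailed(-1, 0, 0, 1), class = "gssa_validation_error")
})

test_that("fisher_two_tailed equals fisher.test on random tables", {
  set.seed(19)
  for (i in 1:300) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    ours <- fisher_two_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours$p_value, ref, tolerance = 1e-12)
  }
})

test_that("adjust_fdr reproduces hand-computed BH q-values", {
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(0.5, 17)), rep(0.5, 17))
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "gssa_validation_error")
})

test_that("adjust_fdr matches the naive quadratic oracle and p.adjust", {
  set.seed(23)
  for (i in 1:25) {
    m <- sample(1:400, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- adjust_fdr(p)
    expect_equal(q, naive_bh(p), tolerance = 1e-14)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= 0 & q <= 1))
    # order-preserving
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("segmentation_test returns exactly C x P valid tables", {
  rl <- ranked_n(1000)
  map <- random_annotation(rl$gene_ids, sizes = rep(c(20, 50), 25), seed = 4)
  res <- segmentation_test(rl, map)
  expect_equal(nrow(res), 50L * 30L)
  expect_true(all(res$a + res$b == res$cut))
  expect_true(all(res$c + res$d == 1000L - res$cut))
  sizes <- lengths(map$assignments)
  expect_true(all(res$a + res$c == sizes[res$term_id]))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("a term spanning the whole universe always gives p = 1", {
  rl <- ranked_n(200)
  map <- map_at_ranks(rl, 1:200)
  res <- segmentation_test(rl, map)
  expect_true(all(res$p_value == 1))
})

test_that("a term packed at the top is maximally significant near its size", {
  rl <- ranked_n(300)
  map <- map_at_ranks(rl, 1:15)
  res <- segmentation_test(rl, map)
  expect_equal(res$a[res$cut == 9], 9L)
  # independent oracle for every one of the 30 tables
  ref <- vapply(seq_len(nrow(res)), function(i) {
    stats::fisher.test(matrix(c(res$a[i], res$b[i], res$c[i], res$d[i]), 2,
                              byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(res$p_value, ref, tolerance = 1e-12)
  # minimal p at the first cut that contains the whole term (cut 19)
  expect_equal(res$cut[which.min(res$p_value)], 19L)
})

test_that("segmentation_test rejects unfiltered maps and empty maps", {
  rl <- ranked_n(100)
  stray <- annotation_map(list(T1 = c(rl$gene_ids[1:5], "ghost")))
  expect_error(segmentation_test(rl, stray), "outside the ranked",
               class = "gssa_validation_error")
})

test_that("classify_terms calls planted extremes and scattered terms correctly", {
  rl <- ranked_n(2000)
  map <- annotation_map(
    list(top = rl$gene_ids[1:20],
         scattered = rl$gene_ids[seq(10, 2000, by = 100)]),
    universe = rl$gene_ids
  )
  res <- gssa(rl, map)
  calls <- res$calls
  top <- calls[calls$term_id == "top", ]
  expect_equal(top$verdict, "SH")
  expect_equal(top$tier, "FDR_0.1pct")
  expect_gte(top$pct_contributing, 95)
  expect_equal(calls$verdict[calls$term_id == "scattered"], "NS")
  expect_true(is.na(calls$first_sig_partition[calls$term_id == "scattered"]))

  bottom_map <- annotation_map(list(bottom = rl$gene_ids[1981:2000]),
                               universe = rl$gene_ids)
  expect_equal(gssa(rl, bottom_map)$calls$verdict, "SL")
})

test_that("reversing the ranking swaps SH and SL with identical q-values", {
  # N a multiple of P+1 makes the cut grid symmetric under reversal
  n <- 31 * 100
  set.seed(77)
  vals <- stats::setNames(rnorm(n), sprintf("g%05d", 1:n))
  rl <- ranked_fixture(vals)
  rev_rl <- ranked_fixture(-vals)
  map <- annotation_map(
    list(hi = rl$gene_ids[1:30], lo = rl$gene_ids[(n - 29):n],
         mid = rl$gene_ids[seq(1, n, length.out = 40)]),
    universe = rl$gene_ids
  )
  fwd <- gssa(rl, map)
  bwd <- gssa(rev_rl, map)
  swap <- c(SH = "SL", SL = "SH", NS = "NS")
  expect_equal(unname(swap[fwd$calls$verdict]), bwd$calls$verdict)
  expect_equal(fwd$calls$q_min, bwd$calls$q_min)
  for (t in names(map$assignments)) {
    expect_equal(sort(fwd$partitions$q_value[fwd$partitions$term_id == t]),
                 sort(bwd$partitions$q_value[bwd$partitions$term_id == t]))
  }
})

test_that("consistent gene relabelling leaves all calls unchanged", {
  rl <- ranked_n(500)
  map <- random_annotation(rl$gene_ids, sizes = c(20, 40, 60), seed = 8)
  res1 <- gssa(rl, map)
  relabel <- stats::setNames(sprintf("x%05d", 1:500), rl$gene_ids)
  rl2 <- rl
  rl2$gene_ids <- unname(relabel[rl$gene_ids])
  map2 <- annotation_map(lapply(map$assignments, function(g) unname(relabel[g])),
                         universe = rl2$gene_ids)
  res2 <- gssa(rl2, map2)
  keep <- setdiff(names(res1$calls), c("term_id", "name"))
  expect_equal(res1$calls[keep], res2$calls[keep])
})

test_that("compare_psg_counts runs a Welch t-test per module group", {
  genes <- sprintf("g%02d", 1:60)
  map <- annotation_map(split(genes, rep(1:6, each = 10)), universe = genes)
  names(map$assignments) <- paste0("T", 1:6)
  map$terms$term_id <- map$terms$name <- paste0("T", 1:6)
  calls <- data.frame(term_id = paste0("T", 1:6),
                      verdict = c("SH", "SH", "SH", "SL", "SL", "SL"))

  # identical groups: every module holds 5 PSGs -> t = 0, p = 1
  psg <- stats::setNames(rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 6), genes)
  r <- compare_psg_counts(calls, map, psg)
  expect_true(r$computable)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  # SH-heavy PSG load: clearly significant, matching stats::t.test
  psg2 <- stats::setNames(c(rep(1, 30), rep(0, 30)), genes)
  psg2[31:34] <- 1 # a little SL noise so variances are non-zero
  r2 <- compare_psg_counts(calls, map, psg2)
  sh <- c(10, 10, 10); sl <- c(4, 0, 0)
  ref <- stats::t.test(sh, sl)
  expect_equal(r2$t_statistic, unname(ref$statistic))
  expect_equal(r2$p_value, ref$p.value)
  expect_lt(r2$p_value, 0.05)

  # fewer than 2 modules in a group: reported not-computable, no error
  calls3 <- transform(calls, verdict = c("SH", "SH", "SH", "SL", "NS", "NS"))
  expect_false(compare_psg_counts(calls3, map, psg)$computable)
})
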