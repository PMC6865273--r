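test_that("contingency tables enforce the feasible-count invariants", {
  expect_error(contingency_table(10, 12, 3, 1), "cannot exceed")
  expect_error(contingency_table(10, 4, 3, 5), "feasible range")
  expect_error(contingency_table(10, 8, 8, 5), "feasible range")  # k < n+K-N
  tab <- contingency_table(10, 4, 3, 2)
  expect_s3_class(tab, "contingency_table")
})

test_that("build_table counts intersections under both conventions", {
  uni <- gene_universe(sprintf("G%02d", 1:20), is_mig = FALSE)
  q <- gene_list(sprintf("G%02d", 1:4), name = "q")
  f <- gene_list(sprintf("G%02d", c(1, 2, 3, 11, 12)), name = "f")
  tab <- build_table(q, f, uni)
  expect_equal(c(tab$N, tab$K, tab$n, tab$k), c(20L, 5L, 4L, 3L))
  # with a query inside the universe the excludes convention stacks the
  # query on the query-free background, giving the same 2x2 cells
  tabx <- build_table(q, f, uni, convention = "universe_excludes_query")
  expect_equal(c(tabx$N, tabx$K, tabx$n, tabx$k), c(20L, 5L, 4L, 3L))
  expect_equal(fisher_two_sided(tabx), fisher_two_sided(tab))
  # genes outside the universe are dropped before counting
  q2 <- gene_list(c(q$members, "ZZZ"), name = "q2")
  expect_equal(build_table(q2, f, uni)$n, 4L)
  # disjoint query/feature; feature = universe saturation
  expect_equal(build_table(q, gene_list("G19"), uni)$k, 0L)
  sat <- build_table(q, gene_list(sprintf("G%02d", 1:20)), uni)
  expect_equal(sat$k, sat$n)
  expect_equal(sat$K, sat$N)
})

test_that("fisher_two_sided matches hand-enumerated and degenerate cases", {
  # perfectly proportional 2x2 [[1,1],[1,1]]
  expect_equal(fisher_two_sided(contingency_table(4, 2, 2, 1)), 1)
  # all 20 C(6,3) arrangements: P(0)=P(3)=1/20 -> two-sided 2/20
  expect_equal(fisher_two_sided(contingency_table(6, 3, 3, 3)), 0.1,
               tolerance = 1e-12)
  # degenerate tables
  expect_equal(fisher_two_sided(contingency_table(10, 0, 4, 0)), 1)
  expect_equal(fisher_two_sided(contingency_table(10, 4, 0, 0)), 1)
  expect_equal(fisher_two_sided(contingency_table(10, 10, 4, 4)), 1)
  # p = 1 at the hypergeometric mode
  N <- 40; K <- 10; n <- 12
  mode_k <- which.max(dhyper(0:min(n, K), K, N - K, n)) - 1
  expect_equal(fisher_two_sided(contingency_table(N, K, n, mode_k)), 1)
})

test_that("fisher_two_sided equals the enumeration oracle and fisher.test", {
  set.seed(303)
  for (i in 1:300) {
    N <- sample(2:500, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- sample(lo:hi, 1)
    p <- fisher_two_sided(N, K = K, n = n, k = k)
    expect_equal(p, fisher_oracle(N, K, n, k), tolerance = 1e-10)
    if (n > 0 && K > 0 && K < N) {
      ft <- fisher.test(matrix(c(k, n - k, K - k, N - n - K + k), 2,
                               byrow = TRUE))$p.value
      expect_equal(p, min(1, ft), tolerance = 1e-7)
    }
  }
})

test_that("fisher p is invariant under transposing query and feature roles", {
  set.seed(404)
  for (i in 1:50) {
    N <- sample(5:200, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- sample(lo:hi, 1)
    expect_equal(fisher_two_sided(N, K = K, n = n, k = k),
                 fisher_two_sided(N, K = n, n = K, k = k),
                 tolerance = 1e-12)
  }
})

test_that("one-sided exceedance tail is monotone in k", {
  N <- 100; K <- 20; n <- 30
  uppers <- vapply(0:20, function(k)
    sum(dhyper(k:min(n, K), K, N - K, n)), numeric(1))
  expect_true(all(diff(uppers) <= 1e-12))
})

test_that("fold enrichment uses unrounded fractions; reporting rounds to one decimal", {
  expect_equal(fold_enrichment(contingency_table(20, 5, 4, 3)), 3.0)
  # query = universe identity
  expect_equal(fold_enrichment(contingency_table(20, 5, 20, 5)), 1.0)
  expect_error(fold_enrichment(contingency_table(20, 0, 4, 0)), "undefined")
  expect_equal(format_fold((8.1 / 100) / (3.4 / 100)), 2.4)
})

test_that("enrichment_result reports fractions, direction and odds ratio", {
  r <- enrichment_result(contingency_table(20444, 648, 742, 33))
  expect_equal(r$query_fraction, 33 / 742)
  expect_equal(r$universe_fraction, 648 / 20444)
  expect_equal(r$direction, "enriched")
  expect_equal(r$odds_ratio, (33 * 19087) / (709 * 615))
  d <- enrichment_result(contingency_table(100, 50, 10, 2))
  expect_equal(d$direction, "depleted")
  prop <- enrichment_result(contingency_table(4, 2, 2, 1))
  expect_equal(prop$direction, "none")
})

test_that("control batteries run one test per feature list", {
  uni <- gene_universe(sprintf("G%03d", 1:100),
                       is_mig = rep(c(TRUE, FALSE), c(10, 90)))
  q <- gene_list(sprintf("G%03d", 1:20), name = "essentialome")
  feats <- list(migs = universe_migs(uni),
                ctrl = gene_list(sprintf("G%03d", 51:60), name = "ctrl"))
  res <- control_battery(q, feats, uni)
  expect_named(res, c("migs", "ctrl"))
  expect_identical(res$migs$p_two_sided,
                   enrich_test(q, feats$migs, uni)$p_two_sided)
  expect_true(all(is.na(vapply(res, `[[`, numeric(1), "p_adjusted"))))
  resbh <- control_battery(q, feats, uni, adjust = "BH")
  expect_false(anyNA(vapply(resbh, `[[`, numeric(1), "p_adjusted")))
  expect_length(control_battery(q, list(), uni), 0)
})

test_that("null Fisher calibration is conservative at alpha = 0.05", {
  # planted odds ratio 1: MIG flags independent of query membership
  set.seed(505)
  n_rep <- 400; N <- 800; K <- 40; n <- 120
  rej <- 0
  for (i in seq_len(n_rep)) {
    k <- rhyper(1, K, N - K, n)
    if (fisher_two_sided(N, K = K, n = n, k = k) < 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("in a control battery only the planted MIG signal shows consistently", {
  cfg <- synthetic_config(n_genes = 4000, n_lines = 10,
                          planted_odds_ratio = 2.5)
  n_sim <- 100
  sig <- matrix(FALSE, n_sim, 4,
                dimnames = list(NULL, c("migs", "ctrl1", "ctrl2", "ctrl3")))
  for (i in seq_len(n_sim)) {
    uni <- generate_universe(cfg, seed = 40000 + i)
    ess <- generate_essentiality(uni, cfg, seed = 90000 + i)
    tot <- total_essentialome(per_line_essentialomes(ess))
    genes <- universe_genes(uni)
    set.seed(140000 + i)  # control lists drawn independently of essentiality
    feats <- list(migs = universe_migs(uni),
                  ctrl1 = gene_list(sample(genes, 150), name = "ctrl1"),
                  ctrl2 = gene_list(sample(genes, 400), name = "ctrl2"),
                  ctrl3 = gene_list(sample(genes, 800), name = "ctrl3"))
    res <- control_battery(gene_list(tot$members, "total"), feats, uni)
    sig[i, ] <- vapply(res, `[[`, numeric(1), "p_two_sided") < 0.05
  }
  expect_gte(mean(sig[, "migs"]), 0.95)          # planted effect found
  band <- 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim)   # null controls stay at alpha
  for (ctrl in c("ctrl1", "ctrl2", "ctrl3"))
    expect_lte(mean(sig[, ctrl]), band)
})
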