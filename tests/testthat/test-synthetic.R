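cfg_small <- synthetic_config(n_genes = 1200, n_lines = 12, seed = 5)

test_that("generators are pure functions of config and seed", {
  u1 <- generate_universe(cfg_small)
  u2 <- generate_universe(cfg_small)
  expect_identical(u1$annotations, u2$annotations)
  e1 <- generate_essentiality(u1, cfg_small)
  e2 <- generate_essentiality(u2, cfg_small)
  expect_identical(e1$values, e2$values)
  x1 <- generate_expression(u1, cfg_small)
  x2 <- generate_expression(u1, cfg_small)
  expect_identical(x1$tpm, x2$tpm)
  c1 <- generate_cdg_lists(u1, synthetic_config(n_genes = 1200, seed = 5,
                                                cdg_sizes = c(a = 50, b = 50,
                                                              c = 50, d = 50,
                                                              e = 50)))
  c2 <- generate_cdg_lists(u1, synthetic_config(n_genes = 1200, seed = 5,
                                                cdg_sizes = c(a = 50, b = 50,
                                                              c = 50, d = 50,
                                                              e = 50)))
  expect_identical(lapply(c1$species_lists, `[[`, "members"),
                   lapply(c2$species_lists, `[[`, "members"))
  # a different seed changes the draw
  expect_false(identical(generate_universe(cfg_small, seed = 6)$annotations,
                         u1$annotations))
})

test_that("universe marginals match the configured MIG share and ages", {
  cfg <- synthetic_config(n_genes = 17000, seed = 23)
  uni <- generate_universe(cfg)
  n_mig <- sum(uni$annotations$is_mig)
  expected <- 0.035 * 17000
  sd3 <- 3 * sqrt(17000 * 0.035 * 0.965)
  expect_gt(n_mig, expected - sd3)
  expect_lt(n_mig, expected + sd3)
  # mig_fraction 0 gives zero MIGs
  none <- generate_universe(synthetic_config(n_genes = 500, mig_fraction = 0,
                                             seed = 2))
  expect_equal(sum(none$annotations$is_mig), 0)
  # planted families are MIG-only with the configured sizes
  fam <- attr(uni, "truth")$family_map
  expect_equal(sort(unname(lengths(fam$families))), c(2L, 2L, 3L))
  ann <- uni$annotations
  expect_true(all(unlist(fam$families) %in% ann$gene[ann$is_mig]))
  # age labels stay on the default ladder
  expect_true(all(ann$age_clade %in% default_clades()))
})

test_that("generated artifacts satisfy the module type invariants", {
  uni <- generate_universe(cfg_small)
  ess <- generate_essentiality(uni, cfg_small)
  expect_s3_class(ess, "essentiality_matrix")
  expect_equal(ess$mode, "calls")
  expect_true(all(ess$values %in% c(0, 1)))
  expect_identical(rownames(ess$values), universe_genes(uni))
  tab <- generate_expression(uni, cfg_small)
  expect_s3_class(tab, "expression_table")
  expect_true(all(tab$tpm >= 0))
  cfg_cdg <- synthetic_config(n_genes = 1200, seed = 5,
                              cdg_sizes = c(a = 60, b = 60, c = 60, d = 60,
                                            e = 60))
  coll <- generate_cdg_lists(uni, cfg_cdg)
  expect_s3_class(coll, "cdg_collection")
  sizes <- vapply(coll$species_lists, function(l) length(l$members), integer(1))
  expect_equal(unname(sizes), rep(60L, 5))
})

test_that("noise-free lines collapse core, majority and total together", {
  cfg <- synthetic_config(n_genes = 800, n_lines = 8, drop_rate = 0,
                          gain_rate = 0, seed = 13)
  uni <- generate_universe(cfg)
  ess <- generate_essentiality(uni, cfg)
  per <- per_line_essentialomes(ess)
  tot <- total_essentialome(per)$members
  expect_identical(core_essentialome(per)$members, tot)
  expect_identical(majority_essentialome(per, 0.95)$members, tot)
  # and the total equals the consensus truth exactly
  truth <- attr(ess, "truth")
  expect_setequal(tot, names(truth$consensus)[truth$consensus == 1])
})

test_that("planted multi-species CDG overlaps are recovered exactly", {
  cfg <- synthetic_config(n_genes = 5000, seed = 41, n_shared2 = 12,
                          n_shared3 = 6,
                          cdg_sizes = c(dog = 120, cat = 120, cattle = 120,
                                        horse = 120, human = 300))
  uni <- generate_universe(cfg)
  coll <- generate_cdg_lists(uni, cfg)
  truth <- attr(coll, "truth")
  expect_length(truth$shared3, 6)
  expect_identical(shared_cdg(coll, 3)$members, truth$shared3)
  expect_identical(shared_cdg(coll, 2)$members,
                   sort(c(truth$shared2, truth$shared3)))
  # error paths
  expect_error(generate_cdg_lists(uni, synthetic_config(
    n_genes = 5000, seed = 1, cdg_sizes = c(a = 6000, b = 10, c = 10,
                                            d = 10, e = 10))),
    "exceed")
})

test_that("truth records score the planted essentiality effect", {
  cfg <- synthetic_config(n_genes = 6000, n_lines = 20,
                          planted_odds_ratio = 3, seed = 97)
  uni <- generate_universe(cfg)
  ess <- generate_essentiality(uni, cfg)
  truth <- attr(ess, "truth")
  ann <- uni$annotations
  # consensus rate among MIGs exceeds the non-MIG rate under a planted OR > 1
  expect_gt(mean(truth$consensus[ann$is_mig]),
            mean(truth$consensus[!ann$is_mig]))
  # the per-gene probabilities encode the planted odds ratio exactly
  p_mig <- unique(round(truth$p_gene[ann$is_mig], 12))
  p_non <- unique(round(truth$p_gene[!ann$is_mig], 12))
  ors <- outer(p_mig / (1 - p_mig), p_non / (1 - p_non), "/")
  expect_true(any(abs(ors - 3) < 1e-6))
})
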