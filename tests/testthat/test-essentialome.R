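make_per_line <- function(...) {
  sets <- list(...)
  out <- lapply(names(sets), function(nm)
    migessentials:::new_essentialome(sets[[nm]], name = nm, rule = "per_line"))
  names(out) <- names(sets)
  out
}

test_that("score thresholding is boundary-inclusive and keeps missingness", {
  m <- essentiality_matrix(
    matrix(c(-1.2, 0.1, -0.5, NA), 2, 2,
           dimnames = list(c("A", "B"), c("L1", "L2"))),
    mode = "scores")
  calls <- call_essential(m, threshold = -0.5)
  expect_equal(calls$mode, "calls")
  expect_equal(calls$values["A", "L1"], 1)   # below cutoff
  expect_equal(calls$values["B", "L1"], 0)   # above cutoff
  expect_equal(calls$values["A", "L2"], 1)   # exactly at cutoff: essential
  expect_true(is.na(calls$values["B", "L2"]))
  # calls-mode input passes through unchanged
  expect_identical(call_essential(calls, threshold = 99), calls)
})

test_that("per-line essentialomes collect call-1 genes; missing is not essential", {
  v <- matrix(c(1, 0, NA, 1), 2, 2,
              dimnames = list(c("A", "B"), c("L1", "L2")))
  per <- per_line_essentialomes(essentiality_matrix(v, mode = "calls"))
  expect_equal(per$L1$members, "A")
  expect_equal(per$L2$members, "B")   # A's NA call excluded
  # all-zero column gives a legal empty essentialome
  v0 <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "L1"))
  expect_length(per_line_essentialomes(
    essentiality_matrix(v0, mode = "calls"))$L1$members, 0)
})

test_that("total, core and majority rules match their set definitions", {
  per <- make_per_line(L1 = c("A", "B"), L2 = c("A", "C"), L3 = "A")
  expect_setequal(total_essentialome(per)$members, c("A", "B", "C"))
  expect_equal(core_essentialome(per)$members, "A")
  # fraction 0.6 of 3 lines -> ceiling(1.8) = 2 lines
  maj <- majority_essentialome(per, fraction = 0.6)
  expect_equal(maj$members, "A")
  expect_equal(maj$params$cutoff_lines, 2L)
  # single line: every rule returns that line's set
  one <- make_per_line(L1 = c("X", "Y"))
  expect_setequal(total_essentialome(one)$members, c("X", "Y"))
  expect_setequal(core_essentialome(one)$members, c("X", "Y"))
  # disjoint lines: empty core
  expect_length(core_essentialome(make_per_line(L1 = "A", L2 = "B"))$members, 0)
  # fraction 1 equals the core rule
  expect_identical(majority_essentialome(per, fraction = 1)$members,
                   core_essentialome(per)$members)
})

test_that("the 95% majority cutoff over 341 lines is 324 lines", {
  expect_equal(ceiling(0.95 * 341), 324)
  per <- replicate(341, migessentials:::new_essentialome("A", "l", "per_line"),
                   simplify = FALSE)
  names(per) <- sprintf("L%03d", 1:341)
  expect_equal(majority_essentialome(per, 0.95)$params$cutoff_lines, 324L)
})

test_that("group essentialomes union within groups and demand full coverage", {
  per <- make_per_line(L1 = "A", L2 = "B", L3 = "C")
  groups <- c(L1 = "AML", L2 = "AML", L3 = "SCL")
  ge <- group_essentialomes(per, groups)
  expect_setequal(ge$AML$members, c("A", "B"))
  expect_equal(ge$SCL$members, "C")
  expect_error(group_essentialomes(per, c(L1 = "AML", L2 = "AML")), "L3")
})

test_that("essentialome rules equal the brute-force counting oracle", {
  set.seed(101)
  for (i in 1:60) {
    m <- random_calls_matrix(sample(3:20, 1), sample(2:10, 1),
                             p = runif(1, 0.1, 0.6))
    f <- runif(1, 0.3, 1)
    per <- per_line_essentialomes(essentiality_matrix(m, mode = "calls"))
    oracle <- oracle_essentialomes(m, fraction = f)
    expect_identical(total_essentialome(per)$members, oracle$total)
    expect_identical(core_essentialome(per)$members, oracle$core)
    expect_identical(majority_essentialome(per, f)$members, oracle$majority)
  }
})

test_that("core/majority/total nest and survive line permutation", {
  set.seed(202)
  for (i in 1:30) {
    m <- random_calls_matrix(15, 8, p = 0.4)
    per <- per_line_essentialomes(essentiality_matrix(m, mode = "calls"))
    core <- core_essentialome(per)$members
    f_hi <- 0.9; f_lo <- 0.5
    maj_hi <- majority_essentialome(per, f_hi)$members
    maj_lo <- majority_essentialome(per, f_lo)$members
    total <- total_essentialome(per)$members
    expect_true(all(core %in% maj_hi))
    expect_true(all(maj_hi %in% maj_lo))
    expect_true(all(maj_lo %in% total))
    # permuting lines changes nothing
    perm <- per[sample(length(per))]
    expect_identical(total_essentialome(perm)$members, total)
    expect_identical(core_essentialome(perm)$members, core)
    expect_identical(majority_essentialome(perm, f_hi)$members, maj_hi)
    # every group essentialome is inside the total
    groups <- setNames(sample(c("g1", "g2"), 8, replace = TRUE), names(per))
    for (ge in group_essentialomes(per, groups))
      expect_true(all(ge$members %in% total))
  }
})
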