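test_that("gamma matches the hand-evaluated 3-tip case", {
  # equal internode intervals g2 = g3 = 1: gamma = -sqrt(3)/5
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_equal(gamma_statistic(tr), -sqrt(3) / 5, tolerance = 1e-12)
})

test_that("gamma agrees with the reference implementation", {
  withr::local_seed(31)
  for (i in 1:10) {
    tr <- ape::rcoal(sample(5:60, 1))
    expect_equal(gamma_statistic(tr), ape::gammaStat(tr), tolerance = 1e-9)
  }
})

test_that("gamma decreases when splits are pushed toward the root", {
  near_present <- caterpillar_with_times(c(0, 7, 8, 9), 10)
  near_root <- caterpillar_with_times(c(0, 0.5, 1, 1.5), 10)
  expect_lt(gamma_statistic(near_root), gamma_statistic(near_present))
})

test_that("gamma rejects invalid input", {
  expect_error(gamma_statistic(ape::read.tree(text = "(a:1,b:1);")),
               "3 tips")
  expect_error(gamma_statistic(ape::read.tree(text = "((a:1,b:3):1,c:2);")),
               "ultrametric")
})

test_that("beta is boundary-low for caterpillars, higher for balance", {
  cat8 <- ape::read.tree(text = "(((((((a,b),c),d),e),f),g),h);")
  bal8 <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  b_cat <- beta_statistic(cat8)
  b_bal <- beta_statistic(bal8)
  expect_identical(b_cat, -2)
  expect_gt(b_bal, b_cat)
  expect_lt(abs(b_cat - beta_grid_oracle(cat8)), 0.02)
  expect_error(beta_statistic(ape::read.tree(text = "((a,b),c);")), "4 tips")
})

test_that("beta agrees with the brute-force grid oracle", {
  withr::local_seed(13)
  for (i in 1:10) {
    tr <- ape::rtree(sample(8:25, 1))
    # implementation refines within a grid step of the 400-point oracle
    expect_lt(abs(beta_statistic(tr) - beta_grid_oracle(tr)), 0.05)
  }
})

test_that("mean range size averages occupied regions over tips", {
  st <- tibble::tibble(taxon = c("a", "b", "c"),
                       r1 = c(1, 1, 1), r2 = c(0, 1, 1), r3 = c(0, 0, 1))
  expect_equal(mean_range_size(st), 2)
  expect_equal(mean_range_size(dplyr::mutate(st, r2 = 1, r3 = 1)), 3)
  expect_equal(mean_range_size(dplyr::mutate(st, r2 = 0, r3 = 0)), 1)
  st$r1[1] <- 0
  expect_error(mean_range_size(st), "empty range")
})

test_that("treeness is the internal share of total branch length", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(treeness(star), 0)
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(treeness(two), 0)
  four <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(treeness(four), 1 / 3)
})

test_that("statistics ignore tip labels and newick rotation", {
  withr::local_seed(19)
  tr <- ape::rcoal(12)
  rotated <- ape::read.tree(text = ape::write.tree(ape::rotate(tr, 14)))
  relabeled <- tr
  relabeled$tip.label <- sample(tr$tip.label)
  for (other in list(rotated, relabeled)) {
    # newick serialization rounds branch lengths, hence the loose tolerance
    expect_equal(gamma_statistic(other), gamma_statistic(tr),
                 tolerance = 1e-6)
    expect_equal(beta_statistic(other), beta_statistic(tr), tolerance = 1e-6)
    expect_equal(treeness(other), treeness(tr), tolerance = 1e-9)
  }
})

test_that("grid designs count cells exactly", {
  expect_identical(grid_tree_count(grid_design(10)), 49950L)
  expect_identical(grid_tree_count(grid_design(5)), 6200L)
  expect_identical(grid_tree_count(grid_design(2)), 350L)
  d <- grid_design(3)
  expect_identical(nrow(d$cells), 26L)
  expect_false(any(d$cells$w_D == 0 & d$cells$e_D == 0 &
                     d$cells$d_D_dest == 0))
  # 0 is always on each axis (needed for the all-zero exclusion to bind)
  expect_true(all(c(0, -2) %in% d$cells$w_D))
  expect_error(grid_design(1), "points_per_axis")
})

test_that("a small grid study returns per-tree statistics rows", {
  d <- grid_design(2, reps = 2, min_tips = 3)
  res <- run_grid_study(d, seed = 77, max_attempts = 400)
  expect_s3_class(res, "ddg_grid_study")
  expect_lte(nrow(res), grid_tree_count(d))
  expect_true(all(res$n_extant >= 3))
  expect_true(all(is.finite(res$treeness)))
  expect_true(all(res$mean_range_size >= 1 & res$mean_range_size <= 3))
  expect_true(all(c("w_D", "e_D", "d_D_dest", "rep", "gamma", "beta")
                  %in% names(res)))
})

test_that("tree_stats composes the per-tree summary row", {
  withr::local_seed(3)
  tr <- ape::rcoal(10)
  st <- tibble::tibble(taxon = tr$tip.label, r1 = 1, r2 = rep(c(0, 1), 5))
  row <- tree_stats(tr, st)
  expect_identical(nrow(row), 1L)
  expect_identical(row$n_extant, 10L)
  expect_equal(row$mean_range_size, 1.5)
  expect_equal(row$gamma, ape::gammaStat(tr), tolerance = 1e-9)
})
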