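p3 <- function(...) {
  args <- utils::modifyList(
    list(rho_w = 0.05, rho_e = 0.02, rho_d = 0.05, rho_b = 0.02,
         n_regions = 3L),
    list(...))
  do.call(ddg_params, args)
}

test_that("log rate factor matches its defining identities", {
  expect_identical(log_rate_factor(1, 2), 1)
  expect_identical(log_rate_factor(5, 0), 1)
  expect_equal(log_rate_factor(exp(1), 1), 2)
  expect_error(log_rate_factor(0.5, 1), "count")
})

test_that("extinction rate follows the crowding exponent", {
  expect_equal(rate_extinction(1, c(1, 0, 0), p3(rho_e = 0.02, e_D = 2)),
               0.02)
  expect_equal(rate_extinction(1, c(7, 0, 0), p3(rho_e = 0.02, e_D = 0)),
               0.02)
  expect_equal(rate_extinction(1, c(exp(2), 0, 0), p3(rho_e = 0.01, e_D = 2)),
               0.09)
  expect_error(rate_extinction(2, c(1, 0, 0), p3()), "n_i")
})

test_that("within-region speciation rate follows the competition exponent", {
  expect_equal(rate_within(1, c(1, 0, 0), p3(rho_w = 0.05, w_D = -1)), 0.05)
  expect_equal(rate_within(1, c(9, 0, 0), p3(rho_w = 0.05, w_D = 0)), 0.05)
  expect_equal(rate_within(1, c(exp(1), 0, 0), p3(rho_w = 0.05, w_D = -1)),
               0.025)
})

test_that("dispersal rate combines source and destination factors", {
  expect_equal(
    rate_dispersal(1, 2, c(1, 0, 0), p3(rho_d = 0.05, d_D_src = -2,
                                        d_D_dest = -2)),
    0.05)
  expect_equal(
    rate_dispersal(1, 2, c(4, 3, 0), p3(rho_d = 0.05)), 0.05)
  expect_equal(
    rate_dispersal(1, 2, c(exp(1), exp(1) - 1, 0),
                   p3(rho_d = 0.05, d_D_src = 1, d_D_dest = 1)),
    0.2)
  expect_error(rate_dispersal(1, 1, c(1, 0, 0), p3()), "distinct")
  expect_error(rate_dispersal(2, 1, c(1, 0, 0), p3()), "n_i")
})

test_that("split edge weights are symmetric and neutral when alone", {
  par <- p3(b_D = -1)
  expect_equal(edge_weight_between(1, 2, c(1, 1, 0), par), 1)
  expect_equal(edge_weight_between(1, 2, c(3, 5, 0), p3(b_D = 0)), 1)
  expect_equal(edge_weight_between(1, 2, c(exp(1), 1, 0), par), 0.5)
  for (n1 in 1:6) for (n2 in 1:6) {
    expect_identical(edge_weight_between(1, 2, c(n1, n2, 0), par),
                     edge_weight_between(2, 1, c(n1, n2, 0), par))
  }
})

test_that("cut sets enumerate the complete bipartite crossing", {
  expect_identical(nrow(cut_set(1, 2)), 1L)
  cs <- cut_set(1, c(2, 3))
  expect_identical(nrow(cs), 2L)
  expect_setequal(paste(cs$i, cs$j), c("1 2", "1 3"))
  expect_identical(nrow(cut_set(c(1, 2), c(3, 4))), 4L)
  expect_error(cut_set(c(1, 2), c(2, 3)), "overlap")
  expect_error(cut_set(integer(0), 1), "nonempty")
})

test_that("split scores invert summed inverse edge weights", {
  par <- p3(rho_b = 0.04)
  # all richness 1: unit weights, score = 1 / #edges
  expect_equal(split_score(1, 2, c(1, 1, 1), par), 1)
  expect_equal(split_score(1, c(2, 3), c(1, 1, 1), par), 0.5)
  expect_equal(split_score(2, c(1, 3), c(1, 1, 1), p3(b_D = 0)), 0.5)
  expect_equal(rate_between(1, 2, c(1, 1, 1), par), 0.04)
  expect_equal(rate_between(1, c(2, 3), c(1, 1, 1), par), 0.02)
})

test_that("the per-lineage event table enumerates every move", {
  par <- p3()
  # single-region lineage: no range splits
  tab1 <- lineage_event_rates(1, c(1, 0, 0), par)
  expect_false("speciation_between" %in% tab1$event)
  # 2-region lineage on 3 regions: 2 within, 2 contractions, 2 dispersal
  # destinations (1 unoccupied region x 2 sources), 1 bipartition
  tab2 <- lineage_event_rates(c(1, 2), c(2, 1, 1), par)
  counts <- table(tab2$event)
  expect_identical(unname(counts[["speciation_within"]]), 2L)
  expect_identical(unname(counts[["extirpation"]]), 2L)
  expect_identical(unname(counts[["dispersal"]]), 2L)
  expect_identical(unname(counts[["speciation_between"]]), 1L)
  expect_true(all(tab2$rate >= 0))
  # diversity-independent reduction: all rates are the base constants
  tab0 <- lineage_event_rates(c(1, 2), c(10, 20, 5), par)
  expect_equal(tab0$rate[tab0$event == "speciation_within"], rep(0.05, 2))
  expect_equal(tab0$rate[tab0$event == "extirpation"], rep(0.02, 2))
  expect_equal(tab0$rate[tab0$event == "dispersal"], rep(0.05, 2))
  # full-range lineage: 2^(3-1) - 1 = 3 bipartitions
  tab3 <- lineage_event_rates(1:3, c(1, 1, 1), par)
  expect_identical(sum(tab3$event == "speciation_between"), 3L)
})

test_that("neutrality: alone-or-zero-exponent always gives the base rate", {
  for (expo in c(-2, -0.5, 1, 3)) {
    par <- p3(rho_w = 0.11, rho_e = 0.07, rho_d = 0.13, rho_b = 0.05,
              w_D = expo, e_D = expo, d_D_src = expo, d_D_dest = expo,
              b_D = expo)
    expect_identical(rate_within(1, c(1, 5, 5), par), 0.11)
    expect_identical(rate_extinction(1, c(1, 5, 5), par), 0.07)
    expect_identical(rate_dispersal(1, 2, c(1, 0, 5), par), 0.13)
    expect_identical(rate_between(1, 2, c(1, 1, 9), par), 0.05)
  }
  par0 <- p3(rho_w = 0.11, rho_e = 0.07, rho_d = 0.13, rho_b = 0.05)
  expect_identical(rate_within(2, c(9, 40, 1), par0), 0.11)
  expect_identical(rate_extinction(2, c(9, 40, 1), par0), 0.07)
  expect_identical(rate_dispersal(1, 3, c(9, 40, 2), par0), 0.13)
})

test_that("rates are monotone in counts with the sign of the exponent", {
  grid <- 1:50
  for (expo in c(-1.5, 2)) {
    par <- p3(w_D = expo, e_D = expo, d_D_src = expo, d_D_dest = expo)
    wv <- vapply(grid, function(n) rate_within(1, c(n, 1, 1), par), 0)
    ev <- vapply(grid, function(n) rate_extinction(1, c(n, 1, 1), par), 0)
    dv_src <- vapply(grid, function(n) rate_dispersal(1, 3, c(n, 1, 0), par), 0)
    dv_dst <- vapply(grid, function(n) rate_dispersal(1, 3, c(1, 1, n), par), 0)
    for (v in list(wv, ev, dv_src, dv_dst)) {
      if (expo > 0) expect_true(all(diff(v) > 0)) else
        expect_true(all(diff(v) < 0))
    }
  }
})

test_that("rates stay finite and nonnegative across extreme counts", {
  for (expo in c(-2, 0, 4)) {
    par <- p3(w_D = expo, e_D = expo, d_D_src = expo, d_D_dest = expo,
              b_D = expo)
    for (n in c(1, 10, 1e3, 1e6)) {
      vals <- c(rate_within(1, c(n, 1, 1), par),
                rate_extinction(1, c(n, 1, 1), par),
                rate_dispersal(1, 3, c(n, 1, n), par),
                rate_between(1, 2, c(n, n, 1), par))
      expect_true(all(is.finite(vals) & vals >= 0))
    }
  }
})
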