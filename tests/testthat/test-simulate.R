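test_that("identical seeds give bit-identical event logs", {
  p <- ddg_params(0.3, 0.1, 0.1, 0.05, e_D = 1, w_D = -0.5, n_regions = 3)
  a <- ddg_simulate(p, max_time = 20, seed = 17)
  b <- ddg_simulate(p, max_time = 20, seed = 17)
  expect_identical(a$events, b$events)
  expect_identical(a$lineages, b$lineages)
  c <- ddg_simulate(p, max_time = 20, seed = 18)
  expect_false(identical(a$events, c$events))
})

test_that("event-log replay reproduces the final state", {
  withr::local_seed(101)
  scenarios <- list(
    ddg_params(0.4, 0.15, 0.1, 0.1, n_regions = 2),
    ddg_params(0.3, 0.05, 0.2, 0.1, e_D = 2, w_D = -1, d_D_dest = -1,
               n_regions = 3),
    ddg_params(0.5, 0.1, 0.3, 0.2, b_D = -1, d_D_src = -0.5, n_regions = 4)
  )
  for (p in scenarios) {
    for (r in 1:5) {
      sim <- ddg_simulate(p, max_time = 12)
      expect_true(sim_consistent(sim))
      # richness census from extant ranges matches the maintained vector
      census <- integer(p$n_regions)
      for (rng in sim$lineages$range[sim$lineages$alive]) {
        census[rng] <- census[rng] + 1L
      }
      expect_identical(census, as.integer(sim$final_richness))
      expect_identical(sum(sim$lineages$alive), sim$n_extant)
    }
  }
})

test_that("all-zero rates leave a single unchanged root lineage", {
  p <- ddg_params(0, 0, 0, 0, n_regions = 2)
  sim <- ddg_simulate(p, max_time = 10, seed = 1)
  expect_true(sim$absorbed)
  expect_identical(nrow(sim$lineages), 1L)
  expect_identical(sim$n_extant, 1L)
  expect_identical(sim$final_time, 10)
  expect_identical(nrow(sim$events), 0L)
})

test_that("pure-birth reduction matches the Yule expectation", {
  withr::local_seed(7)
  p <- ddg_params(0.3, 0, 0, 0, n_regions = 2)
  counts <- replicate(600, ddg_simulate(p, max_time = 4)$n_extant)
  expected <- exp(0.3 * 4)
  # SE of the mean is about sqrt(e^rt (e^rt - 1)) / sqrt(600) ~ 0.11
  expect_lt(abs(mean(counts) - expected), 4 * 0.12)
})

test_that("the taxon cap stops the simulation at the event reaching it", {
  p <- ddg_params(1, 0, 0, 0, n_regions = 2)
  sim <- ddg_simulate(p, max_time = 100, max_taxa = 25, seed = 3)
  expect_true(sim$capped)
  expect_identical(sim$n_extant, 25L)
  expect_lt(sim$final_time, 100)
  # final time equals the time of the last (cap-reaching) event
  expect_identical(sim$final_time, max(sim$events$time))
})

test_that("richness trajectory is a step function consistent with events", {
  p <- ddg_params(0.3, 0.1, 0.15, 0.05, n_regions = 3)
  sim <- ddg_simulate(p, max_time = 15, seed = 5)
  traj <- richness_trajectory(sim)
  expect_identical(nrow(traj), (nrow(sim$events) + 1L) * 3L)
  final <- traj[traj$time == max(traj$time), ]
  expect_identical(as.integer(final$richness[order(final$region)]),
                   as.integer(sim$final_richness))
  start <- traj[traj$time == 0, ]
  expect_identical(as.integer(start$richness[order(start$region)]),
                   c(1L, 0L, 0L))
  # one dispersal event raises the destination count by exactly one
  disp <- sim$events[sim$events$event == "dispersal", ]
  if (nrow(disp) > 0) {
    e1 <- disp[1, ]
    before <- traj$richness[traj$time < e1$time & traj$region == e1$dest]
    after <- traj$richness[traj$time == e1$time & traj$region == e1$dest]
    expect_identical(after, before[length(before)] + 1L)
  }
})

test_that("pruning keeps extant tips, merges branches, stays ultrametric", {
  withr::local_seed(11)
  p <- ddg_params(0.35, 0.12, 0.1, 0.08, n_regions = 3)
  checked <- 0L
  while (checked < 8L) {
    sim <- ddg_simulate(p, max_time = 15)
    if (sim$n_extant < 3L) next
    checked <- checked + 1L
    tr <- prune_to_extant(sim)
    expect_identical(length(tr$tip.label), sim$n_extant)
    expect_setequal(tr$tip.label,
                    paste0("t", sim$lineages$lineage[sim$lineages$alive]))
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_true(ape::is.binary(tr))
    # tip depths equal the simulation horizon minus the root split time
    depths <- ape::node.depth.edgelength(tr)
    tip_depth <- max(depths[seq_len(sim$n_extant)])
    expect_lt(tip_depth, sim$final_time + 1e-9)
  }
})

test_that("a tree without extinction events prunes to itself", {
  p <- ddg_params(0.4, 0, 0.1, 0.1, n_regions = 2)
  sim <- ddg_simulate(p, max_time = 8, seed = 2)
  expect_gt(sim$n_extant, 1L)
  full <- as.phylo(sim)
  pruned <- prune_to_extant(sim)
  expect_identical(length(pruned$tip.label), length(full$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(full), ape::unroot(pruned)), 0,
               ignore_attr = TRUE)
})

test_that("fully extinct trees are reported for rejection logic", {
  p <- ddg_params(0, 5, 0, 0, n_regions = 2)
  sim <- ddg_simulate(p, max_time = 50, seed = 4)
  expect_true(sim$extinct)
  expect_identical(sim$n_extant, 0L)
  expect_error(prune_to_extant(sim), "extinct")
})

test_that("tip states are one-hot with nonempty ranges", {
  p <- ddg_params(0.3, 0.05, 0.2, 0.05, n_regions = 4)
  sim <- ddg_simulate(p, max_time = 12, seed = 9)
  st <- tip_states(sim)
  expect_identical(nrow(st), sim$n_extant)
  mat <- as.matrix(st[, -1])
  expect_true(all(mat %in% c(0L, 1L)))
  expect_true(all(rowSums(mat) >= 1))
  # per-region column sums are the final richness census
  expect_identical(as.integer(colSums(mat)), as.integer(sim$final_richness))
})

test_that("height and extant-count accessors agree with the lineage table", {
  p <- ddg_params(0.3, 0.05, 0.1, 0.05, n_regions = 2)
  sim <- ddg_simulate(p, max_time = 10, seed = 21)
  expect_identical(n_extant(sim), sum(sim$lineages$alive))
  if (sim$n_extant >= 2) {
    tr <- prune_to_extant(sim)
    expect_lte(tree_height(tr), 10)
    expect_gt(tree_height(tr), 0)
  }
  expect_s3_class(glance(sim), "tbl_df")
  expect_identical(glance(sim)$n_extant, sim$n_extant)
  expect_identical(nrow(tidy(sim)), nrow(sim$lineages))
})
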