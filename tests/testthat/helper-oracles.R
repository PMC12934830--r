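# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package internals.

# Reference parameter sets for the three equilibrium solvers
# (all have n* = 19.6712 per region on 3 regions).
params_unconstrained <- function() {
  ddg_params(15, 0.03, 0.05, 1, w_D = -0.5, b_D = -1, d_D_dest = -2,
             d_D_src = -1, e_D = 4, n_regions = 3)
}
params_shared_y <- function() {
  ddg_params(0.610047, 0.01, 0.01, 1, w_D = -1, e_D = 2, d_D_dest = -1,
             n_regions = 3)
}
params_shared_x <- function() {
  ddg_params(3.730315, 0.03, 0.04, 1, w_D = -0.5, e_D = 3, d_D_src = -0.5,
             d_D_dest = -0.5, n_regions = 3)
}

# Naive constant-rate GeoSSE simulator: explicit per-lineage event
# enumeration with ranges stored as plain integer vectors. Constant rates
# only (no diversity dependence). Returns the number of extant species at
# max_time. Used to validate the package's aggregated event engine in its
# diversity-independent reduction.
naive_geosse_n_extant <- function(rw, re, rd, rb, n_regions, max_time,
                                  root_range = 1L) {
  ranges <- list(sort(as.integer(root_range)))
  t <- 0
  repeat {
    if (length(ranges) == 0L) return(0L)
    # enumerate (lineage, event) pairs
    ev <- list()
    for (li in seq_along(ranges)) {
      rng <- ranges[[li]]
      for (r in rng) {
        ev[[length(ev) + 1L]] <- list(li = li, kind = "w", r = r, rate = rw)
        ev[[length(ev) + 1L]] <- list(li = li, kind = "e", r = r, rate = re)
      }
      for (r in rng) for (j in setdiff(seq_len(n_regions), rng)) {
        ev[[length(ev) + 1L]] <- list(li = li, kind = "d", r = r, j = j,
                                      rate = rd)
      }
      m <- length(rng)
      if (m >= 2L) {
        for (s in seq_len(2L^(m - 1L) - 1L)) {
          sel <- as.logical(bitwAnd(s, 2L^(seq_len(m - 1L) - 1L)))
          l <- rng[-1L][sel]
          k <- setdiff(rng, l)
          # unit edge weights: split score is 1 / (#cut edges)
          ev[[length(ev) + 1L]] <- list(li = li, kind = "b", k = k, l = l,
                                        rate = rb / (length(k) * length(l)))
        }
      }
    }
    total <- sum(vapply(ev, `[[`, numeric(1), "rate"))
    if (total <= 0) return(length(ranges))
    t <- t + rexp(1, total)
    if (t >= max_time) return(length(ranges))
    pick <- sample.int(length(ev), 1L,
                       prob = vapply(ev, `[[`, numeric(1), "rate"))
    e <- ev[[pick]]
    if (e$kind == "w") {
      ranges[[length(ranges) + 1L]] <- e$r
    } else if (e$kind == "e") {
      rng <- setdiff(ranges[[e$li]], e$r)
      if (length(rng) == 0L) ranges[[e$li]] <- NULL else ranges[[e$li]] <- rng
    } else if (e$kind == "d") {
      ranges[[e$li]] <- sort(c(ranges[[e$li]], e$j))
    } else {
      ranges[[e$li]] <- sort(e$k)
      ranges[[length(ranges) + 1L]] <- sort(e$l)
    }
  }
}

# Brute-force grid maximum-likelihood estimate of the beta-splitting
# parameter. Independent of the package implementation: per-node split
# probabilities are normalized directly (no log-sum-exp), likelihood is a
# plain product of probabilities accumulated in log space.
beta_grid_oracle <- function(tree, grid = seq(-2 + 1e-6, 10,
                                              length.out = 400L)) {
  n_tip <- length(tree$tip.label)
  # descendant tip counts per node, by repeated passes
  # (simple and clearly correct on small trees)
  nd <- c(rep(1L, n_tip), rep(NA_integer_, tree$Nnode))
  while (anyNA(nd)) {
    for (v in which(is.na(nd))) {
      ch <- tree$edge[tree$edge[, 1L] == v, 2L]
      if (!anyNA(nd[ch])) nd[v] <- sum(nd[ch])
    }
  }
  splits <- lapply((n_tip + 1L):(n_tip + tree$Nnode), function(v) {
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    c(n = nd[v], i = nd[ch[1L]])
  })
  ll <- vapply(grid, function(b) {
    s <- 0
    for (sp in splits) {
      n <- sp[["n"]]
      j <- seq_len(n - 1L)
      q <- gamma(b + 1 + j) * gamma(b + 1 + n - j) /
        (factorial(j) * factorial(n - j))
      if (any(!is.finite(q))) {  # fall back to log-space for large n
        lq <- lgamma(b + 1 + j) + lgamma(b + 1 + n - j) -
          lfactorial(j) - lfactorial(n - j)
        q <- exp(lq - max(lq))
      }
      s <- s + log(q[sp[["i"]]] / sum(q))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# Ultrametric tree with prescribed split times (heights measured from the
# root) on n = length(times) + 1 tips, built as a caterpillar.
caterpillar_with_times <- function(split_times, height) {
  stopifnot(all(diff(split_times) >= 0), all(split_times < height))
  n <- length(split_times) + 1L
  # innermost cherry first
  txt <- sprintf("(t%d:%g,t%d:%g)", n - 1L, height - split_times[n - 1L],
                 n, height - split_times[n - 1L])
  if (n > 2L) {
    for (k in rev(seq_len(n - 2L))) {
      txt <- sprintf("(t%d:%g,%s:%g)", k, height - split_times[k], txt,
                     split_times[k + 1L] - split_times[k])
    }
  }
  ape::read.tree(text = paste0(txt, ";"))
}
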