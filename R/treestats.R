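#' Pybus-Harvey gamma statistic
#'
#' Standardized summary of the distribution of node depths in an ultrametric
#' tree. With internode intervals `g_k` (the duration during which the
#' reconstructed tree has `k` lineages, `k = 2..n`) and
#' `T_i = sum_{k=2}^{i} k * g_k`, the statistic is
#'
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i - T_n/2}
#'   {T_n \sqrt{1 / (12 (n-2))}}.}
#'
#' Negative values indicate divergence times clustered near the root,
#' positive values near the present; pure-birth trees have expectation 0.
#'
#' @param tree An ultrametric `phylo` tree with at least 3 tips.
#' @param tol Ultrametricity tolerance, as a fraction of tree height.
#' @return The gamma statistic (numeric scalar).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' gamma_statistic(tr)  # -0.3464 for equal internode intervals
#' @export
gamma_statistic <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("gamma statistic needs at least 3 tips", call. = FALSE)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n)])
  if (height <= 0 || any(abs(depth[seq_len(n)] - height) > tol * height)) {
    stop("gamma statistic requires an ultrametric tree", call. = FALSE)
  }
  node_times <- sort(depth[(n + 1L):(n + tree$Nnode)])  # root has depth 0
  # g_k: interval with k lineages; k-th lineage appears at node_times[k-1]
  g <- c(diff(node_times), height - node_times[n - 1L])  # g_2..g_n
  Ti <- cumsum((2:n) * g)                                # T_2..T_n
  T_tot <- Ti[n - 1L]
  (mean(Ti[seq_len(n - 2L)]) - T_tot / 2) /
    (T_tot * sqrt(1 / (12 * (n - 2))))
}

# (left, right) descendant-tip counts at each internal node of a binary tree
node_split_sizes <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sz <- c(rep.int(1L, n), integer(nn))
  e <- ape::reorder.phylo(tree, "postorder")
  first <- integer(n + nn); second <- integer(n + nn)
  for (i in seq_len(nrow(e$edge))) {
    p <- e$edge[i, 1L]; ch <- e$edge[i, 2L]
    if (first[p] == 0L) first[p] <- ch
    else if (second[p] == 0L) second[p] <- ch
    else stop("beta statistic requires a binary tree", call. = FALSE)
  }
  for (i in seq_len(nrow(e$edge))) {
    p <- e$edge[i, 1L]; ch <- e$edge[i, 2L]
    sz[p] <- sz[p] + sz[ch]
  }
  ints <- which(second > 0L)
  tibble::tibble(n = sz[ints], left = sz[first[ints]], right = sz[second[ints]])
}

# log-likelihood of the beta-splitting model for observed splits;
# q_n(i | beta) = Gamma(b+1+i) Gamma(b+1+n-i) / (i! (n-i)! a_n(beta))
beta_split_loglik <- function(beta, sizes) {
  term <- function(i, n) {
    lgamma(beta + 1 + i) + lgamma(beta + 1 + n - i) -
      lgamma(i + 1) - lgamma(n - i + 1)
  }
  ll <- 0
  for (n in unique(sizes$n)) {
    j <- seq_len(n - 1L)
    s <- term(j, n)
    smax <- max(s)
    logZ <- smax + log(sum(exp(s - smax)))
    rows <- sizes$n == n
    ll <- ll + sum(term(sizes$left[rows], n)) - sum(rows) * logZ
  }
  ll
}

#' Aldous beta-splitting statistic (maximum likelihood)
#'
#' Maximum-likelihood imbalance parameter of the beta-splitting model fitted
#' to the observed (left, right) clade-size split at every internal node.
#' `beta = 0` corresponds to Yule topologies; `beta = -2` is the maximally
#' imbalanced (caterpillar) boundary. The likelihood is maximized by
#' golden-section/parabolic search on `[-2, 10]` verified against a 400-point
#' grid; boundary estimates are returned as the bound.
#'
#' @param tree A `phylo` tree with at least 4 tips and binary internal nodes.
#' @return The ML estimate of beta, clamped to `[-2, 10]`.
#' @examples
#' cat8 <- ape::read.tree(text = "(((((((a,b),c),d),e),f),g),h);")
#' beta_statistic(cat8)  # at the -2 boundary
#' @export
beta_statistic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4L) stop("beta statistic needs at least 4 tips", call. = FALSE)
  sizes <- node_split_sizes(tree)
  informative <- sum(sizes$n > 2L)
  if (informative < 2L) {
    stop("beta statistic undefined: fewer than 2 informative splits",
         call. = FALSE)
  }
  lo <- -2 + 1e-6; hi <- 10
  opt <- stats::optimize(beta_split_loglik, c(lo, hi), sizes = sizes,
                         maximum = TRUE, tol = 1e-6)
  grid <- seq(lo, hi, length.out = 400L)
  gll <- vapply(grid, beta_split_loglik, numeric(1), sizes = sizes)
  best_grid <- grid[which.max(gll)]          # ties resolve to smaller beta
  est <- if (max(gll) > opt$objective) best_grid else opt$maximum
  if (est <= lo + 1e-4) est <- -2
  if (est >= hi - 1e-4) est <- 10
  est
}

#' Mean geographic range size of the tips
#'
#' Average number of occupied regions per extant species, computed from a
#' one-hot tip-state table (`taxon` column plus one 0/1 column per region),
#' as produced by [tip_states()] or [read_tip_states()].
#'
#' @param states A data frame of tip states.
#' @return Mean range size, in `[1, n_regions]`.
#' @export
mean_range_size <- function(states) {
  cols <- states[vapply(states, is.numeric, logical(1))]
  if (ncol(cols) == 0L) stop("no region columns found", call. = FALSE)
  sizes <- rowSums(cols)
  if (any(sizes < 1)) stop("tip with empty range in state table", call. = FALSE)
  mean(sizes)
}

#' Treeness: proportion of internal branch length
#'
#' The summed length of internal (non-pendant) branches divided by the total
#' branch length of the tree. Star-like trees score near 0; trees whose
#' length is mostly internal score near 1.
#'
#' @param tree A `phylo` tree.
#' @return Treeness in `[0, 1]`.
#' @export
treeness <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  n <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > n
  total <- sum(tree$edge.length)
  if (total == 0) return(0)
  sum(tree$edge.length[internal]) / total
}

#' Tree-shape summary for one simulated tree
#'
#' One-row tibble of the statistics examined across simulation studies:
#' Aldous beta (topology balance), the gamma statistic (node-depth
#' distribution), treeness, mean tip range size, tip count and tree height.
#' Statistics whose preconditions fail (too few tips) are reported as `NA`.
#'
#' @param tree An extant-only `phylo` tree.
#' @param states Optional one-hot tip-state table for `mean_range_size`.
#' @return A one-row tibble.
#' @export
tree_stats <- function(tree, states = NULL) {
  n <- length(tree$tip.label)
  tibble::tibble(
    n_extant = n,
    beta = tryCatch(beta_statistic(tree), error = function(e) NA_real_),
    gamma = tryCatch(gamma_statistic(tree), error = function(e) NA_real_),
    treeness = treeness(tree),
    mean_range_size = if (is.null(states)) NA_real_ else mean_range_size(states),
    height = tree_height(tree)
  )
}

# ---- grid studies -----------------------------------------------------------

#' Design a mesh-grid simulation study over effect exponents
#'
#' Builds the 3-dimensional grid of effect exponents (`w_D`, `e_D`,
#' `d_D_dest`) used to map how diversity dependence shapes tree statistics:
#' `w_D` and `d_D_dest` span a non-positive interval, `e_D` a non-negative
#' one, the all-zero (diversity-independent) cell is excluded, and each
#' remaining cell is replicated `reps` times.
#'
#' @param points_per_axis Number of equally spaced values per exponent axis
#'   (>= 2; endpoints included, so 0 is always a grid value).
#' @param reps Accepted trees per cell (default 50).
#' @param w_range,e_range,d_range Intervals for `w_D`, `e_D`, `d_D_dest`.
#' @param height Fixed tree height: simulations run to this time and are
#'   accepted if at least `min_tips` lineages survive.
#' @param min_tips Minimum extant tips for a valid tree (default 3; smaller
#'   trees are rejected as uninformative).
#' @return A `ddg_grid_design` object; its `cells` tibble has one row per
#'   grid cell.
#' @examples
#' d <- grid_design(10)            # (10^3 - 1) * 50 = 49950 trees
#' grid_tree_count(d)
#' grid_tree_count(grid_design(5)) # 6200
#' @export
grid_design <- function(points_per_axis, reps = 50L,
                        w_range = c(-2, 0), e_range = c(0, 2),
                        d_range = c(-2, 0), height = 100, min_tips = 3L) {
  stopifnot(points_per_axis >= 2L, reps >= 1L)
  axis <- function(rng) seq(rng[1], rng[2], length.out = points_per_axis)
  cells <- tidyr::expand_grid(w_D = axis(w_range), e_D = axis(e_range),
                              d_D_dest = axis(d_range))
  cells <- cells[!(cells$w_D == 0 & cells$e_D == 0 & cells$d_D_dest == 0), ]
  structure(list(cells = cells, reps = as.integer(reps), height = height,
                 min_tips = as.integer(min_tips),
                 points_per_axis = as.integer(points_per_axis)),
            class = "ddg_grid_design")
}

#' @rdname grid_design
#' @param design A `ddg_grid_design` object.
#' @return `grid_tree_count()`: total number of accepted trees the design
#'   requests (cells x reps).
#' @export
grid_tree_count <- function(design) {
  stopifnot(inherits(design, "ddg_grid_design"))
  nrow(design$cells) * design$reps
}

#' @export
print.ddg_grid_design <- function(x, ...) {
  cat("<ddg_grid_design>", nrow(x$cells), "cells x", x$reps, "reps =",
      grid_tree_count(x), "trees; height", x$height, "\n")
  invisible(x)
}

#' Run a grid simulation study
#'
#' For every cell of a [grid_design()], simulates the 3-region Log-DDG
#' process to the fixed height until `reps` valid trees (at least `min_tips`
#' extant lineages at the horizon) are accepted, prunes each to its extant
#' tips, and records the tree-shape statistics. Cells whose acceptance rate
#' exhausts the retry budget are flagged and skipped rather than failing the
#' study.
#'
#' @param design A `ddg_grid_design` object.
#' @param base A [ddg_params()] object carrying the base rates, region count
#'   and the exponents not varied by the grid. Default: the study rates
#'   `rho_w = rho_d = 0.05`, `rho_e = rho_b = 0.02` on 3 regions.
#' @param root_range Root species range (default region 1).
#' @param seed Optional seed.
#' @param max_attempts Attempt budget per cell (default `50 * reps`).
#' @return A tibble (class `ddg_grid_study`) with one row per accepted tree:
#'   the cell exponents, replicate index, and [tree_stats()] columns. Flagged
#'   cells are listed in the `flagged_cells` attribute.
#' @export
run_grid_study <- function(design,
                           base = ddg_params(0.05, 0.02, 0.05, 0.02,
                                             n_regions = 3),
                           root_range = 1L, seed = NULL,
                           max_attempts = NULL) {
  stopifnot(inherits(design, "ddg_grid_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_attempts)) max_attempts <- 50L * design$reps
  cells <- design$cells
  out <- vector("list", nrow(cells))
  flagged <- integer(0)
  for (ci in seq_len(nrow(cells))) {
    par <- base
    par$w_D <- cells$w_D[ci]; par$e_D <- cells$e_D[ci]
    par$d_D_dest <- cells$d_D_dest[ci]
    accepted <- 0L; attempts <- 0L
    rows <- vector("list", design$reps)
    while (accepted < design$reps && attempts < max_attempts) {
      attempts <- attempts + 1L
      sim <- ddg_simulate(par, max_time = design$height,
                          root_range = root_range)
      if (sim$n_extant < design$min_tips) next
      accepted <- accepted + 1L
      tr <- prune_to_extant(sim)
      st <- tree_stats(tr, tip_states(sim))
      rows[[accepted]] <- dplyr::bind_cols(
        tibble::tibble(w_D = par$w_D, e_D = par$e_D,
                       d_D_dest = par$d_D_dest, rep = accepted),
        st
      )
    }
    if (accepted < design$reps) flagged <- c(flagged, ci)
    out[[ci]] <- dplyr::bind_rows(rows[seq_len(accepted)])
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ddg_grid_study", class(res))
  attr(res, "flagged_cells") <- flagged
  attr(res, "design") <- design
  res
}
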