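#' Logarithmic diversity-dependent rate factor
#'
#' The building block of every Log-DDG event rate: `(ln(x) + 1)^p`, where `x`
#' is a species count (or product of counts) and `p` an effect exponent.
#' Diversity dependence acts on the order of magnitude of richness rather
#' than on raw counts, so the factor grows (or shrinks) slowly. The factor is
#' exactly 1 when `x = 1` (a lineage alone) or `p = 0` (no effect).
#'
#' @param x Count argument, >= 1. Callers pass `n_i` for extinction,
#'   within-region speciation and the dispersal source factor; `n_j + 1` for
#'   the dispersal destination factor; `n_i * n_j` for range-split edge
#'   weights.
#' @param p Real effect exponent.
#' @return `(log(x) + 1)^p`, strictly positive. Vectorized over `x` and `p`.
#' @examples
#' log_rate_factor(1, 2)        # 1: no other species present
#' log_rate_factor(exp(1), 1)   # 2
#' @export
log_rate_factor <- function(x, p) {
  if (any(x < 1)) {
    stop("count argument must be >= 1 (inconsistent richness count)",
         call. = FALSE)
  }
  (log(x) + 1)^p
}

#' Per-lineage Log-DDG event rates
#'
#' Rates experienced by a single lineage, given the current per-region
#' richness vector `n` (counts of extant species occupying each region). All
#' rates are per lineage per unit time.
#'
#' * `rate_extinction()`: rate of losing region `i` from the range,
#'   `rho_e * (ln n_i + 1)^e_D`.
#' * `rate_within()`: rate of budding a single-region daughter inside region
#'   `i`, `rho_w * (ln n_i + 1)^w_D`.
#' * `rate_dispersal()`: rate of range expansion from occupied region `i`
#'   into unoccupied region `j`,
#'   `rho_d * (ln n_i + 1)^d_D_src * (ln(n_j + 1) + 1)^d_D_dest`.
#' * `rate_between()`: rate of allopatric speciation splitting the ancestral
#'   range into complementary ranges `k` and `l`,
#'   `rho_b * split_score(k, l, n, params)`.
#'
#' @param i,j Region indices (1-based). For dispersal, `i` is the source and
#'   `j` the destination; they must differ.
#' @param n Integer vector of per-region richness, length `params$n_regions`.
#' @param params A [ddg_params()] object.
#' @return A nonnegative rate (numeric scalar).
#' @examples
#' p <- ddg_params(0.05, 0.02, 0.05, 0.02, e_D = 2, n_regions = 3)
#' rate_extinction(1, c(1, 0, 0), p)  # alone: base rate 0.02
#' rate_extinction(1, c(7, 0, 0), p)  # crowded: elevated
#' @export
rate_extinction <- function(i, n, params) {
  if (n[i] < 1) stop("extinction rate needs n_i >= 1", call. = FALSE)
  params$rho_e * log_rate_factor(n[i], params$e_D)
}

#' @rdname rate_extinction
#' @export
rate_within <- function(i, n, params) {
  if (n[i] < 1) stop("within-region speciation rate needs n_i >= 1",
                     call. = FALSE)
  params$rho_w * log_rate_factor(n[i], params$w_D)
}

#' @rdname rate_extinction
#' @export
rate_dispersal <- function(i, j, n, params) {
  if (i == j) stop("dispersal requires distinct source and destination",
                   call. = FALSE)
  if (n[i] < 1) stop("dispersal rate needs source richness n_i >= 1",
                     call. = FALSE)
  params$rho_d *
    log_rate_factor(n[i], params$d_D_src) *
    log_rate_factor(n[j] + 1, params$d_D_dest)
}

#' Range-split machinery for between-region speciation
#'
#' An allopatric (between-region) speciation event splits an ancestral range
#' `m` into two nonempty complementary ranges `k` and `l`. Its relative rate
#' is governed by the connectivity between the two parts on the region graph
#' (taken to be complete): the cut set `E(k, l)` is all region pairs with one
#' end in each part, each cut edge `(i, j)` carries weight
#' `(ln(n_i * n_j) + 1)^b_D`, and the split score is the inverse of the sum
#' of inverse mean edge weights over the cut. With unit edge weights the
#' score is `1 / |E(k, l)|`, so splits that must sever more connections are
#' proportionally rarer.
#'
#' @param k,l Disjoint, nonempty integer vectors of region indices forming a
#'   bipartition of the ancestral range.
#' @inheritParams rate_extinction
#' @return `edge_weight_between()` a positive scalar, symmetric in `(i, j)`;
#'   `cut_set()` a tibble with columns `i`, `j` (one row per cut edge);
#'   `split_score()` and `rate_between()` positive scalars.
#' @examples
#' p <- ddg_params(0.05, 0.02, 0.05, 0.02, n_regions = 3)
#' cut_set(1, c(2, 3))
#' split_score(1, c(2, 3), c(1, 1, 1), p)  # 0.5: two unit cut edges
#' @export
edge_weight_between <- function(i, j, n, params) {
  if (n[i] < 1 || n[j] < 1) {
    stop("split edge weight needs n_i >= 1 and n_j >= 1", call. = FALSE)
  }
  log_rate_factor(n[i] * n[j], params$b_D)
}

#' @rdname edge_weight_between
#' @export
cut_set <- function(k, l) {
  k <- unique(as.integer(k)); l <- unique(as.integer(l))
  if (length(k) == 0L || length(l) == 0L) {
    stop("both sides of a range split must be nonempty", call. = FALSE)
  }
  if (length(intersect(k, l)) > 0L) {
    stop("invalid range split: parts overlap", call. = FALSE)
  }
  g <- expand.grid(i = k, j = l, KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g[order(g$i, g$j), ])
}

#' @rdname edge_weight_between
#' @export
split_score <- function(k, l, n, params) {
  cs <- cut_set(k, l)
  w <- log_rate_factor(n[cs$i] * n[cs$j], params$b_D)
  1 / sum(1 / w)
}

#' @rdname edge_weight_between
#' @export
rate_between <- function(k, l, n, params) {
  params$rho_b * split_score(k, l, n, params)
}

# internal: unordered bipartitions {k, l} of a region set (2^(m-1) - 1 of them)
enumerate_bipartitions <- function(range) {
  m <- length(range)
  if (m < 2L) return(list())
  out <- vector("list", 2L^(m - 1L) - 1L)
  # fix range[1] in k to enumerate unordered pairs once
  for (s in seq_len(2L^(m - 1L) - 1L)) {
    bits <- as.logical(bitwAnd(s, 2L^(seq_len(m - 1L) - 1L)))
    l <- range[-1L][bits]
    k <- setdiff(range, l)
    out[[s]] <- list(k = k, l = l)
  }
  out
}

#' All event rates available to one lineage
#'
#' Enumerates every event a lineage with the given range can experience under
#' the current richness vector, with its rate: one within-region speciation
#' and one extinction (range-contraction) row per occupied region, one
#' dispersal row per (occupied source, unoccupied destination) pair, and one
#' between-region speciation row per unordered bipartition of the range
#' (none when the range is a single region).
#'
#' @param range Integer vector of occupied regions (1-based).
#' @inheritParams rate_extinction
#' @return A tibble with columns `event` (one of `"speciation_within"`,
#'   `"extirpation"`, `"dispersal"`, `"speciation_between"`), `region`
#'   (region acted on, or dispersal source), `dest` (dispersal destination),
#'   `daughter_range` (list column: range of the new daughter species, for
#'   speciation events) and `rate`.
#' @examples
#' p <- ddg_params(0.05, 0.02, 0.05, 0.02, n_regions = 3)
#' lineage_event_rates(c(1, 2), c(2, 1, 1), p)
#' @export
lineage_event_rates <- function(range, n, params) {
  range <- check_range(range, params$n_regions)
  if (length(n) != params$n_regions || any(n[range] < 1)) {
    stop("richness vector inconsistent with the lineage range", call. = FALSE)
  }
  outs <- setdiff(seq_len(params$n_regions), range)

  rows <- list(
    tibble::tibble(
      event = "speciation_within", region = range, dest = NA_integer_,
      daughter_range = as.list(range),
      rate = params$rho_w * log_rate_factor(n[range], params$w_D)
    ),
    tibble::tibble(
      event = "extirpation", region = range, dest = NA_integer_,
      daughter_range = list(NULL),
      rate = params$rho_e * log_rate_factor(n[range], params$e_D)
    )
  )
  if (length(outs) > 0L) {
    pairs <- expand.grid(region = range, dest = outs, KEEP.OUT.ATTRS = FALSE)
    rows <- c(rows, list(tibble::tibble(
      event = "dispersal", region = pairs$region, dest = pairs$dest,
      daughter_range = list(NULL),
      rate = params$rho_d *
        log_rate_factor(n[pairs$region], params$d_D_src) *
        log_rate_factor(n[pairs$dest] + 1, params$d_D_dest)
    )))
  }
  splits <- enumerate_bipartitions(range)
  if (length(splits) > 0L) {
    rows <- c(rows, list(tibble::tibble(
      event = "speciation_between",
      region = NA_integer_, dest = NA_integer_,
      daughter_range = lapply(splits, `[[`, "l"),
      rate = vapply(splits, function(s) rate_between(s$k, s$l, n, params),
                    numeric(1))
    )))
  }
  dplyr::bind_rows(rows)
}
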