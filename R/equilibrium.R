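#' Balance residual of the local equilibrium-diversity equation
#'
#' At local equilibrium the total per-lineage rate flowing into a region
#' (within-region speciation plus immigration from the other regions)
#' balances the rate flowing out (extinction). Assuming every region holds
#' the same richness `n`, the residual is
#'
#' \deqn{f(n) = \rho_w (\ln n + 1)^{w_D}
#'   + (R - 1)\,\rho_d (\ln n + 1)^{d_{D,src}} (\ln(n + 1) + 1)^{d_{D,dest}}
#'   - \rho_e (\ln n + 1)^{e_D},}
#'
#' with `R` regions. The equilibrium diversity `n*` is a root of `f`.
#' Richness is treated as a continuous variable `n >= 1`; simulated counts
#' are integers, so simulation-based comparisons use means over replicates.
#'
#' @param n Continuous candidate richness, `>= 1` (vectorized).
#' @param params A [ddg_params()] object.
#' @return The residual `f(n)` (incoming minus outgoing rate).
#' @examples
#' p <- ddg_params(0.610047, 0.01, 0.01, 1, w_D = -1, e_D = 2,
#'                 d_D_dest = -1, n_regions = 3)
#' balance_residual(c(5, 19.7, 50), p)
#' @export
balance_residual <- function(n, params) {
  if (any(n < 1)) stop("richness must be >= 1", call. = FALSE)
  lf <- log(n) + 1
  lfd <- log(n + 1) + 1
  params$rho_w * lf^params$w_D +
    (params$n_regions - 1) * params$rho_d *
      lf^params$d_D_src * lfd^params$d_D_dest -
    params$rho_e * lf^params$e_D
}

#' Existence check for a local equilibrium
#'
#' A root of the balance residual exists in a bracket if and only if the
#' residual changes sign between the bracket ends (Bolzano: the residual is
#' continuous in `n`).
#'
#' @inheritParams solve_equilibrium
#' @return A list with `exists` (logical), and the residuals `f_lower`,
#'   `f_upper` at the bracket ends.
#' @export
equilibrium_exists <- function(params, bracket = c(1 + 1e-6, 1e4)) {
  f <- balance_residual(bracket, params)
  list(exists = is.finite(f[1]) && is.finite(f[2]) && f[1] * f[2] < 0,
       f_lower = f[1], f_upper = f[2])
}

new_ddg_equilibrium <- function(n_star, residual, method, iterations,
                                params) {
  structure(list(n_star = n_star, residual = residual, method = method,
                 iterations = iterations, params = params),
            class = "ddg_equilibrium")
}

#' @export
print.ddg_equilibrium <- function(x, ...) {
  cat("<ddg_equilibrium> n* =", format(x$n_star, digits = 8),
      "per region (", x$method, ")\n")
  cat("  residual f(n*) =", format(x$residual, digits = 3),
      " iterations:", x$iterations, "\n")
  invisible(x)
}

#' Numerically solve for the local equilibrium diversity
#'
#' Finds the root of the balance residual on a bracket by Brent's bracketing
#' method, refined by bisection until the residual is below `eps`. Works for
#' the fully unconstrained model (any effect exponents).
#'
#' @param params A [ddg_params()] object.
#' @param bracket Search interval for `n*` (default `[1 + 1e-6, 1e4]`).
#' @param eps Residual tolerance: the solution satisfies `|f(n*)| < eps`
#'   (default `1e-8`).
#' @return A `ddg_equilibrium` object with elements `n_star`, `residual`,
#'   `method`, `iterations`.
#' @examples
#' # fully unconstrained 3-region model with equilibrium near 19.7
#' p <- ddg_params(15, 0.03, 0.05, 1, w_D = -0.5, b_D = -1, d_D_dest = -2,
#'                 d_D_src = -1, e_D = 4, n_regions = 3)
#' solve_equilibrium(p)
#' @export
solve_equilibrium <- function(params, bracket = c(1 + 1e-6, 1e4),
                              eps = 1e-8) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  chk <- equilibrium_exists(params, bracket)
  if (!chk$exists) {
    stop(sprintf(paste0(
      "no equilibrium: balance residual does not change sign on ",
      "[%g, %g] (f = %g and %g); a root exists iff the residual has ",
      "opposite signs at the bracket ends"),
      bracket[1], bracket[2], chk$f_lower, chk$f_upper), call. = FALSE)
  }
  f <- function(n) balance_residual(n, params)
  r <- stats::uniroot(f, interval = bracket, tol = .Machine$double.eps^0.75)
  n_star <- r$root
  iter <- r$iter
  # bisection polish so that |f(n*)| < eps even for steep residuals
  lo <- max(bracket[1], n_star * (1 - 1e-3)); hi <- min(bracket[2], n_star * (1 + 1e-3))
  if (f(lo) * f(hi) > 0) { lo <- bracket[1]; hi <- bracket[2] }
  while (abs(f(n_star)) >= eps && (hi - lo) > .Machine$double.eps * hi) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    n_star <- mid
    iter <- iter + 1L
  }
  new_ddg_equilibrium(n_star, f(n_star), "bracketing", iter, params)
}

#' Closed-form local equilibrium diversity
#'
#' Analytic equilibrium for the constrained model with no diversity
#' dependence on the dispersal source (`d_D_src = 0`) and a shared exponent
#' `y = w_D = d_D_dest` on within-region speciation and inbound dispersal:
#'
#' \deqn{n^* = \exp\!\left[\left(\frac{\rho_w + \rho_d (R - 1)}{\rho_e}
#'   \right)^{1/(e_D - y)} - 1\right],}
#'
#' valid for `e_D != y`, `rho_e > 0`, and intended for the regime
#' `n* >> 0` where `ln(n + 1)` is well approximated by `ln n`.
#'
#' @inheritParams solve_equilibrium
#' @return A `ddg_equilibrium` object.
#' @examples
#' p <- ddg_params(0.610047, 0.01, 0.01, 1, w_D = -1, e_D = 2,
#'                 d_D_dest = -1, n_regions = 3)
#' equilibrium_closed_form(p)  # ~19.67 species per region
#' @export
equilibrium_closed_form <- function(params) {
  if (params$d_D_src != 0) {
    stop("closed form requires no source effect on dispersal (d_D_src = 0)",
         call. = FALSE)
  }
  if (params$w_D != params$d_D_dest) {
    stop("closed form requires a shared exponent w_D = d_D_dest",
         call. = FALSE)
  }
  y <- params$w_D
  if (params$e_D == y) {
    stop("closed form requires e_D != w_D (distinct exponents)",
         call. = FALSE)
  }
  if (params$rho_e <= 0) {
    stop("closed form requires rho_e > 0", call. = FALSE)
  }
  ratio <- (params$rho_w + params$rho_d * (params$n_regions - 1)) /
    params$rho_e
  n_star <- exp(ratio^(1 / (params$e_D - y)) - 1)
  new_ddg_equilibrium(n_star, balance_residual(max(n_star, 1), params),
                      "closed-form", 0L, params)
}

#' Self-consistent fixed-point local equilibrium diversity
#'
#' Analytic equilibrium for the constrained model with a shared exponent
#' `x = w_D = d_D_src = d_D_dest` on within-region speciation and both
#' dispersal factors. Because the immigration term then depends on the
#' (equal) richness of the other regions, the equilibrium solves the
#' self-consistency relation
#'
#' \deqn{n = \exp\!\left[\left(\frac{\rho_w + \rho_d (R - 1)(\ln n + 1)^x}
#'   {\rho_e}\right)^{1/(e_D - x)} - 1\right],}
#'
#' iterated (with damping) to convergence, with a bracketing fallback if the
#' iteration fails. With `rho_d = 0` the relation reduces exactly to the
#' closed form of [equilibrium_closed_form()].
#'
#' @inheritParams solve_equilibrium
#' @param tol Convergence tolerance on successive iterates (default `1e-10`).
#' @param n0 Starting value (default 10).
#' @param max_iter Iteration budget before the bracketing fallback.
#' @return A `ddg_equilibrium` object.
#' @examples
#' p <- ddg_params(3.730315, 0.03, 0.04, 1, w_D = -0.5, e_D = 3,
#'                 d_D_src = -0.5, d_D_dest = -0.5, n_regions = 3)
#' equilibrium_fixed_point(p)  # ~19.67 species per region
#' @export
equilibrium_fixed_point <- function(params, tol = 1e-10, n0 = 10,
                                    max_iter = 500L) {
  if (!(params$w_D == params$d_D_src && params$w_D == params$d_D_dest)) {
    stop("fixed point requires a shared exponent w_D = d_D_src = d_D_dest",
         call. = FALSE)
  }
  x <- params$w_D
  if (params$e_D == x) {
    stop("fixed point requires e_D != w_D (distinct exponents)",
         call. = FALSE)
  }
  if (params$rho_e <= 0) {
    stop("fixed point requires rho_e > 0", call. = FALSE)
  }
  g <- function(n) {
    ratio <- (params$rho_w +
                params$rho_d * (params$n_regions - 1) * (log(n) + 1)^x) /
      params$rho_e
    exp(ratio^(1 / (params$e_D - x)) - 1)
  }
  n <- max(n0, 1 + 1e-9)
  damp <- 0.5
  for (it in seq_len(max_iter)) {
    n_new <- damp * g(n) + (1 - damp) * n
    if (!is.finite(n_new) || n_new < 1) break
    if (abs(n_new - n) < tol) {
      return(new_ddg_equilibrium(n_new, n_new - g(n_new), "fixed-point", it,
                                 params))
    }
    n <- n_new
  }
  # fallback: bracket the self-consistency gap h(n) = g(n) - n
  h <- function(n) g(n) - n
  grid <- exp(seq(log(1 + 1e-6), log(1e6), length.out = 400))
  hv <- h(grid)
  sgn <- which(hv[-1] * hv[-length(hv)] < 0)
  if (length(sgn) == 0) {
    stop(sprintf(paste0("fixed-point iteration did not converge ",
                        "(last iterate %g) and no self-consistent root ",
                        "was bracketed"), n), call. = FALSE)
  }
  r <- stats::uniroot(h, interval = grid[c(sgn[1], sgn[1] + 1L)],
                      tol = .Machine$double.eps^0.75)
  new_ddg_equilibrium(r$root, h(r$root), "fixed-point (bracketing fallback)",
                      max_iter + r$iter, params)
}

#' Crossing-curve table for the balance equation
#'
#' Tabulates the incoming (within-region speciation + immigration) and
#' outgoing (extinction) per-lineage rates over a richness grid; their
#' crossing is the local equilibrium diversity.
#'
#' @inheritParams solve_equilibrium
#' @param n Richness grid (default 200 log-spaced points on the bracket).
#' @return A tibble with columns `n`, `incoming`, `outgoing`, `residual`.
#' @export
balance_curves <- function(params, n = NULL, bracket = c(1 + 1e-6, 1e4)) {
  if (is.null(n)) n <- exp(seq(log(bracket[1]), log(bracket[2]),
                               length.out = 200))
  lf <- log(n) + 1
  lfd <- log(n + 1) + 1
  incoming <- params$rho_w * lf^params$w_D +
    (params$n_regions - 1) * params$rho_d *
      lf^params$d_D_src * lfd^params$d_D_dest
  outgoing <- params$rho_e * lf^params$e_D
  tibble::tibble(n = n, incoming = incoming, outgoing = outgoing,
                 residual = incoming - outgoing)
}
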