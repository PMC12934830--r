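#' Model parameters for the logarithmic diversity-dependent GeoSSE process
#'
#' Bundles the four base event rates and the five diversity-dependent effect
#' exponents of the Log-DDG model. Each per-lineage event rate is a base rate
#' `rho` multiplied by a factor `(ln(count) + 1)^p`, where `count` is a local
#' species richness (or a product of richnesses for range splits) and `p` is
#' the effect exponent for that process. An exponent of 0 recovers the
#' classic constant-rate GeoSSE process.
#'
#' @param rho_w Base within-region speciation rate (events per lineage per
#'   region per unit time), >= 0.
#' @param rho_e Base extinction (range-contraction) rate per occupied region,
#'   >= 0.
#' @param rho_d Base dispersal rate per (source, destination) region pair,
#'   >= 0.
#' @param rho_b Base between-region (allopatric) speciation rate, >= 0.
#' @param w_D,e_D,b_D Effect exponents for within-region speciation,
#'   extinction and between-region speciation.
#' @param d_D_src,d_D_dest Effect exponents for the source- and
#'   destination-richness factors of the dispersal rate.
#' @param n_regions Number of discrete regions (>= 2).
#'
#' @return An object of class `ddg_params`.
#' @examples
#' p <- ddg_params(rho_w = 0.05, rho_e = 0.02, rho_d = 0.05, rho_b = 0.02,
#'                 w_D = -1, e_D = 2, n_regions = 3)
#' submodel_id(p)
#' @export
ddg_params <- function(rho_w, rho_e, rho_d, rho_b,
                       w_D = 0, e_D = 0, d_D_src = 0, d_D_dest = 0, b_D = 0,
                       n_regions = 2L) {
  p <- list(
    rho_w = as.numeric(rho_w), rho_e = as.numeric(rho_e),
    rho_d = as.numeric(rho_d), rho_b = as.numeric(rho_b),
    w_D = as.numeric(w_D), e_D = as.numeric(e_D),
    d_D_src = as.numeric(d_D_src), d_D_dest = as.numeric(d_D_dest),
    b_D = as.numeric(b_D),
    n_regions = as.integer(n_regions)
  )
  validate_ddg_params(p)
  structure(p, class = "ddg_params")
}

validate_ddg_params <- function(p) {
  rates <- c(p$rho_w, p$rho_e, p$rho_d, p$rho_b)
  if (anyNA(rates) || any(rates < 0)) {
    stop("base rates (rho_w, rho_e, rho_d, rho_b) must be nonnegative",
         call. = FALSE)
  }
  exps <- c(p$w_D, p$e_D, p$d_D_src, p$d_D_dest, p$b_D)
  if (anyNA(exps) || any(!is.finite(exps))) {
    stop("effect exponents must be finite", call. = FALSE)
  }
  if (is.na(p$n_regions) || p$n_regions < 2L) {
    stop("n_regions must be an integer >= 2", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ddg_params <- function(x, ...) {
  cat("<ddg_params> Log-DDG model on", x$n_regions, "regions\n")
  cat(sprintf("  base rates: rho_w=%g rho_e=%g rho_d=%g rho_b=%g\n",
              x$rho_w, x$rho_e, x$rho_d, x$rho_b))
  cat(sprintf("  exponents:  w_D=%g e_D=%g d_D_src=%g d_D_dest=%g b_D=%g\n",
              x$w_D, x$e_D, x$d_D_src, x$d_D_dest, x$b_D))
  cat("  submodel id:", submodel_id(x), "\n")
  invisible(x)
}

#' Submodel switches for diversity-dependent effects
#'
#' The eight canonical submodels toggle diversity dependence on extinction
#' (`e_D > 0`), within-region speciation (`w_D < 0`) and inbound dispersal
#' (`d_D_dest < 0`); outbound dispersal and between-region speciation stay
#' diversity-independent. The id encoding is: 0 none; 1 extinction; 2
#' within-speciation; 3 dispersal; 4 extinction + within; 5 extinction +
#' dispersal; 6 within + dispersal; 7 all three.
#'
#' @param extinction,within,dispersal Logical switches for diversity
#'   dependence on extinction, within-region speciation and inbound
#'   dispersal.
#' @return A `ddg_submodel` object (named logical vector of length 3).
#' @examples
#' submodel_spec(7)
#' submodel_spec(extinction = TRUE, dispersal = TRUE)  # submodel 5
#' @export
submodel_spec <- function(extinction = FALSE, within = FALSE,
                          dispersal = FALSE) {
  if (is.numeric(extinction) && missing(within) && missing(dispersal)) {
    id <- as.integer(extinction)
    if (is.na(id) || id < 0L || id > 7L) {
      stop("submodel id must be in 0..7", call. = FALSE)
    }
    flags <- .submodel_table[id + 1L, ]
    return(structure(c(extinction = flags[[1]], within = flags[[2]],
                       dispersal = flags[[3]]),
                     class = "ddg_submodel"))
  }
  structure(c(extinction = isTRUE(extinction), within = isTRUE(within),
              dispersal = isTRUE(dispersal)),
            class = "ddg_submodel")
}

# rows 1..8 are submodel ids 0..7: (extinction, within, dispersal)
.submodel_table <- matrix(c(
  FALSE, FALSE, FALSE,
  TRUE,  FALSE, FALSE,
  FALSE, TRUE,  FALSE,
  FALSE, FALSE, TRUE,
  TRUE,  TRUE,  FALSE,
  TRUE,  FALSE, TRUE,
  FALSE, TRUE,  TRUE,
  TRUE,  TRUE,  TRUE
), ncol = 3, byrow = TRUE)

#' @rdname submodel_spec
#' @param x A `ddg_params` or `ddg_submodel` object.
#' @return `submodel_id()` returns the integer id 0-7.
#' @export
submodel_id <- function(x) {
  flags <- if (inherits(x, "ddg_submodel")) {
    unclass(x)
  } else {
    c(extinction = x$e_D != 0, within = x$w_D != 0, dispersal = x$d_D_dest != 0)
  }
  hit <- which(.submodel_table[, 1] == flags[[1]] &
               .submodel_table[, 2] == flags[[2]] &
               .submodel_table[, 3] == flags[[3]])
  as.integer(hit - 1L)
}

#' @export
print.ddg_submodel <- function(x, ...) {
  on <- names(x)[unclass(x)]
  cat("<ddg_submodel>", submodel_id(x), "-",
      if (length(on)) paste(on, collapse = " + ") else "diversity-independent",
      "\n")
  invisible(x)
}

# internal: check a range is a valid nonempty subset of regions
check_range <- function(range, n_regions) {
  range <- as.integer(range)
  if (length(range) == 0L) stop("range must be nonempty", call. = FALSE)
  if (anyDuplicated(range)) stop("range has duplicate regions", call. = FALSE)
  if (any(range < 1L) || any(range > n_regions)) {
    stop("range contains regions outside 1..n_regions", call. = FALSE)
  }
  sort(range)
}
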