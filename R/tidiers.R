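#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its lineage table
#'
#' @param x A `ddg_sim` object.
#' @param ... Unused.
#' @return The lineage tibble: `lineage`, `parent`, `birth`, `end`, `alive`
#'   and the list-column `range` of occupied regions.
#' @method tidy ddg_sim
#' @export
tidy.ddg_sim <- function(x, ...) x$lineages

#' One-row simulation summary
#'
#' @param x A `ddg_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: lineage/event counts, final time, extant count,
#'   mean final richness and the termination flags.
#' @method glance ddg_sim
#' @export
glance.ddg_sim <- function(x, ...) {
  tibble::tibble(
    n_lineages = nrow(x$lineages),
    n_events = nrow(x$events),
    n_extant = x$n_extant,
    final_time = x$final_time,
    mean_richness = mean(x$final_richness),
    extinct = x$extinct,
    absorbed = x$absorbed,
    capped = x$capped
  )
}

#' Tidy an equilibrium solution
#'
#' @param x A `ddg_equilibrium` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_star`, `residual`, `method`, `iterations`.
#' @method tidy ddg_equilibrium
#' @export
tidy.ddg_equilibrium <- function(x, ...) {
  tibble::tibble(n_star = x$n_star, residual = x$residual,
                 method = x$method, iterations = x$iterations)
}

#' Plot the richness trajectory of a simulation
#'
#' Step plot of the per-region count of extant species over time, the
#' quantity whose long-run plateau is the local equilibrium diversity.
#'
#' @param object A `ddg_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_sim
#' @export
autoplot.ddg_sim <- function(object, ...) {
  traj <- richness_trajectory(object)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$richness,
                                     colour = factor(.data$region))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "extant species in region",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot grid-study trends
#'
#' Cell-mean tree statistics against each diversity-dependent effect
#' exponent, one facet per (statistic, exponent) pair.
#'
#' @param object A `ddg_grid_study` tibble from [run_grid_study()].
#' @param stats Statistics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddg_grid_study
#' @export
autoplot.ddg_grid_study <- function(object,
                                    stats = c("n_extant", "gamma", "beta",
                                              "mean_range_size"),
                                    ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(stats),
    names_to = "statistic", values_to = "value"
  )
  long <- tidyr::pivot_longer(
    long, cols = c("w_D", "e_D", "d_D_dest"),
    names_to = "exponent", values_to = "exponent_value"
  )
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$statistic, .data$exponent,
                    .data$exponent_value),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(means, ggplot2::aes(x = .data$exponent_value,
                                      y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_grid(statistic ~ exponent, scales = "free") +
    ggplot2::labs(x = "effect exponent value", y = "mean statistic") +
    ggplot2::theme_minimal()
}

#' Plot the balance-equation crossing curves
#'
#' Incoming (speciation + immigration) and outgoing (extinction) per-lineage
#' rates against richness; the crossing point is the local equilibrium
#' diversity.
#'
#' @param params A [ddg_params()] object.
#' @param bracket Richness range to display.
#' @return A ggplot object.
#' @export
plot_balance_curves <- function(params, bracket = c(1 + 1e-6, 100)) {
  curves <- balance_curves(params, bracket = bracket)
  long <- tidyr::pivot_longer(curves, cols = c("incoming", "outgoing"),
                              names_to = "flow", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$rate,
                                     colour = .data$flow)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "regional richness n", y = "per-lineage rate") +
    ggplot2::theme_minimal()
}
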