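#' Prior specification for training-set simulation
#'
#' The priors used to generate likelihood-free training data: every base
#' rate is drawn on `[1e-4, 1]` from a two-component scheme (half of the
#' replicates uniform, half log-uniform, so values spanning several orders
#' of magnitude are equally represented); when a diversity-dependent effect
#' is active in the submodel, `e_D ~ U(1e-4, 2)` and `w_D`, `d_D_dest`
#' `~ U(-2, -1e-4)`, otherwise exactly 0. Outbound-dispersal and
#' between-region effects are always 0. Each replicate draws its taxon cap
#' uniformly on `[100, 300]` (rounded to an integer) and its time horizon
#' uniformly on `[70, 100]`; trees with fewer than `min_taxa = 10` extant
#' tips (or full extinction) are rejected and redrawn.
#'
#' @param base_range,e_range,w_range,d_range Support intervals for the base
#'   rates and active effect exponents.
#' @param taxa_range,time_range Supports for the drawn stopping conditions.
#' @param min_taxa Minimum extant tip count of an accepted tree.
#' @param n_regions Number of regions in the simulated system (default 5).
#' @return A `ddg_prior` object.
#' @export
training_prior <- function(base_range = c(1e-4, 1),
                           e_range = c(1e-4, 2),
                           w_range = c(-2, -1e-4),
                           d_range = c(-2, -1e-4),
                           taxa_range = c(100, 300),
                           time_range = c(70, 100),
                           min_taxa = 10L,
                           n_regions = 5L) {
  structure(list(base_range = base_range, e_range = e_range,
                 w_range = w_range, d_range = d_range,
                 taxa_range = taxa_range, time_range = time_range,
                 min_taxa = as.integer(min_taxa),
                 n_regions = as.integer(n_regions)),
            class = "ddg_prior")
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Draw model parameters from the training prior
#'
#' @param submodel A submodel id (0-7) or [submodel_spec()] object selecting
#'   which diversity-dependent effects are active.
#' @param prior A [training_prior()] object.
#' @param component `"uniform"` or `"loguniform"`: which mixture component
#'   the four base rates are drawn from. [make_training_set()] alternates
#'   components by replicate index so any N keeps the 50/50 split.
#' @return A [ddg_params()] object; inactive effect exponents are exactly 0.
#' @examples
#' draw_parameters(7, component = "loguniform")
#' @export
draw_parameters <- function(submodel, prior = training_prior(),
                            component = c("uniform", "loguniform")) {
  component <- match.arg(component)
  flags <- if (inherits(submodel, "ddg_submodel")) submodel
           else submodel_spec(submodel)
  base <- if (component == "uniform") {
    stats::runif(4, prior$base_range[1], prior$base_range[2])
  } else {
    runif_log(4, prior$base_range)
  }
  ddg_params(
    rho_w = base[1], rho_e = base[2], rho_d = base[3], rho_b = base[4],
    e_D = if (flags[["extinction"]])
      stats::runif(1, prior$e_range[1], prior$e_range[2]) else 0,
    w_D = if (flags[["within"]])
      stats::runif(1, prior$w_range[1], prior$w_range[2]) else 0,
    d_D_dest = if (flags[["dispersal"]])
      stats::runif(1, prior$d_range[1], prior$d_range[2]) else 0,
    d_D_src = 0, b_D = 0,
    n_regions = prior$n_regions
  )
}

#' Simulate one accepted training example
#'
#' Draws parameters and stopping conditions from the prior, simulates from a
#' single ancestral species in a uniformly chosen region, and applies
#' rejection sampling: the replicate is redrawn on full tree extinction or
#' fewer than `prior$min_taxa` extant tips. The simulation stops at the
#' first of the drawn time horizon and the drawn taxon cap, so accepted
#' trees have random heights and sizes.
#'
#' @inheritParams draw_parameters
#' @param max_attempts Rejection budget before failing with a diagnostic.
#' @return A `ddg_training_example`: list with `tree` (extant-only `phylo`),
#'   `states` (one-hot tip table), `labels` (one-row tibble of all drawn
#'   parameters, submodel id, root region and realized stop values) and
#'   `sim` (the full `ddg_sim`).
#' @export
simulate_training_example <- function(submodel, prior = training_prior(),
                                      component = c("uniform", "loguniform"),
                                      max_attempts = 1000L) {
  component <- match.arg(component)
  flags <- if (inherits(submodel, "ddg_submodel")) submodel
           else submodel_spec(submodel)
  for (attempt in seq_len(max_attempts)) {
    par <- draw_parameters(flags, prior, component)
    max_taxa <- round(stats::runif(1, prior$taxa_range[1],
                                   prior$taxa_range[2]))
    max_time <- stats::runif(1, prior$time_range[1], prior$time_range[2])
    root_region <- sample.int(prior$n_regions, 1L)
    sim <- ddg_simulate(par, max_time = max_time, root_range = root_region,
                        max_taxa = max_taxa)
    if (sim$extinct || sim$n_extant < prior$min_taxa) next
    tree <- prune_to_extant(sim)
    labels <- tibble::tibble(
      submodel = submodel_id(flags),
      rho_w = par$rho_w, rho_e = par$rho_e, rho_d = par$rho_d,
      rho_b = par$rho_b,
      w_D = par$w_D, e_D = par$e_D, d_D_src = par$d_D_src,
      d_D_dest = par$d_D_dest, b_D = par$b_D,
      n_regions = prior$n_regions,
      root_region = root_region,
      max_taxa = max_taxa, max_time = max_time,
      base_component = component,
      n_extant = sim$n_extant,
      attempts = attempt
    )
    return(structure(list(tree = tree, states = tip_states(sim),
                          labels = labels, sim = sim),
                     class = "ddg_training_example"))
  }
  stop(sprintf(paste0("no accepted tree for submodel %d after %d attempts ",
                      "(last draw: rho_w=%g rho_e=%g)"),
               submodel_id(flags), max_attempts, par$rho_w, par$rho_e),
       call. = FALSE)
}

#' @export
print.ddg_training_example <- function(x, ...) {
  cat("<ddg_training_example> submodel", x$labels$submodel, "-",
      x$labels$n_extant, "extant tips, height",
      format(tree_height(x$tree), digits = 4), "\n")
  invisible(x)
}

#' Generate a training set on disk
#'
#' Writes `n` accepted replicates for one submodel as
#' `<id>.tre` (Newick), `<id>.dat.csv` (one-hot tip states) and
#' `<id>.labels.csv` (drawn parameters), with zero-padded ids, plus a
#' `labels_manifest.csv` collecting all label rows. Base-rate mixture
#' components alternate deterministically by replicate index (odd uniform,
#' even log-uniform) so any `n` preserves the 50/50 split, and each
#' replicate is seeded from its own entry in a seed schedule derived from
#' `seed`, so generation can be parallelized or resumed without changing
#' results.
#'
#' @inheritParams simulate_training_example
#' @param n Number of replicates.
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed for the per-replicate seed schedule.
#' @return The manifest tibble (one row per replicate), invisibly.
#' @export
make_training_set <- function(submodel, n, outdir, seed = NULL,
                              prior = training_prior(),
                              max_attempts = 1000L) {
  stopifnot(n >= 1L)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  width <- max(5L, nchar(as.character(n)))
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(rep_seeds[i])
    component <- if (i %% 2L == 1L) "uniform" else "loguniform"
    ex <- simulate_training_example(submodel, prior, component,
                                    max_attempts = max_attempts)
    id <- formatC(i, width = width, flag = "0")
    write_newick(ex$tree, file.path(outdir, paste0(id, ".tre")))
    write_tip_states(ex$states, file.path(outdir, paste0(id, ".dat.csv")))
    lab <- dplyr::bind_cols(tibble::tibble(replicate = id), ex$labels)
    readr::write_csv(lab, file.path(outdir, paste0(id, ".labels.csv")))
    labels[[i]] <- lab
  }
  manifest <- dplyr::bind_rows(labels)
  readr::write_csv(manifest, file.path(outdir, "labels_manifest.csv"))
  invisible(manifest)
}

#' Read and write one-hot tip-state tables
#'
#' CSV files with a `taxon` column and one 0/1 presence column per region.
#' The reader validates the encoding and rejects rows with an empty range
#' (all zeros).
#'
#' @param states A tip-state table ([tip_states()]).
#' @param path File path.
#' @return `read_tip_states()` returns the validated tibble.
#' @export
write_tip_states <- function(states, path) {
  readr::write_csv(states, path)
  invisible(path)
}

#' @rdname write_tip_states
#' @export
read_tip_states <- function(path) {
  states <- readr::read_csv(path, show_col_types = FALSE)
  region_cols <- states[vapply(states, is.numeric, logical(1))]
  vals <- unlist(region_cols, use.names = FALSE)
  if (!all(vals %in% c(0, 1))) {
    stop("tip-state file is not one-hot encoded (values other than 0/1)",
         call. = FALSE)
  }
  if (any(rowSums(region_cols) == 0)) {
    stop("tip-state file has an all-zero row (empty range)", call. = FALSE)
  }
  states
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; round trips
#' preserve topology, tip labels and branch lengths to formatting precision.
#'
#' @param tree A `phylo` object.
#' @param path File path (conventionally `.tre`).
#' @return `read_newick()` returns a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
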