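# Event-based (Gillespie) simulation of the Log-DDG process.
#
# Rates are piecewise constant between events and depend only on a lineage's
# range and the per-region richness vector, so the engine groups extant
# lineages by range (stored as an integer bitmask) and computes one rate
# table per occupied range per event. Event selection is hierarchical:
# range class ~ count x per-lineage total, then a uniform lineage within the
# class, then the event within the lineage's rate table. This is an exact
# sampler of the continuous-time process.

.EV_WITHIN <- 1L; .EV_EXTIRP <- 2L; .EV_DISP <- 3L
.EV_BETWEEN <- 4L; .EV_GLOBAL_EXT <- 5L

.EV_NAMES <- c("speciation_within", "extirpation", "dispersal",
               "speciation_between", "global_extinction")

mask_bits <- function(n_regions) bitwShiftL(1L, seq_len(n_regions) - 1L)

mask_to_regions <- function(mask, bits) which(bitwAnd(mask, bits) > 0L)

regions_to_mask <- function(regions, bits) {
  m <- 0L
  for (r in regions) m <- bitwOr(m, bits[r])
  m
}

# Per-range event catalogue: regions, dispersal pairs, bipartitions with cut
# edges, plus flat event descriptors aligned with the rate vector layout
# [within | extirpation | dispersal | between].
build_mask_info <- function(mask, n_regions, bits) {
  regs <- mask_to_regions(mask, bits)
  outs <- setdiff(seq_len(n_regions), regs)
  nr <- length(regs)

  disp_src <- integer(0); disp_dest <- integer(0)
  if (length(outs) > 0L && nr > 0L) {
    g <- expand.grid(src = regs, dest = outs, KEEP.OUT.ATTRS = FALSE)
    disp_src <- g$src; disp_dest <- g$dest
  }

  splits <- enumerate_bipartitions(regs)
  ns <- length(splits)
  cut_i <- integer(0); cut_j <- integer(0); cut_sid <- integer(0)
  lmask <- integer(0)
  if (ns > 0L) {
    for (s in seq_len(ns)) {
      k <- splits[[s]]$k; l <- splits[[s]]$l
      g <- expand.grid(i = k, j = l, KEEP.OUT.ATTRS = FALSE)
      cut_i <- c(cut_i, g$i); cut_j <- c(cut_j, g$j)
      cut_sid <- c(cut_sid, rep.int(s, nrow(g)))
      lmask <- c(lmask, regions_to_mask(l, bits))
    }
  }

  nd <- length(disp_src)
  ev_type <- c(rep.int(.EV_WITHIN, nr), rep.int(.EV_EXTIRP, nr),
               rep.int(.EV_DISP, nd), rep.int(.EV_BETWEEN, ns))
  ev_region <- c(regs, regs, disp_src, rep.int(NA_integer_, ns))
  ev_dest <- c(rep.int(NA_integer_, 2L * nr), disp_dest,
               rep.int(NA_integer_, ns))
  ev_dmask <- c(bits[regs], rep.int(NA_integer_, nr + nd), lmask)

  list(regs = regs, nr = nr, disp_src = disp_src, disp_dest = disp_dest,
       nd = nd, ns = ns, cut_i = cut_i, cut_j = cut_j, cut_sid = cut_sid,
       ev_type = ev_type, ev_region = ev_region, ev_dest = ev_dest,
       ev_dmask = ev_dmask)
}

# Rate vector for one lineage of this range under richness n.
# lf = log(n) + 1, lfd = log(n + 1) + 1, precomputed by the caller.
mask_rate_vector <- function(info, lf, lfd, par) {
  w <- par$rho_w * lf[info$regs]^par$w_D
  e <- par$rho_e * lf[info$regs]^par$e_D
  d <- if (info$nd > 0L && par$rho_d > 0) {
    par$rho_d * lf[info$disp_src]^par$d_D_src *
      lfd[info$disp_dest]^par$d_D_dest
  } else rep.int(0, info$nd)
  b <- if (info$ns > 0L && par$rho_b > 0) {
    # cut-edge weight (ln(n_i * n_j) + 1)^b_D = (lf_i + lf_j - 1)^b_D
    we <- (lf[info$cut_i] + lf[info$cut_j] - 1)^par$b_D
    par$rho_b / rowsum(1 / we, info$cut_sid)[, 1L]
  } else rep.int(0, info$ns)
  c(w, e, d, b)
}

#' Simulate a phylogeny under the Log-DDG process
#'
#' Exact event-based simulation of the diversity-dependent GeoSSE
#' birth-death process. Starting from a single root species, the simulator
#' draws exponential waiting times from the summed per-lineage event rates
#' (which are constant between events), picks one event in proportion to its
#' rate, applies it, and updates the per-region richness that drives all
#' diversity-dependent rates. Event semantics: within-region speciation in
#' region `i` buds off a single-region daughter with range `{i}` (the parent
#' is unchanged); between-region speciation splits the parent range `m` into
#' complementary daughter ranges `k` and `l`; dispersal adds a region to the
#' actor's range; extirpation removes a region, killing the lineage when its
#' range was that single region. Extinct lineages are retained in the
#' returned tree.
#'
#' @param params A [ddg_params()] object.
#' @param max_time Simulation horizon (required, > 0). The process stops at
#'   `max_time`, or earlier if `max_taxa` is reached, all lineages die, or
#'   no event has positive rate (absorption).
#' @param root_range Regions occupied by the root species (default region 1).
#' @param max_taxa Optional cap on the number of extant lineages; the
#'   simulation stops at the time of the event that reaches the cap.
#' @param seed Optional integer seed (`set.seed()`); identical seeds give
#'   bit-identical event logs.
#' @return A `ddg_sim` object with components `lineages` (tibble: `lineage`,
#'   `parent`, `birth`, `end`, `alive`, list-column `range`), `events`
#'   (tibble event log), `final_richness`, `n_extant`, `final_time`, and
#'   logical flags `extinct`, `absorbed`, `capped`.
#' @examples
#' p <- ddg_params(0.3, 0.05, 0.1, 0.05, e_D = 1, n_regions = 2)
#' sim <- ddg_simulate(p, max_time = 20, seed = 1)
#' sim
#' @seealso [prune_to_extant()], [richness_trajectory()], [tip_states()]
#' @export
ddg_simulate <- function(params, max_time, root_range = 1L,
                         max_taxa = Inf, seed = NULL) {
  stopifnot(inherits(params, "ddg_params"))
  if (!is.numeric(max_time) || max_time <= 0) {
    stop("max_time must be > 0", call. = FALSE)
  }
  if (!is.infinite(max_taxa) && max_taxa < 1) {
    stop("max_taxa must be >= 1", call. = FALSE)
  }
  if (params$n_regions > 12L) {
    stop("simulation supports at most 12 regions", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  R <- params$n_regions
  bits <- mask_bits(R)
  root_range <- check_range(root_range, R)
  root_mask <- regions_to_mask(root_range, bits)
  nmask <- bitwShiftL(1L, R) - 1L

  infos <- vector("list", nmask)   # lazily built per-range catalogues

  # lineage arrays
  cap_l <- 256L
  parent <- integer(cap_l); birth <- numeric(cap_l); endt <- rep(NA_real_, cap_l)
  cur_mask <- integer(cap_l); alive <- logical(cap_l); lpos <- integer(cap_l)
  K <- 0L

  # per-mask buckets of extant lineage ids
  buckets <- rep(list(integer(8L)), nmask)
  blen <- integer(nmask)

  # event log arrays
  cap_e <- 1024L
  ev_time <- numeric(cap_e); ev_type <- integer(cap_e)
  ev_lin <- integer(cap_e); ev_reg <- integer(cap_e)
  ev_dst <- integer(cap_e); ev_dau <- integer(cap_e); ev_dm <- integer(cap_e)
  NE <- 0L

  grow_lineages <- function() {
    cap2 <- cap_l * 2L
    length(parent) <<- cap2; length(birth) <<- cap2
    endt <<- c(endt, rep(NA_real_, cap_l))
    length(cur_mask) <<- cap2; length(alive) <<- cap2; length(lpos) <<- cap2
    cap_l <<- cap2
  }
  grow_events <- function() {
    cap2 <- cap_e * 2L
    length(ev_time) <<- cap2; length(ev_type) <<- cap2
    length(ev_lin) <<- cap2; length(ev_reg) <<- cap2
    length(ev_dst) <<- cap2; length(ev_dau) <<- cap2; length(ev_dm) <<- cap2
    cap_e <<- cap2
  }

  bucket_add <- function(lin, m) {
    nb <- blen[m] + 1L
    if (nb > length(buckets[[m]])) {
      length(buckets[[m]]) <<- 2L * length(buckets[[m]])
    }
    buckets[[m]][nb] <<- lin
    blen[m] <<- nb
    lpos[lin] <<- nb
    cur_mask[lin] <<- m
  }
  bucket_remove <- function(lin) {
    m <- cur_mask[lin]
    pos <- lpos[lin]
    last <- blen[m]
    moved <- buckets[[m]][last]
    buckets[[m]][pos] <<- moved
    lpos[moved] <<- pos
    blen[m] <<- last - 1L
  }
  new_lineage <- function(par_id, t, m) {
    if (K + 1L > cap_l) grow_lineages()
    K <<- K + 1L
    parent[K] <<- par_id; birth[K] <<- t; alive[K] <<- TRUE
    bucket_add(K, m)
    K
  }
  log_event <- function(t, type, lin, reg, dst, dau, dm) {
    if (NE + 1L > cap_e) grow_events()
    NE <<- NE + 1L
    ev_time[NE] <<- t; ev_type[NE] <<- type; ev_lin[NE] <<- lin
    ev_reg[NE] <<- reg; ev_dst[NE] <<- dst; ev_dau[NE] <<- dau
    ev_dm[NE] <<- dm
  }

  new_lineage(0L, 0, root_mask)
  n <- integer(R); n[root_range] <- 1L
  extant <- 1L
  t <- 0
  extinct <- FALSE; absorbed <- FALSE; capped <- FALSE

  repeat {
    active <- which(blen > 0L)
    lf <- log(n) + 1           # only used at occupied regions
    lfd <- log(n + 1) + 1
    na <- length(active)
    rvs <- vector("list", na)
    tots <- numeric(na)
    for (a in seq_len(na)) {
      m <- active[a]
      if (is.null(infos[[m]])) infos[[m]] <- build_mask_info(m, R, bits)
      rv <- mask_rate_vector(infos[[m]], lf, lfd, params)
      rvs[[a]] <- rv
      tots[a] <- sum(rv)
    }
    weights <- blen[active] * tots
    total <- sum(weights)
    if (!is.finite(total) || total <= 0) {
      absorbed <- TRUE; t <- max_time
      break
    }
    dt <- stats::rexp(1L, total)
    if (t + dt >= max_time) {
      t <- max_time
      break
    }
    t <- t + dt

    ai <- which(cumsum(weights) >= stats::runif(1L) * total)[1L]
    m <- active[ai]
    lin <- buckets[[m]][sample.int(blen[m], 1L)]
    rv <- rvs[[ai]]
    eidx <- which(cumsum(rv) >= stats::runif(1L) * tots[ai])[1L]
    info <- infos[[m]]
    type <- info$ev_type[eidx]

    if (type == .EV_WITHIN) {
      r <- info$ev_region[eidx]
      dau <- new_lineage(lin, t, bits[r])
      n[r] <- n[r] + 1L
      extant <- extant + 1L
      log_event(t, .EV_WITHIN, lin, r, NA_integer_, dau, bits[r])
    } else if (type == .EV_EXTIRP) {
      r <- info$ev_region[eidx]
      newm <- m - bits[r]
      bucket_remove(lin)
      n[r] <- n[r] - 1L
      if (newm > 0L) {
        bucket_add(lin, newm)
        log_event(t, .EV_EXTIRP, lin, r, NA_integer_, NA_integer_,
                  NA_integer_)
      } else {
        alive[lin] <- FALSE; endt[lin] <- t; cur_mask[lin] <- 0L
        extant <- extant - 1L
        log_event(t, .EV_GLOBAL_EXT, lin, r, NA_integer_, NA_integer_,
                  NA_integer_)
      }
    } else if (type == .EV_DISP) {
      r <- info$ev_region[eidx]; j <- info$ev_dest[eidx]
      bucket_remove(lin)
      bucket_add(lin, bitwOr(m, bits[j]))
      n[j] <- n[j] + 1L
      log_event(t, .EV_DISP, lin, r, j, NA_integer_, NA_integer_)
    } else {  # between-region speciation: parent keeps k, daughter gets l
      lm <- info$ev_dmask[eidx]
      km <- m - lm
      bucket_remove(lin)
      bucket_add(lin, km)
      dau <- new_lineage(lin, t, lm)
      extant <- extant + 1L
      log_event(t, .EV_BETWEEN, lin, NA_integer_, NA_integer_, dau, lm)
    }

    if (extant == 0L) {
      extinct <- TRUE
      break
    }
    if (extant >= max_taxa) {
      capped <- TRUE
      break
    }
  }

  idx <- seq_len(K)
  ends <- endt[idx]
  ends[is.na(ends)] <- t
  lineages <- tibble::tibble(
    lineage = idx,
    parent = parent[idx],
    birth = birth[idx],
    end = ends,
    alive = alive[idx],
    range = lapply(cur_mask[idx], mask_to_regions, bits = bits)
  )
  eidx <- seq_len(NE)
  events <- tibble::tibble(
    time = ev_time[eidx],
    event = .EV_NAMES[ev_type[eidx]],
    lineage = ev_lin[eidx],
    region = ev_reg[eidx],
    dest = ev_dst[eidx],
    daughter = ev_dau[eidx],
    daughter_mask = ev_dm[eidx]
  )

  structure(list(
    params = params,
    n_regions = R,
    root_range = root_range,
    max_time = max_time,
    max_taxa = max_taxa,
    final_time = t,
    n_extant = extant,
    final_richness = n,
    lineages = lineages,
    events = events,
    extinct = extinct,
    absorbed = absorbed,
    capped = capped
  ), class = "ddg_sim")
}

#' @export
print.ddg_sim <- function(x, ...) {
  cat("<ddg_sim>", nrow(x$lineages), "lineages,", x$n_extant,
      "extant at time", format(x$final_time, digits = 5), "on",
      x$n_regions, "regions\n")
  cat("  events:", nrow(x$events),
      if (x$extinct) " [tree extinct]" else "",
      if (x$absorbed) " [absorbed: total rate 0]" else "",
      if (x$capped) " [taxon cap reached]" else "", "\n", sep = "")
  cat("  final richness:", paste(x$final_richness, collapse = " "), "\n")
  invisible(x)
}

#' Number of extant lineages and tree height
#'
#' @param x A `ddg_sim` object (`n_extant`) or a `phylo` tree
#'   (`tree_height`).
#' @return `n_extant()` an integer count; `tree_height()` the maximum
#'   root-to-tip path length.
#' @export
n_extant <- function(x) {
  stopifnot(inherits(x, "ddg_sim"))
  x$n_extant
}

#' @rdname n_extant
#' @export
tree_height <- function(x) {
  stopifnot(inherits(x, "phylo"))
  max(ape::node.depth.edgelength(x))
}

# ---- event-log replay -------------------------------------------------------

# Re-derives per-lineage range masks, alive flags, and the per-region
# richness after every event by applying the event log to the initial state.
# Used by richness_trajectory() and the state-replay consistency check.
replay_masks <- function(sim) {
  bits <- mask_bits(sim$n_regions)
  K <- nrow(sim$lineages)
  mask <- integer(K)
  alive <- logical(K)
  mask[1L] <- regions_to_mask(sim$root_range, bits)
  alive[1L] <- TRUE
  ev <- sim$events
  NE <- nrow(ev)
  n <- integer(sim$n_regions)
  n[sim$root_range] <- 1L
  rich <- matrix(0L, nrow = NE + 1L, ncol = sim$n_regions)
  rich[1L, ] <- n
  for (e in seq_len(NE)) {
    type <- ev$event[e]; lin <- ev$lineage[e]
    if (type == "speciation_within") {
      dau <- ev$daughter[e]
      mask[dau] <- ev$daughter_mask[e]
      alive[dau] <- TRUE
      n[ev$region[e]] <- n[ev$region[e]] + 1L
    } else if (type == "speciation_between") {
      dau <- ev$daughter[e]
      lm <- ev$daughter_mask[e]
      mask[dau] <- lm
      alive[dau] <- TRUE
      mask[lin] <- mask[lin] - lm
    } else if (type == "dispersal") {
      mask[lin] <- bitwOr(mask[lin], bits[ev$dest[e]])
      n[ev$dest[e]] <- n[ev$dest[e]] + 1L
    } else if (type == "extirpation") {
      mask[lin] <- mask[lin] - bits[ev$region[e]]
      n[ev$region[e]] <- n[ev$region[e]] - 1L
    } else {  # global_extinction
      mask[lin] <- 0L
      alive[lin] <- FALSE
      n[ev$region[e]] <- n[ev$region[e]] - 1L
    }
    rich[e + 1L, ] <- n
  }
  list(mask = mask, alive = alive, richness = rich)
}

#' Replay the event log and check simulator bookkeeping
#'
#' Applies the recorded event log to the initial single-lineage state and
#' compares the reconstructed final ranges, alive flags and per-region
#' richness with those maintained incrementally during simulation. A `TRUE`
#' result certifies that the event log uniquely reconstructs the final state.
#'
#' @param sim A `ddg_sim` object.
#' @return `TRUE` if the replayed state matches, otherwise `FALSE`.
#' @export
sim_consistent <- function(sim) {
  stopifnot(inherits(sim, "ddg_sim"))
  rp <- replay_masks(sim)
  bits <- mask_bits(sim$n_regions)
  final_mask <- vapply(sim$lineages$range, regions_to_mask, integer(1),
                       bits = bits)
  n_final <- rp$richness[nrow(rp$richness), ]
  identical(rp$mask, final_mask) &&
    identical(rp$alive, sim$lineages$alive) &&
    all(n_final == sim$final_richness) &&
    sum(rp$alive) == sim$n_extant
}

#' Per-region richness trajectory
#'
#' The piecewise-constant per-region count of extant species over the course
#' of a simulation, reconstructed from the event log. Values jump only at
#' event times; the value at the final time equals the extant-range census.
#'
#' @param sim A `ddg_sim` object.
#' @return A long tibble with columns `time`, `region`, `richness`, giving
#'   the count in force from `time` onwards (row at `time = 0` included).
#' @export
richness_trajectory <- function(sim) {
  stopifnot(inherits(sim, "ddg_sim"))
  rp <- replay_masks(sim)
  times <- c(0, sim$events$time)
  colnames(rp$richness) <- seq_len(sim$n_regions)
  out <- tibble::as_tibble(rp$richness)
  out$time <- times
  tidyr::pivot_longer(out, cols = -"time", names_to = "region",
                      values_to = "richness",
                      names_transform = list(region = as.integer))
}

# ---- tree construction ------------------------------------------------------

#' Convert a simulation to an ape phylogeny
#'
#' Builds the complete binary timetree over all lineages (extinct included)
#' implied by the birth and end times in the lineage table. Budding
#' speciation places each daughter's origin as an internal node on the
#' parent's path. Tip `t<i>` corresponds to lineage `i`; extinct tips end at
#' their death time, extant tips at the final time. The time from the origin
#' (single root species at time 0) to the first split is stored as
#' `root.edge`.
#'
#' @param x A `ddg_sim` object.
#' @param ... Unused.
#' @return A `phylo` object, or a single-tip `phylo` when no speciation
#'   occurred.
#' @method as.phylo ddg_sim
#' @export
as.phylo.ddg_sim <- function(x, ...) {
  lin <- x$lineages
  K <- nrow(lin)
  if (K == 1L) {
    return(structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = lin$end[1L] - lin$birth[1L],
      tip.label = "t1", Nnode = 1L
    ), class = "phylo"))
  }
  # internal node for the birth of lineage j (j >= 2): provisional id K + j - 1
  node_of <- c(NA_integer_, K + seq_len(K - 1L))
  kids <- split(2:K, factor(lin$parent[2:K], levels = seq_len(K)))

  n_edge <- 2L * K - 2L
  efrom <- integer(n_edge); eto <- integer(n_edge); elen <- numeric(n_edge)
  ne <- 0L
  for (i in seq_len(K)) {
    ch <- kids[[i]]
    path_nodes <- c(node_of[ch], i)                       # ids along the path
    path_times <- c(lin$birth[ch], lin$end[i])
    anchor <- if (i > 1L) node_of[i] else NA_integer_
    prev_node <- anchor
    prev_time <- lin$birth[i]
    for (s in seq_along(path_nodes)) {
      if (!is.na(prev_node)) {
        ne <- ne + 1L
        efrom[ne] <- prev_node; eto[ne] <- path_nodes[s]
        elen[ne] <- path_times[s] - prev_time
      }
      prev_node <- path_nodes[s]
      prev_time <- path_times[s]
    }
  }

  # remap internal ids to preorder so the edge matrix is cladewise
  root <- node_of[2L]
  ord <- order(efrom)                       # children adjacency by parent id
  adj_start <- integer(2L * K - 1L); adj_n <- integer(2L * K - 1L)
  sf <- efrom[ord]
  for (e in seq_along(sf)) {
    p <- sf[e]
    if (adj_n[p] == 0L) adj_start[p] <- e
    adj_n[p] <- adj_n[p] + 1L
  }
  new_id <- integer(2L * K - 1L)
  new_id[seq_len(K)] <- seq_len(K)
  new_id[root] <- K + 1L
  next_int <- K + 1L
  edge_order <- integer(n_edge); eo <- 0L
  estack <- integer(n_edge); sp <- 0L
  es <- ord[adj_start[root] + seq_len(adj_n[root]) - 1L]
  for (e in rev(es)) { sp <- sp + 1L; estack[sp] <- e }
  while (sp > 0L) {
    e <- estack[sp]; sp <- sp - 1L
    eo <- eo + 1L; edge_order[eo] <- e
    child <- eto[e]
    if (child > K) {
      next_int <- next_int + 1L
      new_id[child] <- next_int
      es <- ord[adj_start[child] + seq_len(adj_n[child]) - 1L]
      for (e2 in rev(es)) { sp <- sp + 1L; estack[sp] <- e2 }
    }
  }
  edge <- cbind(new_id[efrom[edge_order]], new_id[eto[edge_order]])
  storage.mode(edge) <- "integer"
  structure(list(
    edge = edge,
    edge.length = elen[edge_order],
    tip.label = paste0("t", seq_len(K)),
    Nnode = K - 1L,
    root.edge = lin$birth[2L]
  ), class = "phylo")
}

#' Prune a simulated tree to its extant lineages
#'
#' Removes extinct lineages from the complete simulated tree and suppresses
#' the resulting unifurcations, merging branch lengths. When the simulation
#' ran to a fixed horizon the result is ultrametric.
#'
#' @param sim A `ddg_sim` object with at least one extant lineage.
#' @return A `phylo` tree whose tips are the extant lineages (labels
#'   `t<lineage id>`); a single-tip `phylo` if only one lineage survived
#'   (invalid for downstream statistics).
#' @export
prune_to_extant <- function(sim) {
  stopifnot(inherits(sim, "ddg_sim"))
  if (sim$n_extant == 0L) {
    stop("tree is extinct: no extant lineages to keep", call. = FALSE)
  }
  full <- ape::as.phylo(sim)
  keep <- paste0("t", sim$lineages$lineage[sim$lineages$alive])
  if (length(keep) == 1L) {
    # degenerate single-survivor tree
    return(structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = sim$final_time,
      tip.label = keep, Nnode = 1L
    ), class = "phylo"))
  }
  if (length(keep) == nrow(sim$lineages)) return(full)
  ape::keep.tip(full, keep)
}

#' One-hot tip range table
#'
#' Presence (1) / absence (0) of each extant species in each region, in the
#' encoding used by the training-set files: a `taxon` column followed by one
#' 0/1 column per region.
#'
#' @param sim A `ddg_sim` object.
#' @param extant_only Keep only extant lineages (default `TRUE`). Extinct
#'   lineages have empty ranges and are invalid as tip states.
#' @return A tibble with columns `taxon`, `region_1`, ..., `region_R`.
#' @export
tip_states <- function(sim, extant_only = TRUE) {
  stopifnot(inherits(sim, "ddg_sim"))
  lin <- sim$lineages
  if (extant_only) lin <- lin[lin$alive, ]
  onehot <- matrix(0L, nrow = nrow(lin), ncol = sim$n_regions,
                   dimnames = list(NULL, paste0("region_", seq_len(sim$n_regions))))
  for (r in seq_len(nrow(lin))) onehot[r, lin$range[[r]]] <- 1L
  dplyr::bind_cols(tibble::tibble(taxon = paste0("t", lin$lineage)),
                   tibble::as_tibble(onehot))
}
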