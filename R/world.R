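# The simulated lymph-node volume: a toroidal 3D lattice carrying per-site
# free-virion counts and an IFN-beta concentration field, plus the cell
# agents (cytotoxic T cells, epithelial targets, macrophages).
#
# Agents are stored struct-of-arrays (parallel vectors) for speed; sites are
# linear indices 1..prod(dims).

# T-cell state codes
.TC_NAIVE <- 1L
.TC_ACTIVE <- 2L
.TC_DUP <- 3L
.TC_REST <- 4L

# Epithelial status codes
.EP_HEALTHY <- 1L
.EP_INFECTED <- 2L
.EP_PRESENTING <- 3L
.EP_DEAD <- 4L

#' World (lattice and population) configuration
#'
#' Structural parameters of the simulated volume.  The volume represents a
#' 10 microliter fraction of the lymphatic system; lattice dimensions and
#' cell numbers are model choices (they are not dictated by the biology)
#' sized for desk-scale runs.
#'
#' @param dims Integer vector of three positive site counts.
#' @param n_tc Initial number of (naive) cytotoxic T cells.
#' @param n_epi Number of epithelial target cells.
#' @param n_mac Number of macrophages.
#' @param volume_ul Simulated volume in microliters.
#' @param target_naive Homeostasis target for the naive T-cell pool
#'   (defaults to `n_tc`).
#' @param seed Optional integer seed applied by [create_world()].
#'
#' @return A list of class `"world_config"`.
#' @export
world_config <- function(dims = c(8L, 8L, 8L), n_tc = 1024L, n_epi = 2048L,
                         n_mac = 128L, volume_ul = 10, target_naive = n_tc,
                         seed = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || anyNA(dims) || any(dims <= 0L)) {
    stop("`dims` must be three positive integers", call. = FALSE)
  }
  if (n_tc < 0 || n_epi < 0 || n_mac < 0 || volume_ul <= 0) {
    stop("population sizes must be non-negative and volume positive",
         call. = FALSE)
  }
  structure(list(dims = dims, n_tc = as.integer(n_tc),
                 n_epi = as.integer(n_epi), n_mac = as.integer(n_mac),
                 volume_ul = volume_ul,
                 target_naive = as.integer(target_naive), seed = seed),
            class = "world_config")
}

#' Full simulator configuration
#'
#' Aggregates the four parameter groups of the simulator.
#'
#' @param world A [world_config()].
#' @param affinity An [affinity_params()].
#' @param dynamics A [dynamics_params()].
#' @param attrition An [attrition_params()].
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(world = world_config(), affinity = affinity_params(),
                       dynamics = dynamics_params(),
                       attrition = attrition_params()) {
  structure(list(world = world, affinity = affinity, dynamics = dynamics,
                 attrition = attrition),
            class = "sim_config")
}

# 6-neighbourhood with toroidal wrap, as an n_sites x 6 index matrix.
build_neighbors <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  idx <- seq_len(n) - 1L
  x <- idx %% nx
  y <- (idx %/% nx) %% ny
  z <- idx %/% (nx * ny)
  lin <- function(x, y, z) 1L + x + nx * (y + ny * z)
  cbind(lin((x + 1L) %% nx, y, z),
        lin((x - 1L + nx) %% nx, y, z),
        lin(x, (y + 1L) %% ny, z),
        lin(x, (y - 1L + ny) %% ny, z),
        lin(x, y, (z + 1L) %% nz),
        lin(x, y, (z - 1L + nz) %% nz))
}

#' Toroidal 6-neighbourhood of a lattice site
#'
#' @param site Linear site index in `1..prod(dims)`.
#' @param dims Lattice dimensions.
#'
#' @return Integer vector of the six (wrapped) neighbour indices; on
#'   degenerate lattices neighbours may repeat (a 1x1x1 world is its own
#'   neighbour six times).
#' @export
site_neighbors <- function(site, dims) {
  dims <- as.integer(dims)
  n <- prod(dims)
  if (site < 1L || site > n) stop("`site` outside the lattice", call. = FALSE)
  build_neighbors(dims)[site, ]
}

# empty agent tables ----------------------------------------------------

empty_tc <- function() {
  list(receptor = integer(0), site = integer(0), state = integer(0),
       memory = logical(0), age = integer(0), divisions = integer(0),
       div_clock = integer(0), stim_clock = integer(0),
       stim_strain = integer(0))
}

tc_keep <- function(tc, keep) {
  lapply(tc, `[`, keep)
}

tc_bind <- function(tc, new) {
  Map(c, tc, new)
}

#' Create a naive homeostatic world
#'
#' Builds the initial simulation state: no virus, no interferon, no memory
#' cells; naive T cells with uniform receptors, epithelial cells and
#' macrophages placed uniformly at random on the lattice.  Naive ages are
#' drawn from the geometric steady state implied by the homeostatic
#' turnover rate, so the starting population is not artificially young.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; defaults to `config$world$seed`.
#'   When `NULL`, the current RNG state is used.
#'
#' @return An object of class `"sim_state"`.
#' @examples
#' w <- create_world(sim_config(world_config(dims = c(2, 2, 2), n_tc = 16,
#'                                           n_epi = 16, n_mac = 2)),
#'                   seed = 1)
#' w$step
#' @export
create_world <- function(config = sim_config(), seed = config$world$seed) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config` object", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  wc <- config$world
  n_sites <- prod(wc$dims)
  nbr <- build_neighbors(wc$dims)

  tc <- empty_tc()
  n <- wc$n_tc
  if (n > 0L) {
    tc$receptor <- sample_repertoire(n, config$affinity)
    tc$site <- sample.int(n_sites, n, replace = TRUE)
    tc$state <- rep(.TC_NAIVE, n)
    tc$memory <- rep(FALSE, n)
    tc$age <- if (config$dynamics$death_naive > 0) {
      stats::rgeom(n, prob = min(1, config$dynamics$death_naive))
    } else {
      integer(n)
    }
    tc$divisions <- integer(n)
    tc$div_clock <- integer(n)
    tc$stim_clock <- rep(9999L, n)
    tc$stim_strain <- integer(n)
  }

  epi <- list(site = if (wc$n_epi > 0L)
                sample.int(n_sites, wc$n_epi, replace = TRUE) else integer(0),
              status = rep(.EP_HEALTHY, wc$n_epi),
              ivirus = numeric(wc$n_epi),
              strain = integer(wc$n_epi))

  mac_site <- if (wc$n_mac > 0L)
    sample.int(n_sites, wc$n_mac, replace = TRUE) else integer(0)

  structure(list(
    step = 0L,
    alive = TRUE,
    dims = wc$dims,
    n_sites = n_sites,
    nbr = nbr,
    virus = matrix(0, nrow = n_sites, ncol = 0),
    ifn = numeric(n_sites),
    strains = list(),
    tc = tc,
    epi = epi,
    mac_site = mac_site,
    eng = matrix(0, nrow = 0, ncol = 2,
                 dimnames = list(NULL, c("naive", "memory"))),
    cfg = config,
    rec = NULL
  ), class = "sim_state")
}

#' Register a virus strain with the world
#'
#' Adds a strain (with a zeroed virion field) so that per-strain counts and
#' match classes are tracked from this step on.  Injection registers
#' strains automatically; explicit registration is useful to track a
#' challenge strain from the start of a run.
#'
#' @param state A `"sim_state"`.
#' @param strain A [virus_strain()].
#'
#' @return The updated state.
#' @export
register_strain <- function(state, strain) {
  if (!inherits(strain, "virus_strain")) {
    stop("`strain` must be a `virus_strain` object", call. = FALSE)
  }
  if (strain$id %in% vapply(state$strains, `[[`, "", "id")) {
    return(state)
  }
  state$strains[[length(state$strains) + 1L]] <- strain
  state$virus <- cbind(state$virus, numeric(state$n_sites))
  ids <- vapply(state$strains, `[[`, "", "id")
  colnames(state$virus) <- ids
  state$eng <- rbind(state$eng, c(0, 0))
  rownames(state$eng) <- ids
  state
}

strain_index <- function(state, strain) {
  id <- if (inherits(strain, "virus_strain")) strain$id else as.character(strain)
  ids <- vapply(state$strains, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) stop("strain `", id, "` is not registered", call. = FALSE)
  i
}

#' Inject free virions into the volume
#'
#' Adds `round(dose_per_ul * volume_ul)` virions of the given strain,
#' distributed uniformly at random over lattice sites.  The strain is
#' registered if it is not already.
#'
#' @param state A `"sim_state"`.
#' @param strain A [virus_strain()].
#' @param dose_per_ul Virions per microliter (the shipped protocol uses the
#'   saturating dose 1e3).
#' @param volume_ul Injection volume; defaults to the world volume.
#'
#' @return The updated state.
#' @export
inject_virus <- function(state, strain, dose_per_ul,
                         volume_ul = state$cfg$world$volume_ul) {
  if (dose_per_ul < 0) stop("`dose_per_ul` must be >= 0", call. = FALSE)
  state <- register_strain(state, strain)
  total <- round(dose_per_ul * volume_ul)
  if (total == 0) return(state)
  i <- strain_index(state, strain)
  sites <- sample.int(state$n_sites, total, replace = TRUE)
  state$virus[, i] <- state$virus[, i] + tabulate(sites, state$n_sites)
  state
}

#' @export
print.sim_state <- function(x, ...) {
  st <- tabulate(x$tc$state, 4L)
  cat(sprintf("<sim_state> step %d (%s), %dx%dx%d lattice\n", x$step,
              if (x$alive) "alive" else "dead",
              x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("  Tc: %d (naive %d, active %d, duplicating %d, resting %d; memory %d)\n",
              length(x$tc$site), st[1], st[2], st[3], st[4],
              sum(x$tc$memory)))
  cat(sprintf("  epithelial: %d healthy / %d infected+presenting / %d dead\n",
              sum(x$epi$status == .EP_HEALTHY),
              sum(x$epi$status == .EP_INFECTED | x$epi$status == .EP_PRESENTING),
              sum(x$epi$status == .EP_DEAD)))
  if (length(x$strains)) {
    v <- colSums(x$virus) + vapply(seq_along(x$strains), function(i) {
      sum(x$epi$ivirus[x$epi$strain == i])
    }, numeric(1))
    cat("  virions:", paste(sprintf("%s=%g", colnames(x$virus), v),
                            collapse = ", "), "\n")
  }
  cat(sprintf("  IFN-beta total: %.3g pg/ml\n", sum(x$ifn)))
  invisible(x)
}
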