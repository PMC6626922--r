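# Type-I interferon driven attrition: macrophage secretion of IFN-beta at
# danger sites, local diffusion/decay of the field, and the age- and
# affinity-dependent stochastic culling of cytotoxic T cells.

#' Attrition parameters
#'
#' Constants of the attrition death probability
#' `Pr[die] = a^n1 / (a^n1 + k1) * (alpha * i^n2) / (alpha * i^n2 + k2) * (1 - f)`
#' where `a` is cell age in days, `i` the local IFN-beta concentration in
#' pg/ml and `f` the affinity to the currently presented peptide.  `k1` and
#' `k2` are treated as pure numbers on the stated unit scales (days, pg/ml).
#' `n1 > n2` makes age the limiting factor, so culling is much stronger for
#' aged memory than for young naive cells.  `alpha` scales the interferon
#' contribution; `alpha = 0` disables attrition entirely (control).
#'
#' Secretion, danger-threshold, diffusion and decay values are calibration
#' parameters of the field model, not measured constants.
#'
#' @param k1 Age half-saturation constant (vs `a^n1`, days scale).
#' @param k2 IFN half-saturation constant (vs `i^n2`, pg/ml scale).
#' @param n1,n2 Hill exponents; `n1 > n2` is required.
#' @param alpha Attrition level, typically in `0..5`.
#' @param secretion_rate IFN-beta added per macrophage per step at danger
#'   sites (pg/ml).
#' @param danger_threshold Free virions per site that trigger secretion.
#' @param diffusion_frac Per-step fraction of a site's IFN shared equally
#'   with its 6 neighbours.
#' @param decay_frac Per-step first-order decay of the IFN field.
#'
#' @return A list of class `"attrition_params"`.
#' @export
attrition_params <- function(k1 = 1e6, k2 = 1e9, n1 = 3, n2 = 2, alpha = 0,
                             secretion_rate = 1e4, danger_threshold = 10,
                             diffusion_frac = 0.5, decay_frac = 0.1) {
  if (k1 <= 0 || k2 <= 0) stop("`k1`, `k2` must be positive", call. = FALSE)
  if (n1 <= n2) stop("`n1` must exceed `n2` (age is the limiting factor)",
                     call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (diffusion_frac < 0 || diffusion_frac > 1 ||
      decay_frac < 0 || decay_frac > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (secretion_rate < 0 || danger_threshold < 0) {
    stop("secretion and threshold must be >= 0", call. = FALSE)
  }
  structure(list(k1 = k1, k2 = k2, n1 = n1, n2 = n2, alpha = alpha,
                 secretion_rate = secretion_rate,
                 danger_threshold = danger_threshold,
                 diffusion_frac = diffusion_frac, decay_frac = decay_frac),
            class = "attrition_params")
}

#' Attrition death probability
#'
#' The per-step probability that a cytotoxic T cell of age `age` (days)
#' exposed to local IFN-beta concentration `ifn` (pg/ml) dies by bystander
#' attrition, given its affinity `f` to the currently presented peptide.
#' Zero whenever `alpha = 0`, `f = 1`, `age = 0` or `ifn = 0`; monotone
#' increasing in age, interferon and `alpha`, decreasing in `f`.
#'
#' @param age Cell age in days (>= 0); vectorised.
#' @param ifn Local IFN-beta concentration in pg/ml (>= 0); vectorised.
#' @param f Affinity in `[0, 1]`; vectorised.
#' @param params An [attrition_params()] object.
#'
#' @return Death probability in `[0, 1]`.
#' @examples
#' attrition_death_prob(100, 1e3, 0, attrition_params(alpha = 1))
#' @export
attrition_death_prob <- function(age, ifn, f, params = attrition_params()) {
  if (any(age < 0) || any(ifn < 0) || any(f < 0) || any(f > 1)) {
    stop("`age`, `ifn` must be >= 0 and `f` in [0, 1]", call. = FALSE)
  }
  a <- age^params$n1
  i <- params$alpha * ifn^params$n2
  (a / (a + params$k1)) * (i / (i + params$k2)) * (1 - f)
}

#' Macrophage secretion of IFN-beta at danger sites
#'
#' Each macrophage sitting at a site whose total free-virion count is at or
#' above the danger threshold adds `secretion_rate` pg/ml to that site's
#' IFN-beta field (the danger-signal trigger of active attrition).
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
secrete_ifn <- function(state) {
  if (!length(state$mac_site) || !length(state$strains)) return(state)
  ap <- state$cfg$attrition
  vtot <- if (ncol(state$virus) == 1L) state$virus[, 1] else rowSums(state$virus)
  hot <- state$mac_site[vtot[state$mac_site] >= ap$danger_threshold]
  if (!length(hot)) return(state)
  state$ifn <- state$ifn + ap$secretion_rate * tabulate(hot, state$n_sites)
  state
}

#' IFN-beta field diffusion and decay
#'
#' Deterministic local transport: each site sends `diffusion_frac` of its
#' concentration split equally to its six neighbours, then the whole field
#' decays by `decay_frac`, so total mass is `(1 - decay_frac)` times the
#' previous total.  A uniform field is unchanged by the diffusion part.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
update_ifn_field <- function(state) {
  ap <- state$cfg$attrition
  c0 <- state$ifn
  if (sum(c0) == 0) return(state)
  inflow <- numeric(state$n_sites)
  share <- ap$diffusion_frac * c0 / 6
  for (k in 1:6) {
    inflow[state$nbr[, k]] <- inflow[state$nbr[, k]] + share
  }
  state$ifn <- ((1 - ap$diffusion_frac) * c0 + inflow) * (1 - ap$decay_frac)
  state
}

#' Attrition culling of cytotoxic T cells
#'
#' Each T cell dies with probability
#' [attrition_death_prob()]`(age, ifn[site], f_best)`, where `f_best` is
#' the cell's best affinity to any currently presented peptide (0 if it
#' matches none above the cut-off -- such cells are maximally exposed).
#' Removal is immediate.  When `alpha = 0` the step is skipped without
#' consuming random draws, so an `alpha = 0` run is step-for-step identical
#' to one with attrition absent.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
apply_attrition <- function(state) {
  ap <- state$cfg$attrition
  n <- length(state$tc$site)
  if (ap$alpha == 0 || n == 0L || sum(state$ifn) == 0) return(state)
  presented <- unique(state$epi$strain[state$epi$status == .EP_PRESENTING])
  f_best <- numeric(n)
  for (s in presented) {
    f_best <- pmax(f_best, tc_affinity(state, state$strains[[s]]$peptide))
  }
  p <- attrition_death_prob(state$tc$age / 3, state$ifn[state$tc$site],
                            f_best, ap)
  die <- stats::runif(n) < p
  if (any(die)) state$tc <- tc_keep(state$tc, which(!die))
  state
}
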