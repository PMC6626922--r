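# Per-step stochastic update rules: infection, intracellular replication and
# burst, peptide presentation, antigen-competition stimulation, clonal
# expansion under a Hayflick cap, cytotoxic killing, and homeostasis.
#
# One simulation step is 8 h.  Phase order is fixed (see advance()); ties
# inside a phase are resolved by seeded draws, so a run is fully determined
# by its seed.

#' Dynamics parameters
#'
#' Rates and state-machine constants of the cellular dynamics.  None of
#' these is measured directly; they are calibration parameters with shipped
#' defaults chosen so that a saturating primary infection peaks and clears
#' (see the package vignette for the calibration account).
#'
#' @param hayflick_cap Maximum divisions per lineage (replicative
#'   senescence).
#' @param div_time_naive,div_time_memory Steps between divisions for
#'   naive-derived and memory effectors; memory divides faster.
#' @param act_prob_scale Probability that a presenting cell's engagement
#'   slot is used at all in a step (1 = always).
#' @param act_delay_naive Steps an engaged naive cell spends in the
#'   activated state before it becomes an armed, duplicating effector;
#'   memory skips this delay entirely (speed of deployment).
#' @param memory_speed_factor Multiplier (>= 1) on a memory cell's weight in
#'   the competition for a presenting cell; together with the skipped
#'   activation delay this realises memory's speed of deployment.
#' @param kill_prob_scale Scale on the per-contact kill probability
#'   `kill_prob_scale * f(m)`.
#' @param burst_threshold Intracellular virions at which an infected cell
#'   lyses and releases its content.
#' @param stim_timeout Steps without re-engagement after which an effector
#'   stops dividing and enters contraction.
#' @param mem_diff_prob Per-step probability scale for memory
#'   differentiation of an unstimulated effector; the realised probability
#'   is `mem_diff_prob * f(m)^mem_diff_exponent` against the strain that
#'   stimulated the lineage, so high-affinity lineages seed memory
#'   preferentially (affinity-biased memory selection).
#' @param mem_diff_exponent Exponent on the affinity in the memory
#'   differentiation probability; values above 1 concentrate the memory
#'   pool in the top match classes.
#' @param mem_division_budget Divisions a resting memory cell retains under
#'   the Hayflick cap (replicative senescence: a recalled memory lineage can
#'   expand at most `2^mem_division_budget`-fold, whereas a naive lineage
#'   has the full cap available).
#' @param contraction_death Per-step death probability of an unstimulated
#'   effector.
#' @param death_naive,death_memory Per-step homeostatic death probabilities
#'   of naive and memory cells; memory is long-lived.
#' @param influx_gain Per-step fraction of the naive-pool deficit restored
#'   by thymic influx.
#' @param move_prob Per-step probability that a T cell hops to a random
#'   neighbour site.
#' @param virus_diff_frac Per-step fraction of free virions that random-walk
#'   to a neighbour site.
#' @param virus_decay_frac Per-step first-order decay of free virions.
#' @param epi_regen_prob Per-step probability that a dead epithelial cell is
#'   replaced by a healthy one.
#'
#' @return A list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(hayflick_cap = 12L, div_time_naive = 2L,
                            div_time_memory = 1L, act_prob_scale = 1,
                            act_delay_naive = 5L,
                            memory_speed_factor = 12, kill_prob_scale = 1,
                            burst_threshold = 64, stim_timeout = 6L,
                            mem_diff_prob = 0.9, mem_diff_exponent = 3,
                            contraction_death = 0.05,
                            mem_division_budget = 2L,
                            death_naive = 0.005, death_memory = 5e-4,
                            influx_gain = 0.1, move_prob = 0.5,
                            virus_diff_frac = 0.5, virus_decay_frac = 0.4,
                            epi_regen_prob = 0.01) {
  p <- list(hayflick_cap = as.integer(hayflick_cap),
            div_time_naive = as.integer(div_time_naive),
            div_time_memory = as.integer(div_time_memory),
            act_prob_scale = act_prob_scale,
            act_delay_naive = as.integer(act_delay_naive),
            memory_speed_factor = memory_speed_factor,
            kill_prob_scale = kill_prob_scale,
            burst_threshold = burst_threshold,
            stim_timeout = as.integer(stim_timeout),
            mem_diff_prob = mem_diff_prob,
            mem_diff_exponent = mem_diff_exponent,
            mem_division_budget = as.integer(mem_division_budget),
            contraction_death = contraction_death,
            death_naive = death_naive, death_memory = death_memory,
            influx_gain = influx_gain, move_prob = move_prob,
            virus_diff_frac = virus_diff_frac,
            virus_decay_frac = virus_decay_frac,
            epi_regen_prob = epi_regen_prob)
  probs <- c("act_prob_scale", "mem_diff_prob", "contraction_death",
             "death_naive", "death_memory", "influx_gain", "move_prob",
             "virus_diff_frac", "virus_decay_frac", "epi_regen_prob")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$memory_speed_factor < 1) {
    stop("`memory_speed_factor` must be >= 1", call. = FALSE)
  }
  if (p$mem_diff_prob + p$contraction_death > 1) {
    stop("`mem_diff_prob` + `contraction_death` must be <= 1", call. = FALSE)
  }
  if (p$mem_diff_exponent < 0) {
    stop("`mem_diff_exponent` must be >= 0", call. = FALSE)
  }
  if (p$mem_division_budget < 0) {
    stop("`mem_division_budget` must be >= 0", call. = FALSE)
  }
  if (p$act_delay_naive < 1) {
    stop("`act_delay_naive` must be >= 1", call. = FALSE)
  }
  if (p$hayflick_cap < 0 || p$div_time_naive < 1 || p$div_time_memory < 1 ||
      p$stim_timeout < 0 || p$burst_threshold < 0 || p$kill_prob_scale < 0) {
    stop("invalid dynamics constants", call. = FALSE)
  }
  structure(p, class = "dynamics_params")
}

# Per-cell affinity weights of all T cells against one peptide; zero below
# the binding cut-off.
tc_affinity <- function(state, peptide) {
  aff <- state$cfg$affinity
  m <- tcr_pmhc_match(state$tc$receptor, peptide, aff)
  affinity_potential(m, aff)
}

#' Infection of epithelial cells by free virions
#'
#' Each healthy epithelial cell co-located with `v` free virions of a strain
#' with infectivity `q` becomes infected with probability `1 - (1 - q)^v`
#' (one independent contact per virion).  Each infecting virion moves from
#' the field into the cell interior; infections at a site never exceed the
#' virions present there.  With several strains at one site, the infecting
#' strain is drawn in seeded random strain order, so the locally dominant
#' strain wins in proportion to its virions.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_infection <- function(state) {
  if (!length(state$strains) || sum(state$virus) == 0) return(state)
  act <- which(colSums(state$virus) > 0)
  ord <- if (length(act) > 1L) act[sample.int(length(act))] else act
  for (s in ord) {
    v <- state$virus[, s]
    q <- state$strains[[s]]$infectivity
    if (q == 0 || sum(v) == 0) next
    healthy <- which(state$epi$status == .EP_HEALTHY)
    if (!length(healthy)) break
    p_site <- 1 - (1 - q)^v
    hit <- healthy[stats::runif(length(healthy)) < p_site[state$epi$site[healthy]]]
    if (!length(hit)) next
    cnt <- tabulate(state$epi$site[hit], state$n_sites)
    over <- which(cnt > v)
    if (length(over)) {
      # more cells hit than virions present: subsample to the available count
      drop <- unlist(lapply(over, function(ss) {
        at <- hit[state$epi$site[hit] == ss]
        at[sample.int(length(at), length(at) - v[ss])]
      }))
      hit <- setdiff(hit, drop)
      cnt <- tabulate(state$epi$site[hit], state$n_sites)
    }
    state$epi$status[hit] <- .EP_INFECTED
    state$epi$ivirus[hit] <- 1
    state$epi$strain[hit] <- s
    state$virus[, s] <- v - cnt
  }
  state
}

#' Intracellular replication, burst and the lethal-load rule
#'
#' Intracellular virions multiply by the strain's replication factor each
#' step.  A cell reaching the burst threshold lyses: its virions are
#' released to the site's free-virion field and the cell dies.  If any
#' strain's total load (free plus intracellular) exceeds its lethal load
#' per microliter, the host dies and the state's `alive` flag is cleared.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_replication <- function(state) {
  idx <- which(state$epi$ivirus > 0)
  dyn <- state$cfg$dynamics
  if (length(idx)) {
    rates <- vapply(state$strains, `[[`, numeric(1), "replication_rate")
    iv <- state$epi$ivirus[idx] * rates[state$epi$strain[idx]]
    b <- iv >= dyn$burst_threshold
    if (any(b)) {
      bi <- idx[b]
      for (s in unique(state$epi$strain[bi])) {
        sel <- state$epi$strain[bi] == s
        rs <- rowsum(iv[b][sel], state$epi$site[bi][sel])
        at <- as.integer(rownames(rs))
        state$virus[at, s] <- state$virus[at, s] + rs[, 1]
      }
      state$epi$status[bi] <- .EP_DEAD
      state$epi$ivirus[bi] <- 0
      state$epi$strain[bi] <- 0L
    }
    state$epi$ivirus[idx[!b]] <- iv[!b]
  }
  if (length(state$strains)) {
    intr <- vapply(seq_along(state$strains), function(s) {
      sum(state$epi$ivirus[state$epi$strain == s])
    }, numeric(1))
    tot <- colSums(state$virus) + intr
    lethal <- vapply(state$strains, `[[`, numeric(1), "lethal_load")
    if (any(tot / state$cfg$world$volume_ul > lethal)) state$alive <- FALSE
  }
  state
}

#' Peptide presentation on MHC class I
#'
#' Every infected epithelial cell holding intracellular virus processes
#' endogenous antigen and presents the strain's peptide on MHC class I,
#' becoming visible to cytotoxic T cells.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_presentation <- function(state) {
  idx <- state$epi$status == .EP_INFECTED & state$epi$ivirus > 0
  state$epi$status[idx] <- .EP_PRESENTING
  state
}

# Free-virion transport: binomial random walk to the 6 neighbours plus
# first-order decay.  Each direction shift is a bijection on the torus, so
# per-direction adds never collide.
update_virus_field <- function(state) {
  dyn <- state$cfg$dynamics
  ns <- state$n_sites
  for (s in seq_along(state$strains)) {
    v <- round(state$virus[, s])
    if (sum(v) == 0) {
      state$virus[, s] <- v
      next
    }
    moved <- stats::rbinom(ns, v, dyn$virus_diff_frac)
    stay <- v - moved
    add <- numeric(ns)
    rem <- moved
    for (k in 1:6) {
      dk <- if (k < 6L) stats::rbinom(ns, rem, 1 / (7 - k)) else rem
      rem <- rem - dk
      add[state$nbr[, k]] <- add[state$nbr[, k]] + dk
    }
    v2 <- stay + add
    state$virus[, s] <- stats::rbinom(ns, v2, 1 - dyn$virus_decay_frac)
  }
  state
}

# T cells hop to a uniformly chosen neighbour with probability move_prob.
step_movement <- function(state) {
  n <- length(state$tc$site)
  if (n == 0L) return(state)
  p <- state$cfg$dynamics$move_prob
  if (p <= 0) return(state)
  mv <- which(stats::runif(n) < p)
  if (!length(mv)) return(state)
  dir <- sample.int(6L, length(mv), replace = TRUE)
  state$tc$site[mv] <- state$nbr[cbind(state$tc$site[mv], dir)]
  state
}

#' Antigen-competition stimulation of T cells
#'
#' The central bottleneck of the model: per step, each presenting cell
#' engages at most one co-located T cell.  Candidates are T cells whose
#' receptor matches the presented peptide at or above the cut-off; the
#' winner is drawn with probability proportional to
#' `f(m) * memory_speed_factor^memory`.  An engaged naive cell becomes
#' active (it starts duplicating one step later); an engaged resting memory
#' cell starts duplicating immediately -- memory is speedy in deployment.
#' Engagement of an already-expanding cell refreshes its stimulation clock.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_stimulation <- function(state) {
  pres <- which(state$epi$status == .EP_PRESENTING)
  ntc <- length(state$tc$site)
  if (!length(pres) || ntc == 0L) return(state)
  dyn <- state$cfg$dynamics
  strs <- sort(unique(state$epi$strain[pres]))
  W <- matrix(0, ntc, length(strs))
  for (k in seq_along(strs)) {
    w <- tc_affinity(state, state$strains[[strs[k]]]$peptide)
    w[state$tc$memory] <- w[state$tc$memory] * dyn$memory_speed_factor
    W[, k] <- w
  }
  tc_by_site <- split(seq_len(ntc), state$tc$site)
  key <- (match(state$epi$strain[pres], strs) - 1L) * state$n_sites +
    state$epi$site[pres]
  npres <- table(key)
  winners <- integer(0)
  win_strain <- integer(0)
  for (j in seq_along(npres)) {
    kk <- as.numeric(names(npres)[j])
    site <- ((kk - 1L) %% state$n_sites) + 1L
    k <- ((kk - 1L) %/% state$n_sites) + 1L
    cand <- tc_by_site[[as.character(site)]]
    if (is.null(cand)) next
    w <- W[cand, k]
    keep <- w > 0
    if (!any(keep)) next
    cand <- cand[keep]
    w <- w[keep]
    slots <- npres[[j]]
    if (dyn$act_prob_scale < 1) {
      slots <- stats::rbinom(1L, slots, dyn$act_prob_scale)
      if (slots == 0L) next
    }
    nsel <- min(slots, length(cand))
    win <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), nsel, prob = w)]
    winners <- c(winners, win)
    win_strain <- c(win_strain, rep(strs[k], length(win)))
  }
  if (!length(winners)) return(state)
  state$tc$stim_clock[winners] <- 0L
  state$tc$stim_strain[winners] <- win_strain
  st <- state$tc$state[winners]
  mem <- state$tc$memory[winners]
  nv <- winners[st == .TC_NAIVE]
  state$tc$state[nv] <- .TC_ACTIVE
  state$tc$div_clock[nv] <- 0L
  rs <- winners[st == .TC_REST]
  state$tc$state[rs] <- .TC_DUP
  state$tc$div_clock[rs] <- 0L
  # per-strain engagement ledger (naive vs memory), used by the MaN analyses
  for (s in unique(win_strain)) {
    sel <- win_strain == s
    state$eng[s, 1] <- state$eng[s, 1] + sum(!mem[sel])
    state$eng[s, 2] <- state$eng[s, 2] + sum(mem[sel])
  }
  state
}

#' Clonal expansion, contraction and memory differentiation
#'
#' Duplicating cells divide every `div_time` steps (memory faster) while
#' recently stimulated and below the Hayflick cap; daughters inherit the
#' receptor and memory flag and are born at age zero.  Activated naive
#' cells start duplicating after a one-step delay.  Effectors whose
#' stimulation clock exceeds the timeout stop dividing: memory-derived
#' effectors return to the resting memory pool, while naive-derived ones
#' die at the contraction rate or differentiate into resting memory with
#' probability `mem_diff_prob` per step.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_proliferation <- function(state) {
  tc <- state$tc
  dyn <- state$cfg$dynamics
  eff <- tc$state == .TC_ACTIVE | tc$state == .TC_DUP
  if (!any(eff)) return(state)
  tc$stim_clock[eff] <- tc$stim_clock[eff] + 1L

  # promote: active -> armed duplicating effector after the naive delay
  act <- which(tc$state == .TC_ACTIVE)
  tc$div_clock[act] <- tc$div_clock[act] + 1L
  prom <- act[tc$div_clock[act] >= dyn$act_delay_naive]
  tc$state[prom] <- .TC_DUP
  tc$div_clock[prom] <- 0L

  # division of stimulated duplicating cells
  dup <- which(tc$state == .TC_DUP)
  if (length(dup)) {
    tc$div_clock[dup] <- tc$div_clock[dup] + 1L
    dt <- ifelse(tc$memory[dup], dyn$div_time_memory, dyn$div_time_naive)
    can <- dup[tc$div_clock[dup] >= dt &
                 tc$divisions[dup] < dyn$hayflick_cap &
                 tc$stim_clock[dup] <= dyn$stim_timeout]
    if (length(can)) {
      tc$div_clock[can] <- 0L
      tc$divisions[can] <- tc$divisions[can] + 1L
      # daughters carry the lineage age (attrition acts on lineage age,
      # so expanding low-affinity clones stay exposed to culling)
      daughters <- list(receptor = tc$receptor[can], site = tc$site[can],
                        state = rep(.TC_DUP, length(can)),
                        memory = tc$memory[can], age = tc$age[can],
                        divisions = tc$divisions[can],
                        div_clock = integer(length(can)),
                        stim_clock = tc$stim_clock[can],
                        stim_strain = tc$stim_strain[can])
      tc <- tc_bind(tc, daughters)
    }
  }

  # contraction of effectors that lost stimulation; naive-derived cells can
  # only differentiate to memory once their stimulating strain is no longer
  # presented anywhere (stimulation has truly ceased)
  to <- which((tc$state == .TC_ACTIVE | tc$state == .TC_DUP) &
                tc$stim_clock > dyn$stim_timeout)
  if (length(to)) {
    mem <- tc$memory[to]
    tc$state[to[mem]] <- .TC_REST
    tc$div_clock[to[mem]] <- 0L
    nm <- to[!mem]
    if (length(nm)) {
      pres_str <- unique(state$epi$strain[state$epi$status == .EP_PRESENTING])
      ceased <- !(tc$stim_strain[nm] %in% pres_str)
      # memory differentiation is affinity-weighted: p = mem_diff_prob * f
      # against the stimulating strain's peptide
      fm <- numeric(length(nm))
      for (s in unique(tc$stim_strain[nm])) {
        if (s < 1L) next
        sel <- tc$stim_strain[nm] == s
        mm <- tcr_pmhc_match(tc$receptor[nm[sel]],
                             state$strains[[s]]$peptide, state$cfg$affinity)
        fm[sel] <- affinity_potential(mm, state$cfg$affinity)
      }
      u <- stats::runif(length(nm))
      die <- nm[u < dyn$contraction_death]
      diff <- nm[ceased & u >= dyn$contraction_death &
                   u < dyn$contraction_death +
                     dyn$mem_diff_prob * fm^dyn$mem_diff_exponent]
      tc$memory[diff] <- TRUE
      tc$state[diff] <- .TC_REST
      tc$div_clock[diff] <- 0L
      # replicative senescence: memory keeps only a small division budget
      tc$divisions[diff] <- pmax(tc$divisions[diff],
                                 dyn$hayflick_cap - dyn$mem_division_budget)
      if (length(die)) tc <- tc_keep(tc, setdiff(seq_along(tc$site), die))
    }
  }
  state$tc <- tc
  state
}

#' Cytotoxic killing of presenting cells
#'
#' Armed effectors -- duplicating cells and resting memory (which keeps an
#' effector-memory phenotype and kills on contact without needing to
#' re-expand first) -- co-located with a presenting cell whose peptide they
#' match at or above the cut-off kill it with probability
#' `kill_prob_scale * f(m)` per step, independently across effectors.  A
#' killed cell's intracellular virus is destroyed.  This immediate killing
#' by resting memory is what makes memory speedy in deployment: a
#' homologous challenge is eliminated while pathogens are still few, so
#' the lack of further stimulation keeps the effector expansion low.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_killing <- function(state) {
  dyn <- state$cfg$dynamics
  if (dyn$kill_prob_scale == 0) return(state)
  pres <- which(state$epi$status == .EP_PRESENTING)
  eff <- which(state$tc$state == .TC_DUP |
                 (state$tc$state == .TC_REST & state$tc$memory))
  if (!length(pres) || !length(eff)) return(state)
  strs <- sort(unique(state$epi$strain[pres]))
  # per-site survival factor prod(1 - scale * f_i) for each presented strain
  surv <- matrix(1, state$n_sites, length(strs))
  for (k in seq_along(strs)) {
    f <- tc_affinity(state, state$strains[[strs[k]]]$peptide)[eff]
    hasf <- f > 0
    if (!any(hasf)) next
    lg <- rowsum(log1p(-pmin(1, dyn$kill_prob_scale * f[hasf])),
                 state$tc$site[eff][hasf])
    at <- as.integer(rownames(lg))
    surv[at, k] <- exp(lg[, 1])
  }
  pk <- 1 - surv[cbind(state$epi$site[pres], match(state$epi$strain[pres], strs))]
  killed <- pres[stats::runif(length(pres)) < pk]
  if (length(killed)) {
    state$epi$status[killed] <- .EP_DEAD
    state$epi$ivirus[killed] <- 0
    state$epi$strain[killed] <- 0L
  }
  state
}

#' Homeostasis: turnover, thymic influx, ageing, tissue regeneration
#'
#' All cells age by one step.  Naive cells die at the homeostatic turnover
#' rate and resting memory at a much lower one; the naive pool is restored
#' toward its target by thymic influx of fresh, age-zero cells with uniform
#' receptors.  Dead epithelial sites slowly regenerate healthy cells.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
step_homeostasis <- function(state) {
  dyn <- state$cfg$dynamics
  tc <- state$tc
  n <- length(tc$site)
  if (n) {
    tc$age <- tc$age + 1L
    dp <- numeric(n)
    dp[tc$state == .TC_NAIVE] <- dyn$death_naive
    dp[tc$state == .TC_REST & tc$memory] <- dyn$death_memory
    doomed <- dp > 0 & stats::runif(n) < dp
    if (any(doomed)) tc <- tc_keep(tc, which(!doomed))
  }
  deficit <- state$cfg$world$target_naive - sum(tc$state == .TC_NAIVE)
  if (deficit > 0L && dyn$influx_gain > 0) {
    k <- stats::rbinom(1L, deficit, dyn$influx_gain)
    if (k > 0L) {
      tc <- tc_bind(tc, list(
        receptor = sample_repertoire(k, state$cfg$affinity),
        site = sample.int(state$n_sites, k, replace = TRUE),
        state = rep(.TC_NAIVE, k), memory = rep(FALSE, k),
        age = integer(k), divisions = integer(k), div_clock = integer(k),
        stim_clock = rep(9999L, k), stim_strain = integer(k)))
    }
  }
  state$tc <- tc
  dead <- which(state$epi$status == .EP_DEAD)
  if (length(dead) && dyn$epi_regen_prob > 0) {
    reg <- dead[stats::runif(length(dead)) < dyn$epi_regen_prob]
    state$epi$status[reg] <- .EP_HEALTHY
  }
  state
}

# Append this step's counts to the run recorder, if one is attached.
record_step <- function(state) {
  rec <- state$rec
  if (is.null(rec)) return(invisible(state))
  t <- state$step
  if (t < 1L || t > rec$horizon) return(invisible(state))
  aff <- state$cfg$affinity
  r8 <- bitwAnd(state$tc$receptor, 255L)
  for (s in seq_along(state$strains)) {
    if (s > rec$n_strains) break
    m <- 8L + .pop8[bitwXor(r8, state$strains[[s]]$peptide) + 1L]
    idx <- (m - 7L) + 9L * state$tc$memory
    cnt <- tabulate(idx, 18L)
    rec$q[t, , 1L, s] <- cnt[1:9]
    rec$q[t, , 2L, s] <- cnt[10:18]
    rec$vir[t, s] <- sum(state$virus[, s]) +
      sum(state$epi$ivirus[state$epi$strain == s])
  }
  rec$tot[t] <- length(state$tc$site)
  invisible(state)
}

#' Advance the simulation by one 8 h step
#'
#' Applies, in fixed order: infection, replication/burst (with the
#' lethal-load check), presentation, free-virion transport, IFN-beta
#' secretion and field update, T-cell movement, stimulation, proliferation,
#' killing, attrition culling, and homeostasis; then increments the clock
#' and emits the per-step count records.  Stepping a dead state is a no-op
#' with a warning.
#'
#' @param state A `"sim_state"`.
#' @return The updated state.
#' @export
advance <- function(state) {
  if (!state$alive) {
    warning("host is dead; advance() is a no-op", call. = FALSE)
    return(state)
  }
  state <- step_infection(state)
  state <- step_replication(state)
  if (!state$alive) {
    state$step <- state$step + 1L
    record_step(state)
    return(state)
  }
  state <- step_presentation(state)
  state <- update_virus_field(state)
  state <- secrete_ifn(state)
  state <- update_ifn_field(state)
  state <- step_movement(state)
  state <- step_stimulation(state)
  state <- step_proliferation(state)
  state <- step_killing(state)
  state <- apply_attrition(state)
  state <- step_homeostasis(state)
  state$step <- state$step + 1L
  record_step(state)
  state
}
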