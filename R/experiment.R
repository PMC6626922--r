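# The antigenic-distance prime/challenge protocol and the (alpha x d)
# replicate grid.  Priming is always with V0; the challenge virus V_d sits
# at bit distance d from it.  Runs are deterministic given their seed.

#' Prime/challenge protocol configuration
#'
#' One `(d, alpha)` experiment: prime with `V0` at `t_I`, challenge with
#' `V_d` at `t_II`, both at a saturating dose, and advance to the horizon.
#' Times are in 8 h steps.
#'
#' @param d Antigenic distance of the challenge virus, in `0..8`.
#' @param alpha Attrition level, in `0..5` (0 = attrition disabled).
#' @param t_I Prime step (default 0: injected before the first step).
#' @param t_II Challenge step (default 1000).
#' @param dose_per_ul Injected dose, virions per microliter (saturating
#'   default 1e3).
#' @param horizon Total steps simulated (default 1300).
#' @param replicates Replicate count for grid runs (default 20; the full
#'   protocol uses 100, see `paper_scale` in [run_grid()]).
#' @param base_seed Base seed for the replicate seed map.
#' @param sim A [sim_config()]; its attrition level is overridden by
#'   `alpha`.
#' @param panel Virus panel as from [virus_panel()].
#'
#' @return A list of class `"protocol_config"`.
#' @export
protocol_config <- function(d = 0L, alpha = 0L, t_I = 0L, t_II = 1000L,
                            dose_per_ul = 1e3, horizon = 1300L,
                            replicates = 20L, base_seed = 20260930L,
                            sim = sim_config(), panel = virus_panel()) {
  d <- as.integer(d); alpha <- as.integer(alpha)
  if (d < 0L || d > 8L) stop("`d` must lie in 0..8", call. = FALSE)
  if (alpha < 0L) stop("`alpha` must be >= 0", call. = FALSE)
  if (!(t_I < t_II && t_II < horizon)) {
    stop("need t_I < t_II < horizon", call. = FALSE)
  }
  structure(list(d = d, alpha = alpha, t_I = as.integer(t_I),
                 t_II = as.integer(t_II), dose_per_ul = dose_per_ul,
                 horizon = as.integer(horizon),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), sim = sim,
                 panel = panel),
            class = "protocol_config")
}

# Recorder environment pre-allocated for a run.
make_recorder <- function(horizon, strain_ids) {
  rec <- new.env(parent = emptyenv())
  rec$horizon <- horizon
  rec$n_strains <- length(strain_ids)
  rec$q <- array(NA_real_, dim = c(horizon, 9L, 2L, length(strain_ids)),
                 dimnames = list(NULL, as.character(8:16),
                                 c("naive", "memory"), strain_ids))
  rec$vir <- matrix(NA_real_, horizon, length(strain_ids),
                    dimnames = list(NULL, strain_ids))
  rec$tot <- rep(NA_real_, horizon)
  rec
}

finish_run <- function(state, config, seed, challenge_id, injections) {
  rec <- state$rec
  run <- structure(list(
    q = rec$q, virions = rec$vir, total_tc = rec$tot,
    eng = state$eng, alive = state$alive, steps = state$step,
    t_I = config$t_I, t_II = config$t_II, horizon = config$horizon,
    d = config$d, alpha = config$alpha, seed = seed,
    challenge = challenge_id, injections = injections,
    affinity = state$cfg$affinity,
    strains = state$strains), class = "man_run")
  run$t_c <- time_to_clear(run)
  run$cleared <- !is.na(run$t_c)
  run
}

#' Run one prime/challenge experiment
#'
#' Creates a naive world, injects `V0` at `t_I` and `V_d` at `t_II` (both
#' strains are registered from the start so their match-class series cover
#' the whole run), and advances to the horizon or host death.  Dead-host
#' runs are returned with `alive = FALSE`, never dropped.
#'
#' @param config A [protocol_config()].
#' @param seed Integer seed; the run is fully reproducible given
#'   `(config, seed)`.
#'
#' @return An object of class `"man_run"`: per-step match-class count
#'   arrays `q[step, class, naive/memory, strain]`, per-strain virion
#'   series, total T-cell series, the per-strain engagement ledger `eng`,
#'   clearance info (`t_c`, `cleared`) and the run metadata.
#' @export
run_protocol <- function(config = protocol_config(), seed = config$base_seed) {
  set.seed(seed)
  sim <- config$sim
  sim$attrition$alpha <- config$alpha
  state <- create_world(sim, seed = NULL)
  vI <- config$panel[["V0"]]
  vII <- config$panel[[paste0("V", config$d)]]
  state <- register_strain(state, vI)
  state <- register_strain(state, vII)  # no-op when d = 0
  ids <- vapply(state$strains, `[[`, "", "id")
  state$rec <- make_recorder(config$horizon, ids)
  while (state$step < config$horizon && state$alive) {
    if (state$step == config$t_I) {
      state <- inject_virus(state, vI, config$dose_per_ul)
    }
    if (state$step == config$t_II) {
      state <- inject_virus(state, vII, config$dose_per_ul)
    }
    state <- advance(state)
  }
  finish_run(state, config, seed, vII$id,
             injections = data.frame(step = c(config$t_I, config$t_II),
                                     strain = c(vI$id, vII$id),
                                     dose_per_ul = config$dose_per_ul))
}

#' Three-virus run: co-injected homologous and heterologous challenge
#'
#' Primes with `V0`, then at `t_II` co-injects the cross-reacting `V2` and
#' the fully heterologous `V8`, so the MaN silencing of the naive anti-`V2`
#' response and the undisturbed naive anti-`V8` response can be separated
#' in one animal.  Per-strain series are recorded for all three strains.
#'
#' @param config A [protocol_config()]; its `d` is ignored.
#' @param seed Integer seed.
#' @param dose2_per_ul,dose8_per_ul Challenge doses for `V2` and `V8`
#'   (default: the protocol dose).  A zero dose skips that strain's
#'   injection, reducing to [run_protocol()].
#'
#' @return A `"man_run"` whose challenge strain is `V2`.
#' @export
three_virus_run <- function(config = protocol_config(d = 2L),
                            seed = config$base_seed,
                            dose2_per_ul = config$dose_per_ul,
                            dose8_per_ul = config$dose_per_ul) {
  set.seed(seed)
  sim <- config$sim
  sim$attrition$alpha <- config$alpha
  state <- create_world(sim, seed = NULL)
  v0 <- config$panel[["V0"]]
  v2 <- config$panel[["V2"]]
  v8 <- config$panel[["V8"]]
  state <- register_strain(state, v0)
  state <- register_strain(state, v2)
  state <- register_strain(state, v8)
  ids <- vapply(state$strains, `[[`, "", "id")
  state$rec <- make_recorder(config$horizon, ids)
  while (state$step < config$horizon && state$alive) {
    if (state$step == config$t_I) {
      state <- inject_virus(state, v0, config$dose_per_ul)
    }
    if (state$step == config$t_II) {
      if (dose2_per_ul > 0) state <- inject_virus(state, v2, dose2_per_ul)
      if (dose8_per_ul > 0) state <- inject_virus(state, v8, dose8_per_ul)
    }
    state <- advance(state)
  }
  cfg2 <- config; cfg2$d <- 2L
  finish_run(state, cfg2, seed, "V2",
             injections = data.frame(step = c(config$t_I, config$t_II,
                                              config$t_II),
                                     strain = c("V0", "V2", "V8"),
                                     dose_per_ul = c(config$dose_per_ul,
                                                     dose2_per_ul,
                                                     dose8_per_ul)))
}

#' Deterministic seed for a grid cell replicate
#'
#' Injective, version-stable map `(d, alpha, replicate) -> seed` used by
#' [run_grid()]; replicates must stay below 10,000 and alpha below 21.
#'
#' @param d,alpha,replicate Grid coordinates (replicate is 1-based).
#' @param base_seed Base seed.
#' @return An integer seed below 2^31.
#' @export
grid_seed <- function(d, alpha, replicate, base_seed = 20260930L) {
  stopifnot(replicate >= 1, replicate < 1e4, alpha >= 0, alpha <= 20,
            d >= 0, d <= 8)
  as.integer(base_seed + 1e5 * alpha + 1e4 * d + (replicate - 1))
}

#' Scalar summaries of one run
#'
#' The per-run quantities the grid analyses consume: clearance status and
#' `t_c`, post-challenge peak total affinity, peak total T-cell count
#' (`M_tilde`), per-binding-class affinity peaks and the efficacy `E`.
#'
#' @param run A `"man_run"`.
#' @return A one-row data frame.
#' @export
run_summary <- function(run) {
  w <- challenge_window(run)
  qa <- run$q[, , 1L, run$challenge] + run$q[, , 2L, run$challenge]
  ta <- total_affinity(qa, run$affinity)
  pk_class <- apply(qa[w, , drop = FALSE], 2L, max, na.rm = TRUE) *
    affinity_potential(8:16, run$affinity)
  data.frame(d = run$d, alpha = run$alpha, seed = run$seed,
             alive = run$alive, cleared = run$cleared,
             prime_cleared = unname(run$virions[run$t_II, "V0"] == 0),
             t_c = if (is.na(run$t_c)) NA_integer_ else run$t_c,
             peak_TA = suppressWarnings(max(ta[w], na.rm = TRUE)),
             M_tilde = suppressWarnings(max(run$total_tc[w], na.rm = TRUE)),
             peak_A13 = pk_class["13"], peak_A14 = pk_class["14"],
             peak_A15 = pk_class["15"], peak_A16 = pk_class["16"],
             E = efficacy(run), row.names = NULL)
}

#' Run the (alpha x d) experiment grid
#'
#' Executes every combination of the requested attrition levels and
#' antigenic distances with `replicates` seeded repetitions each (the full
#' grid is 6 x 9 = 54 configurations).  Per-run scalar summaries (peak
#' total affinity, time-to-clear, efficacy, peak T-cell count, per-class
#' affinity peaks) are returned as a tidy data frame; full runs are not
#' retained.
#'
#' @param d_values,alpha_values Grid axes (defaults `0:8` and `0:5`).
#' @param replicates Replicates per cell; defaults to the config's value.
#' @param config A [protocol_config()] used for every cell (its `d` and
#'   `alpha` are overridden per cell).
#' @param paper_scale If `TRUE`, use 100 replicates per cell.
#' @param progress Print one line per completed cell.
#'
#' @return A data frame of class `"man_grid"`, one row per
#'   `(d, alpha, replicate)`, with attributes `d_values`, `alpha_values`,
#'   `replicates`, `base_seed` and `n_config`.
#' @export
run_grid <- function(d_values = 0:8, alpha_values = 0:5,
                     replicates = config$replicates,
                     config = protocol_config(), paper_scale = FALSE,
                     progress = FALSE) {
  if (paper_scale) replicates <- 100L
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  rows <- vector("list", length(d_values) * length(alpha_values) * replicates)
  i <- 0L
  for (alpha in alpha_values) {
    for (d in d_values) {
      for (r in seq_len(replicates)) {
        cfg <- config
        cfg$d <- as.integer(d)
        cfg$alpha <- as.integer(alpha)
        seed <- grid_seed(d, alpha, r, config$base_seed)
        run <- run_protocol(cfg, seed)
        i <- i + 1L
        s <- run_summary(run)
        s$replicate <- r
        rows[[i]] <- s
      }
      if (progress) {
        message(sprintf("grid cell d=%d alpha=%d done (%d replicates)",
                        d, alpha, replicates))
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("man_grid", "data.frame"),
            d_values = d_values, alpha_values = alpha_values,
            replicates = replicates, base_seed = config$base_seed,
            n_config = length(d_values) * length(alpha_values))
}

#' @export
print.man_run <- function(x, ...) {
  cat(sprintf("<man_run> d=%d alpha=%d seed=%d: %s, %s\n", x$d, x$alpha,
              x$seed, if (x$alive) "host alive" else "host died",
              if (x$cleared) sprintf("challenge cleared (t_c = %d steps)",
                                     x$t_c)
              else "challenge not cleared (censored)"))
  cat(sprintf("  strains: %s; %d steps recorded; peak Tc count %g\n",
              paste(vapply(x$strains, `[[`, "", "id"), collapse = ", "),
              x$steps, suppressWarnings(max(x$total_tc, na.rm = TRUE))))
  invisible(x)
}

#' @export
summary.man_run <- function(object, ...) {
  s <- run_summary(object)
  cat(sprintf("Prime/challenge run: d=%d, alpha=%d, seed=%d\n",
              object$d, object$alpha, object$seed))
  cat(sprintf("  challenge %s at t_II=%d; %s\n", object$challenge,
              object$t_II,
              if (object$cleared) sprintf("cleared in %d steps", object$t_c)
              else "not cleared"))
  cat(sprintf("  peak TA=%.3f  efficacy E=%.4f  peak Tc count=%g\n",
              s$peak_TA, s$E, s$M_tilde))
  cat(sprintf("  per-class affinity peaks: m=13 %.2f, m=14 %.2f, m=15 %.2f, m=16 %.2f\n",
              s$peak_A13, s$peak_A14, s$peak_A15, s$peak_A16))
  invisible(s)
}
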