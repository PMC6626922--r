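# Deterministic micro-worlds used across the test suite and in examples.

#' Deterministic test fixtures
#'
#' Small, fully specified worlds exercising one mechanism each:
#'
#' * `"cold_world"`: a 2x2x2 world with a small homeostatic population and
#'   no virus; nothing but turnover ever happens.
#' * `"one_site_duel"`: a single-site world holding one presenting cell
#'   (strain `V0`), one aged resting memory cell at the binding cut-off
#'   (m = 13) and one young naive cell at full complementarity (m = 16).
#'   Killing, turnover, influx and viral growth are switched off, so the
#'   only event per step is the single engagement the presenter allows --
#'   the antigen-competition bottleneck in isolation.
#' * `"hot_spot"`: a 2x2x2 world with one macrophage co-located with a
#'   supra-threshold pile of virions and no cells to respond; IFN-beta
#'   secretion and field transport run in isolation.
#'
#' @param name Fixture name.
#' @param seed Integer seed applied before construction.
#'
#' @return A `"sim_state"`.
#' @export
make_fixture <- function(name = c("cold_world", "one_site_duel", "hot_spot"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    cold_world = {
      cfg <- sim_config(world = world_config(dims = c(2L, 2L, 2L),
                                             n_tc = 16L, n_epi = 16L,
                                             n_mac = 2L),
                        dynamics = dynamics_params(death_naive = 0,
                                                   influx_gain = 0))
      create_world(cfg, seed = seed)
    },
    one_site_duel = {
      dyn <- dynamics_params(kill_prob_scale = 0, death_naive = 0,
                             death_memory = 0, influx_gain = 0,
                             epi_regen_prob = 0, move_prob = 0,
                             burst_threshold = Inf, mem_diff_prob = 0,
                             contraction_death = 0,
                             div_time_naive = 3L, div_time_memory = 3L)
      cfg <- sim_config(world = world_config(dims = c(1L, 1L, 1L),
                                             n_tc = 0L, n_epi = 1L,
                                             n_mac = 0L),
                        dynamics = dyn)
      st <- create_world(cfg, seed = seed)
      st <- register_strain(st, virus_strain("V0", 0L,
                                             replication_rate = 1,
                                             infectivity = 0))
      st$epi$status[1] <- .EP_PRESENTING
      st$epi$ivirus[1] <- 1
      st$epi$strain[1] <- 1L
      # memory at the cut-off (5 complementary peptide bits) vs naive at
      # full complementarity (8 of 8)
      st$tc <- tc_bind(st$tc, list(
        receptor = c(31L, 255L), site = c(1L, 1L),
        state = c(.TC_REST, .TC_NAIVE), memory = c(TRUE, FALSE),
        age = c(900L, 30L), divisions = c(0L, 0L),
        div_clock = c(0L, 0L), stim_clock = c(9999L, 9999L),
        stim_strain = c(0L, 0L)))
      st
    },
    hot_spot = {
      cfg <- sim_config(world = world_config(dims = c(2L, 2L, 2L),
                                             n_tc = 0L, n_epi = 0L,
                                             n_mac = 0L))
      st <- create_world(cfg, seed = seed)
      st <- register_strain(st, virus_strain("V0", 0L, infectivity = 0,
                                             replication_rate = 0))
      st$mac_site <- 1L
      st$virus[1L, 1L] <- 100
      st
    })
}
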