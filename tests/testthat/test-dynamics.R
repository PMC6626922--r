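# Unit tests of the per-step rules on forced micro-worlds.

one_site_world <- function(n_epi = 1L, dyn = dynamics_params(), seed = 1) {
  cfg <- sim_config(world = world_config(dims = c(1L, 1L, 1L), n_tc = 0L,
                                         n_epi = n_epi, n_mac = 0L),
                    dynamics = dyn)
  create_world(cfg, seed = seed)
}

add_tc <- function(st, receptor, state = 1L, memory = FALSE, age = 30L,
                   divisions = 0L, stim_clock = 9999L, stim_strain = 0L) {
  n <- length(receptor)
  st$tc <- Map(c, st$tc, list(receptor = as.integer(receptor),
                              site = rep(1L, n), state = rep(state, n),
                              memory = rep(memory, n), age = rep(age, n),
                              divisions = rep(divisions, n),
                              div_clock = integer(n),
                              stim_clock = rep(stim_clock, n),
                              stim_strain = rep(stim_strain, n)))
  st
}

test_that("infection is forced, impossible, or binomial as dictated", {
  st <- one_site_world()
  st <- register_strain(st, virus_strain("V0", 0L, infectivity = 1))
  st$virus[1, 1] <- 1
  st1 <- step_infection(st)
  expect_identical(sum(st1$epi$status == 2L), 1L)
  expect_identical(st1$epi$ivirus[1], 1)
  expect_identical(sum(st1$virus), 0)

  st$strains[[1]]$infectivity <- 0
  st0 <- step_infection(st)
  expect_identical(sum(st0$epi$status == 2L), 0L)

  # 1000 independent virion-cell pairs at infectivity 0.3
  cfg <- sim_config(world = world_config(dims = c(10L, 10L, 10L), n_tc = 0L,
                                         n_epi = 1000L, n_mac = 0L))
  stb <- create_world(cfg, seed = 9)
  stb$epi$site <- 1:1000
  stb <- register_strain(stb, virus_strain("V0", 0L, infectivity = 0.3))
  stb$virus[, 1] <- 1
  set.seed(10)
  stb1 <- step_infection(stb)
  inf <- sum(stb1$epi$status == 2L)
  expect_lt(abs(inf - 300), 3 * sqrt(1000 * 0.3 * 0.7))
})

test_that("intracellular growth doubles, bursts, and trips the lethal load", {
  dyn <- dynamics_params(burst_threshold = Inf)
  st <- one_site_world(dyn = dyn)
  st <- register_strain(st, virus_strain("V0", 0L, replication_rate = 2,
                                         lethal_load = 1e9))
  st$epi$status[1] <- 2L; st$epi$ivirus[1] <- 1; st$epi$strain[1] <- 1L
  for (i in 1:5) st <- step_replication(st)
  expect_identical(st$epi$ivirus[1], 32)

  # replication rate 1 keeps counts constant
  st$strains[[1]]$replication_rate <- 1
  expect_identical(step_replication(st)$epi$ivirus[1], 32)

  # burst releases to the field and kills the cell
  st$cfg$dynamics$burst_threshold <- 32
  stb <- step_replication(st)
  expect_identical(stb$epi$status[1], 4L)
  expect_identical(unname(stb$virus[1, 1]), 32)

  # lethal load zero: any virion kills the host
  st$strains[[1]]$lethal_load <- 0
  expect_false(step_replication(st)$alive)
})

test_that("infected cells present their strain's peptide", {
  st <- one_site_world()
  st <- register_strain(st, virus_strain("V3", 7L))
  expect_identical(sum(step_presentation(st)$epi$status == 3L), 0L)
  st$epi$status[1] <- 2L; st$epi$ivirus[1] <- 1; st$epi$strain[1] <- 1L
  st1 <- step_presentation(st)
  expect_identical(st1$epi$status[1], 3L)
  expect_identical(st1$strains[[st1$epi$strain[1]]]$peptide, 7L)
})

test_that("stimulation respects the per-presenter capacity and the cut-off", {
  # no candidate above the cut-off: no engagement
  st <- one_site_world()
  st <- register_strain(st, virus_strain("V0", 0L))
  st$epi$status[1] <- 3L; st$epi$ivirus[1] <- 1; st$epi$strain[1] <- 1L
  st <- add_tc(st, 15L)  # 4 complementary bits: below m_c
  st1 <- step_stimulation(st)
  expect_identical(sum(st1$eng), 0)
  expect_identical(st1$tc$state, 1L)

  # two presenters, two candidates: both engaged in one step
  st2 <- one_site_world(n_epi = 2L)
  st2 <- register_strain(st2, virus_strain("V0", 0L))
  st2$epi$status[] <- 3L; st2$epi$ivirus[] <- 1; st2$epi$strain[] <- 1L
  st2 <- add_tc(st2, c(255L, 255L))
  st2 <- step_stimulation(st2)
  expect_identical(st2$tc$state, c(2L, 2L))
  expect_identical(sum(st2$eng), 2)

  # engagements never exceed the number of presenting cells
  st3 <- one_site_world(n_epi = 3L)
  st3 <- register_strain(st3, virus_strain("V0", 0L))
  st3$epi$status[] <- 3L; st3$epi$ivirus[] <- 1; st3$epi$strain[] <- 1L
  st3 <- add_tc(st3, rep(255L, 10))
  st3 <- step_stimulation(st3)
  expect_identical(sum(st3$eng), 3)
})

test_that("an engaged memory cell deploys immediately, naive after the delay", {
  dyn <- dynamics_params(act_delay_naive = 4L)
  st <- one_site_world(n_epi = 2L, dyn = dyn)
  st <- register_strain(st, virus_strain("V0", 0L))
  st$epi$status[] <- 3L; st$epi$ivirus[] <- 1; st$epi$strain[] <- 1L
  st <- add_tc(st, 255L, state = 4L, memory = TRUE, age = 900L)
  st <- add_tc(st, 255L, state = 1L)
  st <- step_stimulation(st)
  expect_identical(st$tc$state, c(3L, 2L))  # memory duplicating, naive active
  # the naive cell is promoted only after act_delay_naive proliferation steps
  for (k in 1:3) {
    st <- step_proliferation(st)
    expect_identical(st$tc$state[2], 2L)
  }
  st <- step_proliferation(st)
  expect_identical(st$tc$state[2], 3L)
})

test_that("clonal expansion doubles on schedule and respects the Hayflick cap", {
  dyn <- dynamics_params(div_time_naive = 1L, hayflick_cap = 99L,
                         stim_timeout = 10L)
  st <- one_site_world(dyn = dyn)
  st <- add_tc(st, 200L, state = 3L, stim_clock = 0L, stim_strain = 0L)
  for (k in 1:4) st <- step_proliferation(st)
  expect_identical(length(st$tc$site), 16L)
  expect_true(all(st$tc$receptor == 200L))

  # at the cap, no division
  dyn2 <- dynamics_params(div_time_naive = 1L, hayflick_cap = 3L,
                          stim_timeout = 10L)
  st2 <- one_site_world(dyn = dyn2)
  st2 <- add_tc(st2, 200L, state = 3L, divisions = 3L, stim_clock = 0L)
  st2 <- step_proliferation(st2)
  expect_identical(length(st2$tc$site), 1L)
  expect_true(all(st2$tc$divisions <= 3L))
})

test_that("memory differentiation never happens when its probability is zero", {
  dyn <- dynamics_params(mem_diff_prob = 0, contraction_death = 0.2,
                         stim_timeout = 0L)
  st <- one_site_world(dyn = dyn)
  st <- add_tc(st, rep(255L, 50), state = 3L, stim_clock = 5L,
               stim_strain = 0L)
  set.seed(20)
  for (k in 1:30) st <- step_proliferation(st)
  expect_identical(sum(st$tc$memory), 0L)
})

test_that("killing is certain at full match, graded by affinity, off at zero", {
  mk <- function(scale, receptor, state = 3L) {
    dyn <- dynamics_params(kill_prob_scale = scale)
    cfg <- sim_config(world = world_config(dims = c(1L, 1L, 1L), n_tc = 0L,
                                           n_epi = 1L, n_mac = 0L),
                      affinity = affinity_params(A_L = 0.1),
                      dynamics = dyn)
    st <- create_world(cfg, seed = 1)
    st <- register_strain(st, virus_strain("V0", 0L))
    st$epi$status[1] <- 3L; st$epi$ivirus[1] <- 1; st$epi$strain[1] <- 1L
    add_tc(st, receptor, state = state, stim_clock = 0L)
  }
  expect_identical(step_killing(mk(0, 255L))$epi$status[1], 3L)
  expect_identical(step_killing(mk(1, 255L))$epi$status[1], 4L)

  # m = 13, scale 1: kill probability equals f(13) = A_L = 0.1
  st13 <- mk(1, 31L)
  set.seed(21)
  kills <- sum(vapply(1:4000, function(i) {
    step_killing(st13)$epi$status[1] == 4L
  }, logical(1)))
  expect_lt(abs(kills - 400), 3 * sqrt(4000 * 0.1 * 0.9))

  # resting memory kills on contact; resting non-memory cannot arise,
  # and naive cells never kill
  st <- mk(1, 255L, state = 4L)
  st$tc$memory[1] <- TRUE
  expect_identical(step_killing(st)$epi$status[1], 4L)
  expect_identical(step_killing(mk(1, 255L, state = 1L))$epi$status[1], 3L)
})

test_that("homeostatic influx restores the pool with uniform receptors", {
  cfg <- sim_config(world = world_config(dims = c(4L, 4L, 4L), n_tc = 0L,
                                         n_epi = 0L, n_mac = 0L,
                                         target_naive = 4096L),
                    dynamics = dynamics_params(influx_gain = 1))
  st <- create_world(cfg, seed = 22)
  st <- step_homeostasis(st)
  expect_identical(length(st$tc$site), 4096L)
  expect_true(all(st$tc$age == 0L))  # influx cells are born fresh
  o <- tabulate(st$tc$receptor %/% 4096L + 1L, 16L)
  chi <- sum((o - 256)^2 / 256)
  expect_lt(chi, qchisq(1 - 1e-6, df = 15))
})

test_that("advancing a run twice from one seed gives bit-identical records", {
  cfg <- fast_protocol(d = 2L, sim = sim_config(world = tiny_world_config()))
  r1 <- run_protocol(cfg, seed = 33)
  r2 <- run_protocol(cfg, seed = 33)
  expect_identical(r1$q, r2$q)
  expect_identical(r1$virions, r2$virions)
  expect_identical(r1$t_c, r2$t_c)
})

test_that("a dead state refuses to advance", {
  st <- one_site_world()
  st$alive <- FALSE
  expect_warning(st2 <- advance(st), "dead")
  expect_identical(st2$step, st$step)
})

test_that("one advance() on the one-site duel matches the hand-traced events", {
  st <- make_fixture("one_site_duel", seed = 7)
  set.seed(7)
  st1 <- advance(st)
  # exactly one engagement happened; the presenter survives with its single
  # intracellular virion; nobody died; the clock moved one step
  expect_identical(sum(st1$eng), 1)
  expect_identical(st1$epi$status[1], 3L)
  expect_identical(st1$epi$ivirus[1], 1)
  expect_identical(length(st1$tc$site), 2L)
  expect_identical(st1$step, 1L)
  changed <- which(st1$tc$state != st$tc$state)
  expect_identical(length(changed), 1L)
  if (st1$tc$memory[changed]) {
    expect_identical(st1$tc$state[changed], 3L)  # memory: straight to dup
    expect_identical(unname(st1$eng[1, "memory"]), 1)
  } else {
    expect_identical(st1$tc$state[changed], 2L)  # naive: activated first
    expect_identical(unname(st1$eng[1, "naive"]), 1)
  }
  # and the whole trace is reproducible
  set.seed(7)
  expect_identical(advance(st), st1)
})
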