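test_that("the attrition death probability follows its closed form", {
  ap <- attrition_params(alpha = 1)
  # alpha = 0 is the control: probability identically zero
  ap0 <- attrition_params(alpha = 0)
  grid <- expand.grid(a = c(0, 10, 100, 1e4), i = c(0, 10, 1e3, 1e6),
                      f = c(0, 0.5, 1))
  expect_true(all(attrition_death_prob(grid$a, grid$i, grid$f, ap0) == 0))
  # full protection, newborn cells, or no interferon: zero
  expect_identical(attrition_death_prob(100, 1e3, 1, ap), 0)
  expect_identical(attrition_death_prob(0, 1e3, 0, ap), 0)
  expect_identical(attrition_death_prob(100, 0, 0, ap), 0)
  # printed-constant evaluation: a=100 d, i=1e3 pg/ml, f=0, alpha=1
  expect_equal(attrition_death_prob(100, 1e3, 0, ap),
               0.5 * (1e6 / (1e6 + 1e9)), tolerance = 1e-12)
  expect_error(attrition_death_prob(-1, 0, 0, ap), ">= 0")
  expect_error(attrition_params(n1 = 2, n2 = 2), "n1")
})

test_that("death probability is monotone in age, IFN and alpha, anti-monotone in f", {
  ages <- c(0, 1, 10, 50, 100, 500, 5e3)
  ifns <- c(0, 1, 1e2, 1e3, 1e4, 1e6)
  fs <- c(0, 0.1, 0.25, 0.5, 0.9, 1)
  alphas <- 0:5
  for (alpha in alphas[-1]) {
    ap <- attrition_params(alpha = alpha)
    for (i in ifns) for (f in fs) {
      expect_true(all(diff(attrition_death_prob(ages, i, f, ap)) >= 0))
    }
    for (a in ages) for (f in fs) {
      expect_true(all(diff(attrition_death_prob(a, ifns, f, ap)) >= 0))
    }
    for (a in ages) for (i in ifns) {
      expect_true(all(diff(attrition_death_prob(a, i, fs, ap)) <= 0))
    }
  }
  p_by_alpha <- vapply(alphas, function(al) {
    attrition_death_prob(100, 1e4, 0.2, attrition_params(alpha = al))
  }, numeric(1))
  expect_true(all(diff(p_by_alpha) >= 0))
  # saturation limit
  expect_gte(attrition_death_prob(1e4, 1e6, 0, attrition_params(alpha = 5)),
             0.999)
})

test_that("aged memory is culled far more readily than young naive cells", {
  ap <- attrition_params(alpha = 1)
  p_mem <- attrition_death_prob(300, 1e4, 0, ap)   # aged memory, no match
  p_naive <- attrition_death_prob(20, 1e4, 0, ap)  # young naive, same site
  expect_gt(p_mem / p_naive, 10)
})

test_that("macrophages secrete only at danger sites and the field transports mass", {
  st <- make_fixture("hot_spot")
  sr <- st$cfg$attrition$secretion_rate
  # accumulation without decay or diffusion
  st$cfg$attrition$decay_frac <- 0
  st$cfg$attrition$diffusion_frac <- 0
  s3 <- secrete_ifn(secrete_ifn(secrete_ifn(st)))
  expect_identical(s3$ifn[1], 3 * sr)
  # a macrophage at a cold site stays silent
  cold <- st
  cold$virus[1, 1] <- 0
  expect_identical(sum(secrete_ifn(cold)$ifn), 0)

  # mass conservation under pure diffusion
  st2 <- make_fixture("hot_spot")
  st2$cfg$attrition$decay_frac <- 0
  st2$ifn[3] <- 120
  expect_equal(sum(update_ifn_field(st2)$ifn), 120)
  # a uniform field is a fixed point of diffusion
  st2$ifn[] <- 7
  expect_equal(update_ifn_field(st2)$ifn, rep(7, st2$n_sites))

  # point-source stencil on a 4x4x4 torus, one step, by hand
  cfg <- sim_config(world = world_config(dims = c(4L, 4L, 4L), n_tc = 0L,
                                         n_epi = 0L, n_mac = 0L))
  st3 <- create_world(cfg, seed = 1)
  dfrac <- st3$cfg$attrition$diffusion_frac
  dec <- st3$cfg$attrition$decay_frac
  st3$ifn[22] <- 60
  out <- update_ifn_field(st3)$ifn
  expect_equal(out[22], (1 - dfrac) * 60 * (1 - dec))
  nb <- site_neighbors(22, c(4, 4, 4))
  expect_equal(unname(out[nb]), rep(dfrac * 60 / 6 * (1 - dec), 6))
  expect_equal(sum(out[-c(22, nb)]), 0)
})

test_that("an alpha = 0 run is step-for-step the run with attrition absent", {
  cfg <- sim_config(world = tiny_world_config(),
                    attrition = attrition_params(alpha = 0))
  mk <- function() {
    st <- create_world(cfg, seed = 5)
    st <- inject_virus(st, virus_strain("V0", 0L), 100)
    st$ifn[] <- 1e4  # force a hot field; the control must still ignore it
    st
  }
  set.seed(99); a <- mk(); for (t in 1:30) a <- advance(a)
  # manual phase loop without the attrition-culling step at all
  set.seed(99); b <- mk()
  for (t in 1:30) {
    b <- step_infection(b); b <- step_replication(b)
    b <- step_presentation(b)
    b <- manaim:::update_virus_field(b)
    b <- secrete_ifn(b); b <- update_ifn_field(b)
    b <- manaim:::step_movement(b)
    b <- step_stimulation(b); b <- step_proliferation(b)
    b <- step_killing(b)
    b <- step_homeostasis(b)
    b$step <- b$step + 1L
  }
  expect_identical(a$tc, b$tc)
  expect_identical(a$virus, b$virus)
  expect_identical(a$epi, b$epi)
})

test_that("culling needs interferon, spares matched cells, and hits aged ones", {
  cfg <- sim_config(world = world_config(dims = c(1L, 1L, 1L), n_tc = 0L,
                                         n_epi = 1L, n_mac = 0L),
                    attrition = attrition_params(alpha = 5))
  base <- create_world(cfg, seed = 6)
  base <- register_strain(base, virus_strain("V0", 0L))
  base$epi$status[1] <- 3L; base$epi$ivirus[1] <- 1; base$epi$strain[1] <- 1L
  add <- function(st, receptor, age) {
    st$tc <- Map(c, st$tc, list(receptor = receptor, site = 1L, state = 4L,
                                memory = TRUE, age = age, divisions = 0L,
                                div_clock = 0L, stim_clock = 9999L,
                                stim_strain = 1L))
    st
  }
  # no interferon anywhere: nobody dies
  st <- add(add(base, 255L, 900L), 0L, 900L)
  set.seed(7)
  expect_identical(length(apply_attrition(st)$tc$site), 2L)

  # hot site: the old unmatched cell dies far more often than the matched
  # one (f = 1 is fully protective) and than a young unmatched cell
  st$ifn[1] <- 1e5
  n_unmatched_old <- 0L; n_matched <- 0L
  set.seed(8)
  for (k in 1:400) {
    out <- apply_attrition(st)
    kept <- out$tc$receptor
    n_matched <- n_matched + (255L %in% kept)
    n_unmatched_old <- n_unmatched_old + (0L %in% kept)
  }
  expect_identical(n_matched, 400L)       # full protection
  expect_lt(n_unmatched_old, 100)         # mostly culled

  young <- add(add(base, 0L, 900L), 0L, 15L)
  young$ifn[1] <- 1e5
  deaths_old <- 0L; deaths_young <- 0L
  set.seed(9)
  for (k in 1:400) {
    out <- apply_attrition(young)
    ages <- out$tc$age
    deaths_old <- deaths_old + !(900L %in% ages)
    deaths_young <- deaths_young + !(15L %in% ages)
  }
  expect_gt(deaths_old, 5 * max(deaths_young, 1))
})
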