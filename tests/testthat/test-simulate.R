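test_that("constant secretion with no sinks accumulates linearly", {
  cfg <- conservative_config()
  cfg$kinetics[] <- 0
  cfg$transport$perm_ligand[] <- 0
  cfg$transport$perm_sR1[] <- 0
  cfg$transport$perm_drug[] <- 0
  cfg$transport$lymph_flow <- 0
  cfg$drug$kon <- 0; cfg$drug$koff <- 0
  q <- 4e-19
  cfg$secretion$tumor_cell <- c(hVEGF121 = 0, hVEGF165 = q)
  net <- build_network(cfg)
  y0 <- setNames(numeric(nrow(net$species) + 1),
                 c(net$species$name, "V"))
  y0["V"] <- 0.3
  t_end <- 5e4
  tr <- simulate_model(net, times = c(0, t_end / 2, t_end),
                       init_state = y0, growth_on = FALSE)
  expect_equal(unname(tr$state[2, "tumor.hVEGF165"]), q * t_end / 2,
               tolerance = 1e-8)
  expect_equal(unname(tr$state[3, "tumor.hVEGF165"]), q * t_end,
               tolerance = 1e-8)
})

test_that("a stripped ligand-receptor loop reaches its algebraic steady state", {
  # single receptor type on tumor ECs, one secreted ligand, closed tumor
  q <- 2e-19
  zero_rec <- c(VEGFR1 = 0, VEGFR2 = 0, NRP1 = 0, NRP2 = 0)
  cfg <- modify_config(default_config(), list(
    populations = list(
      muscle = list(receptors = zero_rec),
      ec_normal = list(receptors = zero_rec),
      ec_blood = list(receptors = zero_rec),
      tumor_cell = list(receptors = zero_rec),
      ec_tumor = list(receptors = c(VEGFR1 = 10000, VEGFR2 = 0,
                                    NRP1 = 0, NRP2 = 0))),
    secretion = list(
      tumor_cell = c(hVEGF121 = q, hVEGF165 = 0),
      muscle = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_normal = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_blood = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_tumor = c(mVEGF120 = 0, mVEGF164 = 0)),
    soluble = list(sR1_secretion = c(normal = 0, blood = 0, tumor = 0),
                   a2m_conc = 0, gag_density = c(normal = 0, tumor = 0)),
    transport = list(perm_ligand = c(normal = 0, tumor = 0),
                     perm_sR1 = c(normal = 0, tumor = 0),
                     perm_drug = c(normal = 0, tumor = 0))))
  net <- build_network(cfg)
  V0 <- cfg$growth$V0
  ss <- steady_state(net, duration = 120 * 86400)
  kin <- cfg$kinetics
  geo <- update_tumor_geometry(V0, cfg)
  rho <- cfg$populations$ec_tumor$cells_per_cm3 * 10000 / 6.02214076e23
  C_star <- q / kin$k_int                 # all secretion exits here
  R_star <- rho - C_star
  L_star <- (kin$koff_VEGFR1 + kin$k_int) * C_star * geo$f_int /
    (kin$kon_VEGFR1 * 1000 * R_star)
  expect_equal(ss[["tumor.ec_tumor.hVEGF121_VEGFR1"]], C_star,
               tolerance = 1e-3)
  expect_equal(ss[["tumor.ec_tumor.VEGFR1"]], R_star, tolerance = 1e-3)
  expect_equal(ss[["tumor.hVEGF121"]], L_star, tolerance = 1e-3)
})

test_that("solutions are solver-converged, not grid-limited", {
  net <- test_net()
  ss <- test_ss()
  base <- simulate_model(net, init_state = ss, n_out = 100)
  fine_grid <- simulate_model(net, init_state = ss, n_out = 1000)
  expect_lt(abs(fine_grid$V[1000] / base$V[100] - 1), 1e-3)
  tight <- simulate_model(net, init_state = ss, n_out = 100,
                          solver_opts = list(rtol = 5e-7,
                                             atol_species = 5e-23,
                                             atol_V = 5e-10))
  expect_lt(abs(tight$V[100] / base$V[100] - 1), 1e-3)
})

test_that("states remain nonnegative and V positive along trajectories", {
  net <- test_net()
  tr <- simulate_model(net, init_state = test_ss())
  expect_true(all(tr$V > 0))
  expect_true(min(tr$state) >= 0)   # tiny negatives are clamped to 0
  expect_true(all(diff(tr$time) > 0))
})

test_that("receptor pools are conserved when turnover is disabled", {
  cfg <- conservative_config()   # k_int = 0, hence no insertion either
  net <- build_network(cfg)
  ss0 <- setNames(numeric(nrow(net$species) + 1),
                  c(net$species$name, "V"))
  ss0["V"] <- 0.4
  ss0["tumor.ec_tumor.VEGFR1"] <- 8e-13
  ss0["tumor.ec_tumor.NRP1"] <- 1.6e-12
  ss0["tumor.hVEGF165"] <- 5e-16
  tr <- simulate_model(net, times = seq(0, 7 * 86400, length.out = 20),
                       init_state = ss0, growth_on = FALSE,
                       solver_opts = list(rtol = 1e-11,
                                          atol_species = 1e-30,
                                          atol_V = 1e-13))
  sp <- net$species
  r1_members <- sp$name[sp$population %in% "ec_tumor" &
                          grepl("VEGFR1", sp$constituents)]
  tot <- rowSums(tr$state[, r1_members, drop = FALSE])
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-8)
})

test_that("moles are preserved as the tumor volume changes", {
  # growth dilutes concentrations so amounts C*V stay fixed for species
  # with no other active process
  cfg <- conservative_config()
  cfg$kinetics[] <- 0
  cfg$transport$perm_ligand[] <- 0
  cfg$transport$perm_sR1[] <- 0
  cfg$transport$perm_drug[] <- 0
  cfg$transport$lymph_flow <- 0
  cfg$drug$kon <- 0; cfg$drug$koff <- 0
  net <- build_network(cfg)
  y0 <- setNames(numeric(nrow(net$species) + 1),
                 c(net$species$name, "V"))
  y0["V"] <- 0.05
  y0["tumor.hVEGF165"] <- 1e-15
  # force growth with a fabricated constant signal
  y0[net$ang_species[1]] <- 2e-15
  tr <- simulate_model(net, growth = list(k0 = 2e-6, k1 = 5e-7,
                                          Ang0 = 2e-15),
                       times = seq(0, 28 * 86400, length.out = 15),
                       init_state = y0,
                       solver_opts = list(rtol = 1e-11,
                                          atol_species = 1e-30,
                                          atol_V = 1e-14))
  expect_gt(tr$V[15] / tr$V[1], 2)  # the tumor actually grew
  moles <- tr$state[, "tumor.hVEGF165"] * tr$V
  expect_lt(max(abs(moles / moles[1] - 1)), 1e-8)
})
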