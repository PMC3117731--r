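test_that("spherical cell volume follows the cubic law", {
  expect_equal(round(cell_volume_pl(30), 1), 14.1)
  expect_equal(cell_volume_pl(0.1), (pi / 6) * 0.1^3 * 1e-3)
  expect_equal(cell_volume_pl(60), 8 * cell_volume_pl(30), tolerance = 1e-12)
  expect_error(cell_volume_pl(-1), "positive")
})

test_that("geometry is unit-consistent", {
  g <- fix_geometry()
  expect_equal(g$V_c, g$n_cells * g$v_cell_pl * 1e-9)
  expect_equal(g$V_c, 0.02115, tolerance = 5e-3) # 1.5e6 cells x 14.1 pL
})

test_that("CYP3A4 channels share one competitive denominator", {
  cyp <- fix_reduced()$cyp
  expect_equal(unname(cyp3a4_rates(0, 0, cyp)), rep(0, 4))
  r <- cyp3a4_rates(25600, 0, cyp)
  expect_equal(unname(r[["ASpOH"]]), 1108 / (2 + 25600 / 29700), tolerance = 1e-10)
  # saturation limit in AS: r -> rmax weighted by the competing AS channels
  r_inf <- cyp3a4_rates(1e12, 0, cyp)
  expect_equal(unname(r_inf[["ASpOH"]]), 1108 * 29700 / (25600 + 29700), tolerance = 1e-6)
  expect_error(cyp3a4_rates(-1, 0, cyp), "non-negative")
})

test_that("CYP3A4 reduces to single-substrate Michaelis-Menten without competitors", {
  cyp <- fix_reduced()$cyp
  for (conc in c(0, 1, 50, 1400, 25600, 2e5)) {
    r <- cyp3a4_rates(0, conc, cyp) # only ASL present
    mm <- cyp$rmax[["ASLpOH"]] * conc / (cyp$km[["ASLpOH"]] *
      (1 + conc / cyp$km[["ASLpOH"]] + conc / cyp$km[["ASLoOH"]]))
    expect_equal(unname(r[["ASLpOH"]]), mm, tolerance = 1e-12)
    # with the second ASL channel also removed it is exactly MM
    cyp1 <- cyp
    cyp1$km[["ASLoOH"]] <- 1e300 # competitor term vanishes
    r1 <- cyp3a4_rates(0, conc, cyp1)
    mm1 <- cyp$rmax[["ASLpOH"]] * conc / (cyp$km[["ASLpOH"]] + conc)
    expect_lt(abs(unname(r1[["ASLpOH"]]) - mm1), 1e-12 * max(mm1, 1))
  }
})

test_that("UGT1A3 substrate inhibition has the stated maximum and MM limit", {
  ugt <- ugt_parameters(rmax = 956, km = 12000, ki = 75000)
  expect_equal(ugt1a3_rate(0, ugt), 0)
  expect_equal(ugt1a3_rate(12000, ugt), 442.5926, tolerance = 1e-6)
  copt <- sqrt(12000 * 75000)
  expect_equal(copt, 30000)
  expect_equal(ugt1a3_rate(copt, ugt), 531.1111, tolerance = 1e-6)
  # calculus oracle: the argmax over a fine sweep sits at sqrt(km * ki)
  cs <- seq(1000, 200000, by = 100)
  rs <- vapply(cs, ugt1a3_rate, numeric(1), ugt = ugt)
  expect_equal(cs[which.max(rs)], 30000, tolerance = 0.01)
  # K_I -> infinity recovers Michaelis-Menten
  ugt_inf <- ugt_parameters(rmax = 956, km = 12000, ki = 1e12)
  for (conc in c(10, 1000, 12000, 1e5)) {
    expect_equal(ugt1a3_rate(conc, ugt_inf), 956 * conc / (12000 + conc),
                 tolerance = 1e-6)
  }
})

test_that("hydrolysis is first order", {
  expect_equal(hydrolysis_rate(1000, 0.0025), 2.5)
  expect_equal(hydrolysis_rate(123, 0), 0)
  expect_equal(hydrolysis_rate(0, 0.5), 0)
})

test_that("binding net rate vanishes at the fu-defined equilibrium", {
  b <- binding_parameters(k_dis = 600, fu_acid = 0.5, fu_lactone = 0.05)
  expect_equal(binding_net_rate(10, 10, b, "acid"), 0)
  b1 <- binding_parameters(k_dis = 600, fu_acid = 1, fu_lactone = 0.05)
  expect_equal(binding_net_rate(42, 0, b1, "acid"), 0)
  b2 <- binding_parameters(k_dis = 600, fu_acid = 0.25, fu_lactone = 0.05)
  expect_equal(binding_net_rate(1, 0, b2, "acid"), 1800)
  expect_error(binding_parameters(fu_acid = 1.5), "0, 1")
})

test_that("binding-only dynamics settle at c_free/(c_free+c_bound) = fu", {
  for (fu in c(0.1, 0.5, 0.9)) {
    p <- fix_reduced(fu_acid = fu, fu_lactone = fu / 2)
    # switch every other process off
    p$cyp$rmax[] <- 1e-300; p$ugt$rmax <- 1e-300
    p$hyd <- hydrolysis_parameters(0, 0, 0)
    p$transport$kappa_im[] <- 0; p$transport$kappa_ex[] <- 0
    g <- fix_geometry()
    x0 <- initial_state(g); x0["AS.m"] <- 0; x0["AS.c"] <- 100
    res <- simulate_model(p, g, t_grid = c(0, 0.5, 1), initial = x0,
                          rtol = 1e-10, atol = 1e-12)
    fin <- res$states[nrow(res$states), ]
    expect_equal(fin[["AS.c"]] / (fin[["AS.c"]] + fin[["AS.b"]]), fu,
                 tolerance = 1e-6)
    # binding conserves the intracellular amount
    expect_equal(fin[["AS.c"]] + fin[["AS.b"]], 100, tolerance = 1e-6)
  }
})

test_that("transport fluxes: zero state, reduced arithmetic, full saturation", {
  p <- fix_reduced(); g <- fix_geometry()
  zero <- setNames(rep(0, 18), state_names())
  expect_equal(unname(transport_fluxes(zero, p)), rep(0, 6))
  # kappa_im,AS = 20.3 uL/min on 10000 pmol/ml gives 203 pmol/min
  x <- zero; x["AS.m"] <- 10000
  expect_equal(transport_fluxes(x, p)[["AS"]], 203, tolerance = 1e-10)
  # full variant: MM import saturates at rmax (plus the passive term)
  pf <- fix_full()
  pf$transport$P["AS"] <- 0
  sat <- vapply(c(1e6, 1e7, 1e8), function(cm) {
    xx <- zero; xx["AS.m"] <- cm
    transport_fluxes(xx, pf)[["AS"]]
  }, numeric(1))
  expect_true(all(diff(sat) > 0))
  expect_equal(sat[3], pf$transport$rmax_1b1 + pf$transport$rmax_2b1, tolerance = 1e-3)
  # mismatched variant/block is refused
  bad <- fix_reduced()
  expect_error(kinetic_parameter_set(bad$cyp, bad$ugt, bad$hyd, bad$bind,
                                     bad$transport, variant = "full"), "transport_full")
})

test_that("RHS agrees with the independent amount-balance oracle", {
  g <- fix_geometry()
  set.seed(42)
  for (p in list(fix_reduced(), fix_full())) {
    for (i in 1:10) {
      x <- random_state()
      d_pkg <- ode_rhs(0, x, p, g)
      d_orc <- oracle_rhs(x, p, g)
      expect_lt(max(abs(d_pkg - d_orc)) / max(abs(d_orc)), 1e-8)
    }
  }
  # zero state gives zero derivative; binding-only conserves free+bound
  expect_equal(unname(ode_rhs(0, setNames(rep(0, 18), state_names()),
                              fix_reduced(), g)), rep(0, 18))
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  p <- fix_reduced(); g <- fix_geometry()
  grid <- c(0, 10, 60, 300, 600)
  rc <- simulate_model(p, g, grid, compiled = TRUE)
  rr <- simulate_model(p, g, grid, compiled = FALSE)
  expect_lt(max(abs(rc$states - rr$states) / (abs(rr$states) + 1)), 1e-7)
})

test_that("simulation honours trivial closed forms", {
  g <- fix_geometry()
  # all rate constants (effectively) zero: state constant
  p0 <- fix_reduced()
  p0$cyp$rmax[] <- 1e-300; p0$ugt$rmax <- 1e-300
  p0$hyd <- hydrolysis_parameters(0, 0, 0)
  p0$bind$k_dis <- 0
  p0$transport$kappa_im[] <- 0; p0$transport$kappa_ex[] <- 0
  res <- simulate_model(p0, g, t_grid = c(0, 100, 600))
  expect_equal(res$states[3, ], res$states[1, ], tolerance = 1e-10)
  # only chemical hydrolysis on pure extracellular ASL: exact exponential
  p1 <- p0
  p1$hyd <- hydrolysis_parameters(k_cr = 0.0025, 0, 0)
  x0 <- initial_state(g); x0["AS.m"] <- 0; x0["ASL.m"] <- 1000
  tt <- seq(0, 600, by = 50)
  res1 <- simulate_model(p1, g, t_grid = tt, initial = x0, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(res1$states[, "ASL.m"]), 1000 * exp(-0.0025 * tt),
               tolerance = 1e-6)
  # first state equals the initial condition, time strictly increasing
  expect_equal(unname(res1$states[1, ]), unname(x0))
  expect_true(all(diff(res1$time) > 0))
})

test_that("mass is conserved over 0-1200 min with beta-oxidation off", {
  g <- fix_geometry()
  set.seed(7)
  for (p in list(fix_reduced(), fix_full())) {
    res <- simulate_model(p, g, t_grid = seq(0, 1200, by = 50))
    rec <- recovery_timecourse(res, include_bound = TRUE)
    expect_lt(max(abs(rec - 1)), 1e-6)
    expect_gt(min(res$states), -1e-8) # non-negativity within solver tolerance
  }
})

test_that("recovery excluding the bound pool mirrors the bound amount exactly", {
  p <- fix_reduced(); g <- fix_geometry()
  res <- simulate_model(p, g, t_grid = seq(0, 600, by = 20))
  rec <- recovery_timecourse(res)
  expect_equal(rec[1], 1.0)
  # the measured deficit is exactly the unmeasured bound pool
  bound <- rowSums(res$states[, paste0(c("AS", "ASL", "ASpOH", "ASoOH",
                                         "ASLpOH", "ASLoOH"), ".b")]) *
    g$V_c / (g$initial_AS_m * g$V_m)
  expect_equal(rec, 1 - bound, tolerance = 1e-8)
  # recovery drops below 1 while the bound pool loads and never exceeds 1
  expect_true(all(rec <= 1 + 1e-9))
  expect_lt(min(diff(rec)), 0)
  expect_lt(rec[length(rec)], 1)
  g0 <- g; g0$initial_AS_m <- 0
  res$geometry <- g0
  expect_error(recovery_timecourse(res), "positive")
})

test_that("beta-oxidation removes mass only through the configured sink", {
  p <- default_parameters(3, betaox = TRUE)
  expect_equal(p$betaox$k_as, 0.015)
  g <- fix_geometry()
  res <- simulate_model(p, g, t_grid = seq(0, 600, by = 30))
  rec <- recovery_timecourse(res, include_bound = TRUE)
  expect_lt(rec[length(rec)], 1 - 1e-3) # strictly loses mass
  expect_true(all(diff(rec) <= 1e-9))
})
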