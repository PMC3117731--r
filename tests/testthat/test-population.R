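test_that("relative-abundance scaling reproduces the donor-2 rates", {
  expect_equal(round(scale_rmax(1228, 1027, 611)), 731)
  expect_equal(round(scale_rmax(2756, 1027, 611)), 1640)
  expect_equal(scale_rmax(500, 100, 100), 500)
  expect_error(scale_rmax(500, 0, 100), "positive")
  # linear and composable: scaling by a then b equals scaling by a*b
  r <- 1108
  expect_identical(scale_rmax(scale_rmax(r, 1, 2), 1, 3), scale_rmax(r, 1, 6))
})

test_that("microsomal conversion is a simple scaling", {
  expect_equal(microsomal_convert(1027), 225.94)
  expect_equal(microsomal_convert(42, 1), 42)
  x <- 137.5
  expect_equal(microsomal_convert(x / 0.22), x / 0.22 * 0.22, tolerance = 1e-12)
  expect_lt(abs(microsomal_convert(x / 0.22) * 0.22 / 0.22 - x), 1e-12)
})

test_that("pk_summary matches simple geometric profiles", {
  mk <- function(tt, y) {
    structure(list(time = tt,
                   states = matrix(y, ncol = 18, nrow = length(tt),
                                   dimnames = list(NULL, state_names()))),
              class = "simulation_result")
  }
  tt <- seq(0, 1200, by = 10)
  flat <- mk(tt, 0); flat$states[, "AS.c"] <- 50
  s <- pk_summary(flat, "AS")
  expect_equal(s$auc, 60000)
  expect_equal(s$cmax, 50)
  expect_equal(s$t_cmax, 0) # earliest attainment on ties
  tri <- mk(tt, 0)
  tri$states[, "AS.c"] <- ifelse(tt <= 600, tt / 6, (1200 - tt) / 6)
  s2 <- pk_summary(tri, "AS")
  expect_equal(s2$auc, 60000)
  expect_equal(s2$cmax, 100)
  expect_equal(s2$t_cmax, 600)
  # acid-sum definition adds the hydroxy acids
  tri$states[, "ASpOH.c"] <- 10
  s3 <- pk_summary(tri, "acid_sum")
  expect_equal(s3$cmax, 110)
  expect_error(pk_summary(tri, "AS", window = c(0, 2000)), "window")
})

test_that("AUC is stable under grid refinement", {
  p <- fix_reduced(); g <- fix_geometry()
  g$initial_AS_m <- 50
  r1 <- simulate_model(p, g, t_grid = seq(0, 1200, by = 10))
  r2 <- simulate_model(p, g, t_grid = seq(0, 1200, by = 5))
  a1 <- pk_summary(r1, "acid_sum")$auc
  a2 <- pk_summary(r2, "acid_sum")$auc
  expect_lt(abs(a1 - a2) / a2, 0.001)
})

test_that("a degenerate bank yields identical exposure summaries", {
  p <- fix_reduced(); g <- fix_geometry()
  bank <- data.frame(subject_id = paste0("L", 1:5),
                     cyp3a4_level = 2, ugt1a3_level = 3)
  pop <- run_population(bank, p, g, ref_levels = c(cyp3a4 = 2, ugt1a3 = 3),
                        AS0 = 50, dt = 20)
  expect_equal(nrow(pop), 10)
  for (def in c("AS", "acid_sum")) {
    x <- pop[pop$definition == def, "auc"]
    expect_equal(stats::sd(x), 0)
  }
  sm <- summarize_population(pop)
  expect_true(all(sm$sample_rel_sd_pct == 0))
})

test_that("doubling CYP3A4 abundance lowers parent-drug exposure", {
  p <- fix_reduced(); g <- fix_geometry()
  bank <- generate_liver_bank(n = 20, seed = 8)
  ref <- c(cyp3a4 = mean(bank$cyp3a4_level), ugt1a3 = mean(bank$ugt1a3_level))
  pop1 <- run_population(bank, p, g, ref_levels = ref, AS0 = 50, dt = 20)
  bank2 <- bank; bank2$cyp3a4_level <- 2 * bank2$cyp3a4_level
  pop2 <- run_population(bank2, p, g, ref_levels = ref, AS0 = 50, dt = 20)
  a1 <- pop1[pop1$definition == "AS", "auc"]
  a2 <- pop2[pop2$definition == "AS", "auc"]
  expect_true(all(a2 < a1))
})

test_that("log-logistic ML fit recovers known shape/scale and is equivariant", {
  set.seed(21)
  x <- flexsurv::rllogis(10000, shape = 4, scale = 100)
  ft <- fit_log_logistic(x)
  # closed-form mean a (pi/b) / sin(pi/b) = 111.07 at (4, 100)
  expect_equal(100 * (pi / 4) / sin(pi / 4), 111.0721, tolerance = 1e-4)
  expect_lt(abs(ft$mean - 111.0721) / 111.0721, 0.02)
  expect_lt(abs(ft$shape - 4) / 4, 0.05)
  # scale equivariance
  ft10 <- fit_log_logistic(10 * x)
  expect_lt(abs(ft10$scale / ft$scale - 10) / 10, 0.01)
  expect_error(fit_log_logistic(rep(5, 20)), "degenerate")
  expect_error(fit_log_logistic(c(x[1:9])), "at least 10")
  expect_error(fit_log_logistic(c(-1, x[1:20])), "positive")
})

test_that("fitted moments are flagged when they do not exist", {
  set.seed(3)
  x <- flexsurv::rllogis(3000, shape = 1.5, scale = 50) # mean exists, sd does not
  ft <- fit_log_logistic(x)
  expect_true(ft$moments_exist[["mean"]])
  expect_false(ft$moments_exist[["sd"]])
  expect_equal(ft$sd, stats::sd(x)) # sample moment reported instead
})
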