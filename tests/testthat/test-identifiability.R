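obs_grid <- function(compounds, compartment, times, individual = "1") {
  d <- expand.grid(compound = compounds, time_min = times,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[order(d$compound, d$time_min), ]
  data.frame(individual = individual, time_min = d$time_min,
             compound = d$compound, compartment = compartment,
             replicate_mean = 1, sd = 1, n_replicates = 3, flag = "ok",
             stringsAsFactors = FALSE)
}

test_that("sensitivities match the closed-form derivative of exponential decay", {
  # with only import active, the medium AS pool decays as c0 exp(-kappa/V_m t)
  g <- fix_geometry(initial_AS_m = 1000)
  p <- fix_reduced()
  p$cyp$rmax[] <- 1e-300; p$ugt$rmax <- 1e-300
  p$hyd <- hydrolysis_parameters(0, 0, 0)
  p$transport$kappa_im[] <- 0; p$transport$kappa_ex[] <- 0
  p <- param_set(p, c(transport.kappa_im.AS = 5)) # uL/min -> k = 0.0025/min
  d <- obs_grid("AS", "m", c(50, 100, 150))
  S <- local_sensitivities(p, g, d, "transport.kappa_im.AS")
  # d c / d kappa_uL = (-t/V_m) c0 exp(-k t) / 1000
  k <- 0.005 / 2
  analytic <- (-c(50, 100, 150) / 2) * 1000 * exp(-k * c(50, 100, 150)) / 1000
  expect_equal(unname(S[, 1]), analytic, tolerance = 1e-4)
  # the t = 100 entry corresponds to the textbook -t c0 e^{-kt} derivative
  expect_equal(unname(S[2, 1]) * 2000, -100 * 1000 * exp(-0.25), tolerance = 1e-4)
})

test_that("finite differences converge at second order on a smooth model", {
  g <- fix_geometry(initial_AS_m = 1000)
  p <- fix_reduced()
  p$cyp$rmax[] <- 1e-300; p$ugt$rmax <- 1e-300
  p$hyd <- hydrolysis_parameters(0, 0, 0)
  p$transport$kappa_im[] <- 0; p$transport$kappa_ex[] <- 0
  p <- param_set(p, c(transport.kappa_im.AS = 5))
  d <- obs_grid("AS", "m", 100)
  k <- 0.0025
  exact <- -100 / 2 * 1000 * exp(-k * 100) / 1000
  err <- vapply(c(4e-2, 2e-2, 1e-2), function(h) {
    abs(local_sensitivities(p, g, d, "transport.kappa_im.AS", rel_step = h)[1, 1] - exact)
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 3 & ratios < 5)) # O(h^2): halving h quarters the error
})

test_that("a parameter without influence yields a zero sensitivity column", {
  g <- fix_geometry()
  p <- fix_reduced()
  p$cyp$rmax[] <- 1e-300 # no hydroxylation -> no hydroxy-lactones ever form
  d <- obs_grid(c("AS", "ASL"), "c", c(60, 300))
  S <- local_sensitivities(p, g, d, c("hyd.k_pon_asloh", "ugt.rmax"))
  expect_equal(unname(S[, "hyd.k_pon_asloh"]), rep(0, 4))
  expect_gt(max(abs(S[, "ugt.rmax"])), 0)
})

test_that("FIM on the linear toy model matches the Cramer-Rao closed form", {
  S <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "theta"))
  rep_ <- fisher_information(S, weights = rep(1, 3), theta = 2)
  expect_equal(rep_$fim[1, 1], 14)
  expect_equal(unname(rep_$rel_error_pct), 100 / (2 * sqrt(14)), tolerance = 1e-10)
  expect_false(rep_$singular)
})

test_that("FIM is symmetric PSD, detects collinearity and orthogonality", {
  set.seed(11)
  S <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("p", 1:4)))
  w <- runif(10, 0.5, 2)
  rep_ <- fisher_information(S, w, theta = rep(1, 4))
  expect_lt(max(abs(rep_$fim - t(rep_$fim))), 1e-10)
  ev <- eigen(rep_$fim, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  expect_true(all(abs(rep_$correlation) <= 1))

  # exact collinearity: duplicated column
  S2 <- cbind(a = S[, 1], b = S[, 1], c = S[, 2])
  rep2 <- fisher_information(S2, rep(1, 10), theta = rep(1, 3))
  expect_true(rep2$singular)
  expect_equal(rep2$correlation["a", "b"], 1.0, tolerance = 1e-6)

  # orthogonal design: diagonal FIM, zero correlations
  S3 <- cbind(a = c(1, 0, 0, 0), b = c(0, 2, 0, 0), d = c(0, 0, 3, 0))
  rep3 <- fisher_information(S3, rep(1, 4), theta = rep(1, 3))
  expect_equal(rep3$fim, diag(c(1, 4, 9)), ignore_attr = TRUE)
  off <- rep3$correlation; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-12)
})

test_that("reduced-variant enzyme rates are identifiable on noiseless data", {
  p <- fix_reduced(); g <- fix_geometry()
  d <- generate_timeseries(p, g, noise = noise_model(cv = 0, floor_sd = 0, loq = 0),
                           seed = 1)
  paths <- c(paste0("cyp.rmax.", c("ASpOH", "ASoOH", "ASLpOH", "ASLoOH")), "ugt.rmax")
  rep_ <- identifiability_report(p, g, d, paths)
  expect_true(all(rep_$rel_error_pct < 100))
  expect_length(rep_$flagged_error, 0)
})

test_that("first-order import and passive diffusion of one compound are collinear", {
  p <- fix_full(); g <- fix_geometry()
  d <- generate_timeseries(p, g, noise = noise_model(cv = 0, floor_sd = 0, loq = 0),
                           seed = 2)
  rep_ <- identifiability_report(p, g, d, c("transport.k_im.ASL", "transport.P.ASL",
                                            "transport.k_ex.ASL"))
  expect_true(all(c("transport.k_im.ASL", "transport.P.ASL") %in%
                    rep_$flagged_correlation))
  expect_gt(abs(rep_$correlation["transport.k_im.ASL", "transport.P.ASL"]), 0.95)
})

test_that("a single-time-point design is rank deficient", {
  p <- fix_reduced(); g <- fix_geometry()
  d <- obs_grid(c("AS", "ASL"), "c", 60)
  paths <- c(paste0("cyp.rmax.", c("ASpOH", "ASoOH", "ASLpOH", "ASLoOH")), "ugt.rmax")
  S <- local_sensitivities(p, g, d, paths)
  rep_ <- fisher_information(S, rep(1, nrow(d)))
  expect_true(rep_$singular)
})

test_that("the reduction loop lumps the full variant down to kappa clearances", {
  # truth is a reduced model; the full model is its exact linear-regime
  # unlumping, so the loop must terminate at the reduced structure with the
  # same apparent clearances and no worse an objective
  p_red <- fix_reduced()
  g <- fix_geometry(initial_AS_m = 50) # linear regime of the MM uptake steps
  kim <- p_red$transport$kappa_im; kex <- p_red$transport$kappa_ex
  P <- pmin(kim, kex) * 0.3
  non_as <- setdiff(names(kim), "AS")
  p_full <- p_red
  p_full$transport <- transport_full(
    rmax_1b1 = (kim[["AS"]] - P[["AS"]]) * 18900 * 0.9, km_1b1 = 18900,
    rmax_2b1 = (kim[["AS"]] - P[["AS"]]) * 200 * 0.1, km_2b1 = 200,
    rmax_ex = (kex[["AS"]] - P[["AS"]]) * 5000, km_ex = 5000,
    k_im = (kim - P)[non_as], k_ex = (kex - P)[non_as], P = P)
  p_full$variant <- "full"
  d <- generate_timeseries(p_red, g, noise = noise_model(cv = 0, floor_sd = 0, loq = 0),
                           seed = 4)
  J_before <- objective(p_full, g, d)
  red <- reduce_model(p_full, g, d)
  expect_s3_class(red$params$transport, "transport_reduced")
  expect_identical(red$params$variant, "reduced")
  expect_gt(nrow(red$trace), 0)
  expect_true(all(diff(red$trace$free_params_after) <= 0))
  # endpoint structure: one kappa_im and one kappa_ex per compound, equal to
  # the summed active + passive clearances
  expect_equal(red$params$transport$kappa_im, kim, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(red$params$transport$kappa_ex, kex, tolerance = 1e-6,
               ignore_attr = TRUE)
  J_after <- objective(red$params, g, d)
  expect_lt(J_after, J_before + 1e-3)
})

test_that("reduction is a no-op on reduced input and under impossible thresholds", {
  p <- fix_reduced(); g <- fix_geometry()
  d <- generate_timeseries(p, g, seed = 5)
  red <- reduce_model(p, g, d)
  expect_equal(nrow(red$trace), 0)
  expect_identical(red$params$variant, "reduced")

  pf <- fix_full()
  red2 <- reduce_model(pf, g, d,
                       thresholds = list(rel_error = Inf, corr = 1.1, sens_frac = 0))
  expect_equal(nrow(red2$trace), 0)
  expect_identical(red2$params$variant, "full")
})
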