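#!/usr/bin/env Rscript
# Parameter estimation on synthetic hepatocyte data: generates a noisy
# triplicate time series from the donor-1 model, then re-estimates the five
# maximal enzyme rates and twelve lumped transport clearances with the
# evolutionary strategy and reports how well the truth is recovered.

suppressPackageStartupMessages(library(atorkin))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- "results/02_fit"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

params <- default_parameters(1)
geom <- experiment_geometry()
dataset <- generate_timeseries(params, geom, noise = noise_model(cv = 0.10),
                               seed = seed)
write_timeseries(dataset, file.path(out_dir, "synthetic_donor1_cv10.csv"))

free <- c(paste0("cyp.rmax.", c("ASpOH", "ASoOH", "ASLpOH", "ASLoOH")),
          "ugt.rmax",
          paste0("transport.kappa_im.", c("AS", "ASL", "ASpOH", "ASoOH",
                                          "ASLpOH", "ASLoOH")),
          paste0("transport.kappa_ex.", c("AS", "ASL", "ASpOH", "ASoOH",
                                          "ASLpOH", "ASLoOH")))
specs <- default_bounds(free)
truth <- vapply(free, function(p) param_get(params, p), numeric(1))

fit <- suppressWarnings(
  fit_single(dataset, geom, params, specs, seed = seed, n_starts = 5,
             budget = 4000)
)

comparison <- data.frame(parameter = free, truth = truth,
                         estimate = fit$par[free],
                         error_pct = 100 * abs(fit$par[free] - truth) / truth)
write.csv(comparison, file.path(out_dir, "recovery.csv"), row.names = FALSE)
jsonlite::write_json(
  list(J_star = fit$value, evaluations = fit$evals, seed = fit$seed,
       starts = fit$starts, parameters = as.list(fit$par)),
  file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
write_provenance(out_dir, config = list(cv = 0.10, n_starts = 5, budget = 4000),
                 seed = seed)

cat("Weighted least-squares fit: J* =", round(fit$value, 2),
    "after", fit$evals, "evaluations\n")
cat("Enzyme rates recovered within",
    round(max(comparison$error_pct[1:5]), 2), "% at 10% measurement noise.\n")
print(comparison, row.names = FALSE, digits = 4)
cat("Outputs in", out_dir, "\n")
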