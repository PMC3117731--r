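#!/usr/bin/env Rscript
# Donor-1 baseline simulation: concentration-time profiles of all six
# atorvastatin species over the 0-600 min experiment, the intracellular and
# extracellular acid/lactone AUC ratios, and the recovery time course that
# motivates the unspecific-binding pool.

suppressPackageStartupMessages(library(atorkin))
out_dir <- "results/01_simulate"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

params <- default_parameters(1)
geom <- experiment_geometry() # 2 ml medium, 1.5e6 cells, 10 uM dose

sim <- simulate_model(params, geom, t_grid = seq(0, 600, by = 2))
traj <- as.data.frame(sim)
write.csv(traj, file.path(out_dir, "trajectories_donor1.csv"), row.names = FALSE)

auc <- function(col) {
  y <- sim$states[, col]
  sum(diff(sim$time) * (head(y, -1) + tail(y, -1)) / 2)
}
ratios <- data.frame(
  quantity = c("AUC ratio ASpOH/ASLpOH intracellular",
               "AUC ratio ASoOH/ASLoOH intracellular",
               "AUC ratio ASpOH/ASLpOH extracellular",
               "AUC ratio ASoOH/ASLoOH extracellular"),
  value = c(auc("ASpOH.c") / auc("ASLpOH.c"), auc("ASoOH.c") / auc("ASLoOH.c"),
            auc("ASpOH.m") / auc("ASLpOH.m"), auc("ASoOH.m") / auc("ASLoOH.m")))
write.csv(ratios, file.path(out_dir, "auc_ratios.csv"), row.names = FALSE)

grid <- default_time_grid()
sim_grid <- simulate_model(params, geom, t_grid = grid)
recovery <- data.frame(time_min = grid,
                       recovery_pct = round(100 * recovery_timecourse(sim_grid), 1))
write.csv(recovery, file.path(out_dir, "recovery.csv"), row.names = FALSE)

export_sbml(params, geom, file.path(out_dir, "model_donor1_reduced.xml"))
write_provenance(out_dir, config = list(variant = params$variant, dose_pmol_ml = 10000))

cat("Acid/lactone AUC ratios (0-600 min):\n")
print(ratios, row.names = FALSE)
cat("\nMeasured recovery falls from 100% to",
    recovery$recovery_pct[nrow(recovery)],
    "% as the unspecific bound pool loads.\n")
cat("Outputs in", out_dir, "\n")
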