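# Shared fixtures: canonical parameter sets, a small full-variant set, and
# an independent amount-balance oracle for the ODE right-hand side.

fix_geometry <- function(...) experiment_geometry(...)

fix_reduced <- function(...) default_parameters(1, ...)

# a plausible full-variant parameter set (the full variant exists mainly to
# exercise the reduction machinery; AS export MM parameters are free choices)
fix_full <- function() {
  non_as <- c("ASL", "ASpOH", "ASoOH", "ASLpOH", "ASLoOH")
  kinetic_parameter_set(
    cyp = cyp_parameters(rmax = c(ASpOH = 1108, ASoOH = 3345, ASLpOH = 1228, ASLoOH = 2756),
                         km = c(ASpOH = 25600, ASoOH = 29700, ASLpOH = 1400, ASLoOH = 3900)),
    ugt = ugt_parameters(rmax = 956, km = 12000, ki = 75000),
    hyd = hydrolysis_parameters(k_cr = 0.0025, k_pon_asl = 0.308, k_pon_asloh = 0.280),
    bind = binding_parameters(k_dis = 600, fu_acid = 0.2, fu_lactone = 0.05),
    transport = transport_full(
      rmax_1b1 = 150, km_1b1 = 18900, rmax_2b1 = 2, km_2b1 = 200,
      rmax_ex = 20, km_ex = 5000,
      k_im = setNames(c(0.20, 0.003, 0.0003, 0.025, 0.020), non_as),
      k_ex = setNames(c(0.015, 0.0006, 0.0012, 0.0008, 0.002), non_as),
      P = c(AS = 0.004, ASL = 0.06, ASpOH = 0.0008, ASoOH = 0.0008,
            ASLpOH = 0.008, ASLoOH = 0.006)),
    variant = "full"
  )
}

# independent bookkeeping oracle: assembles d(state)/dt per compound by
# summing every elementary amount flow (pmol/min) and dividing by the
# compartment volume; intentionally written term by term, separately from
# the vectorized implementation in the package.
oracle_rhs <- function(state, params, geometry) {
  cpd <- c("AS", "ASL", "ASpOH", "ASoOH", "ASLpOH", "ASLoOH")
  acid_of <- c(ASL = "AS", ASLpOH = "ASpOH", ASLoOH = "ASoOH")
  V_m <- geometry$V_m; V_c <- geometry$V_c
  get <- function(j, comp) max(state[[paste0(j, ".", comp)]], 0)
  amt <- setNames(rep(0, 18), state_names()) # d(amount)/dt in pmol/min

  # transport
  fl <- transport_fluxes(state, params)
  for (j in cpd) {
    amt[paste0(j, ".m")] <- amt[paste0(j, ".m")] - fl[[j]]
    amt[paste0(j, ".c")] <- amt[paste0(j, ".c")] + fl[[j]]
  }
  # CYP3A4 (intracellular, rate * V_c = amount flux)
  rc <- cyp3a4_rates(get("AS", "c"), get("ASL", "c"), params$cyp)
  for (ch in names(rc)) {
    sub <- if (ch %in% c("ASpOH", "ASoOH")) "AS" else "ASL"
    amt[paste0(sub, ".c")] <- amt[paste0(sub, ".c")] - rc[[ch]] * V_c
    amt[paste0(ch, ".c")] <- amt[paste0(ch, ".c")] + rc[[ch]] * V_c
  }
  # UGT1A3
  ru <- ugt1a3_rate(get("AS", "c"), params$ugt)
  amt["AS.c"] <- amt["AS.c"] - ru * V_c
  amt["ASL.c"] <- amt["ASL.c"] + ru * V_c
  # hydrolysis: chemical both compartments, PON intracellular
  for (l in names(acid_of)) {
    a <- acid_of[[l]]
    r_m <- hydrolysis_rate(get(l, "m"), params$hyd$k_cr) * V_m
    amt[paste0(l, ".m")] <- amt[paste0(l, ".m")] - r_m
    amt[paste0(a, ".m")] <- amt[paste0(a, ".m")] + r_m
    kp <- if (l == "ASL") params$hyd$k_pon_asl else params$hyd$k_pon_asloh
    r_c <- (hydrolysis_rate(get(l, "c"), params$hyd$k_cr) +
              hydrolysis_rate(get(l, "c"), kp)) * V_c
    amt[paste0(l, ".c")] <- amt[paste0(l, ".c")] - r_c
    amt[paste0(a, ".c")] <- amt[paste0(a, ".c")] + r_c
  }
  # binding
  for (j in cpd) {
    cls <- if (j %in% c("AS", "ASpOH", "ASoOH")) "acid" else "lactone"
    rb <- binding_net_rate(get(j, "c"), get(j, "b"), params$bind, cls) * V_c
    amt[paste0(j, ".c")] <- amt[paste0(j, ".c")] - rb
    amt[paste0(j, ".b")] <- amt[paste0(j, ".b")] + rb
  }
  # beta-oxidation sinks
  amt["AS.c"] <- amt["AS.c"] - params$betaox$k_as * get("AS", "c") * V_c
  for (j in c("ASpOH", "ASoOH")) {
    amt[paste0(j, ".c")] <- amt[paste0(j, ".c")] - params$betaox$k_asoh * get(j, "c") * V_c
  }
  vol <- ifelse(grepl("\\.m$", names(amt)), V_m, V_c)
  amt / vol
}

# random non-negative state for property checks
random_state <- function() {
  setNames(runif(18, 0, 5000), state_names())
}
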