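#!/usr/bin/env Rscript
# Collective uptake: run the discrete front-uptake simulator across coverage
# levels, extract the emergent aureole growth Delta(R), and fit the particle
# conservation model to recover phi_is and the adsorption law.

library(aureole)
dir.create("results", showWarnings = FALSE)

g <- cell_geometry()
p <- particle_spec(1, label = "PsCarbo1000")
phi_true <- 0.11

levels <- c(0.06, 0.1, 0.14, 0.18, 0.4, 0.8, 1.2)
rows <- lapply(levels, function(phi) {
  cfg <- load_preset("PsCarbo1000", coating = list(phi_S = phi),
                     sim = list(duration_s = 288000))
  fs <- simulate_front_uptake(cfg)
  st <- fs$states
  Rc <- critical_radius(phi, uptake_params(phi_true), g, p)
  sel <- st$R > 1.5 * Rc
  if (sum(sel) < 10) sel <- st$R > Rc
  slope <- coef(lm(Delta ~ R, data = st[sel, ]))[[2]]
  data.frame(phi_S = phi, R_final_um = st$R[nrow(st)],
             Delta_final_um = st$Delta[nrow(st)], DeltaR_slope = slope,
             ingested = st$ingested[nrow(st)],
             adsorbed = st$adsorbed[nrow(st)],
             conserved = all(st$ingested + st$adsorbed +
                               st$substrate_remaining == fs$initial_total))
})
aureoles <- do.call(rbind, rows)
write.csv(aureoles, "results/aureole_series.csv", row.names = FALSE)
stopifnot(all(aureoles$conserved))

fit <- fit_uptake(aureoles$phi_S, aureoles$DeltaR_slope, g, p)
est <- data.frame(parameter = names(fit$estimates),
                  estimate = as.numeric(fit$estimates))
write.csv(est, "results/uptake_fit.csv", row.names = FALSE)

cat(sprintf("front-uptake simulations at phi_S = %s\n",
            paste(levels, collapse = ", ")))
cat("  particle ledger balanced exactly at every step in every run\n")
cat(sprintf("  recovered phi_is = %.3f (preset %.2f)\n",
            fit$estimates[["phi_is"]], phi_true))
if (!is.na(fit$estimates[["a"]])) {
  cat(sprintf("  adsorption law: a = %.2f above phi_S0 = %.2f\n",
              fit$estimates[["a"]], fit$estimates[["phi_S0"]]))
}
cat("wrote results/aureole_series.csv, results/uptake_fit.csv\n")
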