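#!/usr/bin/env Rscript
# Forward simulation of the PhyB -> PIF3 signalling front end.
#
# Simulates the week after the dark-to-light switch with the red-light
# calibration (K_Pfr = 7, Q_Pfr = 8.75, 8-h PhyB half-life, R_PP = 350,
# 15-min PIF3 half-life), compares the closed-form solutions against the
# numerical integrators, and writes the trajectories and comparison table.

suppressMessages(library(phypif))
dir.create("results", showWarnings = FALSE)

photo <- photo_params()
pif <- pif_params()
times <- seq(0, 7, by = 0.01)

# closed forms vs their numerical oracles ------------------------------------
tr_ode <- integrate_phyb(photo, times)
phyb_cf <- phyb_closed_form(times, photo)
cat(sprintf("PhyB closed form vs scaled ODE: max relative deviation %.2e\n",
            max(abs(tr_ode$phyb - phyb_cf) / phyb_cf)))

tr_two <- integrate_phyb(two_state_photo_params(), times, form = "two_state")
cat(sprintf("Two-state system vs reduction:  max relative deviation %.2e\n",
            max(abs(tr_two$phyb - phyb_cf) / phyb_cf)))

ptr <- integrate_pif(pif, photo, signalling_grid(7, extra = times))
pif_num <- approx(ptr$time, ptr$pif, xout = times, ties = "ordered")$y
pif_cf <- pif_closed_form(times, pif, photo)
late <- times >= 3
cat(sprintf("PIF3 numeric: minimum %.4f at t = %.2f d; day-7 level %.4f\n",
            min(pif_num), times[which.min(pif_num)], pif_num[length(times)]))
cat(sprintf("PIF3 closed form vs numeric: %.1f%% max deviation for t >= 3 d\n",
            100 * max(abs(pif_cf[late] - pif_num[late]) / pif_num[late])))

traj <- data.frame(time = times, phyb = phyb_cf,
                   pfr = pfr_level(times, photo),
                   pif_numeric = pif_num, pif_closed_form = pif_cf)
attr(traj, "params") <- list(photo = photo, pif = pif)
write_trajectory_csv(traj, "results/signalling_trajectories.csv")
write_trajectory_json(traj, "results/signalling_trajectories.json")

cmp <- data.frame(
  quantity = c("phyb_closed_vs_ode_max_rel", "phyb_twostate_vs_ode_max_rel",
               "pif_closed_vs_numeric_max_rel_t3plus",
               "pif_minimum", "pif_minimum_time_days"),
  value = c(max(abs(tr_ode$phyb - phyb_cf) / phyb_cf),
            max(abs(tr_two$phyb - phyb_cf) / phyb_cf),
            max(abs(pif_cf[late] - pif_num[late]) / pif_num[late]),
            min(pif_num), times[which.min(pif_num)]))
write.csv(cmp, "results/signalling_comparison.csv", row.names = FALSE)
cat("wrote results/signalling_trajectories.{csv,json} and results/signalling_comparison.csv\n")
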