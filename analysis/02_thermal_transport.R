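#!/usr/bin/env Rscript
# Stage 2: heat transport. For each replica, the steady-state heat flux
# comes from the thermostat ledger (factor 2 for the periodic two-bilayer
# geometry), the temperature gradient from regression of the membrane
# temperature profile, the conductivity from Fourier's law and the
# conductance from lambda/delta with delta the phosphate-plane separation.
# Replicas are summarized as mean +/- standard error of the mean.

suppressPackageStartupMessages(library(thermolip))

base <- "scratch/inputs"
if (!dir.exists(base)) stop("run analysis/01_simulate_inputs.R first")
reps <- list.dirs(base, recursive = FALSE)
dir.create("results", showWarnings = FALSE)

rows <- lapply(reps, function(dir) {
  gro <- read_gro(file.path(dir, "conf.gro"))
  frames <- collect_frames(read_trajectory(file.path(dir, "traj.gro"), gro$topology))
  ledger <- read_ledger(file.path(dir, "ledger.csv"), area = 64)
  prof <- read.csv(file.path(dir, "profile.csv"))
  prof <- new_profile(prof$z_nm, prof$value)
  tr <- transport_result(heat_flux(ledger),
                         fit_gradient(prof, window = c(3, 7)),
                         bilayer_thickness(frames, gro$topology))
  c(J_q_W_m2 = tr$J_q, gradT_K_m = tr$gradT, lambda_W_Km = tr$lambda,
    delta_nm = tr$delta, G_MW_Km2 = tr$G)
})

agg <- aggregate_replicas(rows)
write.csv(agg, "results/transport.csv", row.names = FALSE)
print(agg, digits = 6)

lam <- agg$mean[agg$metric == "lambda_W_Km"]
cat(sprintf("\nRecovered conductivity %.4f +/- %.4f W/(K m) (generator target 0.124)\n",
            lam, agg$sem[agg$metric == "lambda_W_Km"]))
cat(sprintf("Conductance %.2f MW/(K m^2) across a %.2f nm bilayer\n",
            agg$mean[agg$metric == "G_MW_Km2"], agg$mean[agg$metric == "delta_nm"]))
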