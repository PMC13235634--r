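#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs with known ground truth.
#
# Five replicas, each consisting of: a membrane trajectory (multi-frame GRO)
# whose cold-leaflet cholesterol fraction relaxes with tau = 16.1 ns to
# xs = 0.56 from a symmetric start; a thermostat energy ledger and matching
# membrane temperature profile generated from a target conductivity of
# 0.124 W/(K m); and heating/cooling annealing scans of area per lipid with
# transition midpoints 310/303 K. Everything downstream (stages 02-05) is
# pure analysis of these files.
#
# Bulky trajectory files go under scratch/ (they are regenerable from this
# script); only summary tables land in results/.

suppressPackageStartupMessages(library(thermolip))

base <- "scratch/inputs"
dir.create(base, recursive = TRUE, showWarnings = FALSE)
n_replicas <- 5
lambda_true <- 0.124   # W/(K m)
tau_true <- 16.1       # ns
xs_true <- 0.56

for (r in seq_len(n_replicas)) {
  dir <- file.path(base, sprintf("rep%d", r))
  dir.create(dir, showWarnings = FALSE)
  mem <- gen_membrane_frames(
    n_pc_per_leaflet = 100, n_chol = 100,      # 50:50 PC:CHOL
    n_frames = 35, dt_ps = 3000,
    x_cold_of_t = function(t) 0.5 + (xs_true - 0.5) * (1 - exp(-t / (tau_true * 1000))),
    seed = 100 + r)
  write_gro(mem$frames[[1]], mem$topology, file.path(dir, "conf.gro"))
  write_gro(mem$frames, mem$topology, file.path(dir, "traj.gro"))
  g <- gen_ledger(lambda_true, gradT = -2e9, area = 64, noise_sd = 0.02,
                  seed = 200 + r, window = c(3, 7), T_mid = 347)
  write_ledger(g$ledger, file.path(dir, "ledger.csv"))
  write_profile(g$profile, file.path(dir, "profile.csv"))
  sc <- gen_hysteresis_scan(Tm_heat = 310, Tm_cool = 303,
                            noise = 0.002, seed = 300 + r, replica = r)
  write.csv(rbind(as.data.frame(sc$heating), as.data.frame(sc$cooling)),
            file.path(dir, "annealing.csv"), row.names = FALSE)
  cat(sprintf("replica %d: %d-frame trajectory, ledger (%d samples), annealing scans\n",
              r, 35, length(g$ledger$times)))
}

cat(sprintf("\nInputs for %d replicas under %s\n", n_replicas, base))
cat(sprintf("Ground truth: lambda = %.3f W/(K m), tau = %.1f ns, xs = %.2f, Tm = %.1f K\n",
            lambda_true, tau_true, xs_true, (310 + 303) / 2))
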