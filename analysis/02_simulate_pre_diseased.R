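#!/usr/bin/env Rscript
# Step 2 - simulate the pre-diseased extension trial.
#
# Runs the unloaded knee-extension simulation (60 -> 0 degrees, 60 samples)
# on the pre-diseased model: flexion is prescribed, the five free
# tibiofemoral coordinates equilibrate quasi-statically under gravity,
# ligament and contact forces. Writes the reference kinematic and strain
# curves that every later comparison uses.

library(tkaplan)
dir.create("results", showWarnings = FALSE)

model <- read_knee_model("results/patient_pre_diseased.json")
trace <- simulate_extension(model, t = 60)
stopifnot(all(trace$converged))
write_trace_csv(trace, "results/pre_diseased_kinematics.csv",
                "results/pre_diseased_strains.csv")

message("pre-diseased extension trial:")
message(sprintf("  %d/%d samples converged, max residual %.2g N (contract: 5 N)",
                sum(trace$converged), trace$t, max(trace$residual)))
rng <- round(100 * apply(trace$strain, 2, range), 2)
message("  strain ranges (%): ",
        paste(sprintf("%s [%g, %g]", colnames(rng), rng[1, ], rng[2, ]),
              collapse = ", "))
message("wrote results/pre_diseased_{kinematics,strains}.csv")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  ggplot2::ggsave("results/figures/pre_diseased_kinematics.pdf",
                  plot_trace_overlay(list(pre_diseased = trace)),
                  width = 8, height = 5)
}
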