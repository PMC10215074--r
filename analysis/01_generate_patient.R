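#!/usr/bin/env Rscript
# Step 1 - generate the synthetic pre-diseased patient.
#
# Builds the default synthetic knee (seed 1): eight ligament bundles at
# jittered anatomical attachment sites, per-condyle femoral spheres on a
# near-planar tibial profile with a 5 degree posterior slope, and slack
# lengths calibrated to the full-extension reference strains. Writes the
# model file consumed by the later steps.

library(tkaplan)
dir.create("results", showWarnings = FALSE)

spec <- patient_spec(seed = 1)
model <- generate_knee(spec)
write_knee_model(model, "results/patient_pre_diseased.json")

lig <- model$ligaments
message("generated pre-diseased knee (seed ", spec$seed, "):")
message("  ligaments: ", paste(lig$name, collapse = ", "))
message(sprintf("  slack lengths %.0f-%.0f mm, stiffness %.0f-%.0f N",
                min(lig$L0), max(lig$L0), min(lig$k), max(lig$k)))
message(sprintf("  native tibial slope %.0f deg, shank mass %.1f kg",
                spec$slope, model$mass))
message("wrote results/patient_pre_diseased.json")
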