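#!/usr/bin/env Rscript
# Step 1 — define the synthetic study and write its recipes.
#
# The study is a synthetic twin of a patient-sized CT phantom NPS
# measurement: an elliptical fat-equivalent annulus around a central test
# module, scanned repeatedly at six CTDIvol levels, with two noise-texture
# families standing in for reconstruction algorithms:
#   * fbp_like  — band-pass texture (marginal NPS peak at mid frequency),
#   * mbir_like — Gaussian low-pass texture (power concentrated at low
#                 frequency), with the band center drifting toward lower
#                 frequency as dose drops (dose-dependent smoothing).
# Everything is deterministic given the seed, so the recipe files written
# here ARE the dataset; step 02 regenerates the image stacks from them.

suppressMessages(library(ringnps))
suppressMessages(library(yaml))

out_dir <- "results/recipes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

doses <- c(0.97, 1.69, 2.9, 5.81, 11.62, 18.88)  # CTDIvol ladder, mGy
master_seed <- 20161
n_scans <- 10
sigma_ref <- 10          # HU at 18.88 mGy
g_center <- 2            # center-elevated noise magnitude
r_edge_px <- 256

# mbir-like texture peak drifts 0.2 -> 0.1 /mm as dose falls 18.88 -> 0.97
mbir_f0 <- function(dose) {
  0.1 + 0.1 * log(dose / min(doses)) / log(max(doses) / min(doses))
}

recipes <- list()
k <- 0
for (dose in doses) {
  for (fam in c("fbp_like", "mbir_like")) {
    k <- k + 1
    recipes[[k]] <- list(
      condition = sprintf("%s_%05.2fmGy", fam, dose),
      # both textures are band-pass ridges; they differ in where the
      # marginal-NPS peak sits and how much total power they carry
      family = "bandpass",
      f0_per_mm = if (fam == "fbp_like") 0.30 else mbir_f0(dose),
      width_per_mm = 0.15,
      sigma_ref_hu = if (fam == "fbp_like") sigma_ref else 0.55 * sigma_ref,
      dose_ref_mGy = max(doses),
      dose_mGy = dose,
      n_scans = n_scans,
      seed = master_seed + k,
      g_center = g_center,
      r_edge_px = r_edge_px,
      phantom = list(rows = 512, cols = 512, pixel_spacing_mm = 0.703125,
                     outer_semiaxes_mm = c(170, 135), annulus_hu = -100,
                     module_radius_mm = 100, module_hu = 40,
                     background_hu = -1000))
  }
}

for (r in recipes) {
  write_yaml(r, file.path(out_dir, paste0(r$condition, ".yaml")))
}
cat("wrote", length(recipes), "recipes to", out_dir, "\n")

# Exercise the stack I/O path once: a small series written and re-read.
demo <- generate_scan_series(series_recipe(
  phantom = NULL, noise = noise_model("white", sigma_ref),
  n_scans = 2, dose_mGy = max(doses), seed = master_seed,
  rows = 64, cols = 64, pixel_spacing_mm = 0.703125, condition = "demo"))
dir.create("scratch", showWarnings = FALSE)
write_array_stack(demo, "scratch/demo_stack.stk")
back <- read_array_stack("scratch/demo_stack.stk")
stopifnot(identical(back$pixels, demo$pixels))
cat("array-stack round trip verified (scratch/demo_stack.stk)\n")
cat(sprintf("phantom noise at reference dose: sigma = %.1f HU (white demo sd %.2f)\n",
            sigma_ref, sd(as.vector(demo$pixels))))
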