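# Shared fixture builders; everything is generated in code at test time.

std_spacing <- 0.703125  # 36 cm field of view / 512 matrix, mm

# Stack of pure white-noise "scans" on a flat 0 HU background.
white_stack <- function(n_scans = 4, side = 128, sigma = 10, seed = 1,
                        condition = "white") {
  generate_scan_series(series_recipe(
    phantom = NULL,
    noise = noise_model("white", sigma_ref = sigma),
    n_scans = n_scans, dose_mGy = 18.88, seed = seed,
    condition = condition, rows = side, cols = side,
    pixel_spacing_mm = std_spacing))
}

# Ensemble of independently synthesized patch-sized noise fields with a
# known target spectrum; expected periodogram equals the target exactly.
synth_patches <- function(target, n, spacing = std_spacing, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    ringnps::synthesize_noise_field(target, spacing)
  }))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
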