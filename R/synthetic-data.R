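# Synthetic serum-colour data generator.
#
# Emulates the graded-haemolysis study design: serum from each animal is
# split into subsamples, haemolysate is added to reach nominal haemolysed
# fractions, and the free-Hb concentration in serum (g/L) is the fraction
# of the animal's whole-blood Hb. Absorbance at 540 nm and the RGB colour
# of a photographed cuvette are simulated from published calibration lines,
# with Gaussian noise calibrated so that a study-sized design reproduces
# the published correlation coefficients in expectation.

#' Nominal haemolysed fractions of the graded-haemolysis design
#'
#' The seven haemolysis levels of the study design: 0.0, 0.2, 0.5, 1.0,
#' 2.5, 5.0 and 10 percent, expressed as unitless fractions.
#'
#' @return Numeric vector of length 7, sorted ascending.
#' @export
haemolysis_fractions <- function() {
  c(0, 0.002, 0.005, 0.01, 0.025, 0.05, 0.1)
}

#' Forward-model parameters for the synthetic generator
#'
#' Bundles every constant of the signal forward models: the absorbance and
#' Redbance calibration lines (intercepts and slopes), the target Pearson
#' correlations used to calibrate calibration-scatter noise, weak linear
#' trends for the green and blue channels, the baseline free-Hb spread of
#' blank sera, and within-run replicate (instrument) noise used for
#' precision/LOD studies.
#'
#' Replicate noise is deliberately much smaller than calibration scatter:
#' calibration scatter includes between-animal matrix effects, whereas ten
#' repeat measurements of one specimen only see instrument repeatability
#' (about 0.005 absorbance units for a benchtop spectrophotometer, and
#' about one 8-bit channel unit, i.e. 0.002 Redbance units at R ~ 200, for
#' repeat photographs).
#'
#' @param abs_intercept,abs_slope Absorbance calibration line (A at Hb = 0;
#'   A per g/L).
#' @param red_intercept,red_slope Redbance calibration line (Redbance units;
#'   Redbance per g/L).
#' @param target_r_abs,target_r_red Pearson correlations the calibration
#'   scatter is tuned to reproduce; must lie in (0, 1).
#' @param g_intercept,g_slope,g_noise_sd Green-channel model
#'   `G = g_intercept + g_slope * Hb + N(0, g_noise_sd)`, clamped to
#'   `[1, 255]`. Defaults keep cor(G, Hb) below 0.5 on a study-sized design.
#' @param b_intercept,b_slope,b_noise_sd Blue-channel model, as for green.
#' @param baseline_free_hb_sd SD (g/L) of the baseline free Hb present in
#'   0 % haemolysis blanks; draws are clipped at zero.
#' @param abs_replicate_sd Within-run absorbance repeatability (A).
#' @param red_replicate_sd Within-run Redbance repeatability.
#' @param g_replicate_sd,b_replicate_sd Within-run channel repeatability
#'   (channel units) for repeat photographs.
#' @return An object of class `forward_params` (a named list).
#' @export
forward_params <- function(abs_intercept = 0.1051, abs_slope = 0.0873,
                           red_intercept = 0.0929, red_slope = 0.0187,
                           target_r_abs = 0.991, target_r_red = 0.983,
                           g_intercept = 185, g_slope = -1.0, g_noise_sd = 8,
                           b_intercept = 125, b_slope = -0.5, b_noise_sd = 10,
                           baseline_free_hb_sd = 0.02,
                           abs_replicate_sd = 0.005,
                           red_replicate_sd = 0.002,
                           g_replicate_sd = 0.5, b_replicate_sd = 0.5) {
  if (abs_slope <= 0 || red_slope <= 0)
    stop("calibration slopes must be positive")
  for (r in c(target_r_abs, target_r_red))
    if (r <= 0 || r >= 1) stop("target correlations must lie in (0, 1)")
  if (baseline_free_hb_sd < 0) stop("baseline_free_hb_sd must be >= 0")
  structure(list(
    abs_intercept = abs_intercept, abs_slope = abs_slope,
    red_intercept = red_intercept, red_slope = red_slope,
    target_r_abs = target_r_abs, target_r_red = target_r_red,
    g_intercept = g_intercept, g_slope = g_slope, g_noise_sd = g_noise_sd,
    b_intercept = b_intercept, b_slope = b_slope, b_noise_sd = b_noise_sd,
    baseline_free_hb_sd = baseline_free_hb_sd,
    abs_replicate_sd = abs_replicate_sd,
    red_replicate_sd = red_replicate_sd,
    g_replicate_sd = g_replicate_sd, b_replicate_sd = b_replicate_sd
  ), class = "forward_params")
}

#' Generate a graded-haemolysis study design
#'
#' Draws one whole-blood Hb value per animal from a truncated normal
#' distribution (mean 110 g/L, SD 15, bounds 80-140 g/L, the reference
#' interval of healthy adult dairy cattle) and crosses the animals with the
#' nominal haemolysed fractions. The default design is 10 animals x 7
#' fractions = 70 serum samples.
#'
#' @param n_animals Number of animals (>= 1).
#' @param fractions Haemolysed fractions, each in `[0, 0.1]`.
#' @param seed Integer RNG seed; the design is deterministic given the seed.
#' @param blood_hb_mean,blood_hb_sd,blood_hb_bounds Truncated-normal
#'   parameters for whole-blood Hb (g/L).
#' @return An object of class `study_design`: a list with `animal_ids`,
#'   `blood_hb` (named, g/L), `fractions`, `seed` and `n_samples`.
#' @examples
#' d <- generate_design(10, haemolysis_fractions(), seed = 42)
#' d$n_samples  # 70
#' @export
generate_design <- function(n_animals = 10,
                            fractions = haemolysis_fractions(),
                            seed = 42L,
                            blood_hb_mean = 110, blood_hb_sd = 15,
                            blood_hb_bounds = c(80, 140)) {
  if (length(n_animals) != 1 || n_animals < 1 || n_animals != round(n_animals))
    stop("n_animals must be a positive integer")
  if (length(fractions) == 0)
    stop("fractions must be non-empty")
  if (any(fractions < 0 | fractions > 0.1))
    stop("haemolysed fractions must lie in [0, 0.1]; got ",
         paste(fractions[fractions < 0 | fractions > 0.1], collapse = ", "))
  set.seed(seed)
  blood_hb <- truncnorm::rtruncnorm(n_animals, a = blood_hb_bounds[1],
                                    b = blood_hb_bounds[2],
                                    mean = blood_hb_mean, sd = blood_hb_sd)
  animal_ids <- sprintf("cow%02d", seq_len(n_animals))
  names(blood_hb) <- animal_ids
  structure(list(
    animal_ids = animal_ids,
    blood_hb = blood_hb,
    fractions = sort(fractions),
    seed = as.integer(seed),
    n_samples = n_animals * length(fractions)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Graded-haemolysis study design\n")
  cat(sprintf("  %d animals x %d fractions = %d serum samples\n",
              length(x$animal_ids), length(x$fractions), x$n_samples))
  cat("  whole-blood Hb (g/L):",
      paste(sprintf("%.1f", x$blood_hb), collapse = " "), "\n")
  cat("  fractions:", paste(x$fractions, collapse = " "), "\n")
  invisible(x)
}

#' Serum free-Hb concentration of a graded-haemolysis subsample
#'
#' The free Hb released into serum is the haemolysed fraction times the
#' whole-blood Hb, plus a small non-negative baseline free-Hb term drawn
#' from `N(0, baseline_sd)` and clipped at zero (blank sera are not
#' perfectly Hb-free). Draws use the current RNG stream.
#'
#' @param blood_hb Whole-blood Hb (g/L), positive.
#' @param fraction Haemolysed fraction in `[0, 0.1]`. Recycled against
#'   `blood_hb`.
#' @param baseline_sd SD (g/L) of the baseline free-Hb term; 0 disables it.
#' @return Serum Hb in g/L.
#' @examples
#' serum_hb(100, 0.10)  # 10 g/L
#' @export
serum_hb <- function(blood_hb, fraction, baseline_sd = 0) {
  if (any(blood_hb <= 0)) stop("blood_hb must be positive")
  if (any(fraction < 0 | fraction > 0.1))
    stop("fraction must lie in [0, 0.1]")
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  n <- max(length(blood_hb), length(fraction))
  baseline <- if (baseline_sd > 0) pmax(0, stats::rnorm(n, 0, baseline_sd)) else 0
  blood_hb * fraction + baseline
}

#' Absorbance forward model at 540 nm
#'
#' `A = abs_intercept + abs_slope * Hb + N(0, noise_sd)`, clipped at zero.
#'
#' @param hb Serum Hb (g/L), non-negative.
#' @param params A [forward_params()] object.
#' @param noise_sd Gaussian noise SD in absorbance units (>= 0).
#' @return Absorbance units (vectorized over `hb`).
#' @examples
#' absorbance_forward(0)   # 0.1051
#' absorbance_forward(10)  # 0.9781
#' @export
absorbance_forward <- function(hb, params = forward_params(), noise_sd = 0) {
  if (any(hb < 0)) stop("hb must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- params$abs_intercept + params$abs_slope * hb
  if (noise_sd > 0) mu <- mu + stats::rnorm(length(mu), 0, noise_sd)
  pmax(0, mu)
}

#' Noise SD reproducing a target Pearson correlation
#'
#' For `y = a + b x + e`, `e ~ N(0, s^2)`, the population correlation is
#' `|b| sd(x) / sqrt(b^2 sd(x)^2 + s^2)`. Solving for `s` gives
#' `s = |b| sd(x) sqrt(1 / r^2 - 1)`; data simulated with this SD reproduce
#' the target correlation in expectation over the given design points.
#'
#' @param slope Calibration slope (signal per g/L).
#' @param hb_values Design Hb values (g/L) with non-zero variance.
#' @param target_r Target Pearson correlation in (0, 1).
#' @return Noise SD in signal units.
#' @examples
#' noise_sd_for_target_r(1, c(0, 1, 2), 0.5)  # sqrt(3)
#' @export
noise_sd_for_target_r <- function(slope, hb_values, target_r) {
  if (target_r <= 0 || target_r >= 1) stop("target_r must lie in (0, 1)")
  s <- stats::sd(hb_values)
  if (!is.finite(s) || s == 0)
    stop("hb_values must have non-zero variance")
  abs(slope) * s * sqrt(1 / target_r^2 - 1)
}

#' RGB forward colour model of a haemolysed serum sample
#'
#' The red channel follows the (inverted) Redbance calibration line:
#' noise is injected on the Redbance scale, so the published line is the
#' recoverable truth, then mapped back to the channel scale through
#' `R = 256 * 10^-(red_intercept + red_slope * Hb + e)` and clamped to
#' `[1, 255]`. Green and blue follow weak linear trends with noise large
#' enough that their correlation with Hb stays below 0.5 on a study-sized
#' design. Channel values are kept as real numbers (ImageJ-style region
#' means), not 8-bit integers.
#'
#' @param hb Serum Hb (g/L), non-negative; vectorized.
#' @param params A [forward_params()] object.
#' @param red_noise_sd Redbance-scale noise SD (0 for the noise-free line).
#' @param g_noise_sd,b_noise_sd Channel-scale noise SDs for green and blue;
#'   default to the values in `params`, set to 0 for noise-free output.
#' @return Numeric matrix with one row per `hb` value and columns
#'   `r`, `g`, `b` on the 0-255 scale.
#' @examples
#' rgb_forward(0, g_noise_sd = 0, b_noise_sd = 0)   # R ~ 206.7
#' @export
rgb_forward <- function(hb, params = forward_params(), red_noise_sd = 0,
                        g_noise_sd = params$g_noise_sd,
                        b_noise_sd = params$b_noise_sd) {
  if (any(hb < 0)) stop("hb must be >= 0")
  n <- length(hb)
  redb <- params$red_intercept + params$red_slope * hb
  if (red_noise_sd > 0) redb <- redb + stats::rnorm(n, 0, red_noise_sd)
  r <- pmin(pmax(256 * 10^(-redb), 1), 255)
  g <- params$g_intercept + params$g_slope * hb
  if (g_noise_sd > 0) g <- g + stats::rnorm(n, 0, g_noise_sd)
  b <- params$b_intercept + params$b_slope * hb
  if (b_noise_sd > 0) b <- b + stats::rnorm(n, 0, b_noise_sd)
  cbind(r = r, g = pmin(pmax(g, 1), 255), b = pmin(pmax(b, 1), 255))
}

#' Simulate the full sample table of a study design
#'
#' Produces the analogue of the study's 70 x 7 data matrix: one row per
#' serum sample carrying the reference Hb (the role of the wet-chemistry
#' reference value), the absorbance at 540 nm, the R, G, B channel means
#' and the weighted intensity. Calibration-scatter noise for absorbance and
#' Redbance is calibrated with [noise_sd_for_target_r()] against the
#' design's Hb values so the published correlations are reproduced in
#' expectation.
#'
#' All randomness comes from a single seeded stream with a fixed draw
#' order (baselines, then absorbance noise, then R, G, B noise), so the
#' table is byte-reproducible for a given design and seed.
#'
#' @param design A [generate_design()] object.
#' @param params A [forward_params()] object.
#' @param seed Integer seed; defaults to the design's seed plus one so the
#'   signal stream differs from the blood-Hb stream.
#' @return A `data.frame` with columns `sample_id`, `animal_id`, `fraction`,
#'   `hb_ref`, `absorbance540`, `r_mean`, `g_mean`, `b_mean`, `intensity`.
#' @export
simulate_samples <- function(design, params = forward_params(),
                             seed = design$seed + 1L) {
  stopifnot(inherits(design, "study_design"))
  animal <- rep(design$animal_ids, times = length(design$fractions))
  frac <- rep(design$fractions, each = length(design$animal_ids))
  blood <- design$blood_hb[animal]
  set.seed(seed)
  hb <- serum_hb(blood, frac, baseline_sd = params$baseline_free_hb_sd)
  s_hb <- if (length(hb) > 1) stats::sd(hb) else 0
  if (is.finite(s_hb) && s_hb > 0) {
    sd_abs <- noise_sd_for_target_r(params$abs_slope, hb, params$target_r_abs)
    sd_red <- noise_sd_for_target_r(params$red_slope, hb, params$target_r_red)
  } else {
    # degenerate single-level design: no scatter can be calibrated
    sd_abs <- sd_red <- 0
  }
  a540 <- absorbance_forward(hb, params, noise_sd = sd_abs)
  rgb <- rgb_forward(hb, params, red_noise_sd = sd_red)
  data.frame(
    sample_id = sprintf("%s_f%05.3f", animal, frac),
    animal_id = animal,
    fraction = frac,
    hb_ref = as.numeric(hb),
    absorbance540 = a540,
    r_mean = rgb[, "r"],
    g_mean = rgb[, "g"],
    b_mean = rgb[, "b"],
    intensity = weighted_intensity(rgb[, "r"], rgb[, "g"], rgb[, "b"]),
    row.names = NULL
  )
}

#' Render a uniform serum-colour patch to a PNG file
#'
#' Writes a `size` x `size` 8-bit RGB PNG whose pixels are the requested
#' channel means plus optional Gaussian pixel noise. With noise the ROI
#' mean recovers the requested colour to within the standard error of the
#' mean (the noise also dithers away 8-bit quantization); without noise,
#' integer channel values round-trip exactly.
#'
#' @param rgb Length-3 numeric vector of channel means in `[0, 255]`.
#' @param size Patch side in pixels (>= 1).
#' @param pixel_noise_sd Per-pixel Gaussian noise SD in channel units.
#' @param seed Integer seed; rendering is deterministic per seed.
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
render_patch <- function(rgb, size = 64, pixel_noise_sd = 0, seed = 42L,
                         path) {
  if (length(rgb) != 3 || any(rgb < 0 | rgb > 255))
    stop("rgb must be three channel means in [0, 255]")
  if (size < 1) stop("size must be >= 1")
  set.seed(seed)
  img <- array(0, dim = c(size, size, 3))
  for (k in 1:3) {
    ch <- rgb[k]
    if (pixel_noise_sd > 0)
      ch <- ch + stats::rnorm(size * size, 0, pixel_noise_sd)
    img[, , k] <- pmin(pmax(ch, 0), 255) / 255
  }
  ok <- tryCatch({ png::writePNG(img, target = path); TRUE },
                 error = function(e) stop("cannot write image to '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Write / read the sample table as CSV
#'
#' Delimited-text (UTF-8, comma-separated, header row) serialization of the
#' sample table produced by [simulate_samples()] — the analogue of the
#' study's sample data matrix.
#'
#' @param samples Sample table `data.frame`.
#' @param path CSV file path.
#' @return `write_sample_table` returns `path` invisibly;
#'   `read_sample_table` returns the validated `data.frame`.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "animal_id", "fraction", "hb_ref",
              "absorbance540", "r_mean", "g_mean", "b_mean", "intensity")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("sample table is missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Recover the calibration line from replicated synthetic calibrations
#'
#' Generates `n_reps` independent study-sized calibration sets (7 animals x
#' 7 fractions = 49 samples by default), each with noise calibrated to the
#' target correlation, fits the univariate calibration line to each, and
#' returns the mean fitted slope and mean Pearson correlation. Used to
#' verify that the generator's forward models are recoverable.
#'
#' @param signal `"absorbance"` (A at 540 nm vs Hb) or `"redbance"`
#'   (Redbance transform of the simulated R channel vs Hb).
#' @param n_reps Number of replicate calibration sets.
#' @param seed Master seed; replicate `i` uses `seed * 1000 + i`.
#' @param n_animals Animals per replicate design (7 x 7 fractions = 49).
#' @param params A [forward_params()] object.
#' @return List with `mean_slope`, `mean_r`, `slopes`, `rs`, `n_reps`.
#' @export
calibration_recovery <- function(signal = c("absorbance", "redbance"),
                                 n_reps = 200, seed = 1L, n_animals = 7,
                                 params = forward_params()) {
  signal <- match.arg(signal)
  slopes <- numeric(n_reps)
  rs <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- as.integer(seed) * 1000L + i
    design <- generate_design(n_animals, seed = rep_seed)
    set.seed(rep_seed + 500L)
    animal <- rep(design$animal_ids, times = length(design$fractions))
    frac <- rep(design$fractions, each = n_animals)
    hb <- serum_hb(design$blood_hb[animal], frac,
                   baseline_sd = params$baseline_free_hb_sd)
    if (signal == "absorbance") {
      sd_n <- noise_sd_for_target_r(params$abs_slope, hb, params$target_r_abs)
      y <- absorbance_forward(hb, params, noise_sd = sd_n)
    } else {
      sd_n <- noise_sd_for_target_r(params$red_slope, hb, params$target_r_red)
      y <- redbance(rgb_forward(hb, params, red_noise_sd = sd_n)[, "r"])
    }
    fit <- ols_fit(hb, y)
    slopes[i] <- fit$slope
    rs[i] <- fit$r
  }
  list(mean_slope = mean(slopes), mean_r = mean(rs),
       slopes = slopes, rs = rs, n_reps = n_reps)
}
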