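## Synthetic inputs with known ground truth.
##
## Three generators mirror the three kinds of study input: a small-n
## predictor table with a known linear structure plus Gaussian response
## noise, a rendered granule silhouette whose boundary carries a sinusoidal
## roughness of known amplitude, and colonization mask pairs with an exact
## target area fraction. All draws are isolated under withr::with_seed, so
## a given seed always reproduces the same artifact and never disturbs the
## caller's RNG state.

#' Generate a predictor table with known linear structure
#'
#' Draws `X` uniformly within per-column ranges (optionally through a
#' lower-rank latent factor structure) and sets
#' `y = X beta + N(0, noise_sd^2)`. The response-only noise model is a
#' deliberate simplification: it suffices for testing the estimator even
#' though real measurements carry error on both sides.
#'
#' @param n observations (>= 4). Default 50.
#' @param p predictors (>= 1). Default 3.
#' @param beta true original-scale coefficients, length p.
#' @param noise_sd response noise SD (response units, >= 0). Default 2.
#' @param ranges 2 x p matrix (rows: min, max) of predictor ranges, or a
#'   single c(min, max) recycled; default c(0, 30).
#' @param latent_rank rank of the latent structure, `<= p`; `p` (default)
#'   draws columns independently.
#' @param seed integer seed; identical specs give identical tables.
#' @return list with `X` (n x p), `y`, `beta`, and `spec` (the arguments,
#'   including the RNG algorithm used).
#' @examples
#' tg <- sim_table(seed = 1, noise_sd = 0)
#' fit <- pls_fit(tg$X, tg$y, ncomp = 3)
#' pls_equation(fit)$coefficients  # equals tg$beta
#' @export
sim_table <- function(n = 50, p = 3, beta = c(4, -3, 2), noise_sd = 2,
                      ranges = c(0, 30), latent_rank = p, seed = 1) {
  if (n < 4 || p < 1 || latent_rank < 1 || latent_rank > p)
    gpls_error("need n >= 4, p >= 1, 1 <= latent_rank <= p",
               "graftPLS_range_error")
  if (length(beta) != p)
    gpls_error("beta must have length p", "graftPLS_schema_error")
  if (noise_sd < 0)
    gpls_error("noise_sd must be >= 0", "graftPLS_range_error")
  if (is.vector(ranges) && length(ranges) == 2L)
    ranges <- matrix(ranges, 2L, p)
  ranges <- as.matrix(ranges)
  if (!all(dim(ranges) == c(2L, p)) || any(ranges[1L, ] >= ranges[2L, ]))
    gpls_error("ranges must be a 2 x p matrix with min < max",
               "graftPLS_range_error")
  out <- withr::with_seed(seed, {
    U <- if (latent_rank < p) {
      F0 <- matrix(runif(n * latent_rank), n, latent_rank)
      L <- matrix(runif(latent_rank * p, -1, 1), latent_rank, p)
      Z <- F0 %*% L
      # map each column onto [0, 1] before range scaling
      apply(Z, 2L, function(z) (z - min(z)) / max(diff(range(z)), 1e-12))
    } else matrix(runif(n * p), n, p)
    X <- sweep(sweep(U, 2L, ranges[2L, ] - ranges[1L, ], "*"),
               2L, ranges[1L, ], "+")
    colnames(X) <- paste0("x", seq_len(p))
    y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
  list(X = out$X, y = out$y, beta = setNames(beta, colnames(out$X)),
       spec = list(n = n, p = p, beta = beta, noise_sd = noise_sd,
                   ranges = ranges, latent_rank = latent_rank, seed = seed,
                   rng = "Mersenne-Twister"))
}

#' Render a synthetic granule image with known boundary roughness
#'
#' Renders the apex cap of a large quasi-circular granule whose boundary
#' radius is `base + waviness + roughness`, imaged in a small frame the way
#' a high-magnification micrograph crops a granule surface. With the
#' default geometry the base curvature contributes less than half a pixel
#' to Pa, so the sinusoidal roughness closed forms (Pa = 2A/pi,
#' Pq = A/sqrt(2), Pt = 2A) are recoverable from the rendered image.
#' Material is rendered bright (0.8) on a dark background (0.2).
#'
#' @param seed integer; sets the sinusoid phases (and the random-mode
#'   spectrum). Same seed, same image.
#' @param image_size c(rows, cols) in pixels.
#' @param pixel_size_um micrometres per pixel. Default 0.25 (a 40 x 40 um
#'   field, matching the study's minimum evaluation length).
#' @param base_radius_um granule base radius. Default 1000 (the upper end
#'   of the study's particle sizes).
#' @param roughness_amplitude_um sinusoid amplitude A (um). Default 2.
#' @param roughness_wavelength_um wavelength along the boundary (um); must
#'   exceed 2 pixels. Default 8.
#' @param waviness_amplitude_um long-wave shape term amplitude; default 0
#'   so the perturbation ground truth stays closed-form.
#' @param waviness_wavelength_um waviness wavelength (um). Default 64.
#' @param apex_offset_um depth of the granule apex below the frame top.
#' @param mode `"sinusoid"` (closed-form ground truth) or `"random"`
#'   (band-limited random roughness; ground truth evaluated numerically
#'   from the continuous boundary).
#' @return list with `image` (a `calibrated_image`), `boundary_um` (exact
#'   continuous boundary depth below the frame top, one value per pixel
#'   column), `truth` (analytic `pa`, `pq`, `pt` of the roughness
#'   perturbation), and `spec`.
#' @export
sim_granule_image <- function(seed = 1, image_size = c(160L, 164L),
                              pixel_size_um = 0.25, base_radius_um = 1000,
                              roughness_amplitude_um = 2,
                              roughness_wavelength_um = 8,
                              waviness_amplitude_um = 0,
                              waviness_wavelength_um = 64,
                              apex_offset_um = 10,
                              mode = c("sinusoid", "random")) {
  mode <- match.arg(mode)
  A <- roughness_amplitude_um
  W <- waviness_amplitude_um
  if (A < 0 || W < 0)
    gpls_error("amplitudes must be >= 0", "graftPLS_range_error")
  if (roughness_wavelength_um <= 2 * pixel_size_um)
    gpls_error("roughness wavelength must exceed 2 pixels (unresolvable)",
               "graftPLS_range_error")
  nr <- image_size[1L]; nc <- image_size[2L]
  width_um <- nc * pixel_size_um
  height_um <- nr * pixel_size_um
  R0 <- base_radius_um
  if (R0 <= width_um / 2)
    gpls_error("granule smaller than the frame width: apex cap not renderable",
               "graftPLS_range_error")
  # centre of the granule, in um from the frame's top-left corner
  cx <- width_um / 2
  cy <- apex_offset_um + R0
  sag <- R0 - sqrt(R0^2 - (width_um / 2)^2)  # curvature drop at the frame edge
  A_bound <- if (mode == "sinusoid") A else A * sqrt(5)
  if (apex_offset_um - W - A_bound < 0 ||
      apex_offset_um + sag + W + A_bound > height_um)
    gpls_error("granule boundary exceeds the frame", "graftPLS_range_error")

  ph <- withr::with_seed(seed, runif(12, 0, 2 * pi))
  perturb <- if (mode == "sinusoid") {
    function(s) A * sin(2 * pi * s / roughness_wavelength_um + ph[1L])
  } else {
    # band-limited random roughness: 5 sinusoids within +/- 30% of the
    # nominal frequency, RMS-matched to the single sinusoid (A/sqrt(2))
    freq <- (1 / roughness_wavelength_um) * seq(0.7, 1.3, length.out = 5L)
    amp <- rep(A / sqrt(5), 5L)
    function(s) {
      out <- 0
      for (k in 1:5) out <- out + amp[k] * sin(2 * pi * freq[k] * s + ph[k])
      out
    }
  }
  waviness <- if (W > 0)
    function(s) W * sin(2 * pi * s / waviness_wavelength_um + ph[6L])
  else function(s) 0 * s
  radius_at <- function(phi) R0 + waviness(R0 * phi) + perturb(R0 * phi)

  xs <- (seq_len(nc) - 0.5) * pixel_size_um
  ys <- (seq_len(nr) - 0.5) * pixel_size_um
  dx <- outer(rep(1, nr), xs - cx)
  dy <- outer(ys - cy, rep(1, nc))
  phi <- atan2(dx, -dy)             # angle from the apex direction
  dist <- sqrt(dx^2 + dy^2)
  material <- dist <= radius_at(phi)
  pixels <- matrix(0.2, nr, nc)
  pixels[material] <- 0.8

  # exact continuous boundary depth per pixel column (root of
  # |p - c| = r(phi) along the vertical line through the column centre)
  boundary_um <- vapply(xs, function(x) {
    f <- function(y) sqrt((x - cx)^2 + (y - cy)^2) -
      radius_at(atan2(x - cx, cy - y))
    stats::uniroot(f, c(0, apex_offset_um + sag + W + A_bound + 2 * pixel_size_um),
                   tol = 1e-10)$root
  }, numeric(1))

  truth <- if (mode == "sinusoid") {
    list(pa = 2 * A / pi, pq = A / sqrt(2), pt = 2 * A)
  } else {
    # evaluate the continuous perturbation over the arc actually rendered
    s <- seq(-width_um / 2, width_um / 2, length.out = 20001L)
    yv <- perturb(s); yv <- yv - mean(yv)
    list(pa = mean(abs(yv)), pq = sqrt(mean(yv^2)), pt = max(yv) - min(yv))
  }
  list(image = calibrated_image(pixels, pixel_size_um),
       boundary_um = boundary_um, truth = truth,
       spec = list(seed = seed, image_size = image_size,
                   pixel_size_um = pixel_size_um, base_radius_um = R0,
                   roughness_amplitude_um = A,
                   roughness_wavelength_um = roughness_wavelength_um,
                   waviness_amplitude_um = W,
                   waviness_wavelength_um = waviness_wavelength_um,
                   apex_offset_um = apex_offset_um, mode = mode,
                   rng = "Mersenne-Twister"))
}

#' Generate a total-zone / colonized mask pair with an exact target fraction
#'
#' The colonized mask gets `round(target / 100 * zone_area)` pixels drawn
#' uniformly inside the zone, so [macroporosity()] recovers the target to
#' within half a pixel's worth of percent.
#'
#' @param seed integer seed.
#' @param zone_shape c(rows, cols) of the rectangular total zone.
#' @param target_macroporosity target percentage in \[0, 100\].
#' @return list with `total`, `colonized` (logical masks), `target`,
#'   `achieved` (the exact rounded percentage).
#' @export
sim_mask_pair <- function(seed = 1, zone_shape = c(100L, 100L),
                          target_macroporosity = 50) {
  if (target_macroporosity < 0 || target_macroporosity > 100)
    gpls_error("target macroporosity must lie in [0, 100]",
               "graftPLS_range_error")
  area <- prod(zone_shape)
  k <- round(target_macroporosity / 100 * area)
  total <- matrix(TRUE, zone_shape[1L], zone_shape[2L])
  colonized <- matrix(FALSE, zone_shape[1L], zone_shape[2L])
  if (k > 0) {
    idx <- withr::with_seed(seed, sample.int(area, k))
    colonized[idx] <- TRUE
  }
  list(total = total, colonized = colonized,
       target = target_macroporosity, achieved = 100 * k / area)
}

#' Generate a synthetic graft study table in the dataset schema
#'
#' Emulates a small-n biomaterial table: random compositions normalized to
#' 100 wt%, particle-size intervals and measured properties drawn within
#' the ranges observed across commercial grafts, with the roughness
#' power-mean ordering (Pa <= Pq <= Pt) built in, and a BMC mean generated
#' from a linear structure in CaCO3, Ti and macroporosity plus Gaussian
#' noise. Round-trips through [write_graft_table()] / [read_graft_table()].
#'
#' @param n_materials number of synthetic biomaterials (>= 2).
#' @param seed integer seed.
#' @param bmc_coef linear structure used for the BMC mean: intercept and
#'   coefficients on CaCO3 wt%, Ti wt% and macroporosity.
#' @param noise_sd SD of the Gaussian noise on the BMC mean (%BMC).
#' @return a `graft_table` with attribute `bmc_truth` (the linear
#'   structure used).
#' @export
sim_graft_table <- function(n_materials = 7, seed = 1,
                            bmc_coef = c(intercept = 58, caco3_wt = 3.6,
                                         ti_wt = -0.22, macroporosity = -0.34),
                            noise_sd = 3) {
  if (n_materials < 2L)
    gpls_error("need at least 2 synthetic biomaterials", "graftPLS_range_error")
  tab <- withr::with_seed(seed, {
    comp <- t(vapply(seq_len(n_materials), function(i) {
      w <- runif(6) * c(10, 10, 0.5, 1, 2, 2)^runif(6, 0.5, 1.5)
      100 * w / sum(w)
    }, numeric(6)))
    colnames(comp) <- c("hap_wt", "btcp_wt", "caco3_wt", "collagen_wt",
                        "h2o_wt", "ti_wt")
    mp <- runif(n_materials, 15, 75)
    pa <- runif(n_materials, 0.3, 1.5)
    pq <- pa * runif(n_materials, 1.1, 1.3)
    pt <- pq * runif(n_materials, 3, 5)
    size_min <- runif(n_materials, 100, 700)
    bmc <- pmin(95, pmax(5,
      bmc_coef[1L] + bmc_coef[2L] * comp[, "caco3_wt"] +
        bmc_coef[3L] * comp[, "ti_wt"] + bmc_coef[4L] * mp +
        rnorm(n_materials, 0, noise_sd)))
    data.frame(
      name = sprintf("synthetic-%02d", seq_len(n_materials)),
      origin = sample(c("bovine", "porcine", "bovine/porcine", "synthetic"),
                      n_materials, replace = TRUE),
      comp,
      size_min_um = size_min, size_max_um = size_min + runif(n_materials, 100, 500),
      macroporosity_mean = mp,
      macroporosity_sd = runif(n_materials, 1, 9), macroporosity_n = 6L,
      pa_mean = pa, pa_sd = pa * runif(n_materials, 0.02, 0.2), pa_n = 3L,
      pt_mean = pt, pt_sd = pt * runif(n_materials, 0.05, 0.3), pt_n = 3L,
      pq_mean = pq, pq_sd = pq * runif(n_materials, 0.03, 0.2), pq_n = 3L,
      bmc_6mo_mean = bmc, bmc_6mo_sd = runif(n_materials, 4, 16),
      bmc_6mo_n = 6L,
      regenerated_area_6mo_mean = runif(n_materials, 50, 97),
      regenerated_area_6mo_sd = runif(n_materials, 3, 16),
      regenerated_area_6mo_n = 6L,
      stringsAsFactors = FALSE)
  })
  out <- as_graft_table(tab)
  attr(out, "bmc_truth") <- list(coef = bmc_coef, noise_sd = noise_sd,
                                 seed = seed)
  out
}
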