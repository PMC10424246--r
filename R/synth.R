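#' Seeded synthetic-data generators
#'
#' Every input the analysis pipeline consumes can be generated with known
#' ground truth, so each analysis operation is verifiable by parameter
#' recovery. All generators take an integer `seed`, restore the caller's
#' RNG state on exit, and attach a `ground_truth` list (generator name,
#' parameters, seed); identical seeds yield identical outputs.
#'
#' @name synth
#' @keywords internal
NULL

.ground_truth <- function(generator, seed, ...) {
  list(generator = generator, seed = seed, parameters = list(...))
}

#' Synthetic beating-cilia image stack
#'
#' Emulates a high-speed recording of beating cilia: each pixel oscillates
#' quasi-sinusoidally at the beat frequency `f0` with a linear spatial
#' phase gradient (a crude metachronal wave), a weak second harmonic
#' (beat asymmetry), and additive Gaussian noise. SNR is defined as the
#' oscillation amplitude divided by the noise standard deviation.
#'
#' @param f0 beat frequency (Hz), below Nyquist (`frame_rate/2`).
#' @param frame_rate frames per second.
#' @param n_frames number of frames.
#' @param height,width frame size (pixels).
#' @param snr amplitude / noise-sd ratio; `Inf` for noiseless.
#' @param amplitude oscillation amplitude (intensity units); 0 gives a
#'   flat (non-beating) stack.
#' @param baseline mean intensity.
#' @param phase_gradient spatial phase gradient (rad/pixel along x).
#' @param second_harmonic relative amplitude of the second harmonic.
#' @param seed RNG seed.
#' @return list with `stack` (T x H x W array) and `ground_truth`.
#' @export
gen_cilia_stack <- function(f0 = 8, frame_rate = 100, n_frames = 1024,
                            height = 16, width = 16, snr = 5,
                            amplitude = 1, baseline = 100,
                            phase_gradient = 0.2, second_harmonic = 0.2,
                            seed = 1L) {
  if (f0 >= frame_rate / 2)
    stop("'f0' must be below the Nyquist frequency (frame_rate/2)")
  .check_positive(frame_rate = frame_rate)
  if (n_frames < 32L) stop("'n_frames' must be >= 32")
  withr::with_seed(seed, {
    t <- (seq_len(n_frames) - 1) / frame_rate
    phase <- outer(rep(1, height), phase_gradient * (seq_len(width) - 1))
    stack <- array(baseline, dim = c(n_frames, height, width))
    for (i in seq_len(n_frames)) {
      osc <- amplitude * sin(2 * pi * f0 * t[i] + phase) +
        second_harmonic * amplitude * sin(4 * pi * f0 * t[i] + 2 * phase)
      stack[i, , ] <- stack[i, , ] + osc
    }
    if (is.finite(snr)) {
      if (snr <= 0) stop("'snr' must be positive or Inf")
      noise_sd <- amplitude / snr
      if (amplitude == 0) noise_sd <- 0
      if (noise_sd > 0)
        stack <- stack + array(stats::rnorm(length(stack), sd = noise_sd),
                               dim = dim(stack))
    }
    list(stack = stack,
         ground_truth = .ground_truth("gen_cilia_stack", seed,
           f0 = f0, frame_rate = frame_rate, n_frames = n_frames,
           height = height, width = width, snr = snr, amplitude = amplitude,
           baseline = baseline, phase_gradient = phase_gradient,
           second_harmonic = second_harmonic))
  })
}

#' Synthetic cilia intensity trace
#'
#' Convenience wrapper: a small [gen_cilia_stack()] reduced to its
#' full-frame ROI trace.
#'
#' @inheritParams gen_cilia_stack
#' @return list with `trace` (an [intensity_trace()]) and `ground_truth`.
#' @export
gen_cilia_trace <- function(f0 = 8, frame_rate = 100, n_frames = 1024,
                            snr = 5, seed = 1L, ...) {
  g <- gen_cilia_stack(f0 = f0, frame_rate = frame_rate,
                       n_frames = n_frames, height = 4, width = 4,
                       snr = snr, seed = seed, ...)
  trace <- extract_roi_trace(g$stack, c(1, 1, 4, 4), frame_rate)
  list(trace = trace, ground_truth = g$ground_truth)
}

#' Synthetic tight-junction (cell-boundary) fluorescence image
#'
#' Cell centers are placed on a hexagonal lattice with nearest-neighbor
#' spacing equal to `mean_cell_diameter`, jittered by zero-mean Gaussian
#' displacements (sd = `jitter` x diameter) under a hard-core minimum
#' separation — a Poisson-disc-like point process whose spacing is
#' controlled exactly. Cell boundaries are the Voronoi ridges of the
#' centers, rendered as Gaussian-profile bright lines of width
#' `boundary_width`; Gaussian noise is added at the stated SNR. With
#' `jitter = 0` the layout is an exact hexagonal lattice whose boundary
#' spacings along lattice rows equal the stated diameter.
#'
#' @param mean_cell_diameter target center-to-center spacing (µm).
#' @param jitter center displacement sd as a fraction of the diameter.
#' @param um_per_pixel pixel size (µm).
#' @param boundary_width Gaussian sd of the rendered ridge (µm); 0 renders
#'   no boundaries (flat image).
#' @param snr ridge amplitude / noise sd; `Inf` for noiseless.
#' @param field_px image side length (pixels, square field).
#' @param seed RNG seed.
#' @return list with `image` (matrix), `centers` (µm coordinates) and
#'   `ground_truth`.
#' @export
gen_junction_image <- function(mean_cell_diameter = 25, jitter = 0.2,
                               um_per_pixel = 0.5, boundary_width = 1,
                               snr = 10, field_px = 256, seed = 1L) {
  .check_positive(mean_cell_diameter = mean_cell_diameter,
                  um_per_pixel = um_per_pixel)
  .check_nonnegative(jitter = jitter, boundary_width = boundary_width)
  withr::with_seed(seed, {
    field_um <- field_px * um_per_pixel
    d <- mean_cell_diameter
    pad <- 2 * d
    # hexagonal lattice covering the padded field
    xs <- seq(-pad, field_um + pad, by = d)
    ys <- seq(-pad, field_um + pad, by = d * sqrt(3) / 2)
    centers <- do.call(rbind, lapply(seq_along(ys), function(r) {
      off <- if (r %% 2 == 0) d / 2 else 0
      cbind(xs + off, ys[r])
    }))
    if (jitter > 0) {
      min_sep <- 0.6 * d   # hard core: keeps jittered cells from collapsing
      for (i in seq_len(nrow(centers))) {
        for (try in 1:20) {
          prop <- centers[i, ] + stats::rnorm(2, sd = jitter * d)
          others <- centers[-i, , drop = FALSE]
          dd <- sqrt((others[, 1] - prop[1])^2 + (others[, 2] - prop[2])^2)
          if (all(dd >= min_sep)) { centers[i, ] <- prop; break }
        }
      }
    }
    # Voronoi ridges: pixel brightness from distance difference of the two
    # nearest centers (zero on the ridge)
    px <- (seq_len(field_px) - 0.5) * um_per_pixel
    grid_x <- matrix(px, field_px, field_px, byrow = TRUE)
    grid_y <- matrix(px, field_px, field_px)
    d1 <- matrix(Inf, field_px, field_px)
    d2 <- matrix(Inf, field_px, field_px)
    for (i in seq_len(nrow(centers))) {
      di <- sqrt((grid_x - centers[i, 1])^2 + (grid_y - centers[i, 2])^2)
      closer <- di < d1
      d2[closer] <- d1[closer]
      d1[closer] <- di[closer]
      mid <- !closer & di < d2
      d2[mid] <- di[mid]
    }
    amplitude <- 100
    image <- if (boundary_width > 0) {
      amplitude * exp(-((d2 - d1)^2) / (2 * boundary_width^2))
    } else matrix(0, field_px, field_px)
    if (is.finite(snr)) {
      if (snr <= 0) stop("'snr' must be positive or Inf")
      image <- image + matrix(stats::rnorm(field_px^2, sd = amplitude / snr),
                              field_px, field_px)
    }
    list(image = image, centers = centers, um_per_pixel = um_per_pixel,
         ground_truth = .ground_truth("gen_junction_image", seed,
           mean_cell_diameter = mean_cell_diameter, jitter = jitter,
           um_per_pixel = um_per_pixel, boundary_width = boundary_width,
           snr = snr, field_px = field_px))
  })
}

#' Synthetic LIVE/DEAD two-channel spot field
#'
#' Cells are point spots at minimum-separation random positions; live
#' cells render as Gaussian spots in the live (calcein) channel, dead
#' cells in the dead (ethidium) channel. The live count is
#' `round(n_cells x viability_pct / 100)`.
#'
#' @param n_cells total cell count (0 gives empty images).
#' @param viability_pct ground-truth viability percentage.
#' @param field_px image side (pixels).
#' @param spot_sigma spot Gaussian sd (pixels).
#' @param min_dist minimum center separation (pixels).
#' @param snr spot amplitude / noise sd.
#' @param seed RNG seed.
#' @return list with `live`, `dead` (matrices), `n_live`, `n_dead`,
#'   `ground_truth`.
#' @export
gen_livedead <- function(n_cells = 200, viability_pct = 93, field_px = 512,
                         spot_sigma = 2, min_dist = 10, snr = 20, seed = 1L) {
  if (n_cells < 0 || viability_pct < 0 || viability_pct > 100)
    stop("invalid 'n_cells' or 'viability_pct'")
  withr::with_seed(seed, {
    n_live <- round(n_cells * viability_pct / 100)
    n_dead <- n_cells - n_live
    pts <- .min_dist_points(n_cells, field_px, min_dist)
    amplitude <- 100
    render <- function(idx) {
      img <- matrix(0, field_px, field_px)
      for (i in idx) {
        img <- .add_spot(img, pts[i, 1], pts[i, 2], spot_sigma, amplitude)
      }
      if (is.finite(snr) && snr > 0)
        img <- img + matrix(stats::rnorm(field_px^2, sd = amplitude / snr),
                            field_px, field_px)
      img
    }
    live_idx <- if (n_live > 0) seq_len(n_live) else integer(0)
    dead_idx <- if (n_dead > 0) n_live + seq_len(n_dead) else integer(0)
    list(live = render(live_idx), dead = render(dead_idx),
         n_live = n_live, n_dead = n_dead,
         ground_truth = .ground_truth("gen_livedead", seed,
           n_cells = n_cells, viability_pct = viability_pct,
           field_px = field_px, spot_sigma = spot_sigma,
           min_dist = min_dist, snr = snr))
  })
}

# dart-throwing minimum-distance point placement
.min_dist_points <- function(n, field_px, min_dist, margin = 6,
                             max_tries = 20000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries) {
    p <- stats::runif(2, margin, field_px - margin)
    if (nrow(pts) == 0L ||
        all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= min_dist^2))
      pts <- rbind(pts, p)
    tries <- tries + 1L
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " points at min distance ", min_dist,
         " in a ", field_px, "px field")
  pts
}

.add_spot <- function(img, x, y, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  xi <- max(1, floor(x - r)):min(ncol(img), ceiling(x + r))
  yi <- max(1, floor(y - r)):min(nrow(img), ceiling(y + r))
  gx <- exp(-((xi - x)^2) / (2 * sigma^2))
  gy <- exp(-((yi - y)^2) / (2 * sigma^2))
  img[yi, xi] <- img[yi, xi] + amplitude * outer(gy, gx)
  img
}

#' Synthetic dextran permeability series
#'
#' Cumulative basal tracer amounts sampled hourly: linear accumulation at
#' the stated slope plus Gaussian sampling noise.
#'
#' @param slope true accumulation rate (amount/h).
#' @param noise_sd Gaussian sd of each sampled amount.
#' @param n_timepoints number of samples (hourly from 0).
#' @param intercept amount at time 0.
#' @param seed RNG seed.
#' @param ... passed to [permeability_series()] (e.g. `condition`).
#' @return list with `series` (a [permeability_series()]) and
#'   `ground_truth`.
#' @export
gen_dextran_series <- function(slope = 0.42, noise_sd = 0.05,
                               n_timepoints = 4, intercept = 0, seed = 1L,
                               ...) {
  if (n_timepoints < 3L) stop("'n_timepoints' must be >= 3")
  .check_nonnegative(noise_sd = noise_sd)
  withr::with_seed(seed, {
    times <- seq_len(n_timepoints) - 1
    amounts <- intercept + slope * times +
      stats::rnorm(n_timepoints, sd = noise_sd)
    list(series = permeability_series(times, amounts, ...),
         ground_truth = .ground_truth("gen_dextran_series", seed,
           slope = slope, noise_sd = noise_sd,
           n_timepoints = n_timepoints, intercept = intercept))
  })
}

#' Synthetic per-cell DAPI x GFP histocytometry table
#'
#' Emulates per-cell mean intensities exported from segmented
#' immunofluorescence scans of a virus-reporter (GFP) infection assay.
#' Rows are a mixture of nucleated cells (high DAPI) and a small debris
#' population (low DAPI), as real segmentations contain some non-nuclear
#' objects. Among cells, a fraction `infected_fraction` is infected; GFP
#' intensities are drawn from a low (uninfected) and high (infected)
#' log-normal mixture — fluorescence intensities are positive and
#' right-skewed. Infected counts are deterministic
#' (`round(n_cell_rows x fraction)`), so the realized fraction matches the
#' requested one up to rounding.
#'
#' @param n_cells total table rows (cells + debris).
#' @param infected_fraction fraction of nucleated cells infected (0-1).
#' @param debris_fraction fraction of rows that are low-DAPI debris.
#' @param dapi_meanlog,dapi_sdlog log-normal parameters of cell DAPI.
#' @param gfp_lo_meanlog,gfp_hi_meanlog,gfp_sdlog log-normal parameters of
#'   uninfected / infected GFP.
#' @param seed RNG seed.
#' @return list with `table` (data.frame: `cell_id`, `dapi_mean`,
#'   `gfp_mean`), `truth_labels` (per-row `"debris"`, `"uninfected"`,
#'   `"infected"`) and `ground_truth`.
#' @export
gen_infection_table <- function(n_cells = 5000, infected_fraction = 0.106,
                                debris_fraction = 0.05,
                                dapi_meanlog = log(500), dapi_sdlog = 0.3,
                                gfp_lo_meanlog = log(50),
                                gfp_hi_meanlog = log(1500),
                                gfp_sdlog = 0.5, seed = 1L) {
  if (infected_fraction < 0 || infected_fraction > 1)
    stop("'infected_fraction' must be in [0, 1]")
  if (n_cells < 1L) stop("'n_cells' must be >= 1")
  withr::with_seed(seed, {
    n_debris <- round(n_cells * debris_fraction)
    n_real <- n_cells - n_debris
    n_inf <- round(n_real * infected_fraction)
    labels <- c(rep("debris", n_debris),
                rep("infected", n_inf),
                rep("uninfected", n_real - n_inf))
    dapi <- c(stats::rlnorm(n_debris, log(20), 0.5),
              stats::rlnorm(n_real, dapi_meanlog, dapi_sdlog))
    gfp <- c(stats::rlnorm(n_debris, gfp_lo_meanlog, gfp_sdlog),
             stats::rlnorm(n_inf, gfp_hi_meanlog, gfp_sdlog),
             stats::rlnorm(n_real - n_inf, gfp_lo_meanlog, gfp_sdlog))
    ord <- sample.int(n_cells)
    list(table = data.frame(cell_id = seq_len(n_cells),
                            dapi_mean = dapi[ord], gfp_mean = gfp[ord]),
         truth_labels = labels[ord],
         ground_truth = .ground_truth("gen_infection_table", seed,
           n_cells = n_cells, infected_fraction = infected_fraction,
           debris_fraction = debris_fraction))
  })
}

#' Synthetic TEER differentiation time course
#'
#' Barrier resistance during mucociliary differentiation typically rises
#' to an early peak (tight-junction formation) and then declines as the
#' epithelium matures and sheds. The template is a gamma-shaped curve
#' `peak_value * ((day/peak_day) * exp(1 - day/peak_day))^shape`;
#' replicate readings add Gaussian noise. Records are emitted in raw/blank
#' form so the TEER computation itself is exercised downstream.
#'
#' @param days measurement days.
#' @param peak_value template peak TEER (Ω·cm²).
#' @param peak_day day of the template peak.
#' @param shape curvature exponent (smaller = flatter decline).
#' @param replicate_sd replicate noise sd (Ω·cm²).
#' @param n_reps replicates per day.
#' @param condition condition label.
#' @param blank_resistance cell-free insert resistance (Ω).
#' @param membrane_area insert area (cm²).
#' @param seed RNG seed.
#' @return list with `records` (data.frame for [teer_timecourse()]),
#'   `template` (data.frame `day`, `teer`), `ground_truth`.
#' @export
gen_teer_course <- function(days = c(1, 3, 7, 14, 21, 28),
                            peak_value = 1000, peak_day = 7, shape = 0.8,
                            replicate_sd = 40, n_reps = 3,
                            condition = "printed",
                            blank_resistance = 120, membrane_area = 0.33,
                            seed = 1L) {
  .check_positive(peak_value = peak_value, peak_day = peak_day,
                  shape = shape, membrane_area = membrane_area)
  .check_nonnegative(replicate_sd = replicate_sd)
  withr::with_seed(seed, {
    template <- peak_value * ((days / peak_day) * exp(1 - days / peak_day))^shape
    rows <- do.call(rbind, lapply(seq_along(days), function(i) {
      vals <- pmax(0, template[i] + stats::rnorm(n_reps, sd = replicate_sd))
      data.frame(condition = condition, day = days[i],
                 rep = seq_len(n_reps),
                 raw_resistance = blank_resistance + vals / membrane_area,
                 blank_resistance = blank_resistance,
                 membrane_area = membrane_area)
    }))
    list(records = rows,
         template = data.frame(day = days, teer = template),
         ground_truth = .ground_truth("gen_teer_course", seed,
           days = days, peak_value = peak_value, peak_day = peak_day,
           shape = shape, replicate_sd = replicate_sd, n_reps = n_reps,
           condition = condition, blank_resistance = blank_resistance,
           membrane_area = membrane_area))
  })
}
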