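#' Intensity profile along a line across an image
#'
#' Reproduces the draw-a-line-and-read-intensities workflow used to
#' quantify tight-junction (ZO-1) fluorescence: intensities are sampled by
#' bilinear interpolation at 1-pixel arc-length steps from `p0` to `p1`.
#'
#' Coordinates are 1-based `(x, y)` pairs (`x` = column, `y` = row) with
#' pixel centers at integers.
#'
#' @param image numeric H x W matrix (rows = y, columns = x).
#' @param p0,p1 line endpoints, `c(x, y)` in pixels.
#' @param um_per_pixel physical pixel size (µm/pixel).
#' @return an object of class `line_profile`: `intensities`, `um_per_pixel`,
#'   `endpoints`, `step_px` (1).
#' @export
extract_line_profile <- function(image, p0, p1, um_per_pixel) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix")
  .check_positive(um_per_pixel = um_per_pixel)
  if (length(p0) != 2L || length(p1) != 2L)
    stop("endpoints must be c(x, y) pairs")
  if (all(p0 == p1)) stop("line endpoints coincide")
  h <- nrow(image); w <- ncol(image)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > w || p[2] < 1 || p[2] > h)
      stop("line endpoint outside the image")
  len <- sqrt(sum((p1 - p0)^2))
  s <- seq(0, len, by = 1)                 # 1-pixel arc-length steps
  if (s[length(s)] < len) s <- c(s, len)   # include the far endpoint
  xs <- p0[1] + (p1[1] - p0[1]) * s / len
  ys <- p0[2] + (p1[2] - p0[2]) * s / len
  vals <- .bilinear(image, xs, ys)
  if (length(vals) < 8L)
    stop("line too short: a profile needs at least 8 samples")
  structure(list(intensities = vals, um_per_pixel = um_per_pixel,
                 endpoints = list(p0 = p0, p1 = p1),
                 positions_um = s * um_per_pixel),
            class = "line_profile")
}

.bilinear <- function(image, xs, ys) {
  h <- nrow(image); w <- ncol(image)
  x0 <- pmin(pmax(floor(xs), 1L), w - 1L)
  y0 <- pmin(pmax(floor(ys), 1L), h - 1L)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  i00 <- image[cbind(y0, x0)]
  i01 <- image[cbind(y0, x0 + 1L)]
  i10 <- image[cbind(y0 + 1L, x0)]
  i11 <- image[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Peak positions and spacings of a junction line profile
#'
#' The profile is first smoothed with a Gaussian kernel (`smooth_sigma_um`,
#' default 1 µm — narrower than a junction ridge, so peak positions are
#' preserved while per-pixel shot noise is suppressed). Local maxima are
#' then filtered by topographic prominence (default: 15% of the smoothed
#' profile's dynamic range) and by a minimum mutual separation (default
#' 2 µm, below the size of any epithelial cell). Plateau ties keep the
#' leftmost sample. Peak positions are converted to µm and consecutive
#' peak-to-peak spacings — the ZO-1-to-ZO-1 distances — are returned.
#'
#' @param profile a [extract_line_profile()] result, or a bare numeric
#'   vector (then `um_per_pixel` must be given).
#' @param prominence_frac prominence threshold as a fraction of the
#'   profile's dynamic range.
#' @param min_separation_um minimum distance between reported peaks (µm).
#' @param smooth_sigma_um Gaussian pre-smoothing sd (µm); 0 disables.
#' @param um_per_pixel pixel size, only when `profile` is a bare vector.
#' @return an object of class `peak_set`: `peak_positions` (µm, ascending),
#'   `spacings` (µm), `mean_spacing`, `median_spacing`,
#'   `prominence_threshold` (intensity units).
#' @export
junction_spacings <- function(profile, prominence_frac = 0.15,
                              min_separation_um = 2, smooth_sigma_um = 1,
                              um_per_pixel = NULL) {
  if (inherits(profile, "line_profile")) {
    y <- profile$intensities
    scale <- profile$um_per_pixel
    pos_um <- profile$positions_um
  } else if (is.numeric(profile)) {
    if (is.null(um_per_pixel))
      stop("'um_per_pixel' is required for a bare numeric profile")
    .check_positive(um_per_pixel = um_per_pixel)
    y <- as.numeric(profile)
    scale <- um_per_pixel
    pos_um <- (seq_along(y) - 1) * scale
  } else stop("'profile' must be a line_profile or numeric vector")

  if (smooth_sigma_um > 0) y <- .gauss_smooth(y, smooth_sigma_um / scale)
  dyn <- diff(range(y))
  if (dyn <= 0) stop("insufficient peaks: profile is constant")
  thr <- prominence_frac * dyn
  cand <- .local_maxima(y)
  prom <- .prominence(y, cand)
  cand <- cand[prom >= thr]
  # enforce minimum separation greedily by descending height
  if (length(cand) > 1L) {
    ord <- cand[order(y[cand], decreasing = TRUE)]
    kept <- numeric(0)
    for (i in ord) {
      if (!length(kept) || all(abs(pos_um[i] - pos_um[kept]) >= min_separation_um))
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  if (length(cand) < 2L)
    stop("insufficient peaks: need at least 2 detectable peaks")
  positions <- pos_um[cand]
  spacings <- diff(positions)
  structure(list(peak_positions = positions, spacings = spacings,
                 mean_spacing = mean(spacings),
                 median_spacing = stats::median(spacings),
                 prominence_threshold = thr),
            class = "peak_set")
}

# Gaussian smoothing with reflected edges; sigma in samples
.gauss_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rev(y[seq_len(min(r, n))]), y, y[seq.int(n, max(1L, n - r + 1L))])
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

# indices of local maxima; plateaus contribute their leftmost sample
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L   # walk the plateau
      if (j < n && y[j + 1L] < y[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

# topographic prominence of each peak: height above the higher of the two
# key saddles toward the nearest higher ground on each side
.prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left_min <- y[p]
    i <- p - 1L
    while (i >= 1L && y[i] <= y[p]) { left_min <- min(left_min, y[i]); i <- i - 1L }
    if (i < 1L) left_min <- min(y[1:p])
    right_min <- y[p]
    i <- p + 1L
    n <- length(y)
    while (i <= n && y[i] <= y[p]) { right_min <- min(right_min, y[i]); i <- i + 1L }
    if (i > n) right_min <- min(y[p:n])
    y[p] - max(left_min, right_min)
  }, numeric(1))
}

#' Sample junction spacings over random lines of an image
#'
#' The junction-spacing protocol does not fix where the measurement line is
#' drawn; this helper draws `n_lines` random full-span lines (random
#' orientation through a random interior point), collects all detected
#' peak-to-peak spacings, and reports the pooled summary.
#'
#' @param image H x W intensity image of junction (e.g. ZO-1) fluorescence.
#' @param um_per_pixel pixel size (µm).
#' @param n_lines number of random lines to draw.
#' @param seed RNG seed for line placement.
#' @inheritParams junction_spacings
#' @return list with `spacings` (pooled, µm), `median_spacing`,
#'   `mean_spacing`, `diameter_estimate` and `n_lines_used` (lines with
#'   >= 2 peaks).
#'
#' @details A random line samples *chords* of the cells it crosses, and
#' the mean chord of a convex cell is shorter than its diameter: for a
#' convex body, mean intercept length = pi x area / perimeter, which for
#' hexagonal cells of across-flats diameter d gives pi/4 x d. The
#' `diameter_estimate` therefore applies the standard line-intercept
#' stereology correction, 4/pi x mean spacing, to estimate the mean cell
#' diameter; `mean_spacing` and `median_spacing` report the uncorrected
#' chord statistics, as a single hand-drawn line would.
#' @export
sample_junction_spacings <- function(image, um_per_pixel, n_lines = 20,
                                     prominence_frac = 0.15,
                                     min_separation_um = 2,
                                     smooth_sigma_um = 1, seed = 1L) {
  h <- nrow(image); w <- ncol(image)
  withr::with_seed(seed, {
    all_spacings <- list()
    used <- 0L
    for (i in seq_len(n_lines)) {
      theta <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, 0.25 * w, 0.75 * w)
      cy <- stats::runif(1, 0.25 * h, 0.75 * h)
      half <- max(h, w)
      p0 <- c(cx - half * cos(theta), cy - half * sin(theta))
      p1 <- c(cx + half * cos(theta), cy + half * sin(theta))
      clipped <- .clip_segment(p0, p1, w, h)
      if (is.null(clipped)) next
      res <- tryCatch({
        prof <- extract_line_profile(image, clipped$p0, clipped$p1, um_per_pixel)
        junction_spacings(prof, prominence_frac, min_separation_um,
                          smooth_sigma_um)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        all_spacings[[length(all_spacings) + 1L]] <- res$spacings
        used <- used + 1L
      }
    }
    spacings <- unlist(all_spacings)
    if (!length(spacings)) stop("no junction spacings detected on any line")
    list(spacings = spacings, median_spacing = stats::median(spacings),
         mean_spacing = mean(spacings),
         diameter_estimate = mean(spacings) * 4 / pi,
         n_lines_used = used)
  })
}

# Liang-Barsky style clipping of a segment to the image rectangle
.clip_segment <- function(p0, p1, w, h, margin = 1) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- margin; hi <- if (k == 1) w - margin else h - margin
    if (d[k] == 0) {
      if (p0[k] < lo || p0[k] > hi) return(NULL)
    } else {
      ta <- (lo - p0[k]) / d[k]; tb <- (hi - p0[k]) / d[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      if (t0 >= t1) return(NULL)
    }
  }
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d)
}

#' Marker-positive area of a fluorescence image
#'
#' Thresholds the image into a positive-marker mask and reports both field
#' conventions: the percentage of the field that is positive (the mucin
#' MUC5AC convention) and, when the pixel size is known, the absolute
#' positive area normalized per 10^5 µm² of field (the cilia convention).
#'
#' @param image numeric H x W intensity matrix.
#' @param threshold `"otsu"` (default) or a numeric intensity cutoff.
#' @param um_per_pixel pixel size (µm); required for absolute areas.
#' @param reference_area_um2 normalization reference area (µm²).
#' @return list with `fraction_pct`, and when `um_per_pixel` is given also
#'   `positive_area_um2` and `area_per_reference` (µm² positive per
#'   `reference_area_um2` µm² of field).
#' @export
area_fraction <- function(image, threshold = "otsu", um_per_pixel = NULL,
                          reference_area_um2 = 1e5) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a nonempty matrix")
  if (identical(threshold, "otsu")) {
    thr <- otsu_threshold(image)
  } else {
    thr <- as.numeric(threshold)
    rng <- range(image)
    if (thr < rng[1] || thr > rng[2]) {
      warning("threshold outside the image intensity range; mask is empty")
      thr <- rng[2]
    }
  }
  mask <- image > thr
  out <- list(fraction_pct = 100 * mean(mask), threshold = thr)
  if (!is.null(um_per_pixel)) {
    .check_positive(um_per_pixel = um_per_pixel)
    pos_area <- sum(mask) * um_per_pixel^2
    total_area <- length(mask) * um_per_pixel^2
    out$positive_area_um2 <- pos_area
    out$area_per_reference <- pos_area / total_area * reference_area_um2
  }
  out
}

#' Viability percentage from live/dead counts
#'
#' @param live_count number of live (calcein-positive) cells.
#' @param dead_count number of dead (ethidium-positive) cells.
#' @return viability percentage, 100 x live / (live + dead).
#' @examples
#' viability(90, 10)  # 90
#' @export
viability <- function(live_count, dead_count) {
  .check_nonnegative(live_count = live_count, dead_count = dead_count)
  total <- live_count + dead_count
  if (total == 0) stop("no cells counted: live + dead must be > 0")
  100 * live_count / total
}

#' Count bright cell-like objects in a single-channel image
#'
#' Blob counting: the image is thresholded, connected components are
#' labelled, and components are kept when their pixel area falls within
#' `[min_size, max_size]`. The default `"background"` rule thresholds at
#' median + 6 x MAD of the pixel intensities — robust for spot fields of
#' any density, where Otsu fails when bright objects cover only a tiny
#' fraction of the field. Suits well-separated point-like stains (nuclei,
#' live/dead spots); densely overlapping objects undercount.
#'
#' @param image numeric H x W intensity matrix.
#' @param threshold `"background"` (median + 6 MAD), `"otsu"`, or a
#'   numeric intensity cutoff.
#' @param min_size,max_size component area bounds (pixels).
#' @return integer count (0 is valid).
#' @export
count_cells <- function(image, threshold = "background", min_size = 5,
                        max_size = Inf) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("'image' must be a nonempty matrix")
  rng <- range(image)
  if (rng[1] == rng[2]) return(0L)
  thr <- if (identical(threshold, "background")) {
    stats::median(image) + 6 * stats::mad(image)
  } else if (identical(threshold, "otsu")) {
    otsu_threshold(image)
  } else as.numeric(threshold)
  mask <- (image > thr) * 1
  labels <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(labels[labels > 0]))
  sum(sizes >= min_size & sizes <= max_size)
}

#' Histocytometry gate: DAPI x GFP double-positive percentage
#'
#' Flow-style gating on a per-cell intensity table. Rows are gated first on
#' the nuclear channel (DAPI-positive = a real cell, excluding debris),
#' then on the reporter channel (GFP-positive = infected); the result is
#' the percentage of DAPI-positive rows that are also GFP-positive.
#' Default thresholds are Otsu cuts on log-transformed intensities
#' (fluorescence intensities are positive and right-skewed); fixed
#' thresholds may be supplied instead.
#'
#' @param table data.frame with columns `dapi_mean` and `gfp_mean`
#'   (non-negative per-cell mean intensities).
#' @param t_dapi,t_gfp gate thresholds on the raw intensity scale;
#'   `NULL` (default) derives each by Otsu on `log1p` intensities.
#' @return list with `pct_double_positive`, the thresholds used, and
#'   `gated` — the input table with logical `dapi_pos`, `gfp_pos` columns.
#' @export
histocytometry_gate <- function(table, t_dapi = NULL, t_gfp = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a nonempty data.frame")
  if (!all(c("dapi_mean", "gfp_mean") %in% names(table)))
    stop("'table' needs columns 'dapi_mean' and 'gfp_mean'")
  if (any(table$dapi_mean < 0) || any(table$gfp_mean < 0))
    stop("intensities must be non-negative")
  if (is.null(t_dapi)) t_dapi <- expm1(otsu_threshold(log1p(table$dapi_mean)))
  if (is.null(t_gfp)) t_gfp <- expm1(otsu_threshold(log1p(table$gfp_mean)))
  dapi_pos <- table$dapi_mean >= t_dapi
  gfp_pos <- table$gfp_mean >= t_gfp
  if (!any(dapi_pos)) stop("no DAPI-positive rows at this gate")
  gated <- table
  gated$dapi_pos <- dapi_pos
  gated$gfp_pos <- gfp_pos
  list(pct_double_positive = 100 * sum(dapi_pos & gfp_pos) / sum(dapi_pos),
       t_dapi = t_dapi, t_gfp = t_gfp, gated = gated)
}
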