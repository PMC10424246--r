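#' Otsu threshold for a numeric vector or matrix
#'
#' Histogram-based Otsu threshold: the cut that maximizes between-class
#' variance. Works on raw numeric data of any range (images or per-cell
#' intensity vectors), unlike image-package implementations that require
#' data rescaled to \[0, 1\].
#'
#' @param x numeric vector, matrix or array.
#' @param levels number of histogram bins.
#' @return the threshold value (a point strictly between the two classes,
#'   on the scale of `x`). For constant input, returns that constant.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to threshold")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[levels]
  # between-class variance for a cut after bin k
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, levels)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

# internal: scalar positivity checks with a uniform error message
.check_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.check_nonnegative <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single non-negative finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
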