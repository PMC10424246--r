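#' Blank-subtracted, area-normalized transepithelial electrical resistance
#'
#' TEER in Ω·cm²: the cell-free (blank) insert resistance is subtracted
#' from the raw reading and the difference is multiplied by the membrane
#' area. The default area of 0.33 cm² is the nominal growth area of a
#' 6.5 mm Transwell insert. A raw reading below the blank yields a
#' negative value, which is returned with a warning rather than clipped —
#' it usually indicates an unstable electrode or mislabeled blank.
#'
#' @param raw_resistance raw insert reading (Ω); vectorized.
#' @param blank_resistance cell-free insert reading (Ω).
#' @param membrane_area insert membrane area (cm²).
#' @return TEER values (Ω·cm²), same length as `raw_resistance`.
#' @examples
#' teer(1000, 120)  # 290.4 ohm.cm2
#' @export
teer <- function(raw_resistance, blank_resistance, membrane_area = 0.33) {
  if (any(!is.finite(raw_resistance)) || any(raw_resistance < 0))
    stop("'raw_resistance' must be non-negative")
  if (any(!is.finite(blank_resistance)) || any(blank_resistance < 0))
    stop("'blank_resistance' must be non-negative")
  .check_positive(membrane_area = membrane_area)
  out <- (raw_resistance - blank_resistance) * membrane_area
  if (any(out < 0))
    warning("raw reading below blank: negative TEER value(s) returned")
  out
}

#' Aggregate TEER records into a condition-by-day time course
#'
#' @param records data.frame with columns `condition`, `day`,
#'   `raw_resistance`, `blank_resistance` and optionally `membrane_area`
#'   (else `area` applies to all rows).
#' @param area membrane area (cm²) used when `records` has no
#'   `membrane_area` column.
#' @return data.frame with one row per condition x day: `condition`, `day`,
#'   `n`, `mean_teer`, `sd_teer` (Ω·cm²; `sd_teer` is 0 for single records).
#' @export
teer_timecourse <- function(records, area = 0.33) {
  need <- c("condition", "day", "raw_resistance", "blank_resistance")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("'records' needs columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop("empty TEER record set")
  if (!"membrane_area" %in% names(records)) records$membrane_area <- area
  key <- interaction(records$condition, records$day, drop = TRUE)
  mixed <- vapply(split(records$membrane_area, key),
                  function(a) length(unique(a)) > 1L, logical(1))
  if (any(mixed))
    stop("mixed membrane areas within a condition/day group: ",
         "TEER values would not be comparable")
  vals <- teer(records$raw_resistance, records$blank_resistance,
               membrane_area = 1) * records$membrane_area
  agg <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(condition = records$condition[i[1]], day = records$day[i[1]],
               n = length(i), mean_teer = mean(vals[i]),
               sd_teer = if (length(i) > 1L) stats::sd(vals[i]) else 0)
  }))
  rownames(agg) <- NULL
  agg[order(agg$condition, agg$day), , drop = FALSE]
}

#' Basal-compartment permeability time series
#'
#' Cumulative tracer (e.g. 4 kDa FITC-dextran) amounts collected from the
#' basal compartment at successive times after apical loading.
#'
#' @param times sampling times (h), strictly increasing, >= 3 points.
#' @param basal_amounts cumulative tracer amount or signal at each time.
#' @param apical_concentration apical loading concentration (mg/ml).
#' @param apical_volume apical loading volume (ml); together with the
#'   concentration defines the apical load for normalization.
#' @param condition optional label.
#' @return an object of class `permeability_series`.
#' @export
permeability_series <- function(times, basal_amounts,
                                apical_concentration = 10,
                                apical_volume = NULL,
                                condition = NA_character_) {
  if (length(times) < 3L) stop("a permeability series needs >= 3 time points")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (length(basal_amounts) != length(times))
    stop("'basal_amounts' must match 'times' in length")
  structure(list(times = as.numeric(times),
                 basal_amounts = as.numeric(basal_amounts),
                 apical_concentration = apical_concentration,
                 apical_volume = apical_volume,
                 condition = condition),
            class = "permeability_series")
}

#' Tracer flux rate across the epithelial barrier
#'
#' Least-squares slope of cumulative basal amount versus time. When the
#' apical load (concentration x volume) is known, the slope is also
#' expressed as the fraction of the apical load crossing per hour. A
#' decreasing cumulative amount (sampling noise) triggers a warning but
#' the regression slope is still returned.
#'
#' @param series a [permeability_series()].
#' @return list with `slope` (amount/h), `intercept`, and
#'   `normalized_flux` (fraction of apical load per hour, or `NA` when the
#'   apical load is unknown).
#' @examples
#' s <- permeability_series(0:3, c(0, 1, 2, 3))
#' flux_rate(s)$slope  # 1
#' @export
flux_rate <- function(series) {
  if (!inherits(series, "permeability_series"))
    stop("'series' must be a permeability_series")
  if (any(diff(series$basal_amounts) < 0))
    warning("cumulative basal amounts decrease at some time points ",
            "(sampling noise); slope returned regardless")
  fit <- stats::lm(basal_amounts ~ times,
                   data = list(times = series$times,
                               basal_amounts = series$basal_amounts))
  slope <- unname(stats::coef(fit)[2])
  load <- if (!is.null(series$apical_volume))
    series$apical_concentration * series$apical_volume else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       normalized_flux = if (is.finite(load) && load > 0) slope / load
                         else NA_real_)
}
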