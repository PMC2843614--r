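#' Residual-activity curve from hemagglutination titers
#'
#' Hemagglutination activity is read as the last two-fold dilution step that
#' still agglutinates, so residual activity relative to an unheated control is
#' `2^(titer - control_titer)`, capped at 1. A sample with no agglutination at
#' any dilution (encoded `NA`) has activity 0.
#'
#' @param temperature Numeric vector of incubation temperatures (degrees C),
#'   strictly increasing after sorting.
#' @param titer Integer vector of titers (dilution steps, >= 0); `NA` = no
#'   agglutination.
#' @param control_titer Titer of the unheated control (> 0).
#' @return An `inactivation_curve`: data.frame with columns `temperature` and
#'   `activity` (fraction in `[0, 1]`), sorted by temperature.
#' @export
residual_activity_curve <- function(temperature, titer, control_titer) {
  if (missing(control_titer) || length(control_titer) != 1L || is.na(control_titer))
    stop("a single unheated 'control_titer' is required")
  if (control_titer <= 0) stop("'control_titer' must be positive")
  if (length(temperature) != length(titer))
    stop("'temperature' and 'titer' lengths differ")
  activity <- ifelse(is.na(titer), 0, pmin(1, 2^(titer - control_titer)))
  inactivation_curve(temperature, activity)
}

#' Construct a thermal inactivation curve
#'
#' @param temperature Temperatures in degrees C.
#' @param activity Residual activity fractions in `[0, 1]`.
#' @return Data.frame of class `inactivation_curve`, sorted by temperature.
#' @export
inactivation_curve <- function(temperature, activity) {
  if (length(temperature) < 2L) stop("a curve needs at least two points")
  if (anyDuplicated(temperature)) stop("duplicate temperatures")
  if (any(activity < 0 | activity > 1, na.rm = TRUE))
    stop("activities must lie in [0, 1]")
  ord <- order(temperature)
  structure(data.frame(temperature = as.numeric(temperature)[ord],
                       activity = as.numeric(activity)[ord]),
            class = c("inactivation_curve", "data.frame"))
}

#' Half-activity retention temperature (Tm)
#'
#' Tm is defined operationally: the temperature at which 50% of the unheated
#' activity is retained. It is located as the first downward crossing of 0.5
#' *after the last temperature with activity >= 0.5* (robust to noisy dips
#' below 0.5 at low temperature), by linear interpolation between the two
#' flanking samples. A sampled point exactly at 0.5 returns its own
#' temperature. No extrapolation is ever performed: a curve entirely above or
#' entirely below 0.5 is an error.
#'
#' @param curve An [inactivation_curve()] (or data.frame with `temperature`
#'   and `activity` columns).
#' @param smooth Apply isotonic (monotone non-increasing) pre-smoothing before
#'   locating the crossing. Default `FALSE`.
#' @return List of class `half_activity_temperature` with elements `t_m`
#'   (degrees C) and `method`.
#' @export
half_activity_temperature <- function(curve, smooth = FALSE) {
  tt <- curve$temperature
  aa <- curve$activity
  method <- "linear interpolation at first downward 0.5 crossing"
  if (smooth) {
    # isotonic regression constrained to a non-increasing curve
    fit <- stats::isoreg(tt, -aa)
    aa <- -fit$yf
    method <- paste(method, "after isotonic smoothing")
  }
  above <- which(aa >= 0.5)
  if (!length(above))
    stop("no Tm in range: all activities are below 0.5")
  i <- max(above)
  if (aa[i] == 0.5) {
    tm <- tt[i]
  } else {
    if (i == length(tt))
      stop("no Tm in range: activity never drops below 0.5")
    tm <- tt[i] + (aa[i] - 0.5) / (aa[i] - aa[i + 1]) * (tt[i + 1] - tt[i])
  }
  structure(list(t_m = tm, method = method), class = "half_activity_temperature")
}

#' @export
print.half_activity_temperature <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s)\n", x$t_m, x$method))
  invisible(x)
}

#' Read thermal-activity measurements from CSV
#'
#' Expected columns: `lectin`, `temperature`, and either `activity` (fraction)
#' or `titer` plus a per-lectin control row flagged by `temperature = NA` or a
#' `control` column. Replicates (`replicate` column) are averaged per
#' temperature after conversion to activity.
#'
#' @param path CSV file.
#' @return Named list of [inactivation_curve()] objects, one per lectin.
#' @export
read_activity_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"lectin" %in% names(tab)) tab$lectin <- "sample"
  split_tab <- split(tab, tab$lectin)
  lapply(split_tab, function(d) {
    if ("activity" %in% names(d)) {
      act <- tapply(d$activity, d$temperature, mean)
    } else if (all(c("titer", "control") %in% names(d))) {
      a <- pmin(1, 2^(d$titer - d$control))
      a[is.na(d$titer)] <- 0
      act <- tapply(a, d$temperature, mean)
    } else {
      stop("need an 'activity' column or 'titer' + 'control' columns")
    }
    inactivation_curve(as.numeric(names(act)), as.numeric(act))
  })
}

#' Tabulate Tm estimates for a set of curves
#'
#' @param curves Named list of [inactivation_curve()] objects.
#' @param smooth Passed to [half_activity_temperature()].
#' @return Data.frame with columns `lectin`, `t_m`, `method`. Curves without a
#'   0.5 crossing get `NA` and the error message in `method`.
#' @export
tm_table <- function(curves, smooth = FALSE) {
  rows <- lapply(names(curves), function(nm) {
    res <- tryCatch(half_activity_temperature(curves[[nm]], smooth = smooth),
                    error = function(e) list(t_m = NA_real_, method = conditionMessage(e)))
    data.frame(lectin = nm, t_m = res$t_m, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
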