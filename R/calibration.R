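#' Fit a standard curve for an HPLC analyte
#'
#' Ordinary least squares of detector response (UV peak area for Rg1, Re,
#' Rb1, Rd; ELSD peak area for pseudo-F11) on analyte amount. Under the
#' `log_log` transform both axes are log10-transformed before the fit, the
#' usual linearization for ELSD response. R-squared is the squared Pearson
#' correlation of fitted versus observed response on the fitting scale.
#'
#' @param amounts Numeric vector of analyte amounts (independent variable).
#' @param responses Numeric vector of peak areas (dependent variable).
#' @param transform `"linear"` (default) or `"log_log"`.
#' @param analyte Label stored with the curve.
#' @param response_kind `"uv_area"` or `"elsd_area"`; metadata only.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r2`, `transform`, `analyte`, `response_kind`, `n_points`.
#' @export
fit_standard_curve <- function(amounts, responses,
                               transform = c("linear", "log_log"),
                               analyte = "analyte",
                               response_kind = c("uv_area", "elsd_area")) {
  transform <- match.arg(transform)
  response_kind <- match.arg(response_kind)
  stopifnot(length(amounts) == length(responses))
  if (length(amounts) < 3L) {
    stop("a standard curve needs at least 3 calibration points", call. = FALSE)
  }
  x <- amounts
  y <- responses
  if (transform == "log_log") {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log_log transform requires strictly positive amounts and responses",
           call. = FALSE)
    }
    x <- log10(x)
    y <- log10(y)
  }
  fit <- stats::lm(y ~ x)
  fitted <- stats::fitted(fit)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(fitted, y)^2
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, transform = transform,
                 response_kind = response_kind,
                 n_points = length(amounts)),
            class = "standard_curve")
}

#' Quantify an analyte from a detector response
#'
#' Inverts the calibration: `amount = (response - intercept) / slope`, back-
#' transformed from log10 space for `log_log` curves, then scaled by the
#' dilution factor.
#'
#' @param curve A `standard_curve`.
#' @param response Detector response (peak area).
#' @param dilution_factor Multiplicative dilution correction (default 1).
#' @return Estimated amount on the original scale.
#' @export
quantify <- function(curve, response, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || abs(curve$slope) < 1e-12) {
    stop("degenerate standard curve: slope is zero", call. = FALSE)
  }
  if (curve$transform == "log_log") {
    if (any(response <= 0)) {
      stop("log_log curve requires strictly positive response", call. = FALSE)
    }
    amount <- 10^((log10(response) - curve$intercept) / curve$slope)
  } else {
    amount <- (response - curve$intercept) / curve$slope
  }
  amount * dilution_factor
}

#' Read calibration points and fit curves per analyte
#'
#' @param path CSV with columns `analyte, amount, response` (and optionally
#'   `transform`, `response_kind` constant within analyte).
#' @return Named list of `standard_curve` objects, one per analyte.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "amount", "response")
  missing <- setdiff(need, tolower(names(df)))
  if (length(missing) > 0L) {
    stop("calibration CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  names(df) <- tolower(names(df))
  out <- lapply(split(df, df$analyte), function(d) {
    tr <- if ("transform" %in% names(d)) d$transform[1L] else "linear"
    rk <- if ("response_kind" %in% names(d)) d$response_kind[1L] else "uv_area"
    fit_standard_curve(d$amount, d$response, transform = tr,
                       analyte = d$analyte[1L], response_kind = rk)
  })
  out
}

#' Summarize fitted standard curves as a data.frame
#' @param curves Named list of `standard_curve` objects.
#' @return data.frame with one row per analyte.
#' @export
curve_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(analyte = cv$analyte, slope = cv$slope, intercept = cv$intercept,
               r2 = cv$r2, transform = cv$transform,
               response_kind = cv$response_kind, n_points = cv$n_points,
               stringsAsFactors = FALSE)
  }))
}
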