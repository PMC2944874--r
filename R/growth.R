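#' Weight-length regression
#'
#' Ordinary least squares of `log10(weight)` on `log10(length)`, pooled
#' across strains and sampling periods (a single population regression, as
#' is conventional for relative condition factor).
#'
#' @param measurements Data frame with columns `length` (mm) and `weight`
#'   (g); other columns pass through untouched.
#' @return An object of class `weight_length` with `a` (intercept), `b`
#'   (allometric slope), `n`, and the underlying `lm` fit.
#' @examples
#' d <- tibble::tibble(length = c(50, 80, 120), weight = 1e-5 * c(50, 80, 120)^3)
#' fit_weight_length(d) # b = 3, a = -5
#' @export
fit_weight_length <- function(measurements) {
  stopifnot(is.data.frame(measurements), all(c("length", "weight") %in% names(measurements)))
  bad <- which(!(measurements$length > 0) | !(measurements$weight > 0))
  if (length(bad)) {
    stop_morphherit(sprintf(
      "non-positive length or weight in record(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (length(unique(measurements$length)) < 3) {
    stop_morphherit("weight-length regression needs >= 3 distinct lengths.")
  }
  fit <- lm(log10(weight) ~ log10(length), data = measurements)
  structure(
    list(
      a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
      n = nrow(measurements), fit = fit
    ),
    class = "weight_length"
  )
}

#' @method print weight_length
#' @export
print.weight_length <- function(x, ...) {
  cat(sprintf(
    "<weight_length: log10 W = %.4f + %.4f log10 L (n = %d)>\n",
    x$a, x$b, x$n
  ))
  invisible(x)
}

#' @rdname fit_weight_length
#' @param x A `weight_length` object.
#' @param ... Unused.
#' @method tidy weight_length
#' @export
tidy.weight_length <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname fit_weight_length
#' @method glance weight_length
#' @export
glance.weight_length <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, r.squared = s$r.squared, sigma = s$sigma)
}

#' Relative condition factor
#'
#' `K_n = W / W'` where `W'` is the standard weight predicted for a fish of
#' the same length by the population weight-length regression,
#' `W' = 10^(a + b log10 L)`. Relative condition compensates for allometric
#' growth and is comparable across lengths. Over the fitting sample the mean
#' of `log10(K_n)` is exactly zero (OLS residual property), so the geometric
#' mean of `K_n` is 1.
#'
#' @param measurements Data frame with `length` and `weight` columns.
#' @param model A [fit_weight_length()] model; fitted on `measurements`
#'   when omitted.
#' @return The input tibble with columns `w_standard` and `kn` appended.
#' @export
relative_condition <- function(measurements, model = NULL) {
  model <- model %||% fit_weight_length(measurements)
  stopifnot(inherits(model, "weight_length"))
  w_std <- 10^(model$a + model$b * log10(measurements$length))
  dplyr::mutate(
    tibble::as_tibble(measurements),
    w_standard = w_std,
    kn = .data$weight / w_std
  )
}

#' Accumulated temperature units to hatch
#'
#' Development rate expressed as the sum of daily mean temperatures from
#' fertilization (day 1) through hatch. Sub-daily temperature series should
#' be averaged to daily means first.
#'
#' @param temperatures Numeric vector of daily mean temperatures (deg C),
#'   day 1 = first day post fertilization.
#' @param hatch_day Day index at hatch; 0 gives ATU = 0.
#' @return Accumulated temperature units (deg C x days).
#' @examples
#' accumulated_temperature_units(rep(9.5, 60), 50) # 475
#' @export
accumulated_temperature_units <- function(temperatures, hatch_day) {
  stopifnot(is.numeric(temperatures))
  if (!is.numeric(hatch_day) || length(hatch_day) != 1 || hatch_day < 0 ||
    hatch_day != round(hatch_day)) {
    stop_morphherit("`hatch_day` must be a single non-negative integer.")
  }
  if (hatch_day > length(temperatures)) {
    stop_morphherit("`hatch_day` lies beyond the temperature series.")
  }
  if (hatch_day > 0 && any(temperatures[seq_len(hatch_day)] < 0)) {
    rlang::warn("negative daily temperatures included in ATU sum.")
  }
  if (hatch_day == 0) 0 else sum(temperatures[seq_len(hatch_day)])
}
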