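#' Fit a temperature regression for one call parameter
#'
#' Ordinary least squares of per-individual parameter means on recording
#' air temperature. The fitted slope `b` feeds the Platz-Forester linear
#' correction in [temperature_correct()]; correction is applied only when
#' the slope is significant at `alpha` and the parameter is not exempt
#' (pulse number is conventionally exempted).
#'
#' @param individual_means Numeric vector of per-individual means.
#' @param temperatures_c Air temperature per individual, degrees C.
#' @param parameter Parameter name carried in the model (default "value").
#' @param reference_temperature_c Common temperature to correct to.
#' @param alpha Significance gate on the slope (default 0.05).
#' @param exempt If `TRUE` the parameter is never corrected.
#' @return A `callvar_tempmodel` list: `parameter`, `slope_b`, `intercept`,
#'   `slope_p_value`, `reference_temperature_c`, `corrected`.
#' @export
fit_temperature_regression <- function(individual_means, temperatures_c,
                                       parameter = "value",
                                       reference_temperature_c = 27.6,
                                       alpha = 0.05, exempt = FALSE) {
  ok <- is.finite(individual_means) & is.finite(temperatures_c)
  y <- individual_means[ok]; x <- temperatures_c[ok]
  if (length(y) < 3L) stop("need >= 3 (value, temperature) pairs",
                           call. = FALSE)
  if (stats::var(x) <= 0) {
    stop("temperature has no variance: regression undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # exact collinear input is legitimate here; silence lm's perfect-fit note
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(sm["x", "Estimate"])
  p <- unname(sm["x", "Pr(>|t|)"])
  structure(list(parameter = parameter,
                 slope_b = slope,
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_p_value = p,
                 reference_temperature_c = reference_temperature_c,
                 corrected = (!exempt) && is.finite(p) && p < alpha,
                 exempt = exempt),
            class = "callvar_tempmodel")
}

#' Platz-Forester temperature correction
#'
#' Linear adjustment to the reference temperature using the fitted slope:
#' `x_corr = x - b * (T - T_ref)`. Applied only when the model's
#' `corrected` flag is set (significant slope, non-exempt parameter);
#' otherwise values pass through unchanged.
#'
#' @param value Observed value(s).
#' @param temp_c Recording temperature(s), degrees C.
#' @param model A `callvar_tempmodel` from [fit_temperature_regression()].
#' @return Corrected value(s).
#' @export
temperature_correct <- function(value, temp_c, model) {
  stopifnot(inherits(model, "callvar_tempmodel"))
  if (!isTRUE(model$corrected)) return(value)
  value - model$slope_b * (temp_c - model$reference_temperature_c)
}

#' Reference temperature of a study
#'
#' The count-weighted mean air temperature: the mean over individuals
#' (equivalently, locality temperatures weighted by the number of recorded
#' males), rounded to one decimal for reporting.
#'
#' @param metadata Data.frame with one row per individual and a
#'   `temperature_c` column, or one row per locality with `temperature_c`
#'   and `n_males` columns.
#' @param digits Rounding for reporting (default 1).
#' @return Reference temperature in degrees C.
#' @export
reference_temperature <- function(metadata, digits = 1) {
  if (!("temperature_c" %in% names(metadata))) {
    stop("metadata needs a temperature_c column", call. = FALSE)
  }
  t <- metadata$temperature_c
  w <- if ("n_males" %in% names(metadata)) metadata$n_males else
    rep(1, length(t))
  bad <- !is.finite(t)
  if (any(bad)) {
    who <- if ("individual_id" %in% names(metadata)) {
      paste(metadata$individual_id[bad], collapse = ", ")
    } else if ("locality" %in% names(metadata)) {
      paste(metadata$locality[bad], collapse = ", ")
    } else "some rows"
    stop("missing temperatures for: ", who, call. = FALSE)
  }
  round(sum(t * w) / sum(w), digits)
}

#' Temperature-correct a table of individual means
#'
#' Fits one regression per parameter and corrects the individual means of
#' every significant, non-exempt parameter to the reference temperature.
#'
#' @param means_table Data.frame with columns `individual_id`, `locality`,
#'   `group`, `parameter`, `value`, `temperature_c` (one row per
#'   individual x parameter).
#' @param reference_temperature_c Reference temperature; `NULL` (default)
#'   derives it from the table via [reference_temperature()].
#' @param alpha Slope significance gate.
#' @param exempt_parameters Parameters never corrected (default
#'   `"pulse_number"`).
#' @return List: `table` (the input with a `value_corrected` column) and
#'   `models` (data.frame of per-parameter fits).
#' @export
correct_means_table <- function(means_table, reference_temperature_c = NULL,
                                alpha = 0.05,
                                exempt_parameters = "pulse_number") {
  need <- c("individual_id", "parameter", "value", "temperature_c")
  stopifnot(all(need %in% names(means_table)))
  if (is.null(reference_temperature_c)) {
    per_ind <- means_table[!duplicated(means_table$individual_id),
                           c("individual_id", "temperature_c")]
    reference_temperature_c <- reference_temperature(per_ind)
  }
  means_table$value_corrected <- means_table$value
  models <- list()
  for (par in unique(means_table$parameter)) {
    sel <- means_table$parameter == par
    m <- fit_temperature_regression(
      means_table$value[sel], means_table$temperature_c[sel],
      parameter = par,
      reference_temperature_c = reference_temperature_c,
      alpha = alpha, exempt = par %in% exempt_parameters)
    means_table$value_corrected[sel] <-
      temperature_correct(means_table$value[sel],
                          means_table$temperature_c[sel], m)
    models[[par]] <- data.frame(parameter = par, slope_b = m$slope_b,
                                intercept = m$intercept,
                                slope_p_value = m$slope_p_value,
                                corrected = m$corrected,
                                exempt = m$exempt,
                                reference_temperature_c =
                                  m$reference_temperature_c)
  }
  models <- do.call(rbind, models)
  rownames(models) <- NULL
  list(table = means_table, models = models)
}
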