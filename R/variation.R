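#' Coefficient of variation, in percent
#'
#' `CV = 100 * SD / mean`, with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("CV needs at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Gerhardt's within-individual variability classes
#'
#' `static` for CV_i below 5%, `dynamic` above 12%, `intermediate` in the
#' closed interval `[5, 12]` (both boundaries inclusive to intermediate).
#'
#' @param cv_i_mean Mean within-individual CV, percent (>= 0). Vectorised.
#' @return Character vector in `{"static", "intermediate", "dynamic"}`.
#' @export
classify_cv <- function(cv_i_mean) {
  if (any(!is.finite(cv_i_mean)) || any(cv_i_mean < 0)) {
    stop("cv_i_mean must be finite and non-negative", call. = FALSE)
  }
  ifelse(cv_i_mean < 5, "static",
         ifelse(cv_i_mean <= 12, "intermediate", "dynamic"))
}

#' Validate a long-format measurement table
#'
#' The analysis tables are long format: one row per (individual, call,
#' parameter) with columns `individual_id`, `locality`, `group`,
#' `parameter`, `call_index`, `value`. Each individual belongs to exactly
#' one locality, each locality to exactly one group, and every individual
#' has at least 2 calls per parameter.
#'
#' @param table Data.frame in the long measurement format.
#' @return The table, invisibly, after validation.
#' @export
validate_measurement_table <- function(table) {
  need <- c("individual_id", "locality", "group", "parameter",
            "call_index", "value")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("measurement table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  loc_per_ind <- tapply(table$locality, table$individual_id,
                        function(x) length(unique(x)))
  if (any(loc_per_ind > 1L)) {
    stop("individuals must each belong to exactly one locality",
         call. = FALSE)
  }
  grp_per_loc <- tapply(table$group, table$locality,
                        function(x) length(unique(x)))
  if (any(grp_per_loc > 1L)) {
    stop("localities must each belong to exactly one group", call. = FALSE)
  }
  calls <- tapply(table$value,
                  interaction(table$individual_id, table$parameter,
                              drop = TRUE),
                  function(x) sum(is.finite(x)))
  if (any(calls < 2L)) {
    stop("every individual needs >= 2 calls per parameter", call. = FALSE)
  }
  invisible(table)
}

#' Multi-level coefficients of variation
#'
#' For each parameter, computes the four-level CV decomposition:
#' * `cv_i` — one CV per individual, over its calls (within-individual);
#' * `cv_p` — one CV per locality, over its individuals' mean values;
#' * `cv_g` — one CV per group, over its individuals' mean values;
#' * `cv_o` — a single CV over all individual means.
#'
#' Localities or groups with fewer than 2 individuals get `NA` for their
#' unit CV (with a warning) and are excluded from the level summaries.
#'
#' @param table Long measurement table (see
#'   [validate_measurement_table()]).
#' @return Named list, one element per parameter, each with components
#'   `cv_i`, `cv_p`, `cv_g` (named numeric vectors) and `cv_o` (scalar),
#'   plus `individual_means` (named, with locality/group attributes used
#'   downstream).
#' @export
multilevel_cv <- function(table) {
  validate_measurement_table(table)
  out <- list()
  for (par in unique(table$parameter)) {
    tp <- table[table$parameter == par & is.finite(table$value), ]
    ind_split <- split(tp$value, tp$individual_id, drop = TRUE)
    cv_i <- vapply(ind_split, cv_percent, numeric(1))
    ind_means <- vapply(ind_split, mean, numeric(1))
    ind_loc <- vapply(split(tp$locality, tp$individual_id, drop = TRUE),
                      function(x) x[1L], character(1))
    ind_grp <- vapply(split(tp$group, tp$individual_id, drop = TRUE),
                      function(x) x[1L], character(1))
    unit_cv <- function(means, labels, what) {
      vapply(split(means, labels, drop = TRUE), function(v) {
        if (length(v) < 2L) {
          warning(sprintf("%s with < 2 individuals: CV set to NA", what))
          return(NA_real_)
        }
        cv_percent(v)
      }, numeric(1))
    }
    cv_p <- unit_cv(ind_means, ind_loc, "locality")
    cv_g <- unit_cv(ind_means, ind_grp, "group")
    out[[par]] <- list(
      cv_i = cv_i, cv_p = cv_p, cv_g = cv_g,
      cv_o = cv_percent(ind_means),
      individual_means = structure(ind_means,
                                   locality = ind_loc, group = ind_grp)
    )
  }
  out
}

#' Discriminability ratios
#'
#' The overall CV relative to the lower-level CVs. The headline statistic
#' is `ratio_o_over_i` (overall vs. mean within-individual CV); the
#' overall-vs-group ratio is returned alongside. Large ratios mark
#' parameters whose among-individual spread dwarfs their within-individual
#' noise, i.e. parameters useful for telling individuals or groups apart.
#'
#' @param cv_o Overall CV, percent.
#' @param cv_i_mean Mean within-individual CV, percent.
#' @param cv_g_mean Mean group-level CV, percent.
#' @return List with `ratio_o_over_i` and `ratio_o_over_g` (`NA` with a
#'   warning for a zero denominator).
#' @export
discriminability_ratio <- function(cv_o, cv_i_mean, cv_g_mean) {
  safe_div <- function(num, den, label) {
    if (!is.finite(den) || den == 0) {
      warning("zero or missing denominator for ", label)
      return(NA_real_)
    }
    num / den
  }
  list(ratio_o_over_i = safe_div(cv_o, cv_i_mean, "ratio_o_over_i"),
       ratio_o_over_g = safe_div(cv_o, cv_g_mean, "ratio_o_over_g"))
}

#' One-way (Model II) ANOVA on individual means
#'
#' Random-effects one-way ANOVA of individual means by group. For a
#' balanced or unbalanced one-way layout the F statistic, p-value and
#' eta-squared coincide with the fixed-effects ANOVA, so the sums of
#' squares are computed directly (and are easy to verify by hand).
#'
#' @param individual_means Numeric vector of per-individual means.
#' @param group_labels Group label per individual; >= 2 groups with >= 2
#'   individuals each.
#' @return List with `F`, `p`, `eta_squared`, `df_between`, `df_within`.
#'   If total SS is 0, returns `eta_squared = 0`, `p = 1` with a warning.
#' @export
model2_anova <- function(individual_means, group_labels) {
  stopifnot(length(individual_means) == length(group_labels))
  g <- split(individual_means, group_labels, drop = TRUE)
  if (length(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(g, length, integer(1)) < 2L)) {
    stop("each group needs >= 2 individuals", call. = FALSE)
  }
  grand <- mean(individual_means)
  ss_between <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                           numeric(1)))
  ss_total <- sum((individual_means - grand)^2)
  df_b <- length(g) - 1L
  df_w <- length(individual_means) - length(g)
  if (ss_total <= 0) {
    warning("zero total variance: eta_squared = 0, p = 1")
    return(list(F = 0, p = 1, eta_squared = 0,
                df_between = df_b, df_within = df_w))
  }
  ss_within <- ss_total - ss_between
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       eta_squared = ss_between / ss_total,
       df_between = df_b, df_within = df_w)
}

#' Per-parameter variation summary table
#'
#' The analytical core of the variation stage: for each parameter, the
#' descriptive statistics over individual means, the four CV levels (mean
#' and min-max range for the per-unit levels), Gerhardt's classification,
#' both discriminability ratios, and the group-effect ANOVA.
#'
#' @param table Long measurement table.
#' @return Data.frame, one row per parameter.
#' @export
variation_summary <- function(table) {
  ml <- multilevel_cv(table)
  rows <- lapply(names(ml), function(par) {
    x <- ml[[par]]
    im <- x$individual_means
    ratios <- discriminability_ratio(x$cv_o, mean(x$cv_i),
                                     mean(x$cv_g, na.rm = TRUE))
    an <- model2_anova(as.numeric(im), attr(im, "group"))
    rng <- function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) return(c(NA_real_, NA_real_))
      range(v)
    }
    ri <- rng(x$cv_i); rp <- rng(x$cv_p); rg <- rng(x$cv_g)
    data.frame(
      parameter = par,
      mean = mean(im), sd = stats::sd(im),
      range_lo = min(im), range_hi = max(im),
      cv_i_mean = mean(x$cv_i), cv_i_lo = ri[1], cv_i_hi = ri[2],
      cv_p_mean = mean(x$cv_p, na.rm = TRUE), cv_p_lo = rp[1], cv_p_hi = rp[2],
      cv_g_mean = mean(x$cv_g, na.rm = TRUE), cv_g_lo = rg[1], cv_g_hi = rg[2],
      cv_o = x$cv_o,
      ratio_o_over_i = ratios$ratio_o_over_i,
      ratio_o_over_g = ratios$ratio_o_over_g,
      classification = classify_cv(mean(x$cv_i)),
      anova_F = an$F, anova_p = an$p, eta_squared = an$eta_squared
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
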