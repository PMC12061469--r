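#' Choose the two-group test from the data's distribution
#'
#' The field-standard decision tree: Shapiro-Wilk normality per group; if
#' both groups pass (p > 0.05) the comparison uses a t-test with
#' Bartlett's homogeneity check, otherwise a Wilcoxon rank-sum
#' (Mann-Whitney U) test with Levene's check (Brown-Forsythe, median
#' centred). A homogeneity failure is flagged but does not abort. A
#' constant group makes Shapiro-Wilk undefined and falls to the Wilcoxon
#' branch with a warning.
#'
#' @param values_ne,values_sw Numeric vectors (>= 3 each).
#' @param alpha Normality/homogeneity significance level (default 0.05).
#' @return List: `normality_p_ne`, `normality_p_sw`, `normal` (logical),
#'   `homogeneity_test`, `homogeneity_p`, `homogeneous`, `chosen_test`.
#' @export
choose_test <- function(values_ne, values_sw, alpha = 0.05) {
  stopifnot(length(values_ne) >= 3L, length(values_sw) >= 3L)
  sw_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  p_ne <- sw_p(values_ne); p_sw <- sw_p(values_sw)
  if (is.na(p_ne) || is.na(p_sw)) {
    warning("constant group: normality undefined, using Wilcoxon branch")
    normal <- FALSE
  } else {
    normal <- p_ne > alpha && p_sw > alpha
  }
  vals <- c(values_ne, values_sw)
  grp <- factor(rep(c("a", "b"), c(length(values_ne), length(values_sw))))
  if (normal) {
    htest <- "Bartlett"
    hp <- stats::bartlett.test(vals, grp)$p.value
  } else {
    htest <- "Levene"
    hp <- levene_test(vals, grp)$p.value
  }
  list(normality_p_ne = p_ne, normality_p_sw = p_sw, normal = normal,
       homogeneity_test = htest, homogeneity_p = hp,
       homogeneous = is.finite(hp) && hp > alpha,
       chosen_test = if (normal) "t-test" else "Wilcoxon")
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from a group centre; the default
#' centre is the median (Brown-Forsythe variant, the common default of
#' applied packages).
#'
#' @param values Numeric vector.
#' @param groups Factor of group labels.
#' @param center `"median"` (default) or `"mean"`.
#' @return List with `F`, `df`, `p.value`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  cfun <- if (center == "median") stats::median else mean
  dev <- abs(values - stats::ave(values, groups, FUN = cfun))
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(F = fit$`F value`[1L], df = fit$Df,
       p.value = fit$`Pr(>F)`[1L])
}

#' Compare two geographic groups on every call parameter
#'
#' Runs the [choose_test()] decision tree per parameter on (temperature-
#' corrected) individual means, then the chosen two-sided test. Wilcoxon
#' uses exact enumeration for small tie-free samples and the normal
#' approximation with tie correction otherwise (the behaviour of
#' `stats::wilcox.test`).
#'
#' @param means_table Per-individual means with columns `individual_id`,
#'   `group`, `parameter` and the value column.
#' @param value_col Column holding values to compare (default
#'   `"value_corrected"`, falling back to `"value"` if absent).
#' @param alpha Significance level for flags (default 0.05).
#' @return Data.frame, one row per parameter: group means, normality and
#'   homogeneity p-values, chosen test, p-value and significance flag.
#' @export
compare_groups <- function(means_table, value_col = "value_corrected",
                           alpha = 0.05) {
  if (!value_col %in% names(means_table)) value_col <- "value"
  grps <- sort(unique(means_table$group))
  if (length(grps) != 2L) stop("exactly 2 groups required", call. = FALSE)
  rows <- lapply(unique(means_table$parameter), function(par) {
    sel <- means_table$parameter == par
    v1 <- means_table[[value_col]][sel & means_table$group == grps[1L]]
    v2 <- means_table[[value_col]][sel & means_table$group == grps[2L]]
    if (length(v1) < 2L || length(v2) < 2L) {
      stop("fewer than 2 individuals in a group for ", par, call. = FALSE)
    }
    dec <- choose_test(v1, v2, alpha)
    p <- if (dec$chosen_test == "t-test") {
      stats::t.test(v1, v2, var.equal = TRUE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(v1, v2, exact = NULL)$p.value)
    }
    out <- data.frame(parameter = par,
                      mean_1 = mean(v1), mean_2 = mean(v2),
                      normality_p_1 = dec$normality_p_ne,
                      normality_p_2 = dec$normality_p_sw,
                      homogeneity_test = dec$homogeneity_test,
                      homogeneity_p = dec$homogeneity_p,
                      chosen_test = dec$chosen_test,
                      p_value = p,
                      significant = is.finite(p) && p < alpha)
    names(out)[names(out) == "mean_1"] <- paste0("mean_", grps[1L])
    names(out)[names(out) == "mean_2"] <- paste0("mean_", grps[2L])
    names(out)[names(out) == "normality_p_1"] <-
      paste0("normality_p_", grps[1L])
    names(out)[names(out) == "normality_p_2"] <-
      paste0("normality_p_", grps[2L])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel density summary of a sample
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on
#' a regular grid; the numeric integral over a generous grid is within 1%
#' of 1. Returned as data (grid + density) so rendering stays optional.
#'
#' @param values Numeric vector with >= 2 distinct values.
#' @param from,to Grid limits; defaults extend 3 bandwidths past the data.
#' @param n Grid size (default 512).
#' @return List with `x`, `density`, `bandwidth`.
#' @export
kde_summary <- function(values, from = NULL, to = NULL, n = 512L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) {
    stop("KDE needs at least 2 distinct values", call. = FALSE)
  }
  bw <- stats::bw.nrd0(values)
  if (is.null(from)) from <- min(values) - 3 * bw
  if (is.null(to)) to <- max(values) + 3 * bw
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = from, to = to, n = n)
  list(x = d$x, density = d$y, bandwidth = bw)
}

#' Overlap coefficient of two kernel density estimates
#'
#' Integral of the pointwise minimum of two densities over a shared grid;
#' near 0 for well-separated groups, near 1 for coincident ones.
#'
#' @param values_a,values_b Samples for the two groups.
#' @param n Grid size.
#' @return Overlap in `[0, 1]`.
#' @export
kde_overlap <- function(values_a, values_b, n = 1024L) {
  lo <- min(values_a, values_b); hi <- max(values_a, values_b)
  pad <- 0.25 * (hi - lo)
  ka <- kde_summary(values_a, from = lo - pad, to = hi + pad, n = n)
  kb <- kde_summary(values_b, from = lo - pad, to = hi + pad, n = n)
  dx <- diff(ka$x[1:2])
  sum(pmin(ka$density, kb$density)) * dx
}
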