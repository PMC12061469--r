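#' Great-circle distance matrix between localities
#'
#' Haversine distances on a sphere of radius 6371.0088 km (IUGG mean
#' Earth radius).
#'
#' @param coordinates Data.frame with columns `locality`, `latitude`,
#'   `longitude` (decimal degrees).
#' @return A labelled square matrix of distances in km (class
#'   `callvar_distmat` attribute on units).
#' @export
haversine_matrix <- function(coordinates) {
  stopifnot(all(c("locality", "latitude", "longitude") %in%
                  names(coordinates)))
  lat <- coordinates$latitude; lon <- coordinates$longitude
  bad <- !is.finite(lat) | !is.finite(lon) | abs(lat) > 90 | abs(lon) > 180
  if (any(bad)) {
    stop("invalid coordinates for: ",
         paste(coordinates$locality[bad], collapse = ", "), call. = FALSE)
  }
  r_earth <- 6371.0088
  n <- length(lat)
  phi <- lat * pi / 180; lam <- lon * pi / 180
  d <- matrix(0, n, n, dimnames = list(coordinates$locality,
                                       coordinates$locality))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    h <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    d[i, j] <- d[j, i] <- 2 * r_earth * asin(min(1, sqrt(h)))
  }
  d
}

#' Acoustic distance matrix from population means
#'
#' Univariate metric: entry (i, j) is the absolute difference between the
#' locality mean values of one parameter. A multivariate Euclidean distance
#' over standardised means is available via [acoustic_distance_multi()].
#'
#' @param population_means Named numeric vector, one mean per locality.
#' @return Labelled square matrix of absolute mean differences.
#' @export
acoustic_distance_matrix <- function(population_means) {
  if (any(!is.finite(population_means))) {
    stop("missing locality mean(s): ",
         paste(names(population_means)[!is.finite(population_means)],
               collapse = ", "), call. = FALSE)
  }
  d <- abs(outer(population_means, population_means, "-"))
  dimnames(d) <- list(names(population_means), names(population_means))
  d
}

#' Multivariate acoustic distance (non-default option)
#'
#' Euclidean distance over z-standardised locality means of several
#' parameters.
#'
#' @param means_matrix Localities x parameters matrix of means.
#' @return Labelled square distance matrix.
#' @export
acoustic_distance_multi <- function(means_matrix) {
  z <- scale(means_matrix)
  as.matrix(stats::dist(z))
}

#' Mantel permutation test
#'
#' Pearson correlation between the upper-triangle entries of two distance
#' matrices over the same localities, with significance from random
#' permutations of one matrix's row/column labels (jointly). The default
#' p-value is one-tailed upper (positive r = greater distance, greater
#' acoustic difference), computed as `(1 + #{r_perm >= r_obs}) / (1 + B)`.
#' For 5 or fewer localities, all `n!` relabelings are enumerated
#' exhaustively instead and `p = #{r_perm >= r_obs} / n!` (the identity
#' permutation is part of the enumeration).
#'
#' @param a,b Square symmetric matrices with identical locality labels.
#' @param n_permutations Number of sampled permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (one-tailed upper, default) or
#'   `"two.sided"`.
#' @param exhaustive `NULL` (auto: exhaustive when `n <= 5`), or logical.
#' @return List with `r`, `p`, `n_permutations` (actual count used),
#'   `exhaustive`, `seed`, `alternative`.
#' @export
mantel_test <- function(a, b, n_permutations = 9999L, seed = 1L,
                        alternative = c("greater", "two.sided"),
                        exhaustive = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == ncol(a),
            nrow(b) == ncol(b), nrow(a) == nrow(b))
  if (!identical(rownames(a), rownames(b))) {
    stop("matrix labels differ or are ordered differently", call. = FALSE)
  }
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 localities", call. = FALSE)
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0) {
    stop("constant distance matrix: r undefined", call. = FALSE)
  }
  r_obs <- stats::cor(va, b[ut])
  if (is.null(exhaustive)) exhaustive <- n <= 5L
  r_of_perm <- function(idx) stats::cor(va, b[idx, idx][ut])
  if (exhaustive) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, r_of_perm, numeric(1))
    n_used <- length(perms)
    count <- sum(r_perm >= r_obs - 1e-12)
    p <- switch(alternative,
                greater = count / n_used,
                two.sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12) / n_used)
  } else {
    set.seed(seed)
    r_perm <- vapply(seq_len(n_permutations),
                     function(i) r_of_perm(sample.int(n)), numeric(1))
    n_used <- n_permutations
    p <- switch(alternative,
                greater = (1 + sum(r_perm >= r_obs - 1e-12)) /
                  (1 + n_permutations),
                two.sided = (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) /
                  (1 + n_permutations))
  }
  list(r = r_obs, p = p, n_permutations = n_used,
       exhaustive = exhaustive, seed = seed, alternative = alternative)
}

# all n! permutations, by inserting n into each (n-1)-permutation
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Mantel tests for every parameter of a means table
#'
#' @param means_table Per-individual means table with `locality`,
#'   `parameter`, `value` columns (corrected values may be supplied via
#'   `value_col`).
#' @param coordinates Locality coordinate table for [haversine_matrix()].
#' @param value_col Column holding the values (default `"value"`).
#' @param ... Passed to [mantel_test()].
#' @return Data.frame: `parameter`, `r`, `p`, `n_permutations`, `seed`.
#' @export
mantel_by_parameter <- function(means_table, coordinates,
                                value_col = "value", ...) {
  geo <- haversine_matrix(coordinates)
  rows <- lapply(unique(means_table$parameter), function(par) {
    sel <- means_table$parameter == par
    pm <- tapply(means_table[[value_col]][sel], means_table$locality[sel],
                 mean)
    pm <- pm[rownames(geo)]
    names(pm) <- rownames(geo)
    ac <- acoustic_distance_matrix(pm)
    res <- mantel_test(geo, ac, ...)
    data.frame(parameter = par, r = res$r, p = res$p,
               n_permutations = res$n_permutations,
               exhaustive = res$exhaustive)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
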