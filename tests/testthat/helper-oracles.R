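# Independent brute-force oracles, deliberately written "spreadsheet style"
# with base R only, so they share no code path with the package.

oracle_cv <- function(x) 100 * sd(x) / mean(x)

# four-level CV decomposition computed row by row from a long table
oracle_multilevel <- function(tab, par) {
  tp <- tab[tab$parameter == par, ]
  inds <- unique(tp$individual_id)
  cv_i <- sapply(inds, function(i) oracle_cv(tp$value[tp$individual_id == i]))
  im <- sapply(inds, function(i) mean(tp$value[tp$individual_id == i]))
  loc <- sapply(inds, function(i) tp$locality[tp$individual_id == i][1])
  grp <- sapply(inds, function(i) tp$group[tp$individual_id == i][1])
  cv_p <- sapply(unique(loc), function(l) oracle_cv(im[loc == l]))
  cv_g <- sapply(unique(grp), function(g) oracle_cv(im[grp == g]))
  list(cv_i = cv_i, cv_p = cv_p, cv_g = cv_g, cv_o = oracle_cv(im))
}

# one-way ANOVA sums of squares by hand
oracle_anova <- function(values, groups) {
  grand <- mean(values)
  ssb <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
  }
  sst <- sum((values - grand)^2)
  k <- length(unique(groups)); n <- length(values)
  f <- (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  list(F = f, p = pf(f, k - 1, n - k, lower.tail = FALSE),
       eta_squared = ssb / sst, ss_between = ssb, ss_total = sst)
}

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments of the pooled ranks
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# exhaustive Mantel: upper-tail p over all n! joint relabelings of b
oracle_mantel_exhaustive <- function(a, b) {
  n <- nrow(a)
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  perms <- asplit(permutations_matrix(n), 1)
  r_all <- sapply(perms, function(p) cor(a[ut], b[p, p][ut]))
  list(r = r_obs, p = mean(r_all >= r_obs - 1e-12), r_all = r_all)
}

permutations_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_matrix(n - 1)
  out <- NULL
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out <- rbind(out, append(sub[i, ], n, after = pos - 1))
    }
  }
  out
}

# direct DFT magnitude-squared at one bin of a Hann-windowed segment
oracle_dft_power <- function(x, k) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  xe <- x * w
  ex <- exp(-2i * pi * k * (0:(n - 1)) / n)
  abs(sum(xe * ex))^2
}

# a tiny fully hand-checkable hierarchy: 2 groups x 2 localities x
# 2 individuals x 2 calls, one parameter
tiny_table <- function() {
  data.frame(
    individual_id = rep(c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
                        each = 2),
    locality = rep(c("A", "A", "B", "B", "C", "C", "D", "D"), each = 2),
    group = rep(c("G1", "G1", "G1", "G1", "G2", "G2", "G2", "G2"), each = 2),
    parameter = "p",
    call_index = rep(1:2, 8),
    value = c(10, 12, 14, 16, 20, 22, 26, 28,
              30, 34, 38, 40, 44, 48, 50, 56)
  )
}

study_metadata_from <- function(sim) sim$individuals
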