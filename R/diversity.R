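#' Hill number (effective species number) of order q
#'
#' For relative abundances p, the Hill number is
#' (sum p_i^q)^(1/(1-q)); the q -> 1 limit is exp of Shannon entropy.
#' q = 0 counts species, q = 1 weights them by abundance, q = 2 is the
#' reciprocal Simpson concentration.
#'
#' @param counts non-negative abundance vector with a positive total.
#' @param q diversity order, a non-negative real (default 0).
#' @return effective species number, >= 1 for any non-empty assemblage.
#' @export
hill_number <- function(counts, q = 0) {
  if (sum(counts) == 0) stop("empty assemblage")
  if (q < 0) stop("q must be non-negative")
  p <- counts[counts > 0] / sum(counts)
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Simpson's reciprocal diversity
#'
#' 1 / sum(p_i^2): the Hill number of order 2. Reported for the pooled
#' (global) assemblage of a period.
#'
#' @param counts non-negative abundance vector with a positive total.
#' @return value in \[1, number of species present\].
#' @export
simpson_reciprocal <- function(counts) hill_number(counts, q = 2)

#' Multiplicative alpha/beta/gamma diversity partition
#'
#' Equal-weight Hill-number partition of one period's site-by-species
#' data: gamma is the effective species number of the pooled (column-sum)
#' assemblage, alpha the equal-weight mean within-site effective species
#' number (at q = 0 the arithmetic mean of site richness; at general
#' q != 1 the power mean \code{((1/N) sum_j sum_i p_ij^q)^(1/(1-q))}; at
#' q = 1 exp of the mean site Shannon entropy), and beta = gamma/alpha,
#' the effective number of compositionally distinct communities.
#'
#' @param table an `abundance_table`.
#' @param period period label to partition.
#' @param q diversity order (default 0).
#' @return list with elements `q`, `n_sites`, `alpha`, `beta`, `gamma`,
#'   `richness`, `simpson_reciprocal` (the latter two on the pooled
#'   assemblage).
#' @export
partition_diversity <- function(table, period, q = 0) {
  sub <- subset_period(table, period)
  m <- unclass(sub)
  part <- hill_partition(m, q)
  pooled <- colSums(m)
  c(list(q = q, n_sites = nrow(m)), part,
    list(richness = sum(pooled > 0),
         simpson_reciprocal = simpson_reciprocal(pooled)))
}

hill_partition <- function(m, q) {
  pooled <- colSums(m)
  gamma <- hill_number(pooled, q)
  n <- nrow(m)
  if (abs(q - 1) < 1e-9) {
    hs <- apply(m, 1, function(r) {
      p <- r[r > 0] / sum(r); -sum(p * log(p))
    })
    alpha <- exp(mean(hs))
  } else {
    sq <- apply(m, 1, function(r) {
      p <- r[r > 0] / sum(r); sum(p^q)
    })
    alpha <- mean(sq)^(1 / (1 - q))
  }
  list(alpha = alpha, beta = gamma / alpha, gamma = gamma)
}

#' Bootstrap standard errors for the diversity partition
#'
#' Sites (rows) of the chosen period are resampled with replacement
#' `B_div` times; each replicate's equal-weight Hill partition is
#' recomputed and the standard errors are the standard deviations of the
#' replicate alpha, beta, gamma (and pooled Simpson's reciprocal) values.
#' Point estimates are the plug-in values from [partition_diversity()],
#' not bootstrap means.
#'
#' @param table an `abundance_table`.
#' @param period period label.
#' @param q diversity order (default 0).
#' @param B_div number of bootstrap iterations (default 10000).
#' @param seed integer seed for the resampling.
#' @return list: the [partition_diversity()] elements plus `se_alpha`,
#'   `se_beta`, `se_gamma`, `se_simpson`, `B_div`, `seed`.
#' @export
bootstrap_diversity <- function(table, period, q = 0, B_div = 10000,
                                seed = 1L) {
  sub <- subset_period(table, period)
  m <- unclass(sub)
  n <- nrow(m)
  if (n < 2) stop("bootstrap requires at least 2 sites")
  est <- partition_diversity(table, period, q)
  set.seed(seed)
  reps <- matrix(NA_real_, B_div, 4,
                 dimnames = list(NULL, c("alpha", "beta", "gamma", "simpson")))
  # precompute per-site sum(p^q) (or Shannon) so replicates are cheap
  if (abs(q - 1) < 1e-9) {
    site_stat <- apply(m, 1, function(r) {
      p <- r[r > 0] / sum(r); -sum(p * log(p))
    })
  } else {
    site_stat <- apply(m, 1, function(r) {
      p <- r[r > 0] / sum(r); sum(p^q)
    })
  }
  for (b in seq_len(B_div)) {
    idx <- sample.int(n, n, replace = TRUE)
    pooled <- colSums(m[idx, , drop = FALSE])
    gamma <- hill_number(pooled, q)
    alpha <- if (abs(q - 1) < 1e-9) exp(mean(site_stat[idx]))
             else mean(site_stat[idx])^(1 / (1 - q))
    reps[b, ] <- c(alpha, gamma / alpha, gamma, simpson_reciprocal(pooled))
  }
  se <- apply(reps, 2, stats::sd)
  c(est, list(se_alpha = unname(se["alpha"]), se_beta = unname(se["beta"]),
              se_gamma = unname(se["gamma"]),
              se_simpson = unname(se["simpson"]),
              B_div = B_div, seed = seed))
}
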