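#' Temporal dissimilarity of pooled clusters
#'
#' For one clustering of the matched pairs: pools the member pairs'
#' surveys per period and computes the compositional dissimilarity
#' between the two pooled assemblages of every cluster. This is the
#' quantity whose distribution across clusters is scanned over K.
#'
#' @param table pair-by-species `abundance_table` (rows keyed by pair id,
#'   two periods).
#' @param clusters named vector mapping every pair id to a cluster id.
#' @param index dissimilarity index (see [dissimilarity_matrix()]).
#' @param period_a,period_b the two period labels (defaults "T1", "T2").
#' @return numeric vector of per-cluster dissimilarities, named and
#'   ordered by cluster id.
#' @export
cluster_temporal_change <- function(table, clusters,
                                    index = c("morisita_horn", "jaccard",
                                              "morisita"),
                                    period_a = "T1", period_b = "T2") {
  index <- match.arg(index)
  f <- index_fun(index)
  pooled <- pool_sites(table, clusters)
  m <- unclass(pooled)
  ids <- as.character(sort(unique(unlist(clusters))))
  vapply(ids, function(cl) {
    ka <- paste(cl, period_a, sep = "|")
    kb <- paste(cl, period_b, sep = "|")
    if (!(ka %in% rownames(m)) || !(kb %in% rownames(m)))
      stop("cluster ", cl, " is empty in one period")
    f(m[ka, ], m[kb, ])
  }, numeric(1))
}

#' Scan temporal change across all spatial grains
#'
#' The central procedure: the Ward hierarchy of pairs is cut at every K
#' in `K_range` (default all K from 1, the global pool, to N, the local
#' pairs), member pairs are pooled per cluster and period, and the
#' per-cluster temporal dissimilarities are recorded. At K = N the values
#' equal the local paired dissimilarities; at K = 1 there is a single
#' global value.
#'
#' @param table pair-by-species `abundance_table`.
#' @param tree `merge_tree` over the same pair ids.
#' @param K_range integer vector of grains to evaluate (default 1..N).
#' @param index dissimilarity index.
#' @param period_a,period_b period labels.
#' @return object of class `scale_scan`: list with `per_K` (list mapping
#'   K to its K per-cluster values), `summary` (data.frame K, n, mean,
#'   min, q1, median, q3, max), `index`, `N`.
#' @export
scan_all_scales <- function(table, tree, K_range = NULL,
                            index = c("morisita_horn", "jaccard",
                                      "morisita"),
                            period_a = "T1", period_b = "T2") {
  index <- match.arg(index)
  N <- tree$n_leaves
  if (is.null(K_range)) K_range <- seq_len(N)
  ids <- unique(ab_sites(table))
  if (!setequal(ids, tree$labels))
    stop("tree leaves and table pair ids differ")
  per_K <- lapply(K_range, function(K) {
    cl <- cut_clusters(tree, K)
    cluster_temporal_change(table, cl, index, period_a, period_b)
  })
  names(per_K) <- as.character(K_range)
  summ <- do.call(rbind, lapply(seq_along(K_range), function(i) {
    v <- per_K[[i]]
    q <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(K = K_range[i], n = length(v), mean = mean(v), min = min(v),
               q1 = q[1], median = q[2], q3 = q[3], max = max(v))
  }))
  structure(list(per_K = per_K, summary = summ, index = index, N = N),
            class = "scale_scan")
}

#' @export
print.scale_scan <- function(x, ...) {
  cat(sprintf("<scale_scan> %s dissimilarity over K = %s (N = %d pairs)\n",
              x$index, paste(range(x$summary$K), collapse = ".."), x$N))
  invisible(x)
}

#' Bootstrap discontinuity test for one spatial grain
#'
#' Tests whether the mean dissimilarity observed at a candidate grain K
#' could have been sampled from the local-scale (K = N) values: each of
#' B iterations draws `K_tested` values with replacement from
#' `local_values` and records their mean; the p-value is the exact
#' proportion of iteration means less than or equal to `observed_mean`
#' (one-sided, "probability of sampling a group with a mean at least as
#' small"; no continuity correction). `two_sided = TRUE` doubles the
#' smaller tail.
#'
#' @param local_values the N local (K = N) dissimilarities.
#' @param K_tested number of values drawn per iteration (the size of the
#'   grain under test).
#' @param observed_mean mean dissimilarity observed at that grain.
#' @param B bootstrap iterations (default 100000).
#' @param seed integer seed.
#' @param two_sided double the smaller tail (default FALSE).
#' @return list: `K_tested`, `observed_mean`, `B`, `seed`, `p_value`,
#'   `boot_summary` (min, q1, median, q3, max of the bootstrap means,
#'   type-7 quantiles), `alpha` (0.05), `two_sided`.
#' @export
discontinuity_bootstrap_test <- function(local_values, K_tested,
                                         observed_mean, B = 100000,
                                         seed = 1L, two_sided = FALSE) {
  n <- length(local_values)
  if (n == 0) stop("local_values is empty")
  if (K_tested < 1 || K_tested > n) stop("K_tested out of range 1..", n)
  if (B < 1) stop("B must be >= 1")
  set.seed(seed)
  draws <- matrix(sample(local_values, K_tested * B, replace = TRUE),
                  nrow = K_tested)
  means <- colMeans(draws)
  p_low <- sum(means <= observed_mean) / B
  p <- if (two_sided) min(1, 2 * min(p_low, sum(means >= observed_mean) / B))
       else p_low
  q <- stats::quantile(means, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
  list(K_tested = K_tested, observed_mean = observed_mean, B = B,
       seed = seed, p_value = p,
       boot_summary = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                        max = q[5]),
       alpha = 0.05, two_sided = two_sided)
}

#' Run the discontinuity test at one or more grains of a scan
#'
#' Convenience wrapper: takes the observed mean of each nominated K from
#' the scan and tests it against the local (K = N) values. Nominating
#' which K to test is the analyst's call (typically from inspecting the
#' scan summary); testing many K at once is exploratory and no
#' multiplicity correction is applied -- a warning says so when more than
#' one K is nominated.
#'
#' @param scan a `scale_scan` containing K = N.
#' @param K_test integer vector of grains to test.
#' @param B bootstrap iterations (default 100000).
#' @param seed integer seed (incremented per tested K).
#' @param two_sided see [discontinuity_bootstrap_test()].
#' @return list of test results, one per tested K.
#' @export
test_scan_discontinuities <- function(scan, K_test, B = 100000, seed = 1L,
                                      two_sided = FALSE) {
  if (!as.character(scan$N) %in% names(scan$per_K))
    stop("scan must include K = N (the local scale)")
  if (length(K_test) > 1)
    warning("testing multiple K without multiplicity correction; ",
            "interpret exploratory p-values accordingly")
  local_values <- scan$per_K[[as.character(scan$N)]]
  out <- lapply(seq_along(K_test), function(i) {
    K <- K_test[i]
    if (!as.character(K) %in% names(scan$per_K))
      stop("K = ", K, " not present in scan")
    discontinuity_bootstrap_test(local_values, K,
                                 mean(scan$per_K[[as.character(K)]]),
                                 B = B, seed = seed + i - 1L,
                                 two_sided = two_sided)
  })
  names(out) <- paste0("K", K_test)
  out
}

#' Locate the grain minimizing pooled temporal change
#'
#' Returns the interior K (2..N-1 by default) at which the chosen
#' summary of the per-cluster dissimilarities is smallest -- the
#' candidate domain boundary. The mean is the default statistic: under
#' strong homogenization at some scale the median ties at its floor
#' across neighbouring K (most clusters are unchanged when one merge
#' crosses the scale), while the mean responds to every cluster and is
#' uniquely minimized where all clusters sit at the homogenized scale.
#'
#' @param scan a `scale_scan`.
#' @param stat `"mean"` (default) or `"median"`.
#' @param interior drop K = 1 and K = N before locating the minimum
#'   (default TRUE; K = 1 is a single unreplicated value and K = N is the
#'   local reference).
#' @return the K attaining the minimum (smallest such K on exact ties).
#' @export
find_domain_scale <- function(scan, stat = c("mean", "median"),
                              interior = TRUE) {
  stat <- match.arg(stat)
  s <- scan$summary
  if (interior) s <- s[s$K > 1 & s$K < scan$N, , drop = FALSE]
  if (nrow(s) == 0) stop("no interior K in scan")
  s$K[which.min(s[[stat]])]
}

#' Write scan outputs
#'
#' Long table (K, cluster_id, dissimilarity) and the per-K summary --
#' boxplot-ready.
#'
#' @param scan a `scale_scan`.
#' @param long_path output TSV for per-cluster values.
#' @param summary_path output TSV for the per-K summary.
#' @export
write_scan <- function(scan, long_path, summary_path) {
  long <- do.call(rbind, lapply(names(scan$per_K), function(K) {
    v <- scan$per_K[[K]]
    data.frame(K = as.integer(K), cluster_id = seq_along(v),
               dissimilarity = unname(v))
  }))
  utils::write.table(long, long_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(scan$summary, summary_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(long_path)
}
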