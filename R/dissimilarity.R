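#' Morisita-Horn dissimilarity between two abundance vectors
#'
#' Abundance-based compositional dissimilarity 1 - C with
#' C = 2 * sum(x*y) / ((d_x + d_y) * X * Y), where X = sum(x),
#' Y = sum(y), d_x = sum(x^2)/X^2 and d_y = sum(y^2)/Y^2 (Horn's
#' information-free form of the Morisita overlap). The index depends only
#' on relative abundances, so it is invariant to sampling effort:
#' multiplying either vector by a positive scalar leaves it unchanged.
#'
#' @param x,y non-negative count vectors of equal length, each with at
#'   least one individual.
#' @return dissimilarity in \[0, 1\] (0 = identical relative composition,
#'   1 = no shared species).
#' @export
morisita_horn <- function(x, y) {
  check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  C <- 2 * sum(x * y) / ((dx + dy) * X * Y)
  clamp01(1 - C)
}

#' Classic Morisita dissimilarity (small-sample corrected)
#'
#' The original Morisita overlap for integer counts, replacing d_x by
#' sum(x*(x-1)) / (X*(X-1)). Offered as an alternative to the Horn form;
#' requires at least two individuals per assemblage.
#'
#' @inheritParams morisita_horn
#' @return dissimilarity in \[0, 1\].
#' @export
morisita <- function(x, y) {
  check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  if (X < 2 || Y < 2)
    stop("classic Morisita requires at least 2 individuals per assemblage")
  dx <- sum(x * (x - 1)) / (X * (X - 1))
  dy <- sum(y * (y - 1)) / (Y * (Y - 1))
  C <- 2 * sum(x * y) / ((dx + dy) * X * Y)
  clamp01(1 - C)
}

#' Jaccard dissimilarity between two presence/absence vectors
#'
#' 1 - a/(a+b+c) with a = shared presences and b, c the presences unique
#' to each vector. Abundance vectors are reduced to presence/absence
#' first.
#'
#' @inheritParams morisita_horn
#' @return dissimilarity in \[0, 1\].
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  px <- x > 0; py <- y > 0
  a <- sum(px & py)
  u <- sum(px | py)
  clamp01(1 - a / u)
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    stop("assemblage vectors differ in length")
  if (any(x < 0) || any(y < 0))
    stop("negative abundances")
  if (sum(x) == 0 || sum(y) == 0)
    stop("empty assemblage: dissimilarity is undefined for an all-zero vector")
  invisible(TRUE)
}

clamp01 <- function(v) pmin(1, pmax(0, v))

index_fun <- function(index = c("morisita_horn", "jaccard", "morisita")) {
  switch(match.arg(index),
         morisita_horn = morisita_horn,
         jaccard = jaccard,
         morisita = morisita)
}

#' Pairwise dissimilarity matrix over all surveys of an abundance table
#'
#' @param table an `abundance_table` with at least two rows.
#' @param index `"morisita_horn"` (default), `"jaccard"`, or `"morisita"`.
#' @return symmetric numeric matrix with zero diagonal, values in
#'   \[0, 1\], labelled `site|period` on both margins, with attributes
#'   `index`, `site_id`, `period`.
#' @export
dissimilarity_matrix <- function(table,
                                 index = c("morisita_horn", "jaccard",
                                           "morisita")) {
  index <- match.arg(index)
  if (nrow(table) < 2) stop("need at least two surveys")
  f <- index_fun(index)
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("empty survey row: ", rownames(m)[rs == 0][1])
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- f(m[i, ], m[j, ])
    }
  }
  structure(D, index = index,
            site_id = ab_sites(table), period = ab_periods(table))
}

#' Temporal dissimilarity of matched site pairs
#'
#' Extracts, for each matched pair, the dissimilarity between its
#' period-a survey (at the period-a site) and its period-b survey (at the
#' period-b site) from a full pairwise matrix: the local-scale temporal
#' beta diversity values.
#'
#' @param D matrix from [dissimilarity_matrix()].
#' @param pairs a pair table from [match_sites()] (columns `site_t1`,
#'   `site_t2`), or any data.frame with those columns.
#' @param period_a,period_b period labels of the two surveys being
#'   compared (defaults "T1", "T2").
#' @return named numeric vector, one value per pair, in pair order.
#' @export
paired_temporal_dissimilarity <- function(D, pairs,
                                          period_a = "T1", period_b = "T2") {
  ka <- paste(pairs$site_t1, period_a, sep = "|")
  kb <- paste(pairs$site_t2, period_b, sep = "|")
  miss <- c(setdiff(ka, rownames(D)), setdiff(kb, rownames(D)))
  if (length(miss) > 0)
    stop("survey rows absent from dissimilarity matrix: ",
         paste(miss, collapse = ", "))
  out <- D[cbind(ka, kb)]
  names(out) <- pair_ids(pairs)
  out
}

#' Write a dissimilarity matrix
#'
#' Square labelled CSV, plus optionally a long-format TSV (i, j, value)
#' when `long_path` is given.
#'
#' @param D matrix from [dissimilarity_matrix()].
#' @param path output CSV path.
#' @param long_path optional TSV path for the long format.
#' @export
write_dissimilarity <- function(D, path, long_path = NULL) {
  df <- data.frame(label = rownames(D), as.data.frame(unclass(D)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(D), arr.ind = TRUE)
    long <- data.frame(i = rownames(D)[idx[, 1]], j = colnames(D)[idx[, 2]],
                       value = D[idx])
    utils::write.table(long, long_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
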