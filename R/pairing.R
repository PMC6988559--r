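#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius), used for the straight-line component of the pairing filter.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84);
#'   vectors recycle.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088 * 1000) / 1000
}

pair_ids <- function(pairs) {
  paste(pairs$site_t1, pairs$site_t2, sep = "~")
}

#' Match resurveyed sites to historical sites
#'
#' Each period-2 site is matched to its nearest period-1 site by fluvial
#' (river-network) distance, among candidates that pass two filters:
#' straight-line (haversine) separation below `max_straight_km` and, when
#' `require_same_order` is TRUE, identical Strahler stream order. Under
#' one-to-one matching (the default, preventing pseudo-replication),
#' conflicts where several period-2 sites want the same period-1 site are
#' resolved greedily on a single globally ascending fluvial-distance
#' queue (ties broken lexicographically by site ids), and displaced sites
#' fall through to their next-nearest eligible candidate. The result is
#' deterministic and independent of input row order.
#'
#' @param sites_t1,sites_t2 data.frames with columns `site_id`,
#'   `latitude`, `longitude`, `stream_order`.
#' @param fluvial symmetric matrix of river-km distances whose
#'   dimnames cover all site ids of both periods.
#' @param max_straight_km straight-line retention threshold in km
#'   (default 8).
#' @param require_same_order require equal Strahler order (default TRUE).
#' @param one_to_one forbid reuse of a period-1 site (default TRUE).
#' @return data.frame with columns `site_t1`, `site_t2`, `straight_km`,
#'   `fluvial_km`, `exact_match` (fluvial_km == 0), ordered by `site_t2`.
#' @export
match_sites <- function(sites_t1, sites_t2, fluvial,
                        max_straight_km = 8, require_same_order = TRUE,
                        one_to_one = TRUE) {
  for (df in list(sites_t1, sites_t2)) {
    need <- c("site_id", "latitude", "longitude", "stream_order")
    if (!all(need %in% names(df)))
      stop("site tables require columns: ", paste(need, collapse = ", "))
    if (anyNA(df[need])) stop("missing coordinates or stream order")
  }
  ids <- c(sites_t1$site_id, sites_t2$site_id)
  miss <- setdiff(ids, rownames(fluvial))
  if (length(miss) > 0)
    stop("sites absent from fluvial matrix: ", paste(miss, collapse = ", "))

  # all eligible candidate pairs
  cand <- expand.grid(i1 = seq_len(nrow(sites_t1)), i2 = seq_len(nrow(sites_t2)))
  cand$site_t1 <- sites_t1$site_id[cand$i1]
  cand$site_t2 <- sites_t2$site_id[cand$i2]
  cand$straight_km <- haversine_km(sites_t1$latitude[cand$i1],
                                   sites_t1$longitude[cand$i1],
                                   sites_t2$latitude[cand$i2],
                                   sites_t2$longitude[cand$i2])
  cand$fluvial_km <- fluvial[cbind(cand$site_t1, cand$site_t2)]
  keep <- cand$straight_km < max_straight_km
  if (require_same_order)
    keep <- keep & (sites_t1$stream_order[cand$i1] ==
                      sites_t2$stream_order[cand$i2])
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$fluvial_km, cand$site_t1, cand$site_t2), ,
               drop = FALSE]

  if (one_to_one) {
    used_t1 <- character(0); used_t2 <- character(0)
    sel <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (cand$site_t1[r] %in% used_t1 || cand$site_t2[r] %in% used_t2) next
      sel <- c(sel, r)
      used_t1 <- c(used_t1, cand$site_t1[r])
      used_t2 <- c(used_t2, cand$site_t2[r])
    }
    out <- cand[sel, , drop = FALSE]
  } else {
    # nearest eligible t1 per t2 (cand already sorted by distance)
    out <- cand[!duplicated(cand$site_t2), , drop = FALSE]
  }
  out <- out[order(out$site_t2), c("site_t1", "site_t2", "straight_km",
                                   "fluvial_km"), drop = FALSE]
  out$exact_match <- out$fluvial_km == 0
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no site pairs survived the filters")
  out
}

#' Fluvial distance matrix between matched pairs
#'
#' Pairs inherit the location of their resurveyed (period-2) site; the
#' spatial clustering of pairs runs on these river-km distances.
#'
#' @param pairs pair table from [match_sites()].
#' @param fluvial site-level fluvial distance matrix.
#' @return symmetric matrix labelled by pair id (`site_t1~site_t2`).
#' @export
pair_fluvial_matrix <- function(pairs, fluvial) {
  ids <- pairs$site_t2
  miss <- setdiff(ids, rownames(fluvial))
  if (length(miss) > 0)
    stop("pair sites absent from fluvial matrix: ",
         paste(miss, collapse = ", "))
  D <- fluvial[ids, ids, drop = FALSE]
  dimnames(D) <- list(pair_ids(pairs), pair_ids(pairs))
  D
}

#' Assemble the pair-by-species abundance table
#'
#' Builds the two-period community matrix the scale scan consumes: for
#' each matched pair, the period-a row is the period-a survey of its
#' period-1 site and the period-b row is the period-b survey of its
#' period-2 site, both re-keyed by the pair id.
#'
#' @param table full `abundance_table` across periods.
#' @param pairs pair table from [match_sites()].
#' @param period_a,period_b period labels (defaults "T1", "T2").
#' @return an `abundance_table` with rows (pair_id, period).
#' @export
pair_abundance_table <- function(table, pairs,
                                 period_a = "T1", period_b = "T2") {
  ids <- pair_ids(pairs)
  keys <- rownames(table)
  ka <- paste(pairs$site_t1, period_a, sep = "|")
  kb <- paste(pairs$site_t2, period_b, sep = "|")
  miss <- c(setdiff(ka, keys), setdiff(kb, keys))
  if (length(miss) > 0)
    stop("surveys absent from abundance table: ", paste(miss, collapse = ", "))
  m <- unclass(table)
  out <- rbind(m[ka, , drop = FALSE], m[kb, , drop = FALSE])
  abundance_table(out, c(ids, ids),
                  rep(c(period_a, period_b), each = length(ids)))
}

#' Read a site metadata table
#' @param path CSV with columns `site_id, period, latitude, longitude,
#'   stream_order`.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "period", "latitude", "longitude", "stream_order")
  if (!all(need %in% names(df)))
    stop("site table requires columns: ", paste(need, collapse = ", "))
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates out of range")
  if (any(df$stream_order < 1)) stop("stream_order must be >= 1")
  df
}

#' Read a square fluvial distance matrix
#' @param path CSV whose first column and header carry site ids.
#' @return symmetric numeric matrix (river-km).
#' @export
read_fluvial_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("fluvial matrix must be square and symmetric")
  m
}
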