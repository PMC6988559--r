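#' Configuration for the synthetic riverscape metacommunity
#'
#' Defaults emulate the statistical structure of a mid-sized dendritic
#' drainage resurveyed after decades: 33 paired sites, a regional pool of
#' 50 species with long-tailed (lognormal) abundances including rare
#' near-singletons, site-level species turnover of 0.5 between the two
#' main periods (local change large, regional pool preserved), a lighter
#' 0.15 turnover for an optional one-year resurvey of 8 sites, and 15
#' tributary subdrainages available for planting a domain of scale.
#'
#' @param n_sites number of survey sites (default 33).
#' @param n_species regional pool size (default 50).
#' @param mean_log,sd_log lognormal parameters of regional abundances
#'   (defaults 2.0, 1.2).
#' @param occupancy_decay per-river-km rate at which a species' presence
#'   probability decays with fluvial distance from its focal node
#'   (default 0.015: species ranges span a few neighbouring tributaries
#'   and observed site richness sits near 10 of 50 species).
#' @param tau site-level turnover probability between T1 and T2
#'   (default 0.5).
#' @param tau2 turnover for the one-year T2 -> T3 resurvey (default 0.15).
#' @param n_tributaries number of tributary subdrainages (default 15).
#' @param n_resurvey number of sites resurveyed in T3 (default 8).
#' @param sample_size individuals collected per survey (default 150).
#' @param trib_effect_sd in tributary-homogenization mode, the sd (log
#'   scale) of the tributary-level abundance trend between periods
#'   (default 0.8: decadal catch totals of a small drainage commonly
#'   swing severalfold).
#' @param seed integer seed; the whole dataset is a pure function of
#'   this configuration.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 33, n_species = 50, mean_log = 2.0,
                             sd_log = 1.2, occupancy_decay = 0.015,
                             tau = 0.5, tau2 = 0.15, n_tributaries = 15,
                             n_resurvey = 8, sample_size = 150,
                             trib_effect_sd = 0.8, seed = 1L) {
  stopifnot(n_sites >= 2, n_species >= 2, tau >= 0, tau <= 1,
            tau2 >= 0, tau2 <= 1, sample_size > 0,
            n_tributaries >= 1, n_tributaries <= n_sites,
            n_resurvey <= n_sites)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a dendritic river network
#'
#' Builds a bifurcating tree: a mainstem running to a single outlet with
#' `n_tributaries` junctions (one intermediate mainstem node between
#' consecutive junctions), each junction fed by a tributary consisting of
#' a confluence node splitting into two order-1 headwater branches. Edge
#' lengths are uniform(2, 20) river-km. Strahler orders follow the
#' standard recursion (max child order, +1 when two or more children
#' share the max). Sites are placed two per tributary (a headwater and
#' the confluence), with any remainder placed on mainstem junction nodes
#' so placements span low to high order. The planar embedding draws each
#' edge as a straight segment of 0.7 x its river length (channels
#' meander), which guarantees straight-line distance never exceeds
#' fluvial distance; coordinates are then scaled onto a ~1 degree x 0.5
#' degree pseudo lat/lon box comparable to a 113 x 48 km drainage.
#'
#' @param config a `synthetic_config`.
#' @return list of class `river_network`: `nodes` (data.frame: node, x,
#'   y, latitude, longitude, strahler, tributary, site_id), `edges`
#'   (from, to, length_km), `graph` (igraph), `outlet`, `sites`
#'   (site metadata data.frame), `fluvial` (site-level river-km matrix).
#' @export
generate_network <- function(config) {
  set.seed(config$seed)
  m <- config$n_tributaries
  n_sites <- config$n_sites
  if (n_sites < 2) stop("need at least 2 sites")
  base_per_trib <- 2
  extra <- n_sites - base_per_trib * m
  if (extra > m)
    stop("infeasible config: n_sites must be at most 3 per tributary")
  if (extra < 0) {
    # fewer sites than 2/tributary: drop to 1 per tributary where needed
    if (n_sites < m) stop("infeasible config: n_sites < n_tributaries")
  }

  nodes <- data.frame(node = character(0), kind = character(0),
                      tributary = integer(0), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      length_km = numeric(0), stringsAsFactors = FALSE)
  add_node <- function(id, kind, trib = NA_integer_) {
    nodes <<- rbind(nodes, data.frame(node = id, kind = kind,
                                      tributary = trib,
                                      stringsAsFactors = FALSE))
  }
  add_edge <- function(a, b) {
    edges <<- rbind(edges, data.frame(from = a, to = b,
                                      length_km = stats::runif(1, 2, 20),
                                      stringsAsFactors = FALSE))
  }

  add_node("OUT", "outlet")
  prev <- "OUT"
  for (k in seq_len(m)) {
    mid <- sprintf("M%02da", k)
    jn <- sprintf("J%02d", k)
    add_node(mid, "mainstem"); add_edge(prev, mid)
    add_node(jn, "junction"); add_edge(mid, jn)
    cf <- sprintf("C%02d", k)
    h1 <- sprintf("H%02da", k); h2 <- sprintf("H%02db", k)
    add_node(cf, "confluence", k); add_edge(jn, cf)
    add_node(h1, "headwater", k); add_edge(cf, h1)
    add_node(h2, "headwater", k); add_edge(cf, h2)
    prev <- jn
  }
  # mainstem source above the last junction so the top reach is ordered
  add_node("SRC", "headwater"); add_edge(prev, "SRC")

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node)
  nodes$strahler <- strahler_orders(nodes, edges, root = "OUT")
  # junction nodes belong to the tributary they drain for site bookkeeping
  jn_idx <- match(sprintf("J%02d", seq_len(m)), nodes$node)
  nodes$tributary[jn_idx] <- seq_len(m)

  # site placement: headwater "a" + confluence per tributary, extras at
  # the second headwater of the first tributaries, shortfall drops
  # confluences; sites stay inside their tributary subtree so the
  # tributary partition is spatially coherent
  site_nodes <- character(0)
  for (k in seq_len(m)) site_nodes <- c(site_nodes, sprintf("H%02da", k))
  if (n_sites >= 2 * m)
    for (k in seq_len(m)) site_nodes <- c(site_nodes, sprintf("C%02d", k))
  else
    site_nodes <- c(site_nodes,
                    sprintf("C%02d", seq_len(n_sites - m)))
  if (extra > 0)
    site_nodes <- c(site_nodes, sprintf("H%02db", seq_len(extra)))
  site_nodes <- site_nodes[seq_len(n_sites)]
  ord <- order(site_nodes)
  site_nodes <- site_nodes[ord]
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  nodes$site_id <- NA_character_
  nodes$site_id[match(site_nodes, nodes$node)] <- site_ids

  emb <- embed_network(nodes, edges, root = "OUT")
  nodes$x <- emb$x[nodes$node]; nodes$y <- emb$y[nodes$node]
  ll <- planar_to_lonlat(nodes$x, nodes$y)
  nodes$longitude <- ll$lon; nodes$latitude <- ll$lat

  fl <- igraph::distances(g, weights = igraph::E(g)$length_km)
  site_fl <- fl[site_nodes, site_nodes, drop = FALSE]
  dimnames(site_fl) <- list(site_ids, site_ids)

  si <- match(site_nodes, nodes$node)
  sites <- data.frame(site_id = site_ids, node = site_nodes,
                      latitude = nodes$latitude[si],
                      longitude = nodes$longitude[si],
                      stream_order = nodes$strahler[si],
                      tributary = nodes$tributary[si],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, graph = g, outlet = "OUT",
                 sites = sites, fluvial = site_fl,
                 node_fluvial = fl, config = config),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf("<river_network> %d nodes, %d edges, %d sites, %d tributaries\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$sites),
              x$config$n_tributaries))
  invisible(x)
}

# Strahler order on the tree rooted at the outlet: leaves are order 1; a
# node takes its children's max order, +1 when >= 2 children share it.
strahler_orders <- function(nodes, edges, root) {
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  ord <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$node)
  assign_rec <- function(v, parent) {
    ch <- setdiff(adj[[v]], parent)
    if (length(ch) == 0) { ord[v] <<- 1L; return(1L) }
    co <- vapply(ch, assign_rec, integer(1), parent = v)
    mx <- max(co)
    ord[v] <<- if (sum(co == mx) >= 2) mx + 1L else mx
    ord[v]
  }
  assign_rec(root, NA_character_)
  ord[nodes$node]
}

# Planar embedding: walk the tree from the root, each edge a straight
# segment of 0.7 x its river length, mainstem heading ~north with
# wiggle, tributaries branching off at an angle. Triangle inequality
# then caps straight-line by fluvial distance.
embed_network <- function(nodes, edges, root) {
  adj_to <- split(seq_len(nrow(edges)), edges$from)
  adj_from <- split(seq_len(nrow(edges)), edges$to)
  x <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$node)
  y <- x
  x[root] <- 0; y[root] <- 0
  walk <- function(v, heading) {
    kids <- c(adj_to[[v]], adj_from[[v]])
    for (e in kids) {
      w <- if (edges$from[e] == v) edges$to[e] else edges$from[e]
      if (!is.na(x[w])) next
      turn <- if (grepl("^[CH]", w)) stats::runif(1, 35, 75) *
                sample(c(-1, 1), 1) else stats::runif(1, -20, 20)
      h <- heading + turn * pi / 180
      len <- 0.7 * edges$length_km[e]
      x[w] <<- x[v] + len * sin(h)
      y[w] <<- y[v] + len * cos(h)
      walk(w, h)
    }
  }
  walk(root, 0)
  # uniform contraction onto <= 113 km (N-S) x 48 km (E-W)
  spanx <- diff(range(x)); spany <- diff(range(y))
  s <- min(1, 48 / max(spanx, 1e-9), 113 / max(spany, 1e-9))
  list(x = (x - min(x)) * s, y = (y - min(y)) * s)
}

planar_to_lonlat <- function(x, y, lat0 = 34.2, lon0 = -96.3) {
  list(lat = lat0 + y / 111.195,
       lon = lon0 + x / (111.195 * cos(lat0 * pi / 180)))
}

# Occupancy field: presence probability of species s at site j decays
# with fluvial distance from the species' focal site. Guarantees each
# site hosts at least one species and each species its focal site.
occupancy_field <- function(net, config) {
  S <- config$n_species
  sites <- net$sites$site_id
  D <- net$fluvial
  focal <- sample(sites, S, replace = TRUE)
  prob <- matrix(NA_real_, S, length(sites), dimnames = list(NULL, sites))
  pres <- matrix(FALSE, S, length(sites), dimnames = list(NULL, sites))
  for (s in seq_len(S)) {
    p <- exp(-config$occupancy_decay * D[focal[s], ])
    prob[s, ] <- p
    pres[s, ] <- stats::runif(length(sites)) < p
    pres[s, focal[s]] <- TRUE
  }
  empty <- which(colSums(pres) == 0)
  for (j in empty) pres[which.max(stats::runif(S)), j] <- TRUE
  list(presence = pres, prob = prob, focal = focal)
}

#' Simulate the first-period metacommunity
#'
#' Draws a regional pool of `n_species` lognormal relative abundances,
#' gives each species a contiguous river neighbourhood via a
#' distance-decaying occupancy field centred on a focal site, and samples
#' each site's survey as a multinomial draw of `sample_size` individuals
#' from the locally present species weighted by regional abundance. The
#' long right tail of the lognormal makes near-singleton rare species
#' expected at the defaults; a warning is logged if none is realized.
#'
#' @param net a `river_network`.
#' @param config its `synthetic_config` (defaults to the network's own).
#' @return list: `table` (T1 `abundance_table`), `pool` (regional
#'   weights), `occupancy` (species x site logical matrix), `focal`.
#' @export
simulate_metacommunity <- function(net, config = net$config) {
  set.seed(config$seed + 1L)
  S <- config$n_species
  w <- stats::rlnorm(S, config$mean_log, config$sd_log)
  species <- sprintf("sp%02d", seq_len(S))
  occ <- occupancy_field(net, config)
  sites <- net$sites$site_id
  counts <- matrix(0, length(sites), S, dimnames = list(NULL, species))
  for (j in seq_along(sites)) {
    wt <- w * occ$presence[, j]
    counts[j, ] <- stats::rmultinom(1, config$sample_size, wt)
  }
  tab <- abundance_table(counts, sites, rep("T1", length(sites)))
  pooled <- colSums(counts)
  if (!any(pooled == 1 | (pooled > 0 & pooled <= 2)))
    warning("no near-singleton rare species realized in T1")
  list(table = tab, pool = stats::setNames(w, species),
       occupancy = occ$presence, occ_prob = occ$prob, focal = occ$focal)
}

#' Apply site-level species turnover to produce a later period
#'
#' Identity turnover within a fixed regional pool: at each site, every
#' occupied species is independently dropped (extirpated) with
#' probability `tau` and replaced by a colonizer drawn from outside the
#' site's current species pool, weighted by regional abundance times the
#' occupancy field's presence probability at that site. The colonizer
#' inherits the observed abundance of the species it replaces -- it
#' fills the vacated niche -- so the site's abundance structure and
#' expected richness are stationary while species identities turn over;
#' the new survey is then redrawn multinomially over the updated
#' assemblage. Sites where no
#' drop occurred keep their survey unchanged, so `tau = 0` reproduces
#' the input exactly. Because the regional pool and occupancy field are
#' fixed, pooled composition drifts far less than site composition --
#' high local change with a quasi-stable global assemblage.
#'
#' @param t1 the earlier-period `abundance_table` (single period).
#' @param meta the list returned by [simulate_metacommunity()] (supplies
#'   pool and occupancy).
#' @param tau turnover probability in \[0, 1\].
#' @param config the `synthetic_config`.
#' @param period label for the new period (default "T2").
#' @param seed seed for this step (default config$seed + 2).
#' @param sites optional subset of site ids to resurvey (default all).
#' @return an `abundance_table` for the new period.
#' @export
apply_turnover <- function(t1, meta, tau, config, period = "T2",
                           seed = config$seed + 2L,
                           sites = ab_sites(t1)) {
  stopifnot(tau >= 0, tau <= 1)
  set.seed(seed)
  m <- unclass(t1)
  keep_rows <- ab_sites(t1) %in% sites
  m <- m[keep_rows, , drop = FALSE]
  site_ids <- ab_sites(t1)[keep_rows]
  w <- meta$pool
  out <- m
  for (r in seq_len(nrow(m))) {
    j <- match(site_ids[r], colnames(meta$occupancy))
    present <- which(m[r, ] > 0)
    drop <- present[stats::runif(length(present)) < tau]
    if (length(drop) == 0) next
    # colonizers come from outside the standing assemblage, drawn by
    # regional abundance weighted by the occupancy field's presence
    # probability at this site; each inherits the observed abundance of
    # the species it replaces (it fills the vacated niche), so the
    # site's abundance structure is stationary while identities turn
    # over, and chained applications stay consistent
    cand <- setdiff(seq_len(ncol(m)), present)
    cw <- w[cand] * meta$occ_prob[cand, j]
    ok <- cw > 0
    cand <- cand[ok]; cw <- cw[ok]
    repl <- if (length(cand) > 0)
      cand[sample.int(length(cand), min(length(drop), length(cand)),
                      replace = FALSE, prob = cw)]
    else integer(0)
    wt <- numeric(ncol(m))
    kept <- setdiff(present, drop)
    wt[kept] <- m[r, kept]
    if (length(repl) > 0) wt[repl] <- m[r, drop[seq_along(repl)]]
    if (all(wt == 0)) wt[which.max(w * meta$occ_prob[, j])] <- 1
    out[r, ] <- stats::rmultinom(1, config$sample_size, wt)
  }
  abundance_table(out, site_ids, rep(period, length(site_ids)))
}

#' Apply tributary-homogenized turnover (planted domain of scale)
#'
#' Emulates within-tributary dispersal that reshuffles individuals among
#' a tributary's sites while leaving each tributary's pooled composition
#' (nearly) unchanged: per tributary, the pooled T1 individuals are
#' re-sampled to a new tributary total (a lognormal tributary-level
#' abundance trend, sd `trib_effect_sd` on the log scale) and then
#' redistributed across member sites with random site shares. Site-level
#' change is therefore large, tributary-level change is multinomial
#' noise only, and coarser pools mix tributaries whose relative weights
#' shifted -- planting a minimum of pooled temporal change at
#' K = `n_tributaries`.
#'
#' @param t1 the earlier-period `abundance_table`.
#' @param net the `river_network` (supplies site-tributary membership).
#' @param config the `synthetic_config`.
#' @param period label for the new period (default "T2").
#' @param seed seed (default config$seed + 2).
#' @return an `abundance_table` for the new period.
#' @export
apply_tributary_turnover <- function(t1, net, config, period = "T2",
                                     seed = config$seed + 2L) {
  set.seed(seed)
  m <- unclass(t1)
  site_ids <- ab_sites(t1)
  trib <- net$sites$tributary[match(site_ids, net$sites$site_id)]
  if (anyNA(trib)) stop("sites without tributary membership")
  out <- m * 0
  for (k in unique(trib)) {
    rows <- which(trib == k)
    pooled <- colSums(m[rows, , drop = FALSE])
    g <- stats::rlnorm(1, 0, config$trib_effect_sd)
    # tributary-level abundance trend: a near-exact rescaling, so the
    # tributary's relative composition is conserved (the index is
    # scale-invariant) while its weight in any coarser pool shifts
    new_pool <- round(pooled * g)
    if (sum(new_pool) < length(rows))
      new_pool <- pmax(new_pool, as.numeric(pooled > 0))
    shares <- stats::rgamma(length(rows), shape = 1)
    shares <- shares / sum(shares)
    for (s in which(new_pool > 0)) {
      out[rows, s] <- stats::rmultinom(1, new_pool[s], shares)[, 1]
    }
    # no site may end up empty-handed
    zero <- rows[rowSums(out[rows, , drop = FALSE]) == 0]
    for (r in zero) out[r, which.max(new_pool)] <- 1
  }
  abundance_table(out, site_ids, rep(period, length(site_ids)))
}

#' Generate a complete synthetic dataset
#'
#' Network, first-period metacommunity, second period by site-level (or
#' tributary-homogenized) turnover, and a third period one "year" after
#' the second for a subset of `n_resurvey` sites at the lighter turnover
#' `tau2`. The entire bundle is a pure function of the configuration
#' (seed included).
#'
#' @param config a `synthetic_config`.
#' @param tributary_mode plant the tributary-scale domain in T2
#'   (default FALSE: independent site-level turnover).
#' @param periods how many periods to generate (2 or 3; default 3).
#' @return list of class `synthetic_dataset`: `network`, `table`
#'   (all periods row-bound), `meta` (pool/occupancy), `sites`
#'   (metadata with one row per site and period), `fluvial`, `config`.
#' @export
synthetic_dataset <- function(config = synthetic_config(),
                              tributary_mode = FALSE, periods = 3) {
  stopifnot(periods %in% c(2, 3))
  net <- generate_network(config)
  meta <- simulate_metacommunity(net, config)
  t1 <- meta$table
  t2 <- if (tributary_mode)
    apply_tributary_turnover(t1, net, config)
  else
    apply_turnover(t1, meta, config$tau, config)
  tabs <- list(t1, t2)
  if (periods == 3 && config$n_resurvey >= 1) {
    res_sites <- sort(net$sites$site_id)[seq_len(config$n_resurvey)]
    keep <- ab_sites(t2) %in% res_sites
    t2_sub <- abundance_table(unclass(t2)[keep, , drop = FALSE],
                              ab_sites(t2)[keep], ab_periods(t2)[keep])
    t3 <- apply_turnover(t2_sub, meta, config$tau2, config, period = "T3",
                         seed = config$seed + 3L)
    tabs <- c(tabs, list(t3))
  }
  all_m <- do.call(rbind, lapply(tabs, unclass))
  table <- abundance_table(all_m,
                           unlist(lapply(tabs, ab_sites)),
                           unlist(lapply(tabs, ab_periods)))
  per <- unique(ab_periods(table))
  sites_meta <- do.call(rbind, lapply(per, function(p) {
    s <- net$sites[net$sites$site_id %in% ab_sites(table)[
      ab_periods(table) == p], ]
    data.frame(site_id = s$site_id, period = p, latitude = s$latitude,
               longitude = s$longitude, stream_order = s$stream_order,
               stringsAsFactors = FALSE)
  }))
  structure(list(network = net, table = table, meta = meta,
                 sites = sites_meta, fluvial = net$fluvial,
                 config = config, tributary_mode = tributary_mode),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d sites, %d species, periods: %s (seed %d)\n",
              x$config$n_sites, x$config$n_species,
              paste(unique(ab_periods(x$table)), collapse = ", "),
              x$config$seed))
  invisible(x)
}

#' Serialize a river network as a Newick string
#'
#' The dendritic tree rooted at the outlet, node names preserved and
#' branch lengths in river-km; validated by a round trip through
#' [ape::read.tree()].
#'
#' @param net a `river_network`.
#' @return a single Newick string.
#' @export
network_newick <- function(net) {
  edges <- net$edges
  adj <- split(seq_len(nrow(edges)), edges$from)
  adj2 <- split(seq_len(nrow(edges)), edges$to)
  rec <- function(v, parent, len) {
    eis <- c(adj[[v]], adj2[[v]])
    kids <- character(0)
    for (e in eis) {
      w <- if (edges$from[e] == v) edges$to[e] else edges$from[e]
      if (identical(w, parent)) next
      kids <- c(kids, rec(w, v, edges$length_km[e]))
    }
    body <- if (length(kids) == 0) v
            else paste0("(", paste(kids, collapse = ","), ")", v)
    if (is.na(len)) body else sprintf("%s:%g", body, len)
  }
  s <- paste0(rec(net$outlet, NA_character_, NA_real_), ";")
  stopifnot(inherits(ape::read.tree(text = s), "phylo"))
  s
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Long abundance CSV, sites CSV, square fluvial distance CSV, Newick
#' network tree, and a manifest JSON recording the configuration.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(ds$table, file.path(dir, "abundance.csv"), "long")
  utils::write.csv(ds$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  fl <- data.frame(site_id = rownames(ds$fluvial),
                   as.data.frame(ds$fluvial, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(fl, file.path(dir, "fluvial_km.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  # river network as Newick (rooted at the outlet, edge lengths = river km)
  nwk <- network_newick(ds$network)
  writeLines(nwk, file.path(dir, "network.nwk"))
  cfg <- ds$config; class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg,
                            tributary_mode = ds$tributary_mode),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
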