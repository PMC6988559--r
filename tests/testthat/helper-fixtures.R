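# shared fixtures and independent oracles

# small two-period, four-site community fixture built in code
toy_table <- function() {
  m <- rbind(
    c(5, 3, 0, 2),   # s1 T1
    c(0, 4, 4, 0),   # s2 T1
    c(5, 0, 0, 2),   # s1 T2
    c(1, 4, 3, 0))   # s2 T2
  colnames(m) <- paste0("sp", 1:4)
  abundance_table(m, c("s1", "s2", "s1", "s2"), c("T1", "T1", "T2", "T2"))
}

random_table <- function(n_sites, n_species, seed, period = "T1") {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_sites * n_species, 2), n_sites, n_species,
                dimnames = list(NULL, paste0("sp", seq_len(n_species))))
    if (all(rowSums(m) > 0)) break
  }
  abundance_table(m, sprintf("s%02d", seq_len(n_sites)),
                  rep(period, n_sites))
}

# naive O(N^3) Ward agglomeration via the Lance-Williams recurrence on
# squared dissimilarities: at each step scans every cluster pair for the
# minimal merge cost. Returns the list of partitions after each merge
# (i.e. the K = N-1, ..., 1 cuts), each as a canonical set of sorted
# member-label vectors.
naive_ward_partitions <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  d2 <- D^2
  clusters <- lapply(seq_len(n), function(i) i)
  sizes <- rep(1, n)
  cost <- d2 / 2  # Ward merge cost for singletons: d^2 * (1*1)/(1+1)
  diag(cost) <- Inf
  active <- rep(TRUE, n)
  out <- list()
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bv <- Inf
    for (a in idx) for (b in idx) if (a < b && cost[a, b] < bv) {
      bv <- cost[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    # Lance-Williams update for Ward: cost(ab, c)
    for (c in idx) {
      if (c == a || c == b) next
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c]
      v <- ((na + nc) * cost[a, c] + (nb + nc) * cost[b, c] -
              nc * bv) / (na + nb + nc)
      cost[a, c] <- cost[c, a] <- v
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    cost[b, ] <- cost[, b] <- Inf
    out[[step]] <- canonical_partition(lapply(which(active), function(i)
      labs[clusters[[i]]]))
  }
  out
}

canonical_partition <- function(groups) {
  gs <- lapply(unname(groups), function(g) sort(as.character(g)))
  gs[order(vapply(gs, `[`, character(1), 1))]
}

partition_from_cut <- function(cl) {
  canonical_partition(split(names(cl), cl))
}

# quick synthetic scenario small enough for repeated use in tests
small_config <- function(seed, ...) {
  synthetic_config(n_sites = 12, n_species = 25, n_tributaries = 6,
                   n_resurvey = 4, seed = seed, ...)
}

default_pairs <- function(ds) {
  s <- ds$network$sites$site_id
  data.frame(site_t1 = s, site_t2 = s, stringsAsFactors = FALSE)
}
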