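#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis with defaults at the
#' study's stated values: 8 km straight-line pairing threshold, same
#' stream order required, one-to-one matching, Morisita-Horn index,
#' 100000 bootstrap iterations for the discontinuity test, 10000 for
#' the diversity partition, diversity order q = 0, alpha level 0.05.
#'
#' @param index dissimilarity index name.
#' @param max_straight_km pairing threshold (default 8).
#' @param require_same_order pairing filter (default TRUE).
#' @param one_to_one pairing mode (default TRUE).
#' @param K_test integer vector of grains for the discontinuity test
#'   (default none; pick after inspecting the scan).
#' @param B discontinuity-test bootstrap iterations (default 100000).
#' @param B_div diversity bootstrap iterations (default 10000).
#' @param q diversity order (default 0).
#' @param period_a,period_b main comparison periods (defaults "T1","T2").
#' @param period_c optional short-interval resurvey period compared to
#'   `period_b` when present (default "T3").
#' @param seed integer seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(index = "morisita_horn", max_straight_km = 8,
                            require_same_order = TRUE, one_to_one = TRUE,
                            K_test = integer(0), B = 100000, B_div = 10000,
                            q = 0, period_a = "T1", period_b = "T2",
                            period_c = "T3", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Species persistence between two periods
#'
#' Counts species with pooled abundance > 0 in both periods, only the
#' first, and only the second, plus a rarity breakdown of the
#' non-persistent species: how many occurred at exactly one site (in the
#' period where they occurred) and how many additionally never exceeded
#' one individual per site.
#'
#' @param table an `abundance_table`.
#' @param period_a,period_b period labels.
#' @return list: `n_shared`, `n_only_a`, `n_only_b`, `rarity`
#'   (`one_site`, `one_individual`).
#' @export
species_persistence <- function(table, period_a, period_b) {
  ma <- unclass(subset_period(table, period_a))
  mb <- unclass(subset_period(table, period_b))
  pa <- colSums(ma) > 0
  pb <- colSums(mb) > 0
  only_a <- which(pa & !pb)
  only_b <- which(pb & !pa)
  non_shared <- c(only_a, only_b)
  occ_sites <- function(s) {
    if (s %in% only_a) sum(ma[, s] > 0) else sum(mb[, s] > 0)
  }
  max_ab <- function(s) {
    if (s %in% only_a) max(ma[, s]) else max(mb[, s])
  }
  n_sites <- vapply(non_shared, occ_sites, numeric(1))
  one_site <- sum(n_sites == 1)
  one_ind <- sum(n_sites > 1 &
                   vapply(non_shared, max_ab, numeric(1)) == 1)
  list(n_shared = sum(pa & pb), n_only_a = length(only_a),
       n_only_b = length(only_b),
       rarity = list(one_site = one_site, one_individual = one_ind))
}

#' Run the full scale-dependent change analysis
#'
#' Orchestrates every stage on already-loaded inputs: taxon
#' harmonization, site pairing, local temporal dissimilarities,
#' global-assemblage diversity, the Ward hierarchy and scan over all
#' grains, the discontinuity test at any nominated K, species
#' persistence, and (when a third period is present) the short-interval
#' comparison. Returns a report bundle; [write_pipeline_report()] writes
#' it out.
#'
#' @param table full `abundance_table` across periods (raw names; the
#'   taxon map is applied here).
#' @param sites site metadata data.frame (site_id, period, latitude,
#'   longitude, stream_order).
#' @param fluvial site-level fluvial distance matrix (river-km).
#' @param config a `pipeline_config`.
#' @param taxon_map taxon harmonization map (default
#'   [default_taxon_map()]).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(table, sites, fluvial,
                         config = pipeline_config(),
                         taxon_map = default_taxon_map()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  tab <- stage("harmonize", harmonize_taxa(table, taxon_map))

  s_a <- sites[sites$period == config$period_a, , drop = FALSE]
  s_b <- sites[sites$period == config$period_b, , drop = FALSE]
  pairs <- stage("pair", match_sites(
    s_a, s_b, fluvial, max_straight_km = config$max_straight_km,
    require_same_order = config$require_same_order,
    one_to_one = config$one_to_one))
  if (nrow(pairs) < 2) stop("[pair] fewer than 2 site pairs retained")

  ptab <- stage("pair", pair_abundance_table(
    tab, pairs, config$period_a, config$period_b))
  D <- stage("dissim", dissimilarity_matrix(tab, config$index))
  local_vals <- stage("dissim", paired_temporal_dissimilarity(
    D, pairs, config$period_a, config$period_b))

  div <- stage("diversity", lapply(
    stats::setNames(c(config$period_a, config$period_b),
                    c(config$period_a, config$period_b)),
    function(p) bootstrap_diversity(tab, p, q = config$q,
                                    B_div = config$B_div,
                                    seed = config$seed)))

  Dp <- stage("cluster", pair_fluvial_matrix(pairs, fluvial))
  tree <- stage("cluster", ward_dendrogram(Dp))
  scan <- stage("scan", scan_all_scales(
    ptab, tree, index = config$index,
    period_a = config$period_a, period_b = config$period_b))

  tests <- if (length(config$K_test) > 0)
    stage("test", test_scan_discontinuities(
      scan, config$K_test, B = config$B, seed = config$seed))
  else list()

  persist <- stage("persistence", species_persistence(
    tab, config$period_a, config$period_b))

  one_year <- NULL
  if (config$period_c %in% ab_periods(tab)) {
    c_sites <- unique(ab_sites(tab)[ab_periods(tab) == config$period_c])
    pairs_c <- data.frame(site_t1 = c_sites, site_t2 = c_sites,
                          stringsAsFactors = FALSE)
    one_year <- stage("dissim", paired_temporal_dissimilarity(
      D, pairs_c, config$period_b, config$period_c))
  }

  summary <- list(
    n_pairs = nrow(pairs),
    n_exact_matches = sum(pairs$exact_match),
    local_mean = mean(local_vals), local_min = min(local_vals),
    local_max = max(local_vals),
    local_median = stats::median(local_vals),
    global_value = unname(scan$per_K[["1"]]),
    one_year_mean = if (is.null(one_year)) NULL else mean(one_year),
    persistence = persist,
    diversity = lapply(div, function(d)
      d[c("q", "alpha", "beta", "gamma", "se_alpha", "se_beta",
          "se_gamma", "richness", "simpson_reciprocal", "se_simpson")]),
    p_values = lapply(tests, `[[`, "p_value"),
    index = config$index, seed = config$seed,
    version = as.character(utils::packageVersion("scalescan")))

  structure(list(table = tab, pairs = pairs, pair_table = ptab,
                 local_values = local_vals, diversity = div, tree = tree,
                 scan = scan, tests = tests, persistence = persist,
                 one_year_values = one_year, summary = summary,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<pipeline_report> %d pairs; local %s mean %.3f ",
           "(range %.3f-%.3f); global K=1 value %.3f\n"),
    s$n_pairs, s$index, s$local_mean, s$local_min, s$local_max,
    s$global_value))
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Emits every module's output: pairs TSV, local values TSV,
#' dissimilarity scan tables, Newick dendrogram, cluster cuts, test
#' JSONs, diversity JSON, and the overall summary JSON.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(pair_id = names(report$local_values),
               dissimilarity = unname(report$local_values)),
    file.path(dir, "local_dissimilarity.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  write_scan(report$scan, file.path(dir, "scan_values.tsv"),
             file.path(dir, "scan_summary.tsv"))
  write_newick(report$tree, file.path(dir, "pair_dendrogram.nwk"))
  write_cluster_cuts(report$tree, file.path(dir, "cluster_cuts.tsv"))
  jsonlite::write_json(report$diversity, file.path(dir, "diversity.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(report$tests) > 0)
    jsonlite::write_json(report$tests, file.path(dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
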