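#!/usr/bin/env Rscript
# Step 4 -- the scale scan and bootstrap discontinuity test.
#
# Clusters the site pairs by fluvial distance (Ward), pools assemblages
# at every grain K from the number of pairs down to one, computes each
# cluster's temporal dissimilarity, writes the boxplot-ready per-K
# tables, then nominates the interior grain minimizing pooled change and
# tests it against the local-scale values with the 100,000-iteration
# bootstrap null.

library(scalescan)

seed <- 1L
tab <- harmonize_taxa(read_abundance_table("results/synth/abundance.csv",
                                           "long"))
pairs <- read.delim("results/pairs.tsv")
fluvial <- read_fluvial_matrix("results/synth/fluvial_km.csv")

ptab <- pair_abundance_table(tab, pairs)
tree <- ward_dendrogram(pair_fluvial_matrix(pairs, fluvial))
scan <- scan_all_scales(ptab, tree)
write_scan(scan, "results/scan_values.tsv", "results/scan_summary.tsv")
write_newick(tree, "results/pair_dendrogram.nwk")
write_cluster_cuts(tree, "results/cluster_cuts.tsv")

print(scan)
cat(sprintf("Local (K = %d) mean: %.3f; global (K = 1) value: %.3f\n",
            scan$N, mean(scan$per_K[[as.character(scan$N)]]),
            scan$per_K[["1"]][[1]]))

K_dom <- find_domain_scale(scan)
res <- test_scan_discontinuities(scan, K_dom, B = 100000, seed = seed)
tst <- res[[1]]
jsonlite::write_json(tst, "results/discontinuity_test.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "Candidate domain at K = %d: mean %.3f, p = %.4g (bootstrap median %.3f)\n",
  K_dom, tst$observed_mean, tst$p_value,
  unname(tst$boot_summary["median"])))
cat(if (tst$p_value <= tst$alpha)
      "Pooled change at this grain is unusually low relative to local change.\n"
    else
      "No significant departure from the local-scale distribution.\n")
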