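#!/usr/bin/env Rscript
# Stage 4: summary report over the result bundle.
#
# Lists which reliability table families the pipeline produced and prints
# the regional/link ICC medians (with ranges), the distance-correlation
# medians, and the topographic permutation test outcome.

suppressPackageStartupMessages(library(phaselag))

tables <- report_bundle("results/pipeline")

cat("\nRegional-degree ICC, median (range) per band:\n")
r <- tables$icc_regional
print(data.frame(measure = r$measure, band = r$band,
                 median = round(r$median_icc, 2),
                 range = sprintf("%.2f-%.2f", r$min_icc, r$max_icc)),
      row.names = FALSE)

cat("\nInter-regional link ICC, median (range) per band:\n")
l <- tables$icc_links
print(data.frame(measure = l$measure, band = l$band,
                 median = round(l$median_icc, 2),
                 range = sprintf("%.2f-%.2f", l$min_icc, l$max_icc)),
      row.names = FALSE)

cat("\nMedian Spearman rho, weight vs inter-electrode distance:\n")
d <- tables$distance_rho
print(data.frame(measure = d$measure, band = d$band,
                 rho = round(d$median_rho, 3)), row.names = FALSE)

topo <- tables$topographic
n_sig <- sum(topo$p_corrected < 0.05)
cat(sprintf("\nTopographic band differences: %d of %d channel tests significant at corrected p < 0.05\n",
            n_sig, nrow(topo)))
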