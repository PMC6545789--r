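#!/usr/bin/env Rscript
# Two-cell-type tube, reduced scale: 10% endothelial / 90% smooth-muscle
# wall spheroids around a sacrificial core, 5000 MCS. Compares the adhesion
# hierarchy that drives endothelial cells to line the sacrificial core
# ("sorting") with the broken hierarchy ("scrambled") over paired seeds.

suppressPackageStartupMessages(library(sacrosim))
dir.create("results", showWarnings = FALSE)

seeds <- 1:5
rows <- list()
for (s in seeds) {
  for (v in c("sorting", "scrambled")) {
    pr <- run_protocol("two_type_tube", "reduced", seed = s, variant = v)
    tr <- sorting_trajectory(pr$run, "endothelial", "sacrificial")
    tr$seed <- s
    tr$variant <- v
    rows[[length(rows) + 1L]] <- tr
  }
}
cov <- do.call(rbind, rows)
write.csv(cov, "results/two_type_coverage.csv", row.names = FALSE)

fin <- cov[!is.na(cov$coverage), ]
fin <- do.call(rbind, lapply(split(fin, list(fin$seed, fin$variant)), function(d)
  d[which.max(d$mcs), ]))
final_tab <- reshape(fin[, c("seed", "variant", "coverage")], idvar = "seed",
                     timevar = "variant", direction = "wide")
names(final_tab) <- c("seed", "coverage_scrambled", "coverage_sorting")
write.csv(final_tab, "results/two_type_final_coverage.csv", row.names = FALSE)

cat("Endothelial lining coverage of the sacrificial core, final state:\n")
print(final_tab, row.names = FALSE)
cat(sprintf(
  "\nMean final coverage %.3f (sorting) vs %.3f (scrambled); the right\n",
  mean(final_tab$coverage_sorting), mean(final_tab$coverage_scrambled)))
cat("hierarchy wins in", sum(final_tab$coverage_sorting > final_tab$coverage_scrambled),
    "of", nrow(final_tab), "paired seeds.\n")
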