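#!/usr/bin/env Rscript
# Single-cell-type tube with a sacrificial core, reduced scale (diameter-5
# spheroids, chain of three, 600 MCS with elimination after 500): spheroid
# fusion smooths the outer surface, elimination opens an enclosed lumen,
# and the lumen shrinks during the post-elimination relaxation window.

suppressPackageStartupMessages(library(sacrosim))
dir.create("results", showWarnings = FALSE)

seeds <- 1:3
rows <- list()
lumen_rows <- list()
for (s in seeds) {
  pr <- run_protocol("single_tube", "reduced", seed = s)
  rep <- pr$report
  rep$seed <- s
  rows[[length(rows) + 1L]] <- rep

  vac <- pr$run$vacated[[1]]
  elim_key <- names(pr$run$vacated)[1]
  post <- eliminate_type(pr$run$snapshots[[elim_key]], "sacrificial")$lattice
  lum0 <- lumen_report(post, vac)
  lum1 <- lumen_report(pr$run$final, vac)
  lumen_rows[[length(lumen_rows) + 1L]] <- data.frame(
    seed = s, removed = unname(pr$run$eliminated[1]),
    lumen_at_elimination = lum0$size, vacated_recovered = lum0$vacated_recovered,
    lumen_final = lum1$size,
    medium_in_channel_at_elimination = sum(post$sites[vac] == 0L),
    medium_in_channel_final = sum(pr$run$final$sites[vac] == 0L))
}
trace <- do.call(rbind, rows)
lumen <- do.call(rbind, lumen_rows)
write.csv(trace, "results/single_tube_trace.csv", row.names = FALSE)
write.csv(lumen, "results/single_tube_lumen.csv", row.names = FALSE)

cat("Surface smoothing: construct/medium boundary pairs over MCS (seed means)\n")
print(aggregate(boundary_pairs ~ mcs, trace, mean))
cat("\nLumen formation and collapse:\n")
print(lumen)
cat("\nIn every seed the enclosed lumen recovered >=",
    round(min(lumen$vacated_recovered), 2),
    "of the vacated channel and shrank from",
    round(mean(lumen$lumen_at_elimination)), "to",
    round(mean(lumen$lumen_final)), "sites (seed mean) within the extra MCS.\n")
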