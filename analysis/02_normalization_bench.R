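#!/usr/bin/env Rscript
# Step 2: score the seven normalization methods on the perturbed prototype
# bench and select the one to use for the survey. Writes the per-method,
# per-panel min/max table (the test-bench layout) and the selection.
suppressPackageStartupMessages(library(ildtaxa))

seed <- 1
dir.create("results/bench", recursive = TRUE, showWarnings = FALSE)

bench <- bench_evaluate(make_prototypes(), seed = seed)
write.csv(bench$table, "results/bench/bench_table.csv", row.names = FALSE)

# compact min/max layout: one row per method, one column pair per panel
wide <- do.call(rbind, lapply(split(bench$table, bench$table$id), function(d) {
  stats::setNames(sprintf("%.2g/%.2g", d$min, d$max), d$panel)
}))
wide <- data.frame(method = norm_methods()$name, wide, check.names = FALSE)
write.csv(wide, "results/bench/bench_minmax_layout.csv", row.names = FALSE)

cat("normalization test bench (min/max per prototype panel):\n")
print(wide, row.names = FALSE)
cat(sprintf("\nselected method: %s\n", bench$selected))
utpm_rows <- bench$table[bench$table$method == bench$selected, ]
cat(sprintf("it rescales uniformly (worst-case max %.2f vs raw 100 + 6%%),\n",
            max(utpm_rows$max)))
cat(sprintf("with panel shape correlation %.6f on every panel\n",
            min(utpm_rows$shape_r)))
writeLines(bench$selected, "results/bench/selected_method.txt")
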