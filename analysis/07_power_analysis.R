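#!/usr/bin/env Rscript
# Stage 7: how much power does a 245-patient validation cohort have to
# confirm a gene mutated in 5.3% of patients with HR 1.93 and 70% events?
# Monte-Carlo power with the analytic Schoenfeld cross-check, plus a small
# design grid.

suppressMessages(library(melscreen))
dir.create("results", showWarnings = FALSE)

ref <- power_by_simulation(n = 245, prevalence = 0.053, hr = 1.93,
                           event_fraction = 0.70, n_reps = 10000, seed = 1123)
cat(sprintf("Reference design: power %.3f (95%% CI %.3f-%.3f); Schoenfeld %.3f\n",
            ref$power, ref$ci_low, ref$ci_high,
            power_schoenfeld(245, 0.053, 1.93, 0.70)))

grid <- expand.grid(n = c(245, 500, 1000), hr = c(1.5, 1.93, 2.5))
grid$power <- NA_real_
grid$schoenfeld <- NA_real_
for (i in seq_len(nrow(grid))) {
  r <- power_by_simulation(grid$n[i], 0.053, grid$hr[i], 0.70,
                           n_reps = 2000, seed = 2000 + i)
  grid$power[i] <- r$power
  grid$schoenfeld[i] <- power_schoenfeld(grid$n[i], 0.053, grid$hr[i], 0.70)
}
print(grid, digits = 3)
write.table(grid, "results/power_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("An n=245 cohort is underpowered for HR ~ 2 effects at 5% prevalence;\n")
cat("detecting them reliably (power > 0.9) needs about 1000 patients.\n")
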