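#!/usr/bin/env Rscript
# Step 3: fit the BWB, Medlyn and Ye conductance models to every replicate
# curve of every condition, by least squares on An, and run paired t-tests
# of observed vs model-predicted An per curve.

library(gscompare)

conditions <- c(light_420 = "results/curves_light.csv",
                co2_isat = "results/curves_co2_isat.csv",
                co2_half_isat = "results/curves_co2_half.csv")

fit_rows <- list()
t_rows <- list()
for (cond in names(conditions)) {
  for (cv in read_gas_exchange_table(conditions[[cond]])) {
    for (model in c("bwb", "medlyn", "ye")) {
      f <- suppressWarnings(fit_gs_model(cv, model))
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        condition = cond, species = f$species, replicate = f$replicate,
        model = model, g0 = f$g0, se_g0 = f$se_g0, g1 = f$g1,
        se_g1 = f$se_g1, n = f$n, rss = f$rss, r2_adj = f$r2_adj,
        aic = f$aic, converged = f$converged
      )
      pt <- paired_t_observed_vs_predicted(cv$data$An, f$fitted)
      t_rows[[length(t_rows) + 1L]] <- data.frame(
        condition = cond, species = f$species, replicate = f$replicate,
        model = model, t = pt$t, p = pt$p, df = pt$df, flag = pt$flag
      )
    }
  }
}
fits <- do.call(rbind, fit_rows)
write.csv(fits, "results/fits.csv", row.names = FALSE)
write.csv(do.call(rbind, t_rows), "results/paired_t.csv", row.names = FALSE)

# quick verdicts, replicate-averaged
agg <- aggregate(cbind(r2_adj, aic) ~ condition + model, fits, mean)
cat("replicate-mean fit quality by condition and model:\n")
print(agg[order(agg$condition, -agg$r2_adj), ], row.names = FALSE)
cat("written: results/fits.csv, results/paired_t.csv\n")
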