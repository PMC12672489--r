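#!/usr/bin/env Rscript
# Step 4: verify the pipeline against the packaged reference solution.
#
# Recomputes, from the printed 20 x 6 loading matrix and eigenvalues, the
# norm values, communalities, contribution rates, group labels, the
# nine-indicator minimum data set and its communality weights, and checks
# each against the printed columns (tolerance 0.002, the rounding error of
# 3-decimal loadings; 0.01 for percentage rates).

suppressPackageStartupMessages(library(soilqualkit))

ref <- load_reference_pca()
model <- as_pca_model(ref)
norms <- norm_values(model)
groups <- assign_groups(model)
sel <- build_mds(model, ref$correlations)
weights <- compute_weights(ref$communality[sel$mds])
printed_w <- c(0.120, 0.106, 0.086, 0.114, 0.108, 0.110, 0.123, 0.121, 0.112)

checks <- data.frame(
  check = c("norm values (20 cells)", "communalities (20 cells)",
            "contribution rate PC1", "cumulative rate PC6",
            "group labels (20)", "minimum data set (9 indicators)",
            "weight multiset (9)", "ALP weight", "NAG weight"),
  pass = c(all(abs(norms - ref$norm) <= 0.002),
           all(abs(model$communality - ref$communality) <= 0.002),
           abs(model$contribution_rate[[1]] - 31.828) < 0.01,
           abs(model$cumulative_rate[[6]] - 73.684) < 0.01,
           all(groups == ref$group),
           setequal(sel$mds, c("ALP", "NO3", "ACP", "BG", "POD", "BX",
                               "NH4", "NAG", "TP")),
           all(abs(sort(unname(weights)) - sort(printed_w)) <= 0.002),
           abs(weights[["ALP"]] - 0.120) <= 0.002,
           abs(weights[["NAG"]] - 0.121) <= 0.002))

dir.create("results", showWarnings = FALSE)
write.csv(checks, "results/reference_check.csv", row.names = FALSE)
print(checks, row.names = FALSE)
if (!all(checks$pass)) {
  stop("reference replication failed")
}
cat("all reference checks passed\n")
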