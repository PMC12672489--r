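# Small in-code fixtures shared across test files.

# A tiny hand-built indicator table: 5 samples, 3 indicators.
small_specs <- function() {
  specs <- indicator_specs(c("SOC", "TN", "BD"),
                           unit = c("g.kg-1", "g.kg-1", "g.cm-3"))
  specs$orientation[specs$name == "BD"] <- "less_is_better"
  specs
}

small_table_df <- function() {
  data.frame(
    sample_id = paste0("s", 1:5),
    pattern_id = c("P1", "P1", "P1", "P2", "P2"),
    plot_id = paste0("pl", 1:5),
    SOC = c(20.1, 25.3, 18.7, 30.2, 27.5),
    TN = c(1.2, 1.6, 1.1, 1.9, 1.7),
    BD = c(1.31, 1.22, 1.40, 1.10, 1.18),
    stringsAsFactors = FALSE)
}

small_inventory <- function() {
  data.frame(
    plot_id = c("p1", "p1", "p1"),
    species = c("fir", "oak", "fir"),
    is_broadleaf = c(FALSE, TRUE, FALSE),
    dbh = c(15, 22, 10),
    height = c(12, 16, 8),
    stringsAsFactors = FALSE)
}

# O(n^2) brute-force Gini oracle: mean absolute pairwise difference over
# twice the mean (independent of the package's sorted-rank identity).
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(abs(x[i] - x))
  s / (2 * n^2 * mean(x))
}
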