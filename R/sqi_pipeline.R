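#' Standardize an indicator table
#'
#' Centres each indicator to mean 0 and scales to sample standard
#' deviation 1, the input expected by correlation-based PCA.
#'
#' @param x An `indicator_table` or a numeric samples-by-indicators matrix
#'   with at least 3 rows.
#' @return Numeric matrix of z-scores with the input's column order.
#' @export
standardize_indicators <- function(x) {
  m <- if (inherits(x, "indicator_table")) indicator_matrix(x) else as.matrix(x)
  if (nrow(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 2L, stats::sd)
  zero <- names(which(sds == 0 | !is.finite(sds)))
  if (length(zero)) {
    stop("zero-variance indicator(s): ", paste(zero, collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

cor_from_input <- function(x) {
  m <- if (inherits(x, "indicator_table")) indicator_matrix(x) else as.matrix(x)
  if (nrow(m) == ncol(m) && isTRUE(all.equal(unname(m), unname(t(m)))) &&
      isTRUE(all.equal(unname(diag(m)), rep(1, ncol(m))))) {
    list(R = m, n = NA_integer_)
  } else {
    list(R = stats::cor(m), n = nrow(m))
  }
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO statistic measuring whether a correlation matrix is suitable
#' for factor-analytic decomposition: the ratio of summed squared
#' correlations to summed squared correlations plus summed squared partial
#' correlations (off-diagonal), where partial correlations are obtained
#' from the inverse correlation matrix. Values near 1 indicate compact
#' factors; values below 0.5 are conventionally inadequate.
#'
#' @param x Indicator table, data matrix, or correlation matrix.
#' @return List with `statistic` (overall KMO in \[0, 1\]) and `msa`
#'   (per-indicator measures of sampling adequacy).
#' @export
kmo <- function(x) {
  R <- cor_from_input(x)$R
  inv <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; remove collinear indicators")
  })
  s <- 1 / sqrt(diag(inv))
  Q <- -inv * tcrossprod(s)      # partial correlations, diag = -1
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  msa <- colSums(r2) / (colSums(r2) + colSums(q2))
  list(statistic = sum(r2) / (sum(r2) + sum(q2)),
       msa = stats::setNames(msa, colnames(R)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix differs from the identity, i.e.
#' whether there is any correlation structure for PCA to summarise.
#' chi^2 = -(n - 1 - (2p + 5)/6) ln det(R), with p(p-1)/2 degrees of
#' freedom and an upper-tail chi-square p-value.
#'
#' @param x Indicator table or data matrix; or a correlation matrix, in
#'   which case `n` must be supplied.
#' @param n Number of samples (only needed when `x` is a correlation
#'   matrix).
#' @return List with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(x, n = NULL) {
  ci <- cor_from_input(x)
  R <- ci$R
  if (is.null(n)) n <- ci$n
  if (is.na(n)) stop("supply n when passing a correlation matrix")
  p <- ncol(R)
  if (n <= p) {
    warning("fewer samples than indicators; Bartlett's test is unreliable")
  }
  d <- det(R)
  if (!is.finite(d) || d <= 0) stop("correlation matrix determinant <= 0")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

new_pca_model <- function(loadings, eigenvalues, all_eigenvalues, p) {
  k <- length(eigenvalues)
  contribution <- eigenvalues / p * 100
  structure(list(
    loadings = loadings,
    eigenvalues = eigenvalues,
    all_eigenvalues = all_eigenvalues,
    n_indicators = p,
    communality = rowSums(loadings^2),
    contribution_rate = contribution,
    cumulative_rate = cumsum(contribution)
  ), class = "pca_model")
}

#' Principal component model of the indicator correlation matrix
#'
#' Eigendecomposition of the sample correlation matrix. Components with
#' eigenvalue >= 1 are retained (ties at exactly 1 kept). Loadings are
#' eigenvectors scaled by the square root of their eigenvalue, so each
#' loading is the correlation of indicator and component; communalities are
#' row sums of squared retained loadings. Component sign is fixed so the
#' largest-|loading| entry of each column is positive (sign does not affect
#' norms, communalities, groups or the index). Contribution rates are
#' eigenvalue / p x 100.
#'
#' @param x Standardized data matrix (see [standardize_indicators()]), raw
#'   indicator table/matrix (standardized internally), or correlation
#'   matrix.
#' @return A `pca_model`: list with `loadings` (p x k), `eigenvalues`
#'   (retained), `all_eigenvalues` (all p), `n_indicators`, `communality`,
#'   `contribution_rate`, `cumulative_rate`.
#' @export
run_pca <- function(x) {
  R <- cor_from_input(x)$R
  p <- ncol(R)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values >= 1)
  if (!length(keep)) stop("no component with eigenvalue >= 1")
  ev <- e$values[keep]
  L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev), length(keep))
  for (j in seq_len(ncol(L))) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(R), paste0("PC", seq_along(keep)))
  new_pca_model(L, stats::setNames(ev, colnames(L)), e$values, p)
}

#' Treat a published reference PCA solution as a PCA model
#'
#' Wraps the printed loading matrix and eigenvalues of
#' [load_reference_pca()] in the same `pca_model` structure produced by
#' [run_pca()], recomputing communalities and contribution rates from the
#' printed values, so norm computation, grouping and selection run
#' identically on it.
#'
#' @param ref A `reference_pca` object.
#' @return A `pca_model`.
#' @export
as_pca_model <- function(ref) {
  stopifnot(inherits(ref, "reference_pca"))
  new_pca_model(ref$loadings, ref$eigenvalues,
                all_eigenvalues = unname(ref$eigenvalues),
                p = nrow(ref$loadings))
}

#' Norm values of indicators
#'
#' The norm value of indicator i is the eigenvalue-weighted length of its
#' loading vector over the retained components,
#' N_i = sqrt(sum_k U_ik^2 e_k). It measures the indicator's overall
#' representational power across the retained components and ranks
#' indicators within groups for minimum-data-set selection.
#'
#' @param model A `pca_model`.
#' @return Named numeric vector of norm values, one per indicator.
#' @export
norm_values <- function(model) {
  sqrt(drop(model$loadings^2 %*% model$eigenvalues))
}

#' Assign indicators to component groups
#'
#' Each indicator is assigned to the retained component on which it has the
#' largest absolute loading; exact ties go to the lower component index.
#' This reproduces published group labels even where the maximum loading
#' falls slightly below the conventional 0.5 description.
#'
#' @param model A `pca_model`.
#' @return Named integer vector: indicator -> group (component) index.
#' @export
assign_groups <- function(model) {
  g <- apply(abs(model$loadings), 1L, which.max)
  stats::setNames(as.integer(g), rownames(model$loadings))
}

#' High-norm indicators within each group
#'
#' Within each component group, retains the indicators whose norm value is
#' within 10% of the group maximum (N_i >= 0.9 x max, inclusive).
#'
#' @param groups Named integer vector from [assign_groups()].
#' @param norms Named numeric vector from [norm_values()].
#' @return Named list, one character vector of indicator names per group,
#'   each sorted by decreasing norm.
#' @export
select_high_norm <- function(groups, norms) {
  out <- lapply(split(names(groups), groups), function(members) {
    nv <- sort(norms[members], decreasing = TRUE)
    names(nv)[nv >= 0.9 * nv[1L]]
  })
  out
}

lookup_edge <- function(correlations, x, y) {
  hit <- (correlations$a == x & correlations$b == y) |
    (correlations$a == y & correlations$b == x)
  if (!any(hit)) return(NULL)
  correlations[which(hit)[1L], ]
}

#' Prune correlated indicators within groups
#'
#' Final minimum-data-set step: within each group, high-norm indicators are
#' processed in descending norm order; an indicator is kept unless it is
#' significantly correlated (two-sided p < 0.05 or an explicit significance
#' flag) with an already-kept higher-norm indicator of the same group. The
#' union over groups is the MDS.
#'
#' @param high_sets Per-group retained sets from [select_high_norm()].
#' @param norms Named norm-value vector.
#' @param correlations Data frame with columns `a`, `b`, `significant`
#'   (logical) and optionally `r`; e.g. from [pearson_edges()] or the
#'   reference fixture. A missing fact for a pair that must be consulted is
#'   an error.
#' @param groups Named group vector (for the audit trail).
#' @return List of class `mds_selection`: `mds` (final ordered indicator
#'   vector, by group then descending norm), `group_of`, `norm`,
#'   `high_norm_sets`, and `audit` (per-indicator status data frame).
#' @export
prune_by_correlation <- function(high_sets, norms, correlations,
                                 groups = NULL) {
  audit <- list()
  mds <- character()
  for (g in names(high_sets)) {
    cand <- high_sets[[g]]
    cand <- cand[order(-norms[cand])]
    kept <- character()
    for (ind in cand) {
      dropped_by <- NULL
      for (k in kept) {
        edge <- lookup_edge(correlations, ind, k)
        if (is.null(edge)) {
          stop("missing correlation fact for pair ", ind, " - ", k)
        }
        if (isTRUE(edge$significant)) {
          dropped_by <- k
          break
        }
      }
      if (is.null(dropped_by)) {
        kept <- c(kept, ind)
        audit[[ind]] <- data.frame(
          indicator = ind, group = as.integer(g), norm = unname(norms[ind]),
          status = "retained", detail = if (length(kept) == 1L)
            "highest norm in group" else "not correlated with kept indicators",
          stringsAsFactors = FALSE)
      } else {
        audit[[ind]] <- data.frame(
          indicator = ind, group = as.integer(g), norm = unname(norms[ind]),
          status = "dropped_correlated",
          detail = paste0("significantly correlated with ", dropped_by),
          stringsAsFactors = FALSE)
      }
    }
    mds <- c(mds, kept)
  }
  if (!is.null(groups)) {
    below <- setdiff(names(groups), unlist(high_sets))
    for (ind in below) {
      audit[[ind]] <- data.frame(
        indicator = ind, group = unname(groups[ind]),
        norm = unname(norms[ind]), status = "below_norm_band",
        detail = "norm below 90% of group maximum", stringsAsFactors = FALSE)
    }
  }
  if (!length(mds)) stop("empty minimum data set")
  audit <- do.call(rbind, audit[order(names(audit))])
  rownames(audit) <- NULL
  structure(list(mds = mds, group_of = groups, norm = norms,
                 high_norm_sets = high_sets, audit = audit),
            class = "mds_selection")
}

#' Full minimum-data-set selection from a PCA model
#'
#' Convenience chain: [norm_values()] -> [assign_groups()] ->
#' [select_high_norm()] -> [prune_by_correlation()].
#'
#' @param model A `pca_model`.
#' @param correlations Correlation edge list (see
#'   [prune_by_correlation()]).
#' @return An `mds_selection`.
#' @export
build_mds <- function(model, correlations) {
  norms <- norm_values(model)
  groups <- assign_groups(model)
  high <- select_high_norm(groups, norms)
  prune_by_correlation(high, norms, correlations, groups)
}

#' Nonlinear sigmoid indicator score
#'
#' S = a / (1 + (x / x_m)^b) with maximum score a = 1; b = -2.5 for
#' "more is better" indicators (score increases with x) and b = +2.5 for
#' "less is better". The score is 0.5 at x = x_m; limits at x = 0 are 0
#' (more is better) and 1 (less is better).
#'
#' @param x Observed value(s), >= 0.
#' @param x_m Reference mean value, > 0.
#' @param b Exponent, -2.5 or +2.5 (any nonzero value accepted).
#' @param a Maximum score, default 1.
#' @return Score(s) in \[0, 1\] (open interval for x > 0).
#' @export
snl_score <- function(x, x_m, b, a = 1) {
  if (any(!is.finite(x) | x < 0)) stop("x must be finite and >= 0")
  if (any(!is.finite(x_m) | x_m <= 0)) stop("x_m must be > 0")
  ratio <- (x / x_m)^b
  # 0^negative = Inf -> score 0; 0^positive = 0 -> score 1 (limit conventions)
  a / (1 + ratio)
}

orientation_to_b <- function(orientation) {
  ifelse(orientation == "less_is_better", 2.5, -2.5)
}

#' Scoring specification for a set of indicators
#'
#' Builds the per-indicator nonlinear scoring parameters: the reference
#' value x_m is each indicator's mean over all samples of the run (one
#' shared reference keeps the index comparable between patterns), the
#' exponent b follows the declared orientation, and a = 1.
#'
#' @param table An `indicator_table`.
#' @param indicators Indicator names to score (default all).
#' @return Data frame with columns indicator, orientation, x_m, b, a.
#' @export
scoring_spec <- function(table, indicators = NULL) {
  specs <- attr(table, "specs")
  if (is.null(indicators)) indicators <- specs$name
  m <- indicator_matrix(table)[, indicators, drop = FALSE]
  x_m <- colMeans(m)
  if (any(x_m <= 0)) {
    stop("non-positive mean for indicator(s): ",
         paste(indicators[x_m <= 0], collapse = ", "))
  }
  ori <- specs$orientation[match(indicators, specs$name)]
  data.frame(indicator = indicators, orientation = ori, x_m = unname(x_m),
             b = orientation_to_b(ori), a = 1, stringsAsFactors = FALSE)
}

#' Score indicators of a table
#'
#' @param table An `indicator_table`.
#' @param spec Scoring specification from [scoring_spec()].
#' @return Samples x indicators matrix of scores in (0, 1).
#' @export
score_indicators <- function(table, spec) {
  m <- indicator_matrix(table)[, spec$indicator, drop = FALSE]
  s <- vapply(seq_len(nrow(spec)), function(j) {
    snl_score(m[, j], spec$x_m[j], spec$b[j], spec$a[j])
  }, numeric(nrow(m)))
  s <- matrix(s, nrow = nrow(m),
              dimnames = list(rownames(m), spec$indicator))
  s
}

#' Communality-based indicator weights
#'
#' W_i = C_i / sum(C_i) over the minimum-data-set indicators, where C_i is
#' the indicator's communality (variance explained by the retained
#' components). Weights are positive and sum to 1.
#'
#' @param communalities Named numeric vector of communalities (restricted
#'   to the MDS), all > 0.
#' @return Named weight vector summing to 1.
#' @export
compute_weights <- function(communalities) {
  if (!length(communalities)) stop("empty minimum data set")
  if (any(!is.finite(communalities) | communalities <= 0)) {
    stop("communalities must be > 0")
  }
  communalities / sum(communalities)
}

#' Soil quality classes
#'
#' Five classes on the unit interval. The conventional bound listing
#' overlaps at its endpoints, so the package fixes lower-inclusive bands
#' with a strictly-exclusive top class: very low \[0, 0.28), low
#' \[0.28, 0.37), medium \[0.37, 0.46), high \[0.46, 0.55\], very high
#' (0.55, 1\]. Thus an index of exactly 0.46 is "high" and "very high"
#' requires exceeding 0.55.
#'
#' @param sqi Numeric vector of index values in \[0, 1\].
#' @return Character vector of class labels.
#' @export
classify_sqi <- function(sqi) {
  if (any(!is.finite(sqi) | sqi < 0 | sqi > 1)) stop("SQI must lie in [0, 1]")
  ifelse(sqi > 0.55, "very high",
         ifelse(sqi >= 0.46, "high",
                ifelse(sqi >= 0.37, "medium",
                       ifelse(sqi >= 0.28, "low", "very low"))))
}

#' Weighted additive soil quality index
#'
#' SQI = sum_i W_i S_i per sample, with communality weights W_i and
#' nonlinear scores S_i. Because weights sum to 1 and scores lie in the
#' unit interval, the index is already on a 0-1 scale; no further
#' rescaling is applied.
#'
#' @param scores Samples x indicators score matrix from
#'   [score_indicators()].
#' @param weights Named weight vector from [compute_weights()]; names must
#'   match score columns.
#' @return Data frame with columns `sqi` and `class`, rownames = samples.
#' @export
compute_sqi <- function(scores, weights) {
  if (!setequal(colnames(scores), names(weights))) {
    stop("score columns and weight names disagree")
  }
  if (any(scores < 0 | scores > 1)) stop("scores outside [0, 1]")
  w <- weights[colnames(scores)]
  if (abs(sum(w) - 1) > 1e-10) stop("weights must sum to 1")
  sqi <- drop(scores %*% w)
  data.frame(sqi = sqi, class = classify_sqi(sqi),
             row.names = rownames(scores), stringsAsFactors = FALSE)
}

#' Sensitivity index per pattern
#'
#' SI = max(SQI) / min(SQI) over the replicate samples of each planting
#' pattern; values near 1 mean soil quality is insensitive to the
#' within-pattern variation, larger values mean greater responsiveness.
#'
#' @param sqi Numeric vector of per-sample index values, all > 0.
#' @param pattern Vector of pattern ids, same length.
#' @return Named numeric vector, one SI (>= 1) per pattern.
#' @export
sensitivity_index <- function(sqi, pattern) {
  stopifnot(length(sqi) == length(pattern))
  counts <- table(pattern)
  if (any(counts < 2L)) {
    stop("pattern(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  if (any(sqi <= 0)) stop("SQI must be > 0 for a max/min ratio")
  vapply(split(sqi, pattern), function(v) max(v) / min(v), numeric(1))
}

#' Run the complete minimum-data-set soil quality assessment
#'
#' Executes the full pipeline on a validated indicator table:
#' standardization, KMO and Bartlett adequacy checks (warning if KMO < 0.5
#' or Bartlett p >= 0.05), correlation PCA with eigenvalue >= 1 retention,
#' component grouping, norm values, the within-10%-of-maximum norm band,
#' correlation pruning (Pearson tests computed from the data, two-sided
#' p < 0.05), nonlinear scoring of the selected indicators against their
#' all-sample means, communality weighting, the weighted additive index
#' with class labels, and the per-pattern sensitivity index. Every
#' selection decision is recorded in a human-readable audit.
#'
#' @param table An `indicator_table`.
#' @param alpha Significance level for correlation pruning (default 0.05).
#' @return List of class `sqi_result`: `samples` (sample_id, pattern_id,
#'   plot_id, per-indicator scores, sqi, class), `weights`, `selection`
#'   (`mds_selection`), `pca` (`pca_model`), `kmo`, `bartlett`,
#'   `sensitivity` (per-pattern SI), `scoring` (scoring spec), `audit`
#'   (character vector).
#' @export
run_sqi_pipeline <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "indicator_table"))
  z <- standardize_indicators(table)
  adequacy <- kmo(z)
  bart <- bartlett_sphericity(z)
  audit <- c(
    sprintf("samples: %d, indicators: %d", nrow(z), ncol(z)),
    sprintf("KMO = %.3f; Bartlett chi2 = %.2f (df %d, p = %.3g)",
            adequacy$statistic, bart$chi2, bart$df, bart$p))
  if (adequacy$statistic < 0.5) {
    warning("KMO below 0.5; data may be unsuitable for PCA")
    audit <- c(audit, "WARNING: KMO < 0.5")
  }
  if (bart$p >= alpha) {
    warning("Bartlett's test not significant; correlation structure weak")
    audit <- c(audit, "WARNING: Bartlett p >= alpha")
  }
  model <- run_pca(z)
  audit <- c(audit, sprintf(
    "retained %d components (eigenvalues %s); cumulative contribution %.1f%%",
    length(model$eigenvalues),
    paste(sprintf("%.3f", model$eigenvalues), collapse = ", "),
    model$cumulative_rate[length(model$cumulative_rate)]))
  edges <- pearson_edges(indicator_matrix(table), alpha = alpha)
  selection <- build_mds(model, edges)
  audit <- c(audit, paste0("selection: ", selection$audit$indicator, " [group ",
                           selection$audit$group, ", norm ",
                           sprintf("%.3f", selection$audit$norm), "] ",
                           selection$audit$status, " - ",
                           selection$audit$detail))
  audit <- c(audit, paste0("MDS: ", paste(selection$mds, collapse = ", ")),
             "index scale: weights sum to 1 and scores lie in (0,1), so the index is already 0-1; no extra rescaling")
  spec <- scoring_spec(table, selection$mds)
  scores <- score_indicators(table, spec)
  weights <- compute_weights(model$communality[selection$mds])
  sqi <- compute_sqi(scores, weights)
  samples <- data.frame(sample_id = table$sample_id,
                        pattern_id = table$pattern_id,
                        plot_id = table$plot_id,
                        scores, sqi, stringsAsFactors = FALSE,
                        check.names = FALSE)
  si <- sensitivity_index(sqi$sqi, table$pattern_id)
  structure(list(samples = samples, weights = weights, selection = selection,
                 pca = model, kmo = adequacy, bartlett = bart,
                 sensitivity = si, scoring = spec, audit = audit),
            class = "sqi_result")
}

#' @export
print.sqi_result <- function(x, ...) {
  cat("Minimum-data-set soil quality assessment\n")
  cat(sprintf("  samples: %d   MDS: %s\n", nrow(x$samples),
              paste(x$selection$mds, collapse = ", ")))
  cat(sprintf("  SQI range: %.3f - %.3f\n",
              min(x$samples$sqi), max(x$samples$sqi)))
  cat("  weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}
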