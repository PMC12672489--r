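#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations with two-sided p-values from the
#' t-transformation on n - 2 degrees of freedom. Constant variables yield
#' an undefined correlation and are flagged, never silently set to 0.
#'
#' @param x Numeric matrix or data frame of variables in columns, >= 3
#'   rows.
#' @return List with matrices `r`, `p`, scalar `n`, and `undefined`
#'   (names of constant variables, if any).
#' @export
pearson_matrix <- function(x) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 paired observations")
  sds <- apply(m, 2L, stats::sd)
  undefined <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  if (length(undefined)) {
    r[undefined, ] <- NA_real_
    r[, undefined] <- NA_real_
    p[undefined, ] <- NA_real_
    p[, undefined] <- NA_real_
  }
  list(r = r, p = p, n = n, undefined = undefined)
}

#' Pearson correlation facts as an edge list
#'
#' All variable pairs with r, two-sided p, and a significance flag at
#' `alpha`, in the format consumed by [prune_by_correlation()].
#'
#' @param x Numeric matrix or data frame.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `a`, `b`, `r`, `p`, `significant`.
#' @export
pearson_edges <- function(x, alpha = 0.05) {
  pm <- pearson_matrix(x)
  vars <- colnames(pm$r)
  idx <- which(upper.tri(pm$r), arr.ind = TRUE)
  data.frame(a = vars[idx[, 1]], b = vars[idx[, 2]],
             r = pm$r[idx], p = pm$p[idx],
             significant = !is.na(pm$p[idx]) & pm$p[idx] < alpha,
             stringsAsFactors = FALSE)
}

#' Join soil quality and stand metrics into a pattern-level report
#'
#' Aggregates per-sample SQI values and per-plot stand summaries to one row
#' per planting pattern (mean, sample sd, n for each quantity), with the
#' class of the pattern-mean SQI and the pattern sensitivity index.
#' Plots present on one side only are reported in the `unmatched`
#' attribute and flagged by differing n columns, never dropped silently.
#'
#' @param sqi An `sqi_result` from [run_sqi_pipeline()].
#' @param stands Per-plot stand summary from [stand_summary()].
#' @return Data frame of class `run_report`, one row per pattern:
#'   pattern_id, n_sqi, mean_sqi, sd_sqi, class, si, n_stand, and
#'   mean/sd of cv_d, gini_d_standard, gini_d_dispersion, fb, npp, pbs.
#'   Attributes: `unmatched` (list of plot ids), `seed`, `version`.
#' @export
join_report <- function(sqi, stands) {
  stopifnot(inherits(sqi, "sqi_result"))
  s <- sqi$samples
  overlap <- intersect(s$plot_id, stands$plot_id)
  if (!length(overlap)) stop("no overlapping plots between SQI and stands")
  unmatched <- list(sqi_only = setdiff(s$plot_id, stands$plot_id),
                    stand_only = setdiff(stands$plot_id, s$plot_id))
  agg <- function(v, g) {
    list(mean = tapply(v, g, mean), sd = tapply(v, g, stats::sd),
         n = tapply(v, g, length))
  }
  a_sqi <- agg(s$sqi, s$pattern_id)
  patterns <- names(a_sqi$mean)
  out <- data.frame(pattern_id = patterns,
                    n_sqi = as.integer(a_sqi$n[patterns]),
                    mean_sqi = as.numeric(a_sqi$mean[patterns]),
                    sd_sqi = as.numeric(a_sqi$sd[patterns]),
                    class = classify_sqi(as.numeric(a_sqi$mean[patterns])),
                    si = as.numeric(sqi$sensitivity[patterns]),
                    stringsAsFactors = FALSE)
  st <- stands[stands$plot_id %in% overlap, , drop = FALSE]
  out$n_stand <- as.integer(
    tapply(st$plot_id, st$pattern_id, length)[patterns])
  for (v in c("cv_d", "gini_d_standard", "gini_d_dispersion", "fb", "npp",
              "pbs")) {
    a <- agg(st[[v]], st$pattern_id)
    out[[paste0("mean_", v)]] <- as.numeric(a$mean[patterns])
    out[[paste0("sd_", v)]] <- as.numeric(a$sd[patterns])
  }
  rownames(out) <- NULL
  structure(out, unmatched = unmatched,
            version = as.character(utils::packageVersion("soilqualkit")),
            class = c("run_report", "data.frame"))
}
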