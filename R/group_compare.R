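#' Per-sample proximity-bias summary
#'
#' Composes the distance profile and the avatar null into the per-tumor
#' record used for group comparisons: observed positive-cell median/mean
#' distance, closed-form expected-null median/mean (the all-cell median and
#' mean, the stable large-R limit of the avatar ensemble), their
#' differences (`delta_median`, `delta_mean`; negative = positives
#' concentrate near stroma), the KS statistic of positives against the
#' expected null, and a left-tail empirical p-value of the observed median
#' against `R` avatar medians.
#'
#' @param sample a [tissue_sample] with at least one marker-positive cell,
#'   or a precomputed `distance_profile`.
#' @param R avatar replicates for the empirical p-value.
#' @param seed integer seed for the ensemble.
#' @param treatment,host_model optional label overrides (default: taken
#'   from the sample; `NA` if a bare profile is given).
#' @return A one-row data frame of class `bias_summary` with columns
#'   `sample_id`, `treatment`, `host_model`, `n_cells`, `k_positive`,
#'   `obs_median`, `obs_mean`, `null_median`, `null_mean`, `delta_median`,
#'   `delta_mean`, `ks_d`, `p_left`, `R`, `seed`.
#' @export
sample_bias <- function(sample, R = 1000, seed, treatment = NULL,
                        host_model = NULL) {
  if (inherits(sample, "tissue_sample")) {
    profile <- cell_distances(sample)
    treatment <- treatment %||% sample$treatment
    host_model <- host_model %||% sample$host_model
  } else if (inherits(sample, "distance_profile")) {
    profile <- sample
    treatment <- treatment %||% NA_character_
    host_model <- host_model %||% NA_character_
  } else {
    stop("`sample` must be a tissue_sample or distance_profile",
         call. = FALSE)
  }
  if (!any(profile$marker)) stop("no marker-positive cells", call. = FALSE)
  obs <- summarize_profile(profile, "positive")
  null <- summarize_profile(profile, "all")
  ens <- null_ensemble(profile, R = R, seed = seed)
  out <- data.frame(
    sample_id = profile$sample_id,
    treatment = treatment, host_model = host_model,
    n_cells = null$n, k_positive = obs$n,
    obs_median = obs$median, obs_mean = obs$mean,
    null_median = null$median, null_mean = null$mean,
    delta_median = obs$median - null$median,
    delta_mean = obs$mean - null$mean,
    ks_d = ks_statistic(profile$distance[profile$marker],
                        profile$distance)$statistic,
    p_left = empirical_pvalue(obs$median, ens, tail = "left",
                              statistic = "median_um"),
    R = as.integer(R), seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bias_summary", "data.frame")
  out
}

#' Paired observed-vs-predicted test within a group
#'
#' The per-tumor comparison of observed versus predicted (null) values is
#' paired within tumor, so the two-tailed paired t-test reduces to a
#' one-sample t-test of the per-sample deltas against zero.
#'
#' @param summaries a data frame of stacked [sample_bias()] rows (>= 2
#'   samples).
#' @param statistic `"median"` or `"mean"` endpoint.
#' @return List with `t`, `p.value` (two-tailed), `df`, `n`,
#'   `mean_delta`, and `degenerate` (`TRUE` when the deltas have zero
#'   variance around a nonzero mean, in which case `p.value` is floored at
#'   the smallest positive double).
#' @export
paired_observed_vs_predicted <- function(summaries,
                                         statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  deltas <- summaries[[paste0("delta_", statistic)]]
  if (is.null(deltas)) stop("`summaries` lacks delta columns", call. = FALSE)
  n <- length(deltas)
  if (n < 2L) stop("need at least 2 samples for the paired test",
                   call. = FALSE)
  s <- stats::sd(deltas)
  m <- mean(deltas)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, p.value = 1, df = n - 1L, n = n, mean_delta = 0,
                  degenerate = FALSE))
    }
    return(list(t = sign(m) * Inf, p.value = .Machine$double.xmin,
                df = n - 1L, n = n, mean_delta = m, degenerate = TRUE))
  }
  tt <- stats::t.test(deltas, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), n = n, mean_delta = m, degenerate = FALSE)
}

#' Host-model interaction test (two-way ANOVA)
#'
#' Tests whether the observed-vs-predicted contrast differs between two
#' host models via the interaction term of a two-way ANOVA,
#' `value ~ host_model * condition` with condition in
#' `{observed, predicted}`.
#'
#' Observed and predicted values are measured on the same tumor and are
#' strongly correlated through its geometry, so by default the ANOVA
#' includes a tumor-level error stratum (`Error(sample_id)`); the
#' interaction is then tested within tumor, which is algebraically a
#' comparison of the per-tumor deltas between the two models and is
#' calibrated under the null. `paired = FALSE` fits the plain
#' fixed-effects ANOVA on the long table instead; it ignores the pairing
#' and is markedly conservative when between-tumor variability dominates.
#'
#' @param summaries stacked [sample_bias()] rows covering exactly two
#'   host models, each with >= 2 samples.
#' @param statistic `"median"` or `"mean"` endpoint.
#' @param paired include the tumor-level error stratum (default `TRUE`).
#' @return List with `F`, `p.value`, `df` (numerator, denominator), and
#'   the long `table` used for the fit.
#' @export
interaction_test <- function(summaries, statistic = c("median", "mean"),
                             paired = TRUE) {
  statistic <- match.arg(statistic)
  models <- unique(summaries$host_model)
  if (length(models) != 2L) {
    stop("interaction test needs exactly two host models", call. = FALSE)
  }
  counts <- table(summaries$host_model)
  if (any(counts < 2L)) {
    stop(sprintf("host model '%s' has fewer than 2 samples",
                 names(counts)[which.min(counts)]), call. = FALSE)
  }
  long <- group_long_table(summaries, statistic)
  if (paired) {
    fit <- stats::aov(value ~ host_model * condition +
                        Error(factor(sample_id)), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
  } else {
    fit <- stats::aov(value ~ host_model * condition, data = long)
    tab <- summary(fit)[[1]]
  }
  row <- grep("host_model:condition", rownames(tab))
  list(F = tab[row, "F value"], p.value = tab[row, "Pr(>F)"],
       df = c(tab[row, "Df"], tab[nrow(tab), "Df"]), table = long)
}

# Long (sample, model, condition, value) table for the ANOVA and plots.
group_long_table <- function(summaries, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  obs <- summaries[[paste0("obs_", statistic)]]
  prd <- summaries[[paste0("null_", statistic)]]
  data.frame(
    sample_id = rep(summaries$sample_id, 2L),
    host_model = factor(rep(summaries$host_model, 2L)),
    treatment = rep(summaries$treatment, 2L),
    condition = factor(rep(c("observed", "predicted"),
                           each = nrow(summaries))),
    statistic = statistic,
    value = c(obs, prd)
  )
}

#' Group-level result: paired tests and optional interaction
#'
#' Runs [paired_observed_vs_predicted()] within each (treatment, host
#' model) group and, when exactly two host models are present, the
#' host-model [interaction_test()].
#'
#' @param summaries stacked [sample_bias()] rows.
#' @param statistic `"median"` or `"mean"` endpoint.
#' @return A list of class `group_result`: `statistic`, `paired` (one row
#'   per group: labels, n, mean delta, t, p), `interaction` (or `NULL`),
#'   `summaries`.
#' @export
group_result <- function(summaries, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  key <- interaction(summaries$treatment, summaries$host_model, drop = TRUE)
  paired <- do.call(rbind, lapply(levels(key), function(g) {
    sub <- summaries[key == g, , drop = FALSE]
    res <- paired_observed_vs_predicted(sub, statistic)
    data.frame(treatment = sub$treatment[1], host_model = sub$host_model[1],
               n = res$n, mean_delta = res$mean_delta, t = res$t,
               p.value = res$p.value, degenerate = res$degenerate)
  }))
  inter <- if (length(unique(summaries$host_model)) == 2L &&
               all(table(summaries$host_model) >= 2L)) {
    interaction_test(summaries, statistic)[c("F", "p.value", "df")]
  } else NULL
  structure(list(statistic = statistic, paired = paired,
                 interaction = inter, summaries = summaries),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> endpoint: %s distance\n", x$statistic))
  print(x$paired, row.names = FALSE)
  if (!is.null(x$interaction)) {
    cat(sprintf("host-model interaction: F(%d,%d) = %.3f, p = %.4g\n",
                x$interaction$df[1], x$interaction$df[2], x$interaction$F,
                x$interaction$p.value))
  }
  invisible(x)
}
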