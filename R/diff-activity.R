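#' Storey q-values from a vector of p-values
#'
#' Estimates the proportion of true nulls pi0 and converts p-values to
#' q-values: `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`,
#' capped at 1. With `pi0 = 1` the result equals Benjamini-Hochberg
#' adjusted p-values exactly.
#'
#' pi0 is estimated by the plateau rule `pi0 = #[p > lambda] / (m (1 -
#' lambda))` at a single `lambda` (default 0.5), or, with
#' `pi0_method = "smoother"`, by fitting a cubic smoothing spline to the
#' plateau estimates over `lambda_grid` and evaluating it at the largest
#' lambda. The estimate is clipped to (0, 1] and floored at `1/m` to avoid
#' degenerate all-zero q-values when every p-value is small.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param lambda Tuning parameter for the plateau estimate.
#' @param lambda_grid Grid for the smoother.
#' @param pi0_method `"fixed"` (plateau at `lambda`) or `"smoother"`.
#' @param pi0 Optional override; `pi0 = 1` reduces to BH.
#' @return Numeric q-values, same length and order as `p`.
#' @export
#' @examples
#' p <- c(0.001, 0.02, 0.5, 0.9)
#' storey_qvalues(p, pi0 = 1)  # identical to p.adjust(p, "BH")
storey_qvalues <- function(p, lambda = 0.5,
                           lambda_grid = seq(0.05, 0.9, by = 0.05),
                           pi0_method = c("fixed", "smoother"),
                           pi0 = NULL) {
  if (length(p) == 0) abort_parameter("`p` must be non-empty")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort_parameter("p-values must lie in [0, 1]")
  }
  pi0_method <- match.arg(pi0_method)
  m <- length(p)

  if (is.null(pi0)) {
    if (pi0_method == "fixed") {
      pi0 <- mean(p > lambda) / (1 - lambda)
    } else {
      est <- vapply(lambda_grid,
                    function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda_grid, est, df = 3)
      pi0 <- predict(fit, x = max(lambda_grid))$y
    }
    pi0 <- min(1, max(pi0, 1 / m))
  } else {
    check_scalar_number(pi0, "pi0", lower = 0, upper = 1)
  }

  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  attr(q, "pi0") <- pi0
  q
}

#' Differential activity of vOTUs across months
#'
#' Per-vOTU one-way ANOVA of (metatranscriptome) RPKM across months,
#' with eta-squared effect sizes, Storey q-values across all tested vOTUs,
#' Tukey-Kramer post hoc month pairs for vOTUs passing `q_max`, peak-month
#' assignment from month-mean z-scores, and an overall "seasonal" flag
#' requiring `q <= q_max` and `eta_squared > effect_min`. vOTUs with zero
#' variance across samples are excluded (reported via the `n_excluded`
#' attribute and `glance()`).
#'
#' @param rpkm_long Long tibble: votu_id, sample_id (or library_id), rpkm;
#'   typically restricted to vOTUs classified active.
#' @param samples Tibble mapping the id column to `month`; needs >= 2
#'   months with >= 2 samples each.
#' @param effect_min Minimum eta-squared for the seasonal flag (default
#'   0.3).
#' @param q_max Maximum q-value for the seasonal flag and for running the
#'   post hoc test (default 0.05).
#' @param log_transform Analyze `log10(rpkm + 1)` instead of raw RPKM.
#' @param hosts Optional tibble (votu_id, host_label, host_strategy) to
#'   carry host ecological strategies into the result.
#' @param pi0 Passed to [storey_qvalues()].
#' @return Tibble of class `virome_diffact`: votu_id, f_statistic,
#'   eta_squared, p_value, q_value, seasonal, peak_month, significant_pairs
#'   (list of tibbles month_a, month_b, p_adj), host_label, host_strategy.
#' @export
differential_activity <- function(rpkm_long, samples,
                                  effect_min = 0.3, q_max = 0.05,
                                  log_transform = FALSE,
                                  hosts = NULL, pi0 = NULL) {
  check_columns(rpkm_long, c("votu_id", "rpkm"), "rpkm_long")
  id_col <- intersect(c("sample_id", "library_id"), names(rpkm_long))[1]
  if (is.na(id_col) || !id_col %in% names(samples)) {
    abort_schema("rpkm_long and samples must share sample_id or library_id")
  }
  check_columns(samples, "month", "samples")
  month_of <- setNames(samples$month, samples[[id_col]])
  month_tab <- table(samples$month)
  if (length(month_tab) < 2 || any(month_tab < 2)) {
    abort_parameter("need >= 2 months with >= 2 samples each")
  }

  df <- rpkm_long |>
    mutate(month = unname(month_of[.data[[id_col]]]),
           value = if (log_transform) log10(.data$rpkm + 1) else .data$rpkm)
  if (anyNA(df$month)) abort_schema("sample(s) without month metadata")

  per_votu <- split(df[, c("value", "month")], df$votu_id)
  keep <- vapply(per_votu, function(x) sd(x$value) > 0, logical(1))
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    inform(sprintf("%d vOTU(s) with zero variance excluded", n_excluded))
  }
  per_votu <- per_votu[keep]
  if (length(per_votu) == 0) {
    abort_parameter("no vOTU with non-zero variance to test")
  }

  fits <- purrr::map(per_votu, function(x) {
    x$month <- factor(x$month)
    fit <- aov(value ~ month, data = x)
    a <- anova(fit)
    means <- tapply(x$value, x$month, mean)
    list(fit = fit,
         f = a[1, "F value"], p = a[1, "Pr(>F)"],
         eta = a[1, "Sum Sq"] / sum(a[, "Sum Sq"]),
         peak = names(means)[which.max(means)])
  })

  res <- tibble(
    votu_id = names(fits),
    f_statistic = unname(purrr::map_dbl(fits, "f")),
    eta_squared = unname(purrr::map_dbl(fits, "eta")),
    p_value = unname(purrr::map_dbl(fits, "p")))
  res$q_value <- storey_qvalues(res$p_value, pi0 = pi0)
  res$seasonal <- res$q_value <= q_max & res$eta_squared > effect_min
  res$peak_month <- ifelse(res$q_value <= q_max,
                           unname(purrr::map_chr(fits, "peak")),
                           NA_character_)

  res$significant_pairs <- purrr::map(seq_len(nrow(res)), function(i) {
    if (res$q_value[i] > q_max) return(NULL)
    tk <- TukeyHSD(fits[[res$votu_id[i]]]$fit, "month")$month
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    tibble(month_a = purrr::map_chr(pairs, 1),
           month_b = purrr::map_chr(pairs, 2),
           diff = tk[, "diff"], p_adj = tk[, "p adj"]) |>
      filter(.data$p_adj <= q_max)
  })

  if (!is.null(hosts)) {
    check_columns(hosts, c("votu_id", "host_strategy"), "hosts")
    res <- left_join(res, distinct(hosts, .data$votu_id,
                                   .keep_all = TRUE), by = "votu_id")
  }

  attr(res, "n_excluded") <- n_excluded
  attr(res, "effect_min") <- effect_min
  attr(res, "q_max") <- q_max
  class(res) <- c("virome_diffact", class(res))
  res
}

#' Month-mean z-score activity profiles grouped by host strategy
#'
#' Per vOTU: the month means of (metatranscriptome) RPKM, standardized
#' across months (`z = (mean_m - grand mean) / sd of month means`; all z =
#' 0 when the month means are constant). vOTUs without a host strategy are
#' routed to the `"unassigned"` group.
#'
#' @param rpkm_long Long tibble: votu_id, sample_id (or library_id), rpkm.
#' @param samples Tibble mapping the id column to `month`.
#' @param hosts Optional tibble (votu_id, host_strategy).
#' @return Tibble of class `virome_zscores`: votu_id, month, mean_rpkm, z,
#'   strategy.
#' @export
zscore_profiles <- function(rpkm_long, samples, hosts = NULL) {
  check_columns(rpkm_long, c("votu_id", "rpkm"), "rpkm_long")
  id_col <- intersect(c("sample_id", "library_id"), names(rpkm_long))[1]
  if (is.na(id_col) || !id_col %in% names(samples)) {
    abort_schema("rpkm_long and samples must share sample_id or library_id")
  }
  month_of <- setNames(samples$month, samples[[id_col]])

  out <- rpkm_long |>
    mutate(month = unname(month_of[.data[[id_col]]])) |>
    group_by(.data$votu_id, .data$month) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop_last") |>
    mutate(z = if (sd(.data$mean_rpkm) > 0)
      (.data$mean_rpkm - mean(.data$mean_rpkm)) / sd(.data$mean_rpkm)
      else 0) |>
    ungroup()

  strategy <- if (is.null(hosts)) {
    tibble(votu_id = unique(out$votu_id), strategy = "unassigned")
  } else {
    check_columns(hosts, c("votu_id", "host_strategy"), "hosts")
    tibble(votu_id = unique(out$votu_id)) |>
      left_join(distinct(hosts, .data$votu_id, .data$host_strategy),
                by = "votu_id") |>
      mutate(strategy = dplyr::coalesce(
        ifelse(.data$host_strategy %in% c("none", NA), NA_character_,
               .data$host_strategy), "unassigned")) |>
      select("votu_id", "strategy")
  }

  out <- left_join(out, strategy, by = "votu_id")
  class(out) <- c("virome_zscores", class(out))
  out
}
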