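#' Tidy a PERMANOVA result
#'
#' @param x A `virome_permanova` object.
#' @param ... Unused.
#' @return Tibble with one row per variance component (among, within,
#'   total): term, df, sum_of_squares, r_squared, statistic, p_value.
#' @method tidy virome_permanova
#' @export
tidy.virome_permanova <- function(x, ...) {
  tibble(term = c("among", "within", "total"),
         df = unname(x$df),
         sum_of_squares = unname(x$ss),
         r_squared = c(x$r_squared, 1 - x$r_squared, 1),
         statistic = c(x$statistic, NA_real_, NA_real_),
         p_value = c(x$p_value, NA_real_, NA_real_))
}

#' @rdname tidy.virome_permanova
#' @method glance virome_permanova
#' @export
glance.virome_permanova <- function(x, ...) {
  tibble(statistic = x$statistic, r_squared = x$r_squared,
         p_value = x$p_value, n = x$n, n_groups = x$k, n_perm = x$n_perm)
}

#' Tidy a differential-activity result
#'
#' @param x A `virome_diffact` tibble.
#' @param ... Unused.
#' @return A plain tibble without the list-column of post hoc pairs.
#' @method tidy virome_diffact
#' @export
tidy.virome_diffact <- function(x, ...) {
  out <- as_tibble(x)
  out$significant_pairs <- NULL
  out
}

#' @rdname tidy.virome_diffact
#' @method glance virome_diffact
#' @export
glance.virome_diffact <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_excluded = attr(x, "n_excluded") %||% 0L,
         n_seasonal = sum(x$seasonal),
         effect_min = attr(x, "effect_min"),
         q_max = attr(x, "q_max"),
         pi0 = attr(x$q_value, "pi0") %||% NA_real_)
}
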