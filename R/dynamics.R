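#' Season occupancy classes per vOTU
#'
#' From a long abundance table, classifies each vOTU as all-season core
#' (present, RPKM > 0, in at least one sample of every season) or
#' single-season specific (present only in samples of one season).
#'
#' @param rpkm_long Long tibble with votu_id, library_id (or sample_id),
#'   rpkm.
#' @param samples Tibble mapping the abundance columns to seasons: must
#'   contain `season` and the id column used in `rpkm_long`
#'   (`library_id` or `sample_id`).
#' @return Tibble: votu_id, n_seasons_present, core (logical),
#'   specific_season (label or NA).
#' @export
season_occupancy <- function(rpkm_long, samples) {
  check_columns(rpkm_long, c("votu_id", "rpkm"), "rpkm_long")
  id_col <- intersect(c("library_id", "sample_id"), names(rpkm_long))[1]
  if (is.na(id_col) || !id_col %in% names(samples)) {
    abort_schema("rpkm_long and samples must share library_id or sample_id")
  }
  check_columns(samples, "season", "samples")
  seasons <- unique(samples$season)
  if (length(seasons) == 0 || anyNA(samples$season)) {
    abort_parameter("every sample must have a season")
  }
  counts <- table(samples$season)
  if (any(counts == 0)) abort_parameter("a season has zero samples")

  joined <- rpkm_long |>
    inner_join(samples[, c(id_col, "season")], by = id_col)
  pres <- joined |>
    group_by(.data$votu_id, .data$season) |>
    summarise(present = any(.data$rpkm > 0), .groups = "drop") |>
    filter(.data$present)

  rpkm_long |>
    distinct(.data$votu_id) |>
    left_join(pres |>
                group_by(.data$votu_id) |>
                summarise(n_seasons_present = dplyr::n(),
                          specific_season = if (dplyr::n() == 1)
                            .data$season[1] else NA_character_,
                          .groups = "drop"),
              by = "votu_id") |>
    mutate(n_seasons_present = dplyr::coalesce(.data$n_seasons_present, 0L),
           core = .data$n_seasons_present == length(seasons),
           specific_season = ifelse(.data$n_seasons_present == 1,
                                    .data$specific_season, NA_character_)) |>
    select("votu_id", "n_seasons_present", "core", "specific_season")
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical vectors, 1 for disjoint
#' supports. Errors when both vectors are all zero (undefined).
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort_parameter("x and y must match in length")
  if (any(x < 0) || any(y < 0)) abort_parameter("abundances must be >= 0")
  s <- sum(x + y)
  if (s == 0) abort_parameter("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / s
}

#' Bray-Curtis distance matrix between samples
#'
#' Thin wrapper over `vegan::vegdist(method = "bray")` for a samples x
#' vOTU abundance matrix; all-zero samples are rejected first.
#'
#' @param mat Numeric matrix, samples as rows.
#' @return A `dist` object.
#' @export
bray_curtis_matrix <- function(mat) {
  if (any(rowSums(mat) == 0)) {
    abort_parameter("sample(s) with all-zero abundance")
  }
  vegan::vegdist(mat, method = "bray")
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components, forms the pseudo-F statistic, and obtains a
#' permutation p-value by freely permuting sample labels:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param groups Group labels, one per sample; at least two groups with at
#'   least two samples each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed making the permutations reproducible.
#' @return Object of class `virome_permanova` with elements statistic
#'   (pseudo-F), r_squared, p_value, df, ss, n_perm.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) abort_parameter("`groups` must match the matrix")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort_parameter("need >= 2 groups with >= 2 samples each")
  }
  set_seed_if(seed)

  D2 <- D^2
  k <- length(tab)
  sst <- sum(D2) / (2 * n)
  idx <- split(seq_len(n), groups)
  ssw_of <- function(ix_list) {
    s <- 0
    for (g in ix_list) s <- s + sum(D2[g, g]) / (2 * length(g))
    s
  }
  ssw <- ssw_of(idx)
  ssa <- sst - ssw
  f_obs <- (ssa / (k - 1)) / (ssw / (n - k))

  sizes <- lengths(idx)
  count_ge <- 0L
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    ix <- split(perm, rep.int(seq_along(sizes), sizes))
    ssw_p <- ssw_of(ix)
    f_p <- ((sst - ssw_p) / (k - 1)) / (ssw_p / (n - k))
    if (f_p >= f_obs) count_ge <- count_ge + 1L
  }
  p_value <- (1 + count_ge) / (1 + n_perm)

  structure(list(statistic = f_obs,
                 r_squared = ssa / sst,
                 p_value = p_value,
                 df = c(among = k - 1, within = n - k, total = n - 1),
                 ss = c(among = ssa, within = ssw, total = sst),
                 n_perm = n_perm, n = n, k = k),
            class = "virome_permanova")
}

#' @export
print.virome_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}
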