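#' Accumulate per-position strand-specific depth from read placements
#'
#' Counts, at every contig position, the number of placements covering it,
#' split by strand, per (contig, library). Placements falling outside the
#' contig bounds (or with start > end) are dropped with a warning reporting
#' the count; valid placements are counted toward `mapped_reads`.
#'
#' @param placements Tibble with columns read_id, contig_id, start, end,
#'   strand (`+`/`-`), library_id; coordinates 1-based inclusive.
#' @param contig_lengths Tibble with `contig_id` and `length`, or a named
#'   numeric vector.
#' @return Tibble of class `virome_coverage`: contig_id, library_id,
#'   mapped_reads, and list-columns `depth_plus`, `depth_minus` holding
#'   integer vectors of contig length.
#' @export
accumulate_coverage <- function(placements, contig_lengths) {
  check_columns(placements,
                c("contig_id", "start", "end", "strand", "library_id"),
                "placements")
  if (!is.data.frame(contig_lengths)) {
    contig_lengths <- tibble(contig_id = names(contig_lengths),
                             length = as.integer(unname(contig_lengths)))
  }
  check_columns(contig_lengths, c("contig_id", "length"), "contig_lengths")
  len_of <- setNames(as.integer(contig_lengths$length),
                     contig_lengths$contig_id)

  unknown <- setdiff(unique(placements$contig_id), names(len_of))
  if (length(unknown) > 0) {
    abort_schema(sprintf("placements reference contig(s) without a length: %s",
                         paste(head(unknown, 5), collapse = ", ")))
  }
  if (!all(placements$strand %in% c("+", "-"))) {
    abort_schema("placement strand must be '+' or '-'")
  }

  clen <- len_of[placements$contig_id]
  ok <- placements$start >= 1 & placements$end <= clen &
    placements$start <= placements$end
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warn(sprintf("dropped %d placement(s) outside contig bounds", n_bad))
    placements <- placements[ok, ]
  }

  key <- paste(placements$contig_id, placements$library_id, sep = "\r")
  groups <- split(seq_len(nrow(placements)), key)

  rows <- purrr::map(groups, function(idx) {
    cid <- placements$contig_id[idx[1]]
    lib <- placements$library_id[idx[1]]
    len <- len_of[[cid]]
    dp <- integer(len + 1L)
    dm <- integer(len + 1L)
    plus <- placements$strand[idx] == "+"
    s <- placements$start[idx]; e <- placements$end[idx]
    sp <- s[plus]; ep <- e[plus]
    sm <- s[!plus]; em <- e[!plus]
    if (length(sp) > 0) {
      tp <- tabulate(sp, nbins = len + 1L) - tabulate(ep + 1L, nbins = len + 1L)
      dp <- cumsum(tp)
    } else dp <- integer(len + 1L)
    if (length(sm) > 0) {
      tm <- tabulate(sm, nbins = len + 1L) - tabulate(em + 1L, nbins = len + 1L)
      dm <- cumsum(tm)
    } else dm <- integer(len + 1L)
    tibble(contig_id = cid, library_id = lib,
           mapped_reads = length(idx),
           depth_plus = list(as.integer(dp[seq_len(len)])),
           depth_minus = list(as.integer(dm[seq_len(len)])))
  })

  out <- bind_rows(rows)
  class(out) <- c("virome_coverage", class(out))
  out
}

#' Coverage breadth over an interval
#'
#' Percent of positions in `[start, end]` with depth >= `min_depth` under
#' the given strand mode (`both` sums the strands before thresholding).
#'
#' @param depth_plus,depth_minus Integer depth vectors (full contig).
#' @param start,end 1-based inclusive interval bounds; defaults span the
#'   contig.
#' @param mode `"plus"`, `"minus"`, or `"both"`.
#' @param min_depth Depth threshold (default 1).
#' @return Breadth percent in \[0, 100\].
#' @export
strand_breadth <- function(depth_plus, depth_minus = NULL,
                           start = 1L, end = length(depth_plus),
                           mode = c("both", "plus", "minus"),
                           min_depth = 1L) {
  mode <- match.arg(mode)
  if (end < start || start < 1 || end > length(depth_plus)) {
    abort_parameter("invalid interval")
  }
  v <- switch(mode,
              plus = depth_plus[start:end],
              minus = depth_minus[start:end],
              both = depth_plus[start:end] + depth_minus[start:end])
  100 * mean(v >= min_depth)
}

#' Lower-median depth over an interval
#'
#' The lower median (smaller of the two middle order statistics for even
#' interval lengths) of the per-position depth, computed over all positions
#' of the interval including uncovered ones.
#'
#' @inheritParams strand_breadth
#' @return Non-negative number.
#' @export
strand_median_depth <- function(depth_plus, depth_minus = NULL,
                                start = 1L, end = length(depth_plus),
                                mode = c("both", "plus", "minus")) {
  mode <- match.arg(mode)
  if (end < start || start < 1 || end > length(depth_plus)) {
    abort_parameter("invalid interval")
  }
  v <- switch(mode,
              plus = depth_plus[start:end],
              minus = depth_minus[start:end],
              both = depth_plus[start:end] + depth_minus[start:end])
  lower_median(v)
}

#' Reads per kilobase per million library reads, breadth-masked
#'
#' `RPKM = mapped_reads / (contig_len/1000) / (library_total/1e6)`, set to
#' 0 wherever the contig's coverage breadth is below `breadth_mask`
#' percent. Vectorized over its arguments.
#'
#' @param mapped_reads Read count(s) mapped to the contig.
#' @param contig_len Contig length(s) in bp.
#' @param library_total Total reads in the library (> 0); the library's
#'   sequencing depth, not the mapped-to-catalog count.
#' @param breadth_pct Coverage breadth percent used for masking.
#' @param breadth_mask Mask threshold (default 10%).
#' @return RPKM value(s), >= 0.
#' @export
#' @examples
#' rpkm(100, 10000, 1e6, breadth_pct = 50)  # 10
rpkm <- function(mapped_reads, contig_len, library_total, breadth_pct,
                 breadth_mask = 10) {
  if (any(library_total <= 0)) {
    abort_parameter("`library_total` must be positive")
  }
  val <- mapped_reads / (contig_len / 1000) / (library_total / 1e6)
  ifelse(breadth_pct < breadth_mask, 0, val)
}

#' Per-contig coverage summary across libraries
#'
#' Breadth (plus, minus, combined), lower-median combined depth and mapped
#' read counts for every (contig, library) with coverage.
#'
#' @param coverage A `virome_coverage` tibble from [accumulate_coverage()].
#' @return Tibble: contig_id, library_id, mapped_reads, breadth_plus,
#'   breadth_minus, breadth, median_depth.
#' @export
coverage_summary <- function(coverage) {
  coverage |>
    mutate(
      breadth_plus = purrr::map2_dbl(.data$depth_plus, .data$depth_minus,
                                     ~ strand_breadth(.x, .y, mode = "plus")),
      breadth_minus = purrr::map2_dbl(.data$depth_plus, .data$depth_minus,
                                      ~ strand_breadth(.x, .y, mode = "minus")),
      breadth = purrr::map2_dbl(.data$depth_plus, .data$depth_minus,
                                ~ strand_breadth(.x, .y, mode = "both")),
      median_depth = purrr::map2_dbl(.data$depth_plus, .data$depth_minus,
                                     ~ strand_median_depth(.x, .y,
                                                           mode = "both"))) |>
    select("contig_id", "library_id", "mapped_reads", "breadth_plus",
           "breadth_minus", "breadth", "median_depth") |>
    as_tibble()
}

#' Breadth-masked RPKM abundance table
#'
#' Builds the long vOTU x library RPKM table from accumulated coverage,
#' with RPKM set to 0 wherever combined-strand breadth is below the mask
#' (`breadth_mode = "plus"` masks on coding-strand breadth instead).
#' (contig, library) combinations without any coverage are included with
#' RPKM 0.
#'
#' @param coverage A `virome_coverage` tibble.
#' @param contig_lengths Tibble (`contig_id`, `length`) or named vector.
#' @param libraries Tibble with `library_id` and `total_reads` (and
#'   optionally type/month metadata carried through).
#' @param breadth_mask Mask threshold percent (default 10).
#' @param breadth_mode Breadth used for the mask: `"both"` (default) or
#'   `"plus"`.
#' @return Long tibble: votu_id, library_id, mapped_reads, breadth, rpkm.
#' @export
rpkm_matrix <- function(coverage, contig_lengths, libraries,
                        breadth_mask = 10,
                        breadth_mode = c("both", "plus")) {
  breadth_mode <- match.arg(breadth_mode)
  check_columns(libraries, c("library_id", "total_reads"), "libraries")
  if (!is.data.frame(contig_lengths)) {
    contig_lengths <- tibble(contig_id = names(contig_lengths),
                             length = as.integer(unname(contig_lengths)))
  }
  cs <- coverage_summary(coverage)
  b <- if (breadth_mode == "both") cs$breadth else cs$breadth_plus
  cs$mask_breadth <- b

  tidyr::expand_grid(votu_id = contig_lengths$contig_id,
                     library_id = libraries$library_id) |>
    left_join(cs, by = c(votu_id = "contig_id", "library_id")) |>
    left_join(contig_lengths, by = c(votu_id = "contig_id")) |>
    left_join(libraries[, c("library_id", "total_reads")],
              by = "library_id") |>
    mutate(mapped_reads = dplyr::coalesce(.data$mapped_reads, 0L),
           mask_breadth = dplyr::coalesce(.data$mask_breadth, 0),
           breadth = dplyr::coalesce(.data$breadth, 0),
           rpkm = ifelse(.data$total_reads > 0,
                         rpkm(.data$mapped_reads, .data$length,
                              pmax(.data$total_reads, 1),
                              .data$mask_breadth, breadth_mask),
                         0)) |>
    select("votu_id", "library_id", "mapped_reads", "breadth", "rpkm")
}

#' Pivot a long RPKM table to a vOTU x library matrix
#'
#' @param rpkm_long Output of [rpkm_matrix()].
#' @return Numeric matrix, rows = vOTUs, columns = libraries.
#' @export
rpkm_to_matrix <- function(rpkm_long) {
  wide <- tidyr::pivot_wider(rpkm_long[, c("votu_id", "library_id", "rpkm")],
                             names_from = "library_id",
                             values_from = "rpkm", values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$votu_id
  m
}
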