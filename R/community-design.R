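#' Build a months x depths x locations sampling design
#'
#' Defines the sample layout the synthetic community is observed through:
#' every (month, depth, location, replicate) cell yields exactly one sample
#' with one paired metagenome (`metaG`) and one metatranscriptome (`metaT`)
#' library. The defaults emulate a snow-dominated watershed campaign: four
#' sampling dates from peak snowpack through snowmelt, the plant growing
#' season, and autumn, at three discrete depth increments.
#'
#' @param months Character vector of month labels, in temporal order.
#' @param depths Character vector of depth-increment labels.
#' @param locations Character vector of location labels.
#' @param replicates Number of replicate cores per cell (>= 1).
#' @param library_size_mean Mean sequencing library size (reads per library).
#' @param library_size_dispersion Negative-binomial size parameter for
#'   library-size variation; `Inf` fixes all libraries at the mean.
#' @param seasons Named character vector mapping each month to a season.
#'
#' @return A list of class `virome_design` with tibbles `samples`
#'   (sample_id, month, season, depth, location, replicate) and `libraries`
#'   (library_id, sample_id, type, month, season, depth, location).
#'   Library sizes are drawn at placement-simulation time.
#' @export
#' @examples
#' design <- community_design(replicates = 1)
#' design$samples
community_design <- function(months = c("Mar", "May", "Jun", "Sep"),
                             depths = c("0-5cm", "5-15cm", "15cm+"),
                             locations = c("upslope", "downslope"),
                             replicates = 1,
                             library_size_mean = 1e5,
                             library_size_dispersion = 20,
                             seasons = c(Mar = "winter", May = "snowmelt",
                                         Jun = "summer", Sep = "autumn")) {
  if (length(months) < 1 || length(depths) < 1 || length(locations) < 1) {
    abort_parameter("`months`, `depths` and `locations` must be non-empty")
  }
  check_scalar_number(replicates, "replicates", lower = 1)
  check_scalar_number(library_size_mean, "library_size_mean", lower = 1)
  if (anyDuplicated(months)) abort_parameter("`months` must be unique")
  if (!all(months %in% names(seasons))) {
    abort_parameter("every month needs a season in `seasons`")
  }

  samples <- tidyr::expand_grid(month = months, depth = depths,
                                location = locations,
                                replicate = seq_len(replicates)) |>
    mutate(season = unname(seasons[.data$month]),
           sample_id = sprintf("S_%s_%s_%s_r%d", .data$month, .data$depth,
                               .data$location, .data$replicate)) |>
    select("sample_id", "month", "season", "depth", "location", "replicate")

  libraries <- tidyr::expand_grid(sample_id = samples$sample_id,
                                  type = c("metaG", "metaT")) |>
    left_join(samples, by = "sample_id") |>
    mutate(library_id = sprintf("%s_%s", .data$sample_id, .data$type)) |>
    select("library_id", "sample_id", "type", "month", "season",
           "depth", "location")

  structure(list(samples = samples, libraries = libraries,
                 months = months,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion),
            class = "virome_design")
}

#' @export
print.virome_design <- function(x, ...) {
  cat(sprintf("<virome_design> %d samples (%d months x %d depths x %d locations), %d libraries\n",
              nrow(x$samples), length(x$months),
              length(unique(x$samples$depth)),
              length(unique(x$samples$location)),
              nrow(x$libraries)))
  invisible(x)
}
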