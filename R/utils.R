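## Internal helpers: error signalling, seed handling, small validators.

abort_parameter <- function(msg, ...) {
  rlang::abort(msg, class = "soilvirome_error_parameter", ...)
}

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "soilvirome_error_schema", ...)
}

#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort_parameter(sprintf("`%s` must be a single number in [%s, %s]",
                            name, format(lower), format(upper)))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf("`%s` is missing column(s): %s",
                         name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

## Lower median: for even n the smaller of the two middle order statistics.
## Integer-valued on integer input and conservative at decision boundaries.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x, partial = (n + 1L) %/% 2L)[(n + 1L) %/% 2L]
}

## Activity status ordering used for month-level aggregation:
## absent < present-inactive/detected < active < active-lytic
status_rank <- function(status) {
  r <- c("absent" = 0L, "present-inactive" = 1L, "detected" = 1L,
         "active" = 2L, "active-lytic" = 3L)
  out <- unname(r[status])
  if (anyNA(out)) {
    abort_schema(sprintf("unknown activity status: %s",
                         paste(unique(status[is.na(out)]), collapse = ", ")))
  }
  out
}

rank_to_status <- function(rank, molecule) {
  dna <- c("absent", "present-inactive", "active", "active-lytic")
  rna <- c("absent", "detected", "active")
  ifelse(molecule == "ssRNA", rna[pmin(rank, 2L) + 1L], dna[rank + 1L])
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}
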