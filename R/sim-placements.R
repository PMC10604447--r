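## Read-placement simulation. Placements are the documented TSV dialect
## (read_id, contig_id, start, end, strand, library_id), a stand-in for
## short-read alignments after strand-protocol resolution.

tile_starts <- function(from, to, read_length) {
  if (to < from) return(integer(0))
  seq.int(from, to, by = read_length)
}

## Deterministic full-breadth tiling of an interval at ~`times`x depth.
tile_reads <- function(from, to, strand, times, read_length) {
  starts <- rep(tile_starts(from, to, read_length), times = max(1L, times))
  tibble(start = starts,
         end = pmin(starts + read_length - 1L, to),
         strand = strand)
}

## Random uniform reads inside an interval, clipped at the interval end.
uniform_reads <- function(from, to, strand, count, read_length) {
  if (count <= 0) return(tibble(start = integer(0), end = integer(0),
                                strand = character(0)))
  hi <- max(from, to - read_length + 1L)
  starts <- as.integer(floor(runif(count, from, hi + 1)))
  tibble(start = starts, end = pmin(starts + read_length - 1L, to),
         strand = strand)
}

nb_count <- function(n, mu, nb_size) {
  if (is.infinite(nb_size)) stats::rpois(n, mu) else
    rnbinom(n, mu = mu, size = nb_size)
}

#' Simulate strand-aware read placements from a planted truth
#'
#' Emits per-library read placements honouring the planted activity
#' schedule:
#' * metagenome (`metaG`) libraries carry reads on both strands across every
#'   DNA vOTU, irrespective of activity (the persistent seed-bank signal);
#'   ssRNA genomes leave no metagenome signal.
#' * metatranscriptome (`metaT`) libraries carry, for DNA vOTUs active in
#'   the sample's month, reads strictly on the coding strand of the
#'   scheduled expressed genes; inactive months emit nothing.
#' * ssRNA vOTUs scheduled `detected` emit coding(plus)-strand reads only;
#'   `active` months additionally emit minus-strand reads (replication
#'   intermediates) making up `neg_strand_fraction` of that vOTU's reads.
#'
#' With `noise = "none"` read counts are fixed at their means and reads are
#' tiled end-to-end, so every scheduled signal reaches 100% breadth and the
#' downstream classifiers recover the schedule exactly. With `noise = "nb"`
#' counts are negative-binomial (size `nb_size`) around abundance x library
#' size (metaG) or around `depth_per_active_gene` x interval length / read
#' length (metaT), and read starts are uniform.
#'
#' @param sim A `virome_genomes` object.
#' @param truth A `virome_truth` object over the same genomes.
#' @param design A `virome_design`; its months must equal the truth's.
#' @param depth_per_active_gene Mean per-position depth over an expressed
#'   gene (or over an ssRNA genome) in a metatranscriptome library.
#' @param viral_fraction Fraction of a metagenome library's reads drawn
#'   from the viral community (the rest is non-viral background counted
#'   only in the library totals).
#' @param noise `"nb"` (negative binomial) or `"none"` (deterministic).
#' @param nb_size Negative-binomial size (dispersion) parameter; `Inf`
#'   degrades to Poisson.
#' @param neg_strand_fraction Fraction of an active ssRNA vOTU's
#'   metatranscriptome reads on the minus strand (0-1, default 0.2:
#'   replication intermediates are minority species).
#' @param read_length Read length in bp (reads are clipped at interval
#'   ends).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#'
#' @return List of class `virome_placements`: `placements` tibble (read_id,
#'   contig_id, start, end, strand, library_id) and `libraries` tibble (the
#'   design's libraries with `total_reads` equal to the number of placement
#'   rows of that library).
#' @export
sim_placements <- function(sim, truth, design,
                           depth_per_active_gene = 20,
                           viral_fraction = 0.05,
                           noise = c("nb", "none"),
                           nb_size = 5,
                           neg_strand_fraction = 0.2,
                           read_length = 150,
                           seed = NULL) {
  stopifnot(inherits(sim, "virome_genomes"), inherits(truth, "virome_truth"),
            inherits(design, "virome_design"))
  noise <- match.arg(noise)
  check_scalar_number(neg_strand_fraction, "neg_strand_fraction", 0, 0.99)
  if (!setequal(truth$months, design$months)) {
    abort_schema("truth and design reference different months")
  }
  set_seed_if(seed)

  primary <- filter(sim$genomes, !.data$is_duplicate)
  len_of <- setNames(primary$length, primary$contig_id)
  genes <- sim$genes
  gene_of <- split(genes, genes$gene_id)
  votus <- truth$votus
  dna <- votus[votus$molecule == "DNA", ]
  rna <- votus[votus$molecule == "ssRNA", ]
  sched <- truth$schedule
  expr_by_month <- split(truth$expression, truth$expression$month)
  noiseless <- noise == "none"

  lib_sizes <- if (noiseless || is.infinite(design$library_size_dispersion)) {
    rep(design$library_size_mean, nrow(design$libraries))
  } else {
    pmax(1, rnbinom(nrow(design$libraries),
                    mu = design$library_size_mean,
                    size = design$library_size_dispersion))
  }

  per_library <- purrr::map(seq_len(nrow(design$libraries)), function(i) {
    lib <- design$libraries[i, ]
    L <- lib_sizes[i]
    out <- list()

    if (lib$type == "metaG") {
      if (nrow(dna) > 0) {
        share <- dna$baseline_abundance / sum(dna$baseline_abundance)
        mu <- share * L * viral_fraction
        counts <- if (noiseless) pmax(1, round(mu)) else
          nb_count(nrow(dna), mu, nb_size)
        out <- purrr::pmap(list(dna$votu_id, counts), function(id, cnt) {
          len <- len_of[[id]]
          if (noiseless) {
            bind_rows(tile_reads(1L, len, "+", 1L, read_length),
                      tile_reads(1L, len, "-", 1L, read_length))
          } else if (cnt > 0) {
            r <- uniform_reads(1L, len, "+", cnt, read_length)
            flip <- runif(nrow(r)) < 0.5
            r$strand[flip] <- "-"
            r
          } else NULL
        })
        names(out) <- dna$votu_id
      }
    } else {
      ## metatranscriptome
      month_expr <- expr_by_month[[lib$month]]
      if (!is.null(month_expr) && nrow(month_expr) > 0) {
        dna_out <- purrr::pmap(month_expr, function(votu_id, month, gene_id) {
          g <- gene_of[[gene_id]]
          glen <- g$end - g$start + 1L
          if (noiseless) {
            tile_reads(g$start, g$end, g$strand,
                       max(1L, as.integer(round(depth_per_active_gene))),
                       read_length)
          } else {
            cnt <- nb_count(1, depth_per_active_gene * glen / read_length,
                            nb_size)
            uniform_reads(g$start, g$end, g$strand, cnt, read_length)
          }
        })
        names(dna_out) <- month_expr$votu_id
        out <- c(out, dna_out)
      }

      if (nrow(rna) > 0) {
        st <- sched[sched$month == lib$month &
                      sched$votu_id %in% rna$votu_id, ]
        st <- st[st$status != "absent", ]
        if (nrow(st) > 0) {
          rna_out <- purrr::pmap(st[, c("votu_id", "status")],
                                 function(votu_id, status) {
            len <- len_of[[votu_id]]
            times <- max(1L, as.integer(round(depth_per_active_gene)))
            minus_ratio <- neg_strand_fraction / (1 - neg_strand_fraction)
            if (noiseless) {
              plus <- tile_reads(1L, len, "+", times, read_length)
              if (status == "active") {
                bind_rows(plus, tile_reads(1L, len, "-",
                                           max(1L, round(times * minus_ratio)),
                                           read_length))
              } else plus
            } else {
              mu_plus <- depth_per_active_gene * len / read_length
              plus <- uniform_reads(1L, len, "+",
                                    nb_count(1, mu_plus, nb_size), read_length)
              if (status == "active") {
                minus <- uniform_reads(1L, len, "-",
                                       nb_count(1, mu_plus * minus_ratio,
                                                nb_size), read_length)
                bind_rows(plus, minus)
              } else plus
            }
          })
          names(rna_out) <- st$votu_id
          out <- c(out, rna_out)
        }
      }
    }

    out <- purrr::compact(out)
    if (length(out) == 0) return(NULL)
    df <- bind_rows(out, .id = "contig_id")
    df$library_id <- lib$library_id
    df
  })

  placements <- bind_rows(purrr::compact(per_library)) |>
    group_by(.data$library_id) |>
    mutate(read_id = sprintf("%s_r%06d", .data$library_id, row_number())) |>
    ungroup() |>
    select("read_id", "contig_id", "start", "end", "strand", "library_id")

  ## Library totals: mapped viral reads (= placement rows) plus simulated
  ## unmapped background making up the non-viral majority of a soil
  ## library, so per-million normalization stays month-stable as it does
  ## when viral reads are a small fraction of sequencing depth.
  totals <- placements |>
    dplyr::count(.data$library_id, name = "mapped_reads")
  libraries <- design$libraries |>
    left_join(totals, by = "library_id") |>
    mutate(mapped_reads = dplyr::coalesce(.data$mapped_reads, 0L),
           target = lib_sizes,
           unmapped_reads = pmax(0L, as.integer(.data$target) -
                                   .data$mapped_reads),
           total_reads = .data$mapped_reads + .data$unmapped_reads) |>
    select(-"target")

  structure(list(placements = placements, libraries = libraries),
            class = "virome_placements")
}

#' Simulate a metatranscriptome abundance matrix directly from a truth
#'
#' A matrix-level shortcut past read placement: per-vOTU per-library
#' negative-binomial read counts around abundance x library size, scaled by
#' the planted activity schedule, converted to RPKM. Active months of a
#' seasonal vOTU get the full signal, all other months zero; constitutively
#' active vOTUs get a month-independent mean. Intended for statistical
#' power/recovery studies of the differential-activity procedure at
#' community sizes where per-read simulation is unnecessary.
#'
#' @param sim,truth,design As for [sim_placements()].
#' @param mean_reads_active Mean mapped reads for an active vOTU-library at
#'   baseline abundance 1/n.
#' @param nb_size Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return Long tibble: votu_id, library_id, sample_id, month, rpkm.
#' @export
sim_expression_matrix <- function(sim, truth, design,
                                  mean_reads_active = 400,
                                  nb_size = 5,
                                  seed = NULL) {
  stopifnot(inherits(truth, "virome_truth"), inherits(design, "virome_design"))
  set_seed_if(seed)
  primary <- filter(sim$genomes, !.data$is_duplicate)
  len_of <- setNames(primary$length, primary$contig_id)
  metat <- filter(design$libraries, .data$type == "metaT")
  n_votu <- nrow(truth$votus)

  grid <- tidyr::expand_grid(votu_id = truth$votus$votu_id,
                             library_id = metat$library_id) |>
    left_join(metat[, c("library_id", "sample_id", "month")],
              by = "library_id") |>
    left_join(truth$schedule, by = c("votu_id", "month")) |>
    left_join(truth$votus[, c("votu_id", "baseline_abundance")],
              by = "votu_id") |>
    mutate(active = .data$status %in% c("active", "active-lytic", "detected"),
           mu = ifelse(.data$active,
                       .data$baseline_abundance * n_votu * mean_reads_active,
                       0))
  grid$reads <- ifelse(grid$mu > 0, nb_count(nrow(grid), grid$mu, nb_size), 0L)
  grid |>
    mutate(length = unname(len_of[.data$votu_id]),
           rpkm = .data$reads / (.data$length / 1000) /
             (design$library_size_mean / 1e6)) |>
    select("votu_id", "library_id", "sample_id", "month", "rpkm")
}
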