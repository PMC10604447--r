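#' Call expressed genes from metatranscriptome strand coverage
#'
#' A gene is expressed in a library when its coding strand has at least
#' `gene_breadth` percent of positions covered (>= 1x) and a positive
#' lower-median depth over the gene interval. Breadth and median are
#' computed on the gene's coding strand only; coverage on the opposite
#' strand never makes a gene expressed. Gene/library combinations without
#' any coverage are reported with breadth 0.
#'
#' @param coverage A `virome_coverage` tibble, typically restricted to
#'   metatranscriptome libraries (pass `libraries` to enforce this).
#' @param genes Tibble: gene_id, contig_id, start, end, strand.
#' @param libraries Optional libraries tibble with `library_id` and `type`;
#'   when given, only `metaT` libraries are evaluated.
#' @param gene_breadth Coding-strand breadth threshold percent (default 50).
#' @return Tibble: gene_id, contig_id, library_id, coding_breadth,
#'   coding_median_depth, expressed.
#' @export
call_expressed_genes <- function(coverage, genes, libraries = NULL,
                                 gene_breadth = 50) {
  check_columns(genes, c("gene_id", "contig_id", "start", "end", "strand"),
                "genes")
  cov <- coverage
  if (!is.null(libraries)) {
    metat <- libraries$library_id[libraries$type == "metaT"]
    cov <- filter(cov, .data$library_id %in% metat)
  }
  lib_ids <- unique(cov$library_id)
  if (length(lib_ids) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(0), contig_id = character(0),
                  library_id = character(0), coding_breadth = numeric(0),
                  coding_median_depth = numeric(0), expressed = logical(0)))
  }

  genes_by_contig <- split(seq_len(nrow(genes)), genes$contig_id)

  ## evaluate genes only where coverage exists; everything else is breadth 0
  covered <- purrr::map(seq_len(nrow(cov)), function(i) {
    cid <- cov$contig_id[i]
    gi <- genes_by_contig[[cid]]
    if (is.null(gi)) return(NULL)
    dp <- cov$depth_plus[[i]]; dm <- cov$depth_minus[[i]]
    ng <- length(gi)
    b <- numeric(ng); md <- numeric(ng)
    for (j in seq_len(ng)) {
      g <- gi[j]
      s <- genes$start[g]; e <- genes$end[g]
      if (s < 1 || e > length(dp)) {
        abort_schema(sprintf("gene %s outside contig %s bounds",
                             genes$gene_id[g], cid))
      }
      v <- if (genes$strand[g] == "+") dp[s:e] else dm[s:e]
      b[j] <- 100 * mean(v >= 1L)
      md[j] <- lower_median(v)
    }
    tibble(gene_id = genes$gene_id[gi], contig_id = cid,
           library_id = cov$library_id[i],
           coding_breadth = b, coding_median_depth = md)
  })
  covered <- bind_rows(purrr::compact(covered))

  tidyr::expand_grid(gene_idx = seq_len(nrow(genes)),
                     library_id = lib_ids) |>
    mutate(gene_id = genes$gene_id[.data$gene_idx],
           contig_id = genes$contig_id[.data$gene_idx]) |>
    select(-"gene_idx") |>
    left_join(covered, by = c("gene_id", "contig_id", "library_id")) |>
    mutate(coding_breadth = dplyr::coalesce(.data$coding_breadth, 0),
           coding_median_depth = dplyr::coalesce(.data$coding_median_depth, 0),
           expressed = .data$coding_breadth >= gene_breadth &
             .data$coding_median_depth > 0) |>
    select("gene_id", "contig_id", "library_id", "coding_breadth",
           "coding_median_depth", "expressed")
}

#' Classify DNA vOTU activity per sample
#'
#' Applies the expressed-gene decision framework per sample: a vOTU with at
#' least one expressed gene in the sample's metatranscriptome is `active`,
#' and `active-lytic` if any expressed gene belongs to the lytic category
#' set (virion structure, encapsidation, lysis). With no expressed gene,
#' the vOTU is `present-inactive` when its metagenome combined-strand
#' breadth reaches `presence_breadth` percent in the sample's metagenome
#' library, and `absent` otherwise. Expression takes precedence over the
#' presence test: transcription implies presence. Samples without a
#' metagenome library fall back to the expression evidence alone.
#'
#' @param expressed_calls Output of [call_expressed_genes()].
#' @param coverage `virome_coverage` for the metagenome libraries.
#' @param votus Tibble with `votu_id` (representative contig ids) and
#'   optionally `molecule`; only DNA vOTUs should be passed.
#' @param genes Tibble with gene_id and `category`.
#' @param libraries Libraries tibble (library_id, sample_id, type).
#' @param samples Samples tibble (sample_id, month).
#' @param lytic_categories Category labels counted as lytic.
#' @param presence_breadth Metagenome breadth threshold percent for
#'   presence (default 10, matching the RPKM mask).
#' @return Tibble: votu_id, sample_id, molecule, status, n_expressed,
#'   n_lytic.
#' @export
classify_dna_activity <- function(expressed_calls, coverage, votus, genes,
                                  libraries, samples,
                                  lytic_categories = LYTIC_CATEGORIES,
                                  presence_breadth = 10) {
  check_columns(genes, c("gene_id", "category"), "genes")
  check_columns(libraries, c("library_id", "sample_id", "type"), "libraries")
  if (length(lytic_categories) == 0) {
    abort_parameter("`lytic_categories` must be non-empty")
  }
  unknown_cat <- setdiff(unique(genes$category),
                         c(GENE_CATEGORIES, lytic_categories))
  if (length(unknown_cat) > 0) {
    warn(sprintf("unknown gene categor%s treated as non-lytic: %s",
                 if (length(unknown_cat) > 1) "ies" else "y",
                 paste(unknown_cat, collapse = ", ")))
  }

  ids <- votus$votu_id
  lib_sample <- setNames(libraries$sample_id, libraries$library_id)

  expr <- expressed_calls |>
    filter(.data$expressed, .data$contig_id %in% ids) |>
    left_join(genes[, c("gene_id", "category")], by = "gene_id") |>
    mutate(sample_id = unname(lib_sample[.data$library_id])) |>
    group_by(votu_id = .data$contig_id, .data$sample_id) |>
    summarise(n_expressed = dplyr::n_distinct(.data$gene_id),
              n_lytic = dplyr::n_distinct(
                .data$gene_id[.data$category %in% lytic_categories]),
              .groups = "drop")

  metag <- libraries[libraries$type == "metaG", ]
  presence <- coverage |>
    filter(.data$library_id %in% metag$library_id,
           .data$contig_id %in% ids) |>
    coverage_summary() |>
    mutate(sample_id = unname(lib_sample[.data$library_id])) |>
    group_by(votu_id = .data$contig_id, .data$sample_id) |>
    summarise(present = any(.data$breadth >= presence_breadth),
              .groups = "drop")

  tidyr::expand_grid(votu_id = ids, sample_id = samples$sample_id) |>
    left_join(expr, by = c("votu_id", "sample_id")) |>
    left_join(presence, by = c("votu_id", "sample_id")) |>
    mutate(n_expressed = dplyr::coalesce(.data$n_expressed, 0L),
           n_lytic = dplyr::coalesce(.data$n_lytic, 0L),
           present = dplyr::coalesce(.data$present, FALSE),
           molecule = "DNA",
           status = dplyr::case_when(
             .data$n_lytic >= 1 ~ "active-lytic",
             .data$n_expressed >= 1 ~ "active",
             .data$present ~ "present-inactive",
             TRUE ~ "absent")) |>
    select("votu_id", "sample_id", "molecule", "status",
           "n_expressed", "n_lytic")
}

#' Classify ssRNA vOTU activity per sample
#'
#' Strand-specific decision rule for positive-sense ssRNA genomes: a vOTU
#' is `detected` in a sample when the coding strand of its genome is
#' covered over at least `rna_breadth` percent of positions at >= 1x with a
#' positive lower-median depth, and `active` (replicating) when the
#' antisense strand is additionally covered over at least `rna_breadth`
#' percent at >= 1x — antisense coverage is the signature of the
#' complementary replication intermediate. The antisense test is
#' breadth-only; the median-depth clause applies to the coding strand.
#'
#' @param coverage `virome_coverage` over metatranscriptome libraries.
#' @param votus Tibble with `votu_id` for the ssRNA representatives and
#'   optionally `coding_strand` (default `+`).
#' @param libraries,samples As in [classify_dna_activity()].
#' @param rna_breadth Breadth threshold percent (default 50).
#' @return Tibble: votu_id, sample_id, molecule, status.
#' @export
classify_rna_activity <- function(coverage, votus, libraries, samples,
                                  rna_breadth = 50) {
  ids <- votus$votu_id
  coding <- if ("coding_strand" %in% names(votus)) {
    setNames(votus$coding_strand, votus$votu_id)
  } else {
    setNames(rep("+", length(ids)), ids)
  }
  metat <- libraries[libraries$type == "metaT", ]
  lib_sample <- setNames(libraries$sample_id, libraries$library_id)

  obs <- coverage |>
    filter(.data$library_id %in% metat$library_id,
           .data$contig_id %in% ids)
  calls <- if (nrow(obs) == 0) {
    tibble(votu_id = character(0), sample_id = character(0),
           rank = integer(0))
  } else {
    purrr::pmap(obs, function(contig_id, library_id, mapped_reads,
                              depth_plus, depth_minus, ...) {
      cs <- coding[[contig_id]]
      sense_mode <- if (cs == "+") "plus" else "minus"
      anti_mode <- if (cs == "+") "minus" else "plus"
      b_sense <- strand_breadth(depth_plus, depth_minus, mode = sense_mode)
      md_sense <- strand_median_depth(depth_plus, depth_minus,
                                      mode = sense_mode)
      b_anti <- strand_breadth(depth_plus, depth_minus, mode = anti_mode)
      detected <- b_sense >= rna_breadth && md_sense > 0
      tibble(votu_id = contig_id,
             sample_id = unname(lib_sample[[library_id]]),
             rank = if (detected && b_anti >= rna_breadth) 2L
                    else if (detected) 1L else 0L)
    }) |> bind_rows()
  }

  best <- if (nrow(calls) == 0) calls else
    calls |>
      group_by(.data$votu_id, .data$sample_id) |>
      summarise(rank = max(.data$rank), .groups = "drop")
  tidyr::expand_grid(votu_id = ids, sample_id = samples$sample_id) |>
    left_join(best, by = c("votu_id", "sample_id")) |>
    mutate(rank = dplyr::coalesce(.data$rank, 0L),
           molecule = "ssRNA",
           status = c("absent", "detected", "active")[.data$rank + 1L]) |>
    select("votu_id", "sample_id", "molecule", "status")
}

#' Aggregate per-sample activity calls to months
#'
#' A vOTU's month status is the maximum of its per-sample statuses under
#' the ordering absent < present-inactive/detected < active < active-lytic
#' — i.e. a vOTU is active in a month when it is active in at least one of
#' that month's samples.
#'
#' @param calls Per-sample calls with columns votu_id, sample_id, molecule,
#'   status (DNA and RNA calls may be mixed).
#' @param samples Samples tibble mapping sample_id to month.
#' @return Tibble: votu_id, month, molecule, status.
#' @export
aggregate_by_month <- function(calls, samples) {
  check_columns(calls, c("votu_id", "sample_id", "molecule", "status"),
                "calls")
  check_columns(samples, c("sample_id", "month"), "samples")
  missing <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(missing) > 0) {
    abort_schema(sprintf("sample(s) without month metadata: %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  calls |>
    left_join(samples[, c("sample_id", "month")], by = "sample_id") |>
    mutate(rank = status_rank(.data$status)) |>
    group_by(.data$votu_id, .data$month, .data$molecule) |>
    summarise(rank = max(.data$rank), .groups = "drop") |>
    mutate(status = rank_to_status(.data$rank, .data$molecule)) |>
    select("votu_id", "month", "molecule", "status")
}
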