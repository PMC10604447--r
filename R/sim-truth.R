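LYTIC_CATEGORIES <- c("virion-structure", "encapsidation", "lysis")
HOST_STRATEGIES <- c("winter-adapted", "snowmelt-specialist",
                     "spring-adapted", "none")

#' Plant a ground-truth activity schedule over a simulated community
#'
#' Emulates a seed-bank viral community: all DNA vOTUs persist in
#' metagenomes year-round, a majority-but-not-all subset is transcriptionally
#' active in every month, a small seasonal subset (default 5%, mirroring the
#' scale of differential fractions reported for soil phage communities) is
#' active only in one peak month, and the remainder never transcribes.
#' Active months of "lytic" vOTUs always include at least one expressed gene
#' from the lytic category set (virion structure, encapsidation, lysis);
#' active months of non-lytic vOTUs express only non-lytic genes. ssRNA
#' vOTUs get month statuses absent / detected / active; "active" months
#' imply minus-strand replication intermediates at simulation time.
#'
#' Duplicate contigs planted by [sim_genomes()] carry no truth of their own:
#' the schedule is defined per vOTU, i.e. per primary genome.
#'
#' @param sim A `virome_genomes` object from [sim_genomes()].
#' @param months Month labels; must match the sampling design.
#' @param active_fraction Fraction of DNA vOTUs active in at least one month
#'   (includes the seasonal subset).
#' @param seasonal_fraction Fraction of DNA vOTUs with a single-month
#'   activity peak.
#' @param lytic_fraction Fraction of active DNA vOTUs undergoing lytic
#'   infection when active.
#' @param strategy_fraction Fraction of seasonal vOTUs whose host has a
#'   recognized ecological strategy (peak-month matched).
#' @param expressed_genes_per_month Target number of expressed genes per
#'   active vOTU-month (capped by the gene complement).
#' @param rna_status_probs Probabilities of absent / detected / active for
#'   each ssRNA vOTU-month.
#' @param seed Integer seed.
#'
#' @return List of class `virome_truth`: `votus` tibble (votu_id, molecule,
#'   baseline_abundance, lytic, seasonal, peak_month, host_label,
#'   host_strategy), `schedule` tibble (votu_id, month, status), and
#'   `expression` tibble (votu_id, month, gene_id).
#' @export
sim_truth <- function(sim,
                      months = c("Mar", "May", "Jun", "Sep"),
                      active_fraction = 0.7,
                      seasonal_fraction = 0.05,
                      lytic_fraction = 0.2,
                      strategy_fraction = 0.4,
                      expressed_genes_per_month = 3,
                      rna_status_probs = c(absent = 0.45, detected = 0.35,
                                           active = 0.20),
                      seed = NULL) {
  stopifnot(inherits(sim, "virome_genomes"))
  check_scalar_number(active_fraction, "active_fraction", 0, 1)
  check_scalar_number(seasonal_fraction, "seasonal_fraction", 0, active_fraction)
  check_scalar_number(lytic_fraction, "lytic_fraction", 0, 1)
  set_seed_if(seed)

  primary <- filter(sim$genomes, !.data$is_duplicate)
  genes <- sim$genes
  month_strategy <- c(Mar = "winter-adapted", May = "snowmelt-specialist",
                      Jun = "spring-adapted")

  dna_ids <- primary$contig_id[primary$molecule == "DNA"]
  rna_ids <- primary$contig_id[primary$molecule == "ssRNA"]

  n_dna <- length(dna_ids)
  n_seasonal <- as.integer(round(n_dna * seasonal_fraction))
  n_active <- max(as.integer(round(n_dna * active_fraction)), n_seasonal)
  shuffled <- sample(dna_ids)
  seasonal_ids <- head(shuffled, n_seasonal)
  constitutive_ids <- head(tail(shuffled, n_dna - n_seasonal),
                           n_active - n_seasonal)
  active_ids <- c(seasonal_ids, constitutive_ids)

  ## lytic status is only meaningful where a lytic-category gene exists
  has_lytic <- genes |>
    group_by(.data$contig_id) |>
    summarise(has = any(.data$category %in% LYTIC_CATEGORIES)) |>
    (\(d) setNames(d$has, d$contig_id))()
  has_nonlytic <- genes |>
    group_by(.data$contig_id) |>
    summarise(has = any(!.data$category %in% LYTIC_CATEGORIES)) |>
    (\(d) setNames(d$has, d$contig_id))()

  lytic <- setNames(rep(FALSE, n_dna), dna_ids)
  candidates <- active_ids[has_lytic[active_ids]]
  n_lytic <- min(length(candidates),
                 as.integer(round(length(active_ids) * lytic_fraction)))
  lytic[sample(candidates, n_lytic)] <- TRUE
  ## active vOTUs with only lytic-category genes cannot express a clean
  ## non-lytic set; they are necessarily lytic
  lytic[active_ids[!has_nonlytic[active_ids]]] <- TRUE

  peak_month <- setNames(rep(NA_character_, n_dna), dna_ids)
  peak_month[seasonal_ids] <- sample(months, n_seasonal, replace = TRUE)

  host_label <- setNames(sprintf("host_%02d", sample(12, n_dna, TRUE)), dna_ids)
  host_strategy <- setNames(rep("none", n_dna), dna_ids)
  with_strategy <- seasonal_ids[runif(n_seasonal) < strategy_fraction]
  host_strategy[with_strategy] <-
    dplyr::coalesce(month_strategy[peak_month[with_strategy]], "none")

  dna_schedule <- tidyr::expand_grid(votu_id = dna_ids, month = months) |>
    mutate(status = dplyr::case_when(
      .data$votu_id %in% seasonal_ids &
        .data$month == peak_month[.data$votu_id] &
        lytic[.data$votu_id] ~ "active-lytic",
      .data$votu_id %in% seasonal_ids &
        .data$month == peak_month[.data$votu_id] ~ "active",
      .data$votu_id %in% seasonal_ids ~ "inactive",
      .data$votu_id %in% constitutive_ids & lytic[.data$votu_id] ~ "active-lytic",
      .data$votu_id %in% constitutive_ids ~ "active",
      TRUE ~ "inactive"))

  ## expressed gene sets: drawn once per vOTU and reused in every active
  ## month, so constitutively active vOTUs carry a stable (non-seasonal)
  ## expression signal; only the schedule itself makes a vOTU seasonal
  gene_split <- split(genes, genes$contig_id)
  pick_genes <- function(votu_id) {
    g <- gene_split[[votu_id]]
    lyt <- g$gene_id[g$category %in% LYTIC_CATEGORIES]
    non <- g$gene_id[!g$category %in% LYTIC_CATEGORIES]
    k <- min(expressed_genes_per_month, nrow(g))
    if (lytic[[votu_id]]) {
      picked <- sample(lyt, 1)
      pool <- setdiff(g$gene_id, picked)
      if (k > 1 && length(pool) > 0) {
        picked <- c(picked, sample(pool, min(k - 1, length(pool))))
      }
      picked
    } else {
      sample(non, min(k, length(non)))
    }
  }
  gene_sets <- purrr::map(setNames(active_ids, active_ids), pick_genes)
  expression <- dna_schedule |>
    filter(.data$status %in% c("active", "active-lytic")) |>
    (\(d) tibble(votu_id = rep(d$votu_id, lengths(gene_sets[d$votu_id])),
                 month = rep(d$month, lengths(gene_sets[d$votu_id])),
                 gene_id = unlist(gene_sets[d$votu_id],
                                  use.names = FALSE)))()

  rna_schedule <- tidyr::expand_grid(votu_id = rna_ids, month = months) |>
    mutate(status = sample(names(rna_status_probs),
                           dplyr::n(), replace = TRUE,
                           prob = rna_status_probs))

  votus <- tibble(
    votu_id = c(dna_ids, rna_ids),
    molecule = c(rep("DNA", n_dna), rep("ssRNA", length(rna_ids))),
    baseline_abundance = rlnorm(n_dna + length(rna_ids), 0, 0.8),
    lytic = c(unname(lytic), rep(FALSE, length(rna_ids))),
    seasonal = c(dna_ids %in% seasonal_ids, rep(FALSE, length(rna_ids))),
    peak_month = c(unname(peak_month), rep(NA_character_, length(rna_ids))),
    host_label = c(unname(host_label), rep(NA_character_, length(rna_ids))),
    host_strategy = c(unname(host_strategy), rep(NA_character_, length(rna_ids)))) |>
    mutate(baseline_abundance = .data$baseline_abundance /
             sum(.data$baseline_abundance))

  structure(list(votus = votus,
                 schedule = bind_rows(dna_schedule, rna_schedule),
                 expression = expression,
                 months = months),
            class = "virome_truth")
}

#' @export
print.virome_truth <- function(x, ...) {
  cat(sprintf("<virome_truth> %d vOTUs (%d seasonal, %d lytic), %d months\n",
              nrow(x$votus), sum(x$votus$seasonal), sum(x$votus$lytic),
              length(x$months)))
  invisible(x)
}
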