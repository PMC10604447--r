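PIPELINE_STAGES <- c("simulate", "cluster", "coverage", "activity",
                     "annotate-tree", "stats")

#' Build a pipeline configuration
#'
#' Assembles the full configuration for the synthetic-community analysis
#' pipeline: simulation scale, sampling design, and every decision
#' threshold of the analysis stages. Defaults are the study values
#' (retention at 5 kbp / 50% completeness, clustering at 95% ANI / 85% AF,
#' 10% RPKM breadth mask, 50% gene and ssRNA breadth, support collapse at
#' 50, effect size > 0.3 at q <= 0.05, UniFrac alpha 0.5). Any entry can be
#' overridden through `...` using `section$name` syntax, e.g.
#' `pipeline_config(out_dir, thresholds = list(ani = 97))` merges into the
#' defaults.
#'
#' @param out_dir Directory that receives all stage outputs.
#' @param seed Master seed; all stage randomness derives from it.
#' @param ... Named lists merged over the default sections `sim`, `design`,
#'   `tree`, `thresholds`, or scalar fields (`stranded_protocol`).
#' @return A list of class `virome_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stranded_protocol = "rf",
    sim = list(n_votus = 40, length_range = c(5000, 20000),
               gene_density = 1, rna_fraction = 0.3,
               duplicate_fraction = 0.15,
               active_fraction = 0.7, seasonal_fraction = 0.05,
               lytic_fraction = 0.2,
               depth_per_active_gene = 20, noise = "nb", nb_size = 5,
               neg_strand_fraction = 0.2, read_length = 150),
    design = list(months = c("Mar", "May", "Jun", "Sep"),
                  depths = c("0-5cm", "5-15cm", "15cm+"),
                  locations = c("upslope", "downslope"),
                  replicates = 1,
                  library_size_mean = 1e5,
                  library_size_dispersion = 20),
    tree = list(n_clades = 6, tips_per_clade = c(3, 8),
                ref_fraction = 0.5, low_support_fraction = 0.1),
    thresholds = list(min_len = 5000, min_completeness = 50,
                      ani = 95, af = 85, breadth_mask = 10,
                      gene_breadth = 50, rna_breadth = 50,
                      support_collapse = 50,
                      effect_min = 0.3, q_max = 0.05,
                      unifrac_alpha = 0.5))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "virome_config")
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  for (nm in c("ani", "af", "breadth_mask", "gene_breadth", "rna_breadth",
               "support_collapse", "min_completeness")) {
    check_scalar_number(th[[nm]], paste0("thresholds$", nm), 0, 100)
  }
  check_scalar_number(th$effect_min, "thresholds$effect_min", 0, 1)
  check_scalar_number(th$q_max, "thresholds$q_max", 0, 1)
  check_scalar_number(th$unifrac_alpha, "thresholds$unifrac_alpha", 0, 1)
  check_scalar_number(th$min_len, "thresholds$min_len", 0, Inf)
  if (!cfg$stranded_protocol %in% c("rf", "fr", "unstranded")) {
    abort_parameter("stranded_protocol must be rf, fr or unstranded")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return A `virome_config` (reader) or `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out_dir <- raw$out_dir %||% "."
  seed <- raw$seed %||% 1
  raw$out_dir <- NULL; raw$seed <- NULL
  do.call(pipeline_config, c(list(out_dir = out_dir, seed = seed), raw))
}

#' @rdname read_pipeline_config
#' @param config A `virome_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_input <- function(path, stage) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("stage '%s' needs missing input: %s", stage, path),
                 class = "soilvirome_error_missing_input")
  }
  path
}

## Atomic, all-or-nothing output commit: writers run against .tmp paths,
## everything is renamed into place only after all writers succeeded.
commit_outputs <- function(writers, paths) {
  tmp <- paste0(paths, ".tmp")
  on_fail <- function(e) {
    unlink(tmp[file.exists(tmp)])
    rlang::abort(sprintf("stage failed, partial outputs removed: %s",
                         conditionMessage(e)), parent = e)
  }
  tryCatch({
    for (i in seq_along(writers)) writers[[i]](tmp[i])
    for (i in seq_along(paths)) {
      if (!file.rename(tmp[i], paths[i])) stop("rename failed: ", paths[i])
    }
  }, error = on_fail)
  invisible(paths)
}

write_provenance <- function(cfg, stage, inputs, outputs) {
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  prov <- list(
    stage = stage,
    tool = "soilvirome",
    version = as.character(utils::packageVersion("soilvirome")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tf)),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))),
    outputs = basename(outputs))
  unlink(tf)
  jsonlite::write_json(prov,
                       stage_path(cfg, sprintf("provenance_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic community, placements, tree), `cluster`
#' (retention filter + ANI/AF vOTU clustering), `coverage` (strand
#' coverage summaries and breadth-masked RPKM tables), `activity`
#' (expressed genes and DNA/ssRNA activity classification), `annotate-tree`
#' (support collapse, clade propagation, UniFrac), `stats` (occupancy,
#' Bray-Curtis/PERMANOVA, differential activity, z-score profiles), `all`.
#' Each stage reads only files under `config$out_dir`, writes its outputs
#' atomically, and drops a provenance JSON (config hash, seed, input
#' checksums, tool version). Truth tables written by `simulate` are never
#' read back by any analysis stage.
#'
#' @param stage Stage name (see above).
#' @param config A `virome_config` from [pipeline_config()].
#' @return Invisibly, the vector of output paths.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "virome_config"))
  stage <- match.arg(stage, c(PIPELINE_STAGES, "all"))
  if (stage == "all") {
    out <- purrr::map(PIPELINE_STAGES, run_stage, config = config)
    return(invisible(unlist(out)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fun <- switch(stage,
                simulate = stage_simulate,
                cluster = stage_cluster,
                coverage = stage_coverage,
                activity = stage_activity,
                `annotate-tree` = stage_annotate_tree,
                stats = stage_stats)
  inform(sprintf("[soilvirome] running stage '%s'", stage))
  fun(config)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) run_stage("all", config)

write_tsv_fn <- function(df) function(p) readr::write_tsv(df, p)

stage_simulate <- function(cfg) {
  s <- cfg$sim
  sim <- sim_genomes(n = s$n_votus, length_range = s$length_range,
                     gene_density = s$gene_density,
                     rna_fraction = s$rna_fraction,
                     duplicate_fraction = s$duplicate_fraction,
                     seed = cfg$seed)
  design <- do.call(community_design, cfg$design)
  truth <- sim_truth(sim, months = cfg$design$months,
                     active_fraction = s$active_fraction,
                     seasonal_fraction = s$seasonal_fraction,
                     lytic_fraction = s$lytic_fraction,
                     seed = cfg$seed + 1L)
  pl <- sim_placements(sim, truth, design,
                       depth_per_active_gene = s$depth_per_active_gene,
                       noise = s$noise, nb_size = s$nb_size,
                       neg_strand_fraction = s$neg_strand_fraction,
                       read_length = s$read_length,
                       seed = cfg$seed + 2L)
  tr <- sim_annotated_tree(n_clades = cfg$tree$n_clades,
                           tips_per_clade = cfg$tree$tips_per_clade,
                           ref_fraction = cfg$tree$ref_fraction,
                           low_support_fraction = cfg$tree$low_support_fraction,
                           seed = cfg$seed + 3L)

  meta <- select(sim$genomes, -"sequence")
  hosts <- truth$votus |>
    select("votu_id", "host_label", "host_strategy")

  names_out <- c("genomes.fasta", "contig_metadata.tsv", "genes.gff3",
                 "gene_categories.tsv", "samples.tsv", "libraries.tsv",
                 "placements.tsv", "hosts.tsv", "tree.nwk",
                 "tree_annotations.tsv",
                 "truth_votus.tsv", "truth_schedule.tsv",
                 "truth_expression.tsv", "truth_tree.tsv")
  paths <- stage_path(cfg, names_out)
  writers <- list(
    function(p) write_genomes_fasta(sim$genomes, p),
    write_tsv_fn(meta),
    function(p) write_genes_gff3(sim$genes, p),
    write_tsv_fn(select(sim$genes, "gene_id", "category")),
    write_tsv_fn(design$samples),
    write_tsv_fn(pl$libraries),
    function(p) write_placements_tsv(pl$placements, p),
    write_tsv_fn(hosts),
    function(p) ape::write.tree(tr$tree, p),
    write_tsv_fn(tr$annotations),
    write_tsv_fn(truth$votus),
    write_tsv_fn(truth$schedule),
    write_tsv_fn(truth$expression),
    write_tsv_fn(tr$truth))
  commit_outputs(writers, paths)
  write_provenance(cfg, "simulate", character(0), paths)
  invisible(paths)
}

stage_cluster <- function(cfg) {
  th <- cfg$thresholds
  fa <- require_input(stage_path(cfg, "genomes.fasta"), "cluster")
  meta_p <- require_input(stage_path(cfg, "contig_metadata.tsv"), "cluster")
  contigs <- read_genomes_fasta(fa) |>
    left_join(readr::read_tsv(meta_p, show_col_types = FALSE) |>
                select("contig_id", "molecule", "completeness"),
              by = "contig_id")
  retained <- retention_filter(contigs, min_len = th$min_len,
                               min_completeness = th$min_completeness)
  records <- ani_table(retained)
  votus <- greedy_cluster(records, retained,
                          min_ani = th$ani, min_af = th$af)
  paths <- stage_path(cfg, c("votus.tsv", "ani_records.tsv"))
  commit_outputs(list(write_tsv_fn(votus), write_tsv_fn(records)), paths)
  write_provenance(cfg, "cluster", c(fa, meta_p), paths)
  invisible(paths)
}

read_rep_inputs <- function(cfg, stage) {
  votus_p <- require_input(stage_path(cfg, "votus.tsv"), stage)
  meta_p <- require_input(stage_path(cfg, "contig_metadata.tsv"), stage)
  pl_p <- require_input(stage_path(cfg, "placements.tsv"), stage)
  lib_p <- require_input(stage_path(cfg, "libraries.tsv"), stage)
  votus <- readr::read_tsv(votus_p, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_p, show_col_types = FALSE)
  placements <- read_placements_tsv(pl_p)
  libraries <- readr::read_tsv(lib_p, show_col_types = FALSE)
  reps <- distinct(votus, .data$representative_id)$representative_id
  lengths <- meta |>
    filter(.data$contig_id %in% reps) |>
    select("contig_id", "length")
  list(votus = votus, meta = meta, libraries = libraries,
       placements = filter(placements, .data$contig_id %in% reps),
       lengths = lengths, reps = reps,
       inputs = c(votus_p, meta_p, pl_p, lib_p))
}

stage_coverage <- function(cfg) {
  th <- cfg$thresholds
  x <- read_rep_inputs(cfg, "coverage")
  cov <- accumulate_coverage(x$placements, x$lengths)
  summ <- coverage_summary(cov)
  metag <- filter(x$libraries, .data$type == "metaG")
  metat <- filter(x$libraries, .data$type == "metaT")
  rpkm_g <- rpkm_matrix(filter(cov, .data$library_id %in% metag$library_id),
                        x$lengths, metag, breadth_mask = th$breadth_mask)
  rpkm_t <- rpkm_matrix(filter(cov, .data$library_id %in% metat$library_id),
                        x$lengths, metat, breadth_mask = th$breadth_mask)
  paths <- stage_path(cfg, c("coverage_summary.tsv", "rpkm_metag.tsv",
                             "rpkm_metat.tsv"))
  commit_outputs(list(write_tsv_fn(summ), write_tsv_fn(rpkm_g),
                      write_tsv_fn(rpkm_t)), paths)
  write_provenance(cfg, "coverage", x$inputs, paths)
  invisible(paths)
}

stage_activity <- function(cfg) {
  th <- cfg$thresholds
  x <- read_rep_inputs(cfg, "activity")
  genes_p <- require_input(stage_path(cfg, "genes.gff3"), "activity")
  samples_p <- require_input(stage_path(cfg, "samples.tsv"), "activity")
  genes <- read_genes_gff3(genes_p)
  samples <- readr::read_tsv(samples_p, show_col_types = FALSE)

  rep_meta <- filter(x$meta, .data$contig_id %in% x$reps)
  dna <- tibble(votu_id = rep_meta$contig_id[rep_meta$molecule == "DNA"])
  rna <- tibble(votu_id = rep_meta$contig_id[rep_meta$molecule == "ssRNA"])
  cov <- accumulate_coverage(x$placements, x$lengths)
  metat_ids <- x$libraries$library_id[x$libraries$type == "metaT"]

  expr <- call_expressed_genes(filter(cov, .data$library_id %in% metat_ids),
                               filter(genes, .data$contig_id %in% x$reps),
                               gene_breadth = th$gene_breadth)
  dna_calls <- classify_dna_activity(expr, cov, dna, genes,
                                     x$libraries, samples,
                                     presence_breadth = th$breadth_mask)
  rna_calls <- classify_rna_activity(cov, rna, x$libraries, samples,
                                     rna_breadth = th$rna_breadth)
  sample_calls <- bind_rows(dna_calls[, c("votu_id", "sample_id",
                                          "molecule", "status")],
                            rna_calls)
  month_calls <- aggregate_by_month(sample_calls, samples)

  paths <- stage_path(cfg, c("expressed_genes.tsv", "activity_samples.tsv",
                             "activity_months.tsv"))
  commit_outputs(list(write_tsv_fn(expr),
                      write_tsv_fn(bind_rows(dna_calls |>
                                               select(-"n_expressed",
                                                      -"n_lytic"),
                                             rna_calls)),
                      write_tsv_fn(month_calls)), paths)
  write_provenance(cfg, "activity", c(x$inputs, genes_p, samples_p), paths)
  invisible(paths)
}

stage_annotate_tree <- function(cfg) {
  th <- cfg$thresholds
  tree_p <- require_input(stage_path(cfg, "tree.nwk"), "annotate-tree")
  ann_p <- require_input(stage_path(cfg, "tree_annotations.tsv"),
                         "annotate-tree")
  tree <- ape::read.tree(tree_p)
  ann <- read_tree_annotations(ann_p)
  collapsed <- collapse_low_support(tree, threshold = th$support_collapse)
  taxa <- propagate_annotations(collapsed, ann, field = "taxon")
  hosts <- propagate_annotations(collapsed, ann, field = "host")
  assignments <- taxa |>
    rename(taxon = "assignment", taxon_clade_size = "clade_size",
           taxon_n_ref = "n_ref") |>
    left_join(hosts |>
                rename(host = "assignment", host_clade_size = "clade_size",
                       host_n_ref = "n_ref"),
              by = "tip")

  ## dataset-level phylogenetic distance: query tips vs reference tips
  comm <- ann |>
    mutate(dataset = ifelse(.data$class == "reference",
                            "reference", "this_study"),
           abundance = 1) |>
    select("dataset", "tip", "abundance")
  uf_gen <- unifrac(comm, collapsed, alpha = th$unifrac_alpha,
                    mode = "generalized")
  uf_unw <- unifrac(comm, collapsed, alpha = th$unifrac_alpha,
                    mode = "unweighted")
  uf <- tibble(dataset_a = "this_study", dataset_b = "reference",
               generalized = uf_gen["this_study", "reference"],
               unweighted = uf_unw["this_study", "reference"],
               alpha = th$unifrac_alpha)

  paths <- stage_path(cfg, c("tree_assignments.tsv", "unifrac.tsv",
                             "tree_collapsed.nwk"))
  commit_outputs(list(write_tsv_fn(assignments), write_tsv_fn(uf),
                      function(p) ape::write.tree(collapsed, p)), paths)
  write_provenance(cfg, "annotate-tree", c(tree_p, ann_p), paths)
  invisible(paths)
}

stage_stats <- function(cfg) {
  th <- cfg$thresholds
  rpkm_g_p <- require_input(stage_path(cfg, "rpkm_metag.tsv"), "stats")
  rpkm_t_p <- require_input(stage_path(cfg, "rpkm_metat.tsv"), "stats")
  months_p <- require_input(stage_path(cfg, "activity_months.tsv"), "stats")
  samples_p <- require_input(stage_path(cfg, "samples.tsv"), "stats")
  lib_p <- require_input(stage_path(cfg, "libraries.tsv"), "stats")
  meta_p <- require_input(stage_path(cfg, "contig_metadata.tsv"), "stats")
  hosts_p <- require_input(stage_path(cfg, "hosts.tsv"), "stats")

  rpkm_g <- readr::read_tsv(rpkm_g_p, show_col_types = FALSE)
  rpkm_t <- readr::read_tsv(rpkm_t_p, show_col_types = FALSE)
  month_calls <- readr::read_tsv(months_p, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_p, show_col_types = FALSE)
  libraries <- readr::read_tsv(lib_p, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_p, show_col_types = FALSE)
  hosts <- readr::read_tsv(hosts_p, show_col_types = FALSE)

  lib_sample <- setNames(libraries$sample_id, libraries$library_id)
  season_of <- samples[, c("sample_id", "season", "month")]

  ## occupancy: metagenome presence for DNA vOTUs, metatranscriptome for RNA
  dna_ids <- meta$contig_id[meta$molecule == "DNA"]
  occ_input <- bind_rows(filter(rpkm_g, .data$votu_id %in% dna_ids),
                         filter(rpkm_t, !.data$votu_id %in% dna_ids)) |>
    mutate(sample_id = unname(lib_sample[.data$library_id]))
  occupancy <- season_occupancy(occ_input |>
                                  select("votu_id", "sample_id", "rpkm"),
                                samples)

  ## active DNA vOTUs: activity-based community structure
  active_dna <- month_calls |>
    filter(.data$molecule == "DNA",
           .data$status %in% c("active", "active-lytic")) |>
    distinct(.data$votu_id) |>
    pull("votu_id")

  act_rpkm <- rpkm_t |>
    filter(.data$votu_id %in% active_dna) |>
    mutate(sample_id = unname(lib_sample[.data$library_id]))

  perm_tbl <- NULL
  diff_tbl <- NULL
  z_tbl <- NULL
  bc_tbl <- NULL
  mat <- rpkm_to_matrix(act_rpkm |>
                          select(votu_id = "votu_id",
                                 library_id = "sample_id", "rpkm"))
  keep_samples <- colnames(mat)[colSums(mat) > 0]
  if (length(active_dna) >= 2 && length(keep_samples) >= 8) {
    m <- t(mat[, keep_samples, drop = FALSE])
    groups <- setNames(samples$month, samples$sample_id)[rownames(m)]
    pm <- tryCatch(permanova(bray_curtis_matrix(m), groups,
                             n_perm = 999, seed = cfg$seed + 10L),
                   error = function(e) NULL)
    if (!is.null(pm)) {
      perm_tbl <- glance(pm)
      bc_tbl <- as_tibble(as.matrix(bray_curtis_matrix(m)),
                          rownames = "sample_id")
    }
  }
  diff_input <- act_rpkm |> select("votu_id", "sample_id", "rpkm")
  diff <- tryCatch(differential_activity(diff_input, samples,
                                         effect_min = th$effect_min,
                                         q_max = th$q_max, hosts = hosts),
                   error = function(e) NULL)
  if (!is.null(diff)) {
    diff_tbl <- tidy(diff)
    z_tbl <- zscore_profiles(diff_input |>
                               filter(.data$votu_id %in%
                                        diff$votu_id[diff$seasonal]),
                             samples, hosts = hosts)
  }

  paths <- stage_path(cfg, c("occupancy.tsv", "permanova.tsv",
                             "differential_activity.tsv",
                             "zscore_profiles.tsv", "bray_curtis.tsv"))
  commit_outputs(list(
    write_tsv_fn(occupancy),
    write_tsv_fn(perm_tbl %||% tibble()),
    write_tsv_fn(diff_tbl %||% tibble()),
    write_tsv_fn(z_tbl %||% tibble()),
    write_tsv_fn(bc_tbl %||% tibble())), paths)
  write_provenance(cfg, "stats",
                   c(rpkm_g_p, rpkm_t_p, months_p, samples_p, lib_p,
                     meta_p, hosts_p), paths)
  invisible(paths)
}
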