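test_that("community design enumerates one sample and two libraries per cell", {
  d <- community_design(months = c("Mar", "May"), depths = c("a", "b"),
                        locations = "up", replicates = 2)
  expect_equal(nrow(d$samples), 2 * 2 * 1 * 2)
  expect_equal(nrow(d$libraries), 2 * nrow(d$samples))
  expect_setequal(unique(d$libraries$type), c("metaG", "metaT"))
  per_sample <- table(d$libraries$sample_id, d$libraries$type)
  expect_true(all(per_sample == 1))
  expect_error(community_design(months = character(0)),
               class = "soilvirome_error_parameter")
  expect_error(community_design(replicates = 0),
               class = "soilvirome_error_parameter")
})

test_that("genome generation honours forced parameters and determinism", {
  sim <- sim_genomes(1, c(5000, 5000), gene_density = 1, rna_fraction = 0,
                     seed = 1)
  expect_equal(sim$genomes$length, 5000)
  expect_equal(nchar(sim$genomes$sequence), 5000)
  expect_equal(nrow(sim$genes), 5)

  a <- sim_genomes(5, c(5000, 9000), seed = 42)
  b <- sim_genomes(5, c(5000, 9000), seed = 42)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genomes_fasta(a$genomes, f1)
  write_genomes_fasta(b$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_genomes(0), class = "soilvirome_error_parameter")
  expect_error(sim_genomes(2, c(100, 5000)),
               class = "soilvirome_error_parameter")
  expect_error(sim_genomes(2, c(5000, 300000)),
               class = "soilvirome_error_parameter")
})

test_that("molecule mix lands in the binomial interval and genes are valid", {
  sim <- sim_genomes(200, c(5000, 8000), rna_fraction = 0.5, seed = 7)
  n_rna <- sum(sim$genomes$molecule == "ssRNA")
  ## central 99% interval of Binomial(200, 0.5)
  expect_gte(n_rna, qbinom(0.005, 200, 0.5))
  expect_lte(n_rna, qbinom(0.995, 200, 0.5))

  lens <- setNames(sim$genomes$length, sim$genomes$contig_id)
  expect_true(all(sim$genes$start >= 1))
  expect_true(all(sim$genes$end <= lens[sim$genes$contig_id]))
  expect_true(all(sim$genes$start <= sim$genes$end))
  expect_true(all(sim$genes$category %in%
                    c("virion-structure", "encapsidation", "lysis",
                      "replication", "lysogeny", "unknown")))
  ## every genome has at least one gene
  expect_setequal(unique(sim$genes$contig_id), sim$genomes$contig_id)
  ## no overlap on the same strand (blocks are globally disjoint)
  overlaps <- sim$genes |>
    dplyr::group_by(contig_id) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(start[-1] <= end[-dplyr::n()]))
  expect_false(any(overlaps$bad))
  ## ssRNA genes are all plus-strand (genome sense)
  rna_genes <- sim$genes[sim$genes$contig_id %in%
                           sim$genomes$contig_id[sim$genomes$molecule ==
                                                   "ssRNA"], ]
  expect_true(all(rna_genes$strand == "+"))
})

test_that("planted truth respects its invariants", {
  sim <- sim_genomes(60, c(5000, 12000), rna_fraction = 0.3, seed = 3)
  truth <- sim_truth(sim, seed = 4)
  votus <- truth$votus
  expect_equal(sum(votus$baseline_abundance), 1)

  ## every active-lytic month expresses at least one lytic-category gene
  lytic_months <- truth$schedule[truth$schedule$status == "active-lytic", ]
  cats <- setNames(sim$genes$category, sim$genes$gene_id)
  for (i in seq_len(nrow(lytic_months))) {
    g <- truth$expression$gene_id[
      truth$expression$votu_id == lytic_months$votu_id[i] &
        truth$expression$month == lytic_months$month[i]]
    expect_true(any(cats[g] %in% c("virion-structure", "encapsidation",
                                   "lysis")))
  }
  ## non-lytic active months express no lytic gene
  plain <- truth$schedule[truth$schedule$status == "active", ]
  for (i in seq_len(nrow(plain))) {
    g <- truth$expression$gene_id[
      truth$expression$votu_id == plain$votu_id[i] &
        truth$expression$month == plain$month[i]]
    expect_false(any(cats[g] %in% c("virion-structure", "encapsidation",
                                    "lysis")))
  }
  ## DNA statuses never "absent"; RNA statuses from the RNA alphabet
  dna_st <- truth$schedule$status[truth$schedule$votu_id %in%
                                    votus$votu_id[votus$molecule == "DNA"]]
  expect_true(all(dna_st %in% c("inactive", "active", "active-lytic")))
  rna_st <- truth$schedule$status[truth$schedule$votu_id %in%
                                    votus$votu_id[votus$molecule == "ssRNA"]]
  expect_true(all(rna_st %in% c("absent", "detected", "active")))
})

test_that("placements follow the schedule and the library table", {
  sim <- sim_genomes(20, c(5000, 10000), rna_fraction = 0.4, seed = 10)
  design <- small_design()
  truth <- sim_truth(sim, seed = 11)
  pl <- sim_placements(sim, truth, design, noise = "nb", seed = 12)

  ## mapped reads in the emitted table equal placement rows per library
  rows <- table(pl$placements$library_id)
  for (lib in pl$libraries$library_id) {
    expect_equal(unname(pl$libraries$mapped_reads[
      pl$libraries$library_id == lib]),
      if (lib %in% names(rows)) unname(rows[[lib]]) else 0L)
  }
  expect_equal(pl$libraries$total_reads,
               pl$libraries$mapped_reads + pl$libraries$unmapped_reads)

  ## determinism
  pl2 <- sim_placements(sim, truth, design, noise = "nb", seed = 12)
  expect_identical(pl, pl2)

  metat <- pl$libraries$library_id[pl$libraries$type == "metaT"]
  lib_month <- setNames(pl$libraries$month, pl$libraries$library_id)

  ## a DNA vOTU inactive in every month has zero metatranscriptome reads
  never <- truth$schedule |>
    dplyr::group_by(votu_id) |>
    dplyr::summarise(never = all(status == "inactive"))
  for (id in never$votu_id[never$never]) {
    expect_equal(sum(pl$placements$contig_id == id &
                       pl$placements$library_id %in% metat), 0)
  }

  ## ssRNA "detected" months have zero minus-strand reads
  rna_ids <- truth$votus$votu_id[truth$votus$molecule == "ssRNA"]
  det <- truth$schedule[truth$schedule$votu_id %in% rna_ids &
                          truth$schedule$status == "detected", ]
  pr <- pl$placements[pl$placements$library_id %in% metat, ]
  pr$month <- unname(lib_month[pr$library_id])
  for (i in seq_len(nrow(det))) {
    sel <- pr$contig_id == det$votu_id[i] & pr$month == det$month[i]
    expect_true(all(pr$strand[sel] == "+"))
  }
  ## ssRNA "active" months do have minus-strand reads
  act <- truth$schedule[truth$schedule$votu_id %in% rna_ids &
                          truth$schedule$status == "active", ]
  if (nrow(act) > 0) {
    i <- 1
    sel <- pr$contig_id == act$votu_id[i] & pr$month == act$month[i]
    expect_true(any(pr$strand[sel] == "-"))
  }

  ## month mismatch is a schema error
  design2 <- community_design(months = c("Jan", "Feb"),
                              seasons = c(Jan = "winter", Feb = "winter"))
  expect_error(sim_placements(sim, truth, design2, seed = 1),
               class = "soilvirome_error_schema")
})

test_that("noiseless placements make every scheduled signal full-breadth", {
  sim <- sim_genomes(12, c(5000, 9000), rna_fraction = 0.4, seed = 20)
  design <- small_design()
  truth <- sim_truth(sim, seed = 21)
  pl <- sim_placements(sim, truth, design, noise = "none",
                       depth_per_active_gene = 20, seed = 22)
  cov <- accumulate_coverage(pl$placements,
                             sim$genomes[, c("contig_id", "length")])
  expr <- call_expressed_genes(cov, sim$genes, pl$libraries)
  lib_month <- setNames(pl$libraries$month, pl$libraries$library_id)
  expr$month <- unname(lib_month[expr$library_id])
  scheduled <- dplyr::semi_join(
    expr, truth$expression,
    by = c(contig_id = "votu_id", "month", "gene_id"))
  expect_true(all(scheduled$coding_breadth >= 50))
  expect_true(all(scheduled$coding_median_depth > 0))
  expect_true(all(scheduled$expressed))
})
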