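## A hand-built coverage fixture: one contig, one library, controllable
## per-position depth on each strand.
mk_cov <- function(dp, dm, contig = "c", lib = "S1_metaT") {
  out <- tibble::tibble(contig_id = contig, library_id = lib,
                        mapped_reads = 1L,
                        depth_plus = list(as.integer(dp)),
                        depth_minus = list(as.integer(dm)))
  class(out) <- c("virome_coverage", class(out))
  out
}

test_that("expressed-gene calling applies the 50% breadth boundary exactly", {
  genes <- tibble::tibble(gene_id = "g1", contig_id = "c",
                          start = 1L, end = 300L, strand = "+")
  dp <- integer(400); dp[1:150] <- 1L
  calls <- call_expressed_genes(mk_cov(dp, integer(400)), genes)
  expect_equal(calls$coding_breadth, 50)
  expect_equal(calls$coding_median_depth, 0)  # lower median of 150/150 split
  expect_false(calls$expressed)               # breadth ok, median 0

  ## one extra covered position pushes the lower median to 1 -> expressed
  dp151 <- dp; dp151[151] <- 1L
  calls2 <- call_expressed_genes(mk_cov(dp151, integer(400)), genes)
  expect_true(calls2$expressed)

  ## 149 covered positions: below breadth, never expressed
  dp149 <- integer(400); dp149[1:149] <- 1L
  expect_false(call_expressed_genes(mk_cov(dp149, integer(400)),
                                    genes)$expressed)

  ## coverage only on the non-coding strand never expresses the gene
  anti <- call_expressed_genes(mk_cov(integer(400), rep(5L, 400)), genes)
  expect_false(anti$expressed)
  expect_equal(anti$coding_breadth, 0)

  ## a gene outside the contig bounds is a schema error
  bad <- tibble::tibble(gene_id = "g2", contig_id = "c",
                        start = 390L, end = 500L, strand = "+")
  expect_error(call_expressed_genes(mk_cov(dp, integer(400)), bad),
               class = "soilvirome_error_schema")
})

test_that("DNA classification maps expression and presence to statuses", {
  samples <- tibble::tibble(sample_id = "S1", month = "May")
  libraries <- tibble::tibble(library_id = c("S1_metaG", "S1_metaT"),
                              sample_id = "S1", type = c("metaG", "metaT"))
  genes <- tibble::tibble(gene_id = c("terminase", "integrase"),
                          contig_id = "c", start = c(1L, 500L),
                          end = c(300L, 800L), strand = "+",
                          category = c("encapsidation", "lysogeny"))
  votus <- tibble::tibble(votu_id = "c")
  dp_g <- rep(1L, 1000)  # fully present in the metagenome
  cov_g <- mk_cov(dp_g, integer(1000), lib = "S1_metaG")

  expr_of <- function(which_gene) {
    dp <- integer(1000)
    sel <- genes[genes$gene_id == which_gene, ]
    dp[sel$start:sel$end] <- 2L
    call_expressed_genes(mk_cov(dp, integer(1000)), genes)
  }

  ## expressed terminase (encapsidation) -> active-lytic
  st <- classify_dna_activity(expr_of("terminase"), cov_g, votus, genes,
                              libraries, samples)
  expect_equal(st$status, "active-lytic")
  ## expressed integrase (lysogeny) -> active, not lytic
  st2 <- classify_dna_activity(expr_of("integrase"), cov_g, votus, genes,
                               libraries, samples)
  expect_equal(st2$status, "active")
  expect_equal(st2$n_lytic, 0L)

  ## no expression, present in metagenome -> present-inactive
  no_expr <- call_expressed_genes(mk_cov(integer(1000), integer(1000)),
                                  genes)
  st3 <- classify_dna_activity(no_expr, cov_g, votus, genes,
                               libraries, samples)
  expect_equal(st3$status, "present-inactive")

  ## no signal anywhere -> absent
  cov_empty <- mk_cov(integer(1000), integer(1000), lib = "S1_metaG")
  st4 <- classify_dna_activity(no_expr, cov_empty, votus, genes,
                               libraries, samples)
  expect_equal(st4$status, "absent")

  ## unknown category labels warn and count as non-lytic
  genes_u <- genes |> dplyr::mutate(category = c("mystery", "mystery"))
  expect_warning(
    stu <- classify_dna_activity(expr_of("terminase"), cov_g, votus,
                                 genes_u, libraries, samples),
    "non-lytic")
  expect_equal(stu$status, "active")
})

test_that("ssRNA classification needs both strands for activity", {
  samples <- tibble::tibble(sample_id = "S1", month = "May")
  libraries <- tibble::tibble(library_id = "S1_metaT", sample_id = "S1",
                              type = "metaT")
  votus <- tibble::tibble(votu_id = "c")
  len <- 1000

  mk <- function(plus_frac, minus_frac, depth = 2L) {
    dp <- integer(len); dm <- integer(len)
    if (plus_frac > 0) dp[seq_len(round(len * plus_frac))] <- depth
    if (minus_frac > 0) dm[seq_len(round(len * minus_frac))] <- 1L
    mk_cov(dp, dm)
  }

  ## coding 60% + antisense 55% -> active
  expect_equal(classify_rna_activity(mk(0.6, 0.55), votus, libraries,
                                     samples)$status, "active")
  ## coding 60%, antisense 10% -> detected
  expect_equal(classify_rna_activity(mk(0.6, 0.1), votus, libraries,
                                     samples)$status, "detected")
  ## coding 40% -> absent
  expect_equal(classify_rna_activity(mk(0.4, 0.55), votus, libraries,
                                     samples)$status, "absent")
  ## antisense breadth has no median-depth requirement (1x everywhere is
  ## enough) but the coding strand median must be positive
  halfcov <- mk(0.5, 0.5)
  expect_equal(classify_rna_activity(halfcov, votus, libraries,
                                     samples)$status, "absent")
})

test_that("month aggregation takes the maximum status", {
  samples <- tibble::tibble(sample_id = sprintf("S%d", 1:3), month = "May")
  calls <- tibble::tibble(votu_id = "v", sample_id = sprintf("S%d", 1:3),
                          molecule = "DNA",
                          status = c("present-inactive", "active",
                                     "present-inactive"))
  agg <- aggregate_by_month(calls, samples)
  expect_equal(agg$status, "active")

  calls$status <- rep("absent", 3)
  expect_equal(aggregate_by_month(calls, samples)$status, "absent")

  calls$status <- c("present-inactive", "present-inactive", "absent")
  expect_equal(aggregate_by_month(calls, samples)$status,
               "present-inactive")

  calls$status <- c("active", "active-lytic", "absent")
  expect_equal(aggregate_by_month(calls, samples)$status, "active-lytic")

  ## sample without month metadata is a schema error
  expect_error(aggregate_by_month(calls |>
                                    dplyr::mutate(sample_id = c("S1", "S2",
                                                                "ghost")),
                                  samples),
               class = "soilvirome_error_schema")
})

test_that("adding placements never demotes a status (monotonicity)", {
  set.seed(404)
  sim <- sim_genomes(8, c(5000, 8000), rna_fraction = 0.4, seed = 50)
  design <- small_design()
  truth <- sim_truth(sim, seed = 51)
  pl <- sim_placements(sim, truth, design, noise = "nb", seed = 52)
  base_calls <- classify_chain(sim, truth, pl, design)

  ## add further metatranscriptome reads for a random subset of contigs
  metat <- pl$libraries$library_id[pl$libraries$type == "metaT"]
  extra <- purrr::map(sample(nrow(sim$genomes), 4), function(i) {
    len <- sim$genomes$length[i]
    starts <- seq(1L, len, by = 150L)
    tibble::tibble(read_id = sprintf("x%d_%d", i, seq_along(starts)),
                   contig_id = sim$genomes$contig_id[i],
                   start = starts, end = pmin(starts + 149L, len),
                   strand = "+", library_id = metat[1])
  }) |> dplyr::bind_rows()
  pl2 <- pl
  pl2$placements <- dplyr::bind_rows(pl$placements, extra)
  more_calls <- classify_chain(sim, truth, pl2, design)

  cmp <- dplyr::inner_join(base_calls, more_calls,
                           by = c("votu_id", "month", "molecule"),
                           suffix = c("_base", "_more"))
  expect_true(all(soilvirome:::status_rank(cmp$status_more) >=
                    soilvirome:::status_rank(cmp$status_base)))
})
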