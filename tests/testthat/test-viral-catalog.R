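test_that("retention filter keeps long or complete contigs", {
  contigs <- tibble::tibble(
    contig_id = c("long_unknown", "short_complete", "short_unknown",
                  "short_incomplete", "boundary_len", "boundary_comp"),
    length = c(6000, 3000, 3000, 3000, 5000, 1200),
    completeness = c(NA, 60, NA, 20, NA, 50))
  kept <- retention_filter(contigs)$contig_id
  expect_setequal(kept, c("long_unknown", "short_complete", "boundary_len",
                          "boundary_comp"))
})

test_that("insertion-sequence-only and unannotated contigs can be dropped", {
  contigs <- tibble::tibble(contig_id = c("a", "b", "c", "d"))
  ann <- tibble::tibble(
    contig_id = c("a", "a", "b", "c", "d", "d"),
    annotation = c("Transposase", "IS110 insertion element", "terminase",
                   NA, NA, "phage portal protein"))
  kept <- filter_is_elements(contigs, ann)$contig_id
  expect_setequal(kept, c("b", "d"))
})

test_that("pairwise ANI handles identity, substring and disjoint cases", {
  set.seed(101)
  a <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
             collapse = "")
  ident <- pairwise_ani("a", "a2", a, a)
  expect_equal(ident$ani, 100)
  expect_equal(ident$af_query, 100)
  expect_equal(ident$af_target, 100)

  ## exact substring: 85% of the longer sequence
  b <- substr(a, 1, 5100)
  sub <- pairwise_ani("a", "b", a, b)
  expect_equal(sub$ani, 100)
  expect_equal(sub$af_target, 100)
  expect_equal(sub$af_query, 85, tolerance = 0.02)

  ## no shared 11-mer: a sequence over a disjoint alphabet arrangement
  set.seed(102)
  c_seq <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  rec <- pairwise_ani("a", "c", a, c_seq)
  if (nrow(rec) > 0) expect_lt(rec$af_query, 85)  # spurious micro-hits only

  ## reverse-complement orientation is detected
  rc <- pairwise_ani("a", "rc", a, soilvirome:::revcomp(substr(a, 501, 5500)))
  expect_equal(rc$ani, 100)
  expect_equal(rc$af_target, 100)

  ## point mutations reduce ANI roughly proportionally
  chars <- strsplit(a, "")[[1]]
  pos <- sample(6000, 120)
  chars[pos] <- vapply(chars[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  mut <- pairwise_ani("a", "m", a, paste(chars, collapse = ""))
  expect_equal(mut$ani, 98, tolerance = 0.5)

  expect_error(pairwise_ani("x", "y", "", "ACGT"),
               class = "soilvirome_error_parameter")
})

test_that("greedy clustering matches hand-traced and trivial cases", {
  contigs <- tibble::tibble(contig_id = c("A", "B", "C"),
                            length = c(9000, 8000, 7000))
  recs <- tibble::tibble(query = c("A", "B", "A"),
                         target = c("B", "C", "C"),
                         ani = c(96, 96, 90),
                         af_query = c(90, 90, 90),
                         af_target = c(90, 90, 90))
  cl <- greedy_cluster(recs, contigs)
  rep_of <- setNames(cl$representative_id, cl$member_id)
  expect_equal(unname(rep_of[c("A", "B", "C")]), c("A", "A", "C"))

  ## two identical-length identical sequences: lexicographically smaller id
  ties <- tibble::tibble(contig_id = c("z1", "a1"), length = c(5000, 5000))
  tie_rec <- tibble::tibble(query = "a1", target = "z1", ani = 100,
                            af_query = 100, af_target = 100)
  cl2 <- greedy_cluster(tie_rec, ties)
  expect_equal(unique(cl2$representative_id), "a1")

  ## all pairs below threshold: singletons
  cl3 <- greedy_cluster(recs |> dplyr::mutate(ani = 80), contigs)
  expect_equal(nrow(dplyr::distinct(cl3, votu_id)), 3)

  ## unknown contig in records is a schema error
  expect_error(greedy_cluster(tibble::tibble(query = "A", target = "ghost",
                                             ani = 99, af_query = 99,
                                             af_target = 99),
                              contigs),
               class = "soilvirome_error_schema")
})

test_that("greedy clustering equals the brute-force oracle on random instances", {
  set.seed(202)
  for (rep in seq_len(100)) {
    n <- sample(3:30, 1)
    ids <- sprintf("c%02d", seq_len(n))
    contigs <- tibble::tibble(contig_id = ids,
                              length = sample(5000:20000, n, replace = TRUE))
    recs <- random_records(ids)
    got <- greedy_cluster(recs, contigs)
    rep_of <- setNames(got$representative_id, got$member_id)
    want <- brute_greedy(recs, contigs)
    expect_identical(unname(rep_of[ids]), unname(want[ids]))

    ## partition + representative-longest invariants
    expect_setequal(got$member_id, ids)
    expect_equal(anyDuplicated(got$member_id), 0)
    lens <- setNames(contigs$length, contigs$contig_id)
    expect_true(all(lens[got$representative_id] >= lens[got$member_id]))
  }
})

test_that("raising clustering thresholds never decreases vOTU count", {
  set.seed(203)
  ids <- sprintf("c%02d", 1:20)
  contigs <- tibble::tibble(contig_id = ids,
                            length = sample(5000:20000, 20, replace = TRUE))
  recs <- random_records(ids)
  n_votus <- function(ani, af)
    nrow(dplyr::distinct(greedy_cluster(recs, contigs, ani, af), votu_id))
  for (ani in c(86, 90, 94, 98)) {
    expect_lte(n_votus(ani, 85), n_votus(ani + 2, 85))
  }
  for (af in c(55, 70, 85)) {
    expect_lte(n_votus(90, af), n_votus(90, af + 10))
  }
})

test_that("ani_table + greedy_cluster merge planted near-duplicates", {
  sim <- sim_genomes(8, c(5000, 9000), rna_fraction = 0,
                     duplicate_fraction = 0.25, seed = 33)
  recs <- ani_table(sim$genomes)
  cl <- greedy_cluster(recs, sim$genomes)
  dups <- sim$genomes[sim$genomes$is_duplicate, ]
  rep_of <- setNames(cl$representative_id, cl$member_id)
  expect_gt(nrow(dups), 0)
  expect_equal(unname(rep_of[dups$contig_id]), dups$source_id)
})
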