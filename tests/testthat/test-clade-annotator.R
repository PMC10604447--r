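test_that("branch collapse contracts exactly the low-support edges", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,((C:1,D:1)30:1,E:2)80:1)100;")
  col <- collapse_low_support(tr, 50)
  ## the support-30 node becomes a polytomy (C,D,E) under the support-80 node
  expect_equal(col$Nnode, tr$Nnode - 1)
  ## path lengths to tips are preserved
  d0 <- ape::dist.nodes(tr)[seq_len(5), 6]   # root distances
  d1 <- ape::dist.nodes(col)[seq_len(5), 6]
  expect_equal(d1[order(col$tip.label)], d0[order(tr$tip.label)],
               ignore_attr = TRUE)

  ## all supports high: identity; threshold 0: identity
  expect_equal(ape::write.tree(collapse_low_support(tr, 0)),
               ape::write.tree(tr))
  hi <- ape::read.tree(text = "((A:1,B:1)99:1,(C:1,D:1)98:1)100;")
  expect_equal(ape::write.tree(collapse_low_support(hi, 50)),
               ape::write.tree(hi))

  ## a single low node on a 4-tip tree gives a star over its children
  t4 <- ape::read.tree(text = "((A:1,B:1)30:1,(C:1,D:1)70:1)100;")
  c4 <- collapse_low_support(t4, 50)
  expect_equal(c4$Nnode, 2)

  ## idempotence at the same threshold
  ts <- sim_annotated_tree(low_support_fraction = 0.3, seed = 60)
  once <- collapse_low_support(ts$tree, 50)
  twice <- collapse_low_support(once, 50)
  expect_equal(ape::write.tree(twice), ape::write.tree(once))
})

test_that("annotation propagation follows the unanimity rule", {
  ## clade (refT, query) -> assigned
  tr <- ape::read.tree(text = "((ref1:1,q1:1):1,(ref2:1,q2:1):1);")
  ann <- tibble::tibble(tip = c("ref1", "ref2"),
                        class = "reference",
                        taxon = c("Levi", "Cysto"))
  res <- propagate_annotations(tr, ann, "taxon")
  expect_equal(res$assignment[res$tip == "q1"], "Levi")
  expect_equal(res$assignment[res$tip == "q2"], "Cysto")

  ## clade (refT1, refT2 != T1, query): first informative clade
  ## non-unanimous -> unassigned
  tr2 <- ape::read.tree(text = "((refA:1,refB:1,q:1):1,out:2);")
  ann2 <- tibble::tibble(tip = c("refA", "refB", "out"),
                         class = c("reference", "reference", "query"),
                         taxon = c("T1", "T2", NA))
  res2 <- propagate_annotations(tr2, ann2, "taxon")
  expect_true(is.na(res2$assignment[res2$tip == "q"]))

  ## references with missing annotation are ignored, not unanimity-breaking
  ann3 <- tibble::tibble(tip = c("refA", "refB"),
                         class = "reference",
                         taxon = c("T1", NA))
  res3 <- propagate_annotations(tr2, ann3, "taxon")
  expect_equal(res3$assignment[res3$tip == "q"], "T1")

  ## no annotated reference anywhere is a parameter error
  expect_error(propagate_annotations(
    tr2, tibble::tibble(tip = "refA", class = "reference",
                        taxon = NA_character_), "taxon"),
    class = "soilvirome_error_parameter")

  ## unrooted tree is a parameter error
  unr <- ape::unroot(ape::rtree(5))
  expect_error(propagate_annotations(
    unr, tibble::tibble(tip = unr$tip.label[1], class = "reference",
                        taxon = "T"), "taxon"),
    class = "soilvirome_error_parameter")
})

test_that("propagation equals exhaustive clade enumeration on random trees", {
  set.seed(505)
  for (rep in seq_len(50)) {
    rt <- random_annotated_tree(sample(6:32, 1))
    got <- propagate_annotations(rt$tree, rt$annotations, "taxon")
    want <- brute_propagate(rt$tree, rt$annotations, "taxon")
    merged <- dplyr::inner_join(got, want, by = "tip",
                                suffix = c("_got", "_want"))
    expect_equal(nrow(merged), nrow(want))
    expect_identical(merged$assignment_got, merged$assignment_want)
  }
})

test_that("clade-structured simulations are recovered and members inherit", {
  ts <- sim_annotated_tree(seed = 70)
  res <- propagate_annotations(ts$tree, ts$annotations, "taxon")
  cmp <- dplyr::inner_join(ts$truth, res, by = "tip")
  expect_true(all(cmp$assignment == cmp$taxon))
  hosts <- propagate_annotations(ts$tree, ts$annotations, "host")
  cmp_h <- dplyr::inner_join(ts$truth, hosts, by = "tip")
  expect_true(all(cmp_h$assignment == cmp_h$host))

  ## cluster members inherit the representative's assignment verbatim
  clusters <- tibble::tibble(
    representative_id = rep(cmp$tip[1], 5),
    member_id = sprintf("m%d", 1:5))
  memb <- propagate_to_cluster_members(
    res |> dplyr::select(tip, assignment), clusters)
  expect_equal(unique(memb$assignment), cmp$taxon[1])

  ## unassigned / missing representative -> NA with warning
  ghost <- tibble::tibble(representative_id = "ghost", member_id = "m9")
  expect_warning(m2 <- propagate_to_cluster_members(
    res |> dplyr::select(tip, assignment), ghost), "unassigned")
  expect_true(is.na(m2$assignment))

  ## member under two representatives violates the partition
  dup <- tibble::tibble(representative_id = c("a", "b"),
                        member_id = c("m", "m"))
  expect_error(propagate_to_cluster_members(
    res |> dplyr::select(tip, assignment), dup),
    class = "soilvirome_error_schema")
})

test_that("collapse then propagate is stable under repeated collapse", {
  ts <- sim_annotated_tree(low_support_fraction = 0.25, seed = 71)
  c1 <- collapse_low_support(ts$tree, 50)
  r1 <- propagate_annotations(c1, ts$annotations, "taxon")
  c2 <- collapse_low_support(c1, 50)
  r2 <- propagate_annotations(c2, ts$annotations, "taxon")
  expect_identical(r1, r2)
})
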