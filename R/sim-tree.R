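#' Simulate a clade-structured reference/query phylogeny
#'
#' Builds a rooted tree of monophyletic clades, each carrying one planted
#' taxon (and host) label. Within a clade, some tips are "reference" tips
#' annotated with the clade's labels and the rest are "query" tips whose
#' correct assignment is the clade label — the planted truth for testing
#' unanimity-based annotation propagation. Internal-node supports are drawn
#' above the collapse threshold by default so the planted clades survive
#' branch collapsing; `low_support_fraction` lets some backbone nodes fall
#' below it.
#'
#' @param n_clades Number of monophyletic clades.
#' @param tips_per_clade Two-element range of tips per clade (>= 2).
#' @param ref_fraction Probability a tip is a reference (at least one per
#'   clade is forced).
#' @param low_support_fraction Fraction of internal nodes given support
#'   below 50.
#' @param seed Integer seed.
#'
#' @return List of class `virome_tree_sim`: `tree` (rooted `ape::phylo`
#'   with numeric node labels as supports), `annotations` tibble (tip,
#'   class, taxon, host), and `truth` tibble (tip, taxon, host) for the
#'   query tips.
#' @export
sim_annotated_tree <- function(n_clades = 6,
                               tips_per_clade = c(3, 8),
                               ref_fraction = 0.5,
                               low_support_fraction = 0,
                               seed = NULL) {
  check_scalar_number(n_clades, "n_clades", lower = 2)
  set_seed_if(seed)

  backbone <- ape::rtree(n_clades, tip.label = sprintf("BB%d", seq_len(n_clades)))
  tree <- backbone
  annotations <- list()
  truth <- list()

  for (i in seq_len(n_clades)) {
    m <- sample(seq(tips_per_clade[1], tips_per_clade[2]), 1)
    taxon <- sprintf("Taxon_%02d", i)
    host <- sprintf("Host_%02d", i)
    labels <- sprintf("c%02d_t%02d", i, seq_len(m))
    clade <- ape::rtree(m, tip.label = labels)
    is_ref <- runif(m) < ref_fraction
    if (!any(is_ref)) is_ref[sample(m, 1)] <- TRUE
    if (all(is_ref) && m > 1) is_ref[sample(m, 1)] <- FALSE
    annotations[[i]] <- tibble(
      tip = labels,
      class = ifelse(is_ref, "reference", "query"),
      taxon = ifelse(is_ref, taxon, NA_character_),
      host = ifelse(is_ref, host, NA_character_))
    truth[[i]] <- tibble(tip = labels[!is_ref], taxon = taxon, host = host)
    where <- which(tree$tip.label == sprintf("BB%d", i))
    tree <- ape::bind.tree(tree, clade, where = where)
  }

  nn <- tree$Nnode
  supports <- sample(60:100, nn, replace = TRUE)
  low <- runif(nn) < low_support_fraction
  supports[low] <- sample(10:49, sum(low), replace = TRUE)
  tree$node.label <- as.character(supports)

  structure(list(tree = tree,
                 annotations = bind_rows(annotations),
                 truth = bind_rows(truth)),
            class = "virome_tree_sim")
}
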