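#' UniFrac-family distances between datasets on a shared phylogeny
#'
#' Computes pairwise unweighted or generalized UniFrac distances between
#' datasets (communities) whose members are tips of a rooted tree with
#' branch lengths.
#'
#' For each branch `i` with length `b_i`, let `p_i` and `q_i` be the
#' proportions of the two datasets descending from the branch. The
#' unweighted distance is the branch length unique to either dataset
#' divided by the total branch length spanned by their union. The
#' generalized distance is
#' `sum(b_i (p_i+q_i)^alpha |p_i-q_i|/(p_i+q_i)) / sum(b_i (p_i+q_i)^alpha)`
#' over branches with `p_i + q_i > 0`; `alpha` (default 0.5) controls the
#' weight placed on abundant lineages and is honoured in generalized mode
#' only.
#'
#' @param communities Either a numeric matrix with datasets as rows and
#'   tip labels as columns, or a long tibble with columns `dataset`, `tip`,
#'   and `abundance`. Presence/absence data (0/1 tip membership) is the
#'   usual input for cluster-sharing comparisons.
#' @param tree Rooted `ape::phylo` with branch lengths covering all tips
#'   that appear in `communities`.
#' @param alpha Abundance-weighting exponent for the generalized form.
#' @param mode `"generalized"` or `"unweighted"`.
#' @return A symmetric distance matrix (datasets x datasets) with zero
#'   diagonal; values in \[0, 1\].
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' comm <- rbind(s1 = c(A = 1, B = 1, C = 0, D = 0),
#'               s2 = c(A = 0, B = 0, C = 1, D = 1))
#' unifrac(comm, tr, mode = "unweighted")
unifrac <- function(communities, tree, alpha = 0.5,
                    mode = c("generalized", "unweighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort_parameter("tree must have branch lengths")
  }
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)

  if (is.data.frame(communities)) {
    check_columns(communities, c("dataset", "tip", "abundance"),
                  "communities")
    wide <- tidyr::pivot_wider(communities, names_from = "tip",
                               values_from = "abundance", values_fill = 0,
                               id_cols = "dataset")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$dataset
    communities <- m
  }
  if (is.null(rownames(communities))) {
    rownames(communities) <- sprintf("dataset_%d", seq_len(nrow(communities)))
  }
  missing_tips <- setdiff(colnames(communities), tree$tip.label)
  if (length(missing_tips) > 0) {
    abort_parameter(sprintf("tips absent from tree: %s",
                            paste(head(missing_tips, 5), collapse = ", ")))
  }
  totals <- rowSums(communities)
  if (any(totals <= 0)) {
    abort_parameter("every dataset must have positive total abundance")
  }

  ## per-branch descendant abundance for each dataset
  ntip <- ape::Ntip(tree)
  abund <- matrix(0, nrow = nrow(communities), ncol = ntip,
                  dimnames = list(rownames(communities), tree$tip.label))
  abund[, colnames(communities)] <- communities
  sets <- node_tip_sets(tree)
  n_edge <- nrow(tree$edge)
  branch_prop <- matrix(0, nrow = nrow(communities), ncol = n_edge)
  for (e in seq_len(n_edge)) {
    tips <- sets[[tree$edge[e, 2]]]
    branch_prop[, e] <- rowSums(abund[, tips, drop = FALSE]) / totals
  }
  b <- tree$edge.length

  k <- nrow(communities)
  d <- matrix(0, k, k, dimnames = list(rownames(communities),
                                       rownames(communities)))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      p <- branch_prop[i, ]; q <- branch_prop[j, ]
      if (mode == "unweighted") {
        pres_p <- p > 0; pres_q <- q > 0
        union <- pres_p | pres_q
        if (!any(union)) next
        d[i, j] <- d[j, i] <- sum(b[xor(pres_p, pres_q)]) / sum(b[union])
      } else {
        s <- p + q
        keep <- s > 0
        if (!any(keep)) next
        w <- b[keep] * s[keep]^alpha
        d[i, j] <- d[j, i] <- sum(w * abs(p[keep] - q[keep]) / s[keep]) /
          sum(w)
      }
    }
  }
  d
}
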