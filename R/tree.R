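## Phylogeny utilities: support-based branch collapse and unanimity-based
## annotation propagation. Trees are `ape::phylo`; reference/query tip
## metadata travels as a tibble (tip, class, taxon, host, ...).

## A collapsed tree can legitimately carry a basal polytomy, which
## ape::is.rooted() reports as unrooted; trees produced by
## collapse_low_support() are tagged and still treated as rooted.
is_rooted_tree <- function(tree) {
  isTRUE(attr(tree, "rooted")) || ape::is.rooted(tree)
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

parent_vector <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

## tip sets per node (indices into tip labels), by post-order accumulation
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(ntip)) sets[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Collapse low-support branches
#'
#' Contracts every internal edge whose child node's support is below
#' `threshold`: the node's children are reattached to its parent and the
#' contracted edge's length is added to the children's edges, so
#' root-to-tip path lengths are preserved. Tips are never removed; nodes
#' with missing (non-numeric) supports are kept. Applying the same
#' threshold twice is a no-op after the first pass.
#'
#' @param tree A rooted `ape::phylo` whose `node.label` holds numeric
#'   supports (0-100).
#' @param threshold Support threshold (default 50); nodes with support
#'   strictly below it are collapsed.
#' @return The collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_rooted_tree(tree)) abort_parameter("tree must be rooted")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  supports <- node_supports(tree)
  flagged_nodes <- (ntip + seq_len(tree$Nnode))[!is.na(supports) &
                                                  supports < threshold]
  flagged_nodes <- setdiff(flagged_nodes, root)
  if (length(flagged_nodes) == 0) {
    attr(tree, "rooted") <- TRUE
    return(tree)
  }

  parent <- parent_vector(tree)
  elen <- rep(NA_real_, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  flagged <- rep(FALSE, ntip + tree$Nnode)
  flagged[flagged_nodes] <- TRUE

  keep_internal <- setdiff(ntip + seq_len(tree$Nnode), flagged_nodes)
  new_id <- integer(ntip + tree$Nnode)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[keep_internal] <- ntip + seq_along(keep_internal)

  new_edges <- list()
  new_lens <- numeric(0)
  for (v in c(seq_len(ntip), keep_internal)) {
    if (v == root) next
    p <- parent[v]
    len <- elen[v]
    while (flagged[p]) {
      len <- len + elen[p]
      p <- parent[p]
    }
    new_edges[[length(new_edges) + 1L]] <- c(new_id[p], new_id[v])
    new_lens <- c(new_lens, len)
  }

  out <- list(edge = do.call(rbind, new_edges),
              tip.label = tree$tip.label,
              Nnode = length(keep_internal))
  if (!is.null(tree$edge.length)) out$edge.length <- new_lens
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[keep_internal - ntip]
  }
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  attr(out, "rooted") <- TRUE
  out
}

#' Propagate reference annotations through unanimous clades
#'
#' For each query tip, walks its ancestors from the tip toward the root and
#' stops at the first (most recent) ancestor whose clade contains at least
#' one reference tip annotated for the requested field. If every annotated
#' reference in that clade carries the same value, the query is assigned
#' that value; otherwise it is left unassigned. References lacking an
#' annotation for the field are ignored (they neither assign nor break
#' unanimity). Queries none of whose ancestors contain an annotated
#' reference are unassigned.
#'
#' @param tree A rooted `ape::phylo`.
#' @param annotations Tibble with columns `tip`, `class`
#'   (`reference`/`query`), and the annotation field(s) (e.g. `taxon`,
#'   `host`); tips absent from the table are treated as queries.
#' @param field Which annotation field to propagate.
#' @return Tibble: tip, assignment (NA = unassigned), clade_size (tips in
#'   the assigning clade), n_ref (annotated references supporting the
#'   assignment).
#' @export
propagate_annotations <- function(tree, annotations, field = c("taxon", "host")) {
  stopifnot(inherits(tree, "phylo"))
  field <- match.arg(field)
  if (!is_rooted_tree(tree)) abort_parameter("tree must be rooted")
  check_columns(annotations, c("tip", "class"), "annotations")
  if (!field %in% names(annotations)) {
    abort_schema(sprintf("annotations lack a `%s` column", field))
  }

  ntip <- ape::Ntip(tree)
  labels <- tree$tip.label
  ann <- annotations[match(labels, annotations$tip), ]
  is_ref <- !is.na(ann$class) & ann$class == "reference"
  value <- ifelse(is_ref, ann[[field]], NA_character_)
  if (!any(is_ref & !is.na(value))) {
    abort_parameter(sprintf(
      "no reference tip is annotated for field `%s`", field))
  }

  parent <- parent_vector(tree)
  sets <- node_tip_sets(tree)
  queries <- which(!is_ref)

  res <- purrr::map(queries, function(q) {
    node <- parent[q]
    repeat {
      vals <- value[sets[[node]]]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) {
        u <- unique(vals)
        return(tibble(tip = labels[q],
                      assignment = if (length(u) == 1) u else NA_character_,
                      clade_size = length(sets[[node]]),
                      n_ref = if (length(u) == 1) length(vals) else 0L))
      }
      if (node == ntip + 1L) break
      node <- parent[node]
    }
    tibble(tip = labels[q], assignment = NA_character_,
           clade_size = NA_integer_, n_ref = 0L)
  })
  bind_rows(res)
}

#' Propagate tree-tip assignments to cluster members
#'
#' Every member of a cluster inherits the assignment of its representative
#' (the member that was placed on the tree) verbatim. Representatives
#' missing from the assignment table yield unassigned members with a
#' warning; a member listed under two representatives violates the cluster
#' partition and is an error.
#'
#' @param assignments Output of [propagate_annotations()] (columns tip,
#'   assignment).
#' @param clusters Tibble with `representative_id` and `member_id`.
#' @return Tibble: member_id, representative_id, assignment.
#' @export
propagate_to_cluster_members <- function(assignments, clusters) {
  check_columns(assignments, c("tip", "assignment"), "assignments")
  check_columns(clusters, c("representative_id", "member_id"), "clusters")
  dup <- clusters |>
    distinct(.data$representative_id, .data$member_id) |>
    dplyr::count(.data$member_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_schema(sprintf("member(s) listed under multiple representatives: %s",
                         paste(head(dup$member_id, 5), collapse = ", ")))
  }
  missing_rep <- setdiff(unique(clusters$representative_id), assignments$tip)
  if (length(missing_rep) > 0) {
    warn(sprintf("%d representative(s) absent from assignments; their members are unassigned",
                 length(missing_rep)))
  }
  clusters |>
    left_join(assignments[, c("tip", "assignment")],
              by = c(representative_id = "tip")) |>
    select("member_id", "representative_id", "assignment")
}
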