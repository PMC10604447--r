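## Independent brute-force oracles used across tests. These deliberately
## avoid sharing code paths with the package implementations.

## Per-base coverage counter: loop over placements and positions.
brute_coverage <- function(placements, len, library, contig) {
  dp <- integer(len); dm <- integer(len)
  sel <- placements$library_id == library & placements$contig_id == contig
  for (i in which(sel)) {
    pos <- placements$start[i]:placements$end[i]
    if (placements$strand[i] == "+") dp[pos] <- dp[pos] + 1L
    else dm[pos] <- dm[pos] + 1L
  }
  list(plus = dp, minus = dm)
}

## Greedy clustering oracle: direct restatement of the rule with
## data-frame scans instead of hashed lookups.
brute_greedy <- function(records, contigs, min_ani = 95, min_af = 85) {
  ord <- contigs[order(-contigs$length, contigs$contig_id), ]
  find_rec <- function(a, b) {
    i <- which((records$query == a & records$target == b) |
                 (records$query == b & records$target == a))
    if (length(i) == 0) return(NULL)
    records[i[1], ]
  }
  len <- setNames(ord$length, ord$contig_id)
  seeds <- character(0)
  rep_of <- character(0)
  for (id in ord$contig_id) {
    assigned <- NA_character_
    for (s in seeds) {
      r <- find_rec(id, s)
      if (is.null(r)) next
      af_short <- if (len[[id]] < len[[s]]) {
        if (r$query == id) r$af_query else r$af_target
      } else if (len[[s]] < len[[id]]) {
        if (r$query == s) r$af_query else r$af_target
      } else {
        max(r$af_query, r$af_target)
      }
      if (r$ani >= min_ani && af_short >= min_af) {
        assigned <- s
        break
      }
    }
    if (is.na(assigned)) {
      seeds <- c(seeds, id)
      rep_of[id] <- id
    } else {
      rep_of[id] <- assigned
    }
  }
  rep_of
}

## Random symmetric alignment-record tables for clustering tests.
random_records <- function(ids) {
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.5
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(query = character(0), target = character(0),
                          ani = numeric(0), af_query = numeric(0),
                          af_target = numeric(0)))
  }
  tibble::tibble(query = pairs[, 1], target = pairs[, 2],
                 ani = stats::runif(nrow(pairs), 85, 100),
                 af_query = stats::runif(nrow(pairs), 50, 100),
                 af_target = stats::runif(nrow(pairs), 50, 100))
}

## Exhaustive clade-enumeration oracle for annotation propagation: tip
## sets computed by climbing from every tip, candidate clades ranked by
## size.
brute_propagate <- function(tree, annotations, field) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tipsets <- vector("list", ntip + nnode)
  for (tip in seq_len(ntip)) {
    node <- tip
    while (node != 0) {
      if (node > ntip) tipsets[[node]] <- c(tipsets[[node]], tip)
      node <- parent[node]
    }
  }
  ann <- annotations[match(tree$tip.label, annotations$tip), ]
  ref_val <- ifelse(!is.na(ann$class) & ann$class == "reference",
                    ann[[field]], NA_character_)
  out <- list()
  for (tip in seq_len(ntip)) {
    if (!is.na(ann$class[tip]) && ann$class[tip] == "reference") next
    cands <- which(vapply(seq_len(ntip + nnode), function(nd) {
      nd > ntip && tip %in% tipsets[[nd]] &&
        any(!is.na(ref_val[tipsets[[nd]]]))
    }, logical(1)))
    if (length(cands) == 0) {
      out[[length(out) + 1]] <- tibble::tibble(tip = tree$tip.label[tip],
                                               assignment = NA_character_)
      next
    }
    best <- cands[which.min(lengths(tipsets[cands]))]
    vals <- unique(stats::na.omit(ref_val[tipsets[[best]]]))
    out[[length(out) + 1]] <- tibble::tibble(
      tip = tree$tip.label[tip],
      assignment = if (length(vals) == 1) vals else NA_character_)
  }
  dplyr::bind_rows(out)
}

## Random annotated tree (not clade-structured): arbitrary reference
## placement, several taxa, for adversarial propagation tests.
random_annotated_tree <- function(ntip, n_taxa = 3, ref_prob = 0.4,
                                  na_prob = 0.2) {
  tree <- ape::rtree(ntip)
  is_ref <- stats::runif(ntip) < ref_prob
  if (!any(is_ref)) is_ref[sample(ntip, 1)] <- TRUE
  taxon <- ifelse(is_ref,
                  sprintf("T%d", sample(n_taxa, ntip, replace = TRUE)),
                  NA_character_)
  taxon[is_ref & stats::runif(ntip) < na_prob] <- NA_character_
  if (all(is.na(taxon))) taxon[which(is_ref)[1]] <- "T1"
  ann <- tibble::tibble(tip = tree$tip.label,
                        class = ifelse(is_ref, "reference", "query"),
                        taxon = taxon)
  list(tree = tree, annotations = ann)
}

## Small default community for classifier tests.
small_design <- function(replicates = 1) {
  community_design(depths = "0-5cm", locations = "upslope",
                   replicates = replicates)
}

truth_expectation <- function(truth) {
  dplyr::transmute(truth$schedule, votu_id = votu_id, month = month,
                   expect = ifelse(status == "inactive",
                                   "present-inactive", status))
}

## Full classification chain from placements to month-level calls.
classify_chain <- function(sim, truth, pl, design) {
  cov <- accumulate_coverage(pl$placements,
                             sim$genomes[, c("contig_id", "length")])
  expr <- call_expressed_genes(cov, sim$genes, pl$libraries)
  dna <- truth$votus[truth$votus$molecule == "DNA", ]
  rna <- truth$votus[truth$votus$molecule == "ssRNA", ]
  calls <- dplyr::bind_rows(
    classify_dna_activity(expr, cov, dna, sim$genes, pl$libraries,
                          design$samples)[, c("votu_id", "sample_id",
                                              "molecule", "status")],
    classify_rna_activity(cov, rna, pl$libraries, design$samples))
  aggregate_by_month(calls, design$samples)
}

## Fixed 6-tip tree with an explicit, hand-written branch table used as an
## independent enumeration oracle.
fixed_tree <- function() {
  ape::read.tree(text = "(((A:1,B:2):1,C:3):1,((D:1,E:1):2,F:1):1);")
}
fixed_branches <- list(
  list(len = 1, tips = "A"), list(len = 2, tips = "B"),
  list(len = 1, tips = c("A", "B")), list(len = 3, tips = "C"),
  list(len = 1, tips = c("A", "B", "C")),
  list(len = 1, tips = "D"), list(len = 1, tips = "E"),
  list(len = 2, tips = c("D", "E")), list(len = 1, tips = "F"),
  list(len = 1, tips = c("D", "E", "F")))

oracle_unifrac <- function(x, y, alpha, mode) {
  px <- x / sum(x); py <- y / sum(y)
  num <- 0; den <- 0
  for (b in fixed_branches) {
    p <- sum(px[b$tips]); q <- sum(py[b$tips])
    if (mode == "unweighted") {
      if ((p > 0) != (q > 0)) num <- num + b$len
      if (p > 0 || q > 0) den <- den + b$len
    } else if (p + q > 0) {
      w <- b$len * (p + q)^alpha
      num <- num + w * abs(p - q) / (p + q)
      den <- den + w
    }
  }
  num / den
}

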