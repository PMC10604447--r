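#' Retention filter for predicted viral contigs
#'
#' Keeps contigs that are at least `min_len` bp long or estimated to be at
#' least `min_completeness` percent complete. An unknown (`NA`) completeness
#' estimate fails the completeness clause, so short contigs without an
#' estimate are dropped.
#'
#' @param contigs Tibble with columns `contig_id`, `length`, and
#'   `completeness` (percent, may be `NA`).
#' @param min_len Minimum length in bp (default 5000).
#' @param min_completeness Minimum completeness percent (default 50).
#' @return The retained rows of `contigs`.
#' @export
#' @examples
#' contigs <- tibble::tibble(contig_id = c("a", "b", "c"),
#'                           length = c(6000, 3000, 3000),
#'                           completeness = c(NA, 60, NA))
#' retention_filter(contigs)$contig_id  # "a" and "b"
retention_filter <- function(contigs, min_len = 5000, min_completeness = 50) {
  check_columns(contigs, c("contig_id", "length", "completeness"), "contigs")
  filter(contigs,
         .data$length >= min_len |
           (!is.na(.data$completeness) &
              .data$completeness >= min_completeness))
}

#' Drop contigs annotated only as insertion-sequence elements
#'
#' Optional catalog cleanup: removes contigs whose gene annotations either
#' all match insertion-sequence keywords or are entirely missing. Off by
#' default in the pipeline.
#'
#' @param contigs Tibble with `contig_id`.
#' @param annotations Tibble with `contig_id` and free-text `annotation`
#'   per gene (`NA` = unannotated).
#' @param keywords Case-insensitive keywords marking insertion-sequence
#'   genes.
#' @return Rows of `contigs` that survive.
#' @export
filter_is_elements <- function(contigs, annotations,
                               keywords = c("transposase",
                                            "insertion sequence",
                                            "insertion element")) {
  check_columns(annotations, c("contig_id", "annotation"), "annotations")
  pattern <- paste(keywords, collapse = "|")
  flag <- annotations |>
    group_by(.data$contig_id) |>
    summarise(drop = all(is.na(.data$annotation)) ||
                all(!is.na(.data$annotation) &
                      stringr::str_detect(tolower(.data$annotation),
                                          tolower(pattern))))
  drop_ids <- flag$contig_id[flag$drop]
  filter(contigs, !.data$contig_id %in% drop_ids)
}

## --- k-mer seeded fragment aligner --------------------------------------
## Exact k-mer seeds chained per diagonal with ungapped end extension;
## mismatches inside a chained span are counted against identity. Intended
## for desk-scale catalogs; precomputed alignment records from an external
## aligner can be supplied to greedy_cluster() instead.

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  split(seq_len(n - k + 1), kmers)
}

## Precompute everything a sequence contributes to pairwise alignment:
## character vectors and k-mer strings for both orientations plus the
## forward k-mer position index.
ani_prep <- function(seq, k) {
  n <- nchar(seq)
  rc <- revcomp(seq)
  list(n = n,
       chars = strsplit(seq, "", fixed = TRUE)[[1]],
       rc_chars = strsplit(rc, "", fixed = TRUE)[[1]],
       kmers = if (n >= k) substring(seq, 1:(n - k + 1), k:n) else character(0),
       rc_kmers = if (n >= k) substring(rc, 1:(n - k + 1), k:n) else character(0),
       idx = kmer_positions(seq, k))
}

## Core fragment finder over prepped sequences; returns the record tibble.
ani_align_prepped <- function(query_id, target_id, pa, pb, k, max_gap,
                              min_fragment_identity) {
  empty <- tibble(query = character(0), target = character(0),
                  ani = numeric(0), af_query = numeric(0),
                  af_target = numeric(0), aligned_length = numeric(0))
  frags <- list()
  for (orient in c("fwd", "rev")) {
    kb <- if (orient == "fwd") pb$kmers else pb$rc_kmers
    chars_b <- if (orient == "fwd") pb$chars else pb$rc_chars
    if (length(kb) == 0) next
    hit <- pa$idx[kb]
    keep <- lengths(hit) > 0
    if (!any(keep)) next
    posb <- rep.int(which(keep), lengths(hit[keep]))
    posa <- unlist(hit[keep], use.names = FALSE)
    fr <- chain_fragments(pa$chars, chars_b, posa, posb, k, max_gap)
    if (length(fr) > 0 && orient == "rev") {
      fr <- purrr::map(fr, function(f) {
        b1 <- f[["b1"]]; b2 <- f[["b2"]]
        f[["b1"]] <- pb$n - b2 + 1L
        f[["b2"]] <- pb$n - b1 + 1L
        f
      })
    }
    frags <- c(frags, fr)
  }
  if (length(frags) == 0) return(empty)
  fm <- do.call(rbind, frags)
  fm <- fm[fm[, "id"] * 100 >= min_fragment_identity &
             fm[, "len"] >= k, , drop = FALSE]
  if (nrow(fm) == 0) return(empty)
  af_q <- merged_coverage(fm[, "a1"], fm[, "a2"], pa$n)
  af_t <- merged_coverage(fm[, "b1"], fm[, "b2"], pb$n)
  tibble(query = query_id, target = target_id,
         ani = 100 * sum(fm[, "id"] * fm[, "len"]) / sum(fm[, "len"]),
         af_query = af_q, af_target = af_t,
         aligned_length = sum(fm[, "len"]))
}

## fragments between chars_a and chars_b (character vectors) given seed hit
## positions (pa, pb on the same diagonal set)
chain_fragments <- function(chars_a, chars_b, pa, pb, k, max_gap) {
  diag <- pb - pa
  out <- list()
  for (d in unique(diag)) {
    ps <- sort(pa[diag == d])
    brk <- c(0L, which(diff(ps) > max_gap), length(ps))
    for (j in seq_len(length(brk) - 1L)) {
      seg <- ps[(brk[j] + 1L):brk[j + 1L]]
      a1 <- seg[1]; a2 <- seg[length(seg)] + k - 1L
      b1 <- a1 + d
      ## ungapped extension
      while (a1 > 1L && b1 > 1L && chars_a[a1 - 1L] == chars_b[b1 - 1L]) {
        a1 <- a1 - 1L; b1 <- b1 - 1L
      }
      b2 <- a2 + d
      while (a2 < length(chars_a) && b2 < length(chars_b) &&
             chars_a[a2 + 1L] == chars_b[b2 + 1L]) {
        a2 <- a2 + 1L; b2 <- b2 + 1L
      }
      len <- a2 - a1 + 1L
      ident <- mean(chars_a[a1:a2] == chars_b[(a1:a2) + d])
      out[[length(out) + 1L]] <- c(a1 = a1, a2 = a2, b1 = a1 + d,
                                   b2 = a2 + d, len = len, id = ident)
    }
  }
  out
}

merged_coverage <- function(starts, ends, total_len) {
  if (length(starts) == 0) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  covered <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      covered <- covered + (cur_e - cur_s + 1)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  covered <- covered + (cur_e - cur_s + 1)
  100 * covered / total_len
}

#' Pairwise ANI and aligned fractions between two sequences
#'
#' Finds local alignment fragments between two nucleotide sequences (both
#' orientations of the second sequence are scanned), merges overlapping
#' fragments per sequence, and reports the alignment-length-weighted mean
#' percent identity (ANI) together with the aligned fraction (AF) of each
#' sequence. Fragments below `min_fragment_identity` or shorter than `k`
#' are discarded; if nothing remains, a zero-row tibble is returned (no
#' shared seed means the pair is treated as ANI 0 downstream).
#'
#' @param query_id,target_id Sequence identifiers for the output record.
#' @param query,target Nucleotide sequence strings.
#' @param k Seed k-mer size.
#' @param max_gap Maximum gap (bp) between chained seeds on a diagonal.
#' @param min_fragment_identity Reporting floor for fragment identity
#'   (percent).
#' @return Tibble with columns query, target, ani, af_query, af_target,
#'   aligned_length; zero rows when no fragment is found.
#' @export
pairwise_ani <- function(query_id, target_id, query, target,
                         k = 11, max_gap = 100, min_fragment_identity = 70) {
  if (nchar(query) == 0 || nchar(target) == 0) {
    abort_parameter("sequences must be non-empty")
  }
  ani_align_prepped(query_id, target_id,
                    ani_prep(query, k), ani_prep(target, k),
                    k, max_gap, min_fragment_identity)
}

#' All-vs-all alignment records for a contig set
#'
#' Runs [pairwise_ani()] over every unordered pair (optionally restricted to
#' pairs of the same molecule type); each pair appears once with the
#' lexicographically smaller id as query.
#'
#' @param contigs Tibble with `contig_id`, `sequence`, and optionally
#'   `molecule`.
#' @param same_molecule_only Skip DNA-vs-ssRNA pairs (they share no
#'   homology by construction in the simulator).
#' @inheritParams pairwise_ani
#' @return Tibble of alignment records (possibly zero rows).
#' @export
ani_table <- function(contigs, k = 11, max_gap = 100,
                      min_fragment_identity = 70,
                      same_molecule_only = TRUE) {
  check_columns(contigs, c("contig_id", "sequence"), "contigs")
  n <- nrow(contigs)
  if (n < 2) return(pairwise_ani("x", "y", "ACGTACGTACGTACGT",
                                 "TTTTTTTTTTTTTTTT")[0, ])
  ids <- contigs$contig_id
  o <- order(ids)
  contigs <- contigs[o, ]
  ids <- contigs$contig_id
  mol <- if ("molecule" %in% names(contigs)) contigs$molecule else
    rep("DNA", n)
  preps <- purrr::map(contigs$sequence, ani_prep, k = k)
  recs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (same_molecule_only && mol[i] != mol[j]) next
      r <- ani_align_prepped(ids[i], ids[j], preps[[i]], preps[[j]],
                             k, max_gap, min_fragment_identity)
      if (nrow(r) > 0) recs[[length(recs) + 1]] <- r
    }
  }
  if (length(recs) == 0) return(pairwise_ani("x", "y", "ACGTACGTACGTACGT",
                                             "TTTTTTTTTTTTTTTT")[0, ])
  bind_rows(recs)
}

#' Greedy ANI/AF clustering of contigs into vOTUs
#'
#' Contigs are ordered by decreasing length (ties broken by lexicographic
#' id). Each contig joins the first earlier seed with ANI >= `min_ani` and
#' aligned fraction of the shorter sequence >= `min_af`; otherwise it seeds
#' a new vOTU. The seed is the representative, so representatives are
#' always longest members.
#'
#' @param records Alignment records as from [ani_table()] (columns query,
#'   target, ani, af_query, af_target); each unordered pair at most once.
#' @param contigs Tibble with `contig_id` and `length` covering every id in
#'   `records`.
#' @param min_ani Minimum percent identity (default 95).
#' @param min_af Minimum aligned fraction of the shorter sequence (default
#'   85).
#' @return Tibble (votu_id, representative_id, member_id); members
#'   partition the input contigs.
#' @export
greedy_cluster <- function(records, contigs, min_ani = 95, min_af = 85) {
  check_columns(contigs, c("contig_id", "length"), "contigs")
  if (nrow(records) > 0) {
    check_columns(records, c("query", "target", "ani", "af_query",
                             "af_target"), "records")
    unknown <- setdiff(unique(c(records$query, records$target)),
                       contigs$contig_id)
    if (length(unknown) > 0) {
      abort_schema(sprintf("alignment records reference unknown contig(s): %s",
                           paste(head(unknown, 5), collapse = ", ")))
    }
  }

  ord <- contigs |>
    arrange(dplyr::desc(.data$length), .data$contig_id)
  len_of <- setNames(ord$length, ord$contig_id)

  ## symmetric lookup: key -> (ani, af of the shorter member of the pair)
  rec_env <- new.env(parent = emptyenv(), size = max(16L, nrow(records) * 2L))
  if (nrow(records) > 0) {
    for (i in seq_len(nrow(records))) {
      q <- records$query[i]; t <- records$target[i]
      lq <- len_of[[q]]; lt <- len_of[[t]]
      af_short <- if (lq < lt) records$af_query[i]
        else if (lt < lq) records$af_target[i]
        else max(records$af_query[i], records$af_target[i])
      assign(paste(sort(c(q, t)), collapse = "\r"),
             c(records$ani[i], af_short), envir = rec_env)
    }
  }

  seeds <- character(0)
  assignment <- character(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    id <- ord$contig_id[i]
    hit <- NA_character_
    for (s in seeds) {
      key <- paste(sort(c(id, s)), collapse = "\r")
      v <- rec_env[[key]]
      if (!is.null(v) && v[1] >= min_ani && v[2] >= min_af) {
        hit <- s
        break
      }
    }
    if (is.na(hit)) {
      seeds <- c(seeds, id)
      assignment[i] <- id
    } else {
      assignment[i] <- hit
    }
  }

  votu_ids <- setNames(sprintf("vOTU_%04d", seq_along(seeds)), seeds)
  tibble(votu_id = unname(votu_ids[assignment]),
         representative_id = assignment,
         member_id = ord$contig_id) |>
    arrange(.data$votu_id, .data$member_id)
}
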