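GENE_CATEGORIES <- c("virion-structure", "encapsidation", "lysis",
                     "replication", "lysogeny", "unknown")

#' Simulate viral genomes with gene annotations
#'
#' Generates random viral contigs (DNA or positive-sense ssRNA), a gene
#' complement with functional-category labels, and per-contig completeness
#' estimates. Optionally plants mutated, truncated near-duplicates of some
#' genomes so that downstream ANI/AF clustering has real work to do; the
#' duplicates are always shorter than their source, which keeps the source
#' as the longest (hence representative) member of its cluster.
#'
#' Genes are laid out in non-overlapping blocks, so coordinates never
#' overlap on either strand. ssRNA genomes carry all genes on the genome
#' (plus) strand, reflecting positive-sense coding.
#'
#' @param n Number of primary genomes (>= 1).
#' @param length_range Two-element numeric, genome length bounds in bp;
#'   must lie within \[1000, 200000\].
#' @param gene_density Genes per kbp (> 0); each genome gets
#'   `max(1, round(length/1000 * gene_density))` genes.
#' @param rna_fraction Probability that a genome is ssRNA.
#' @param duplicate_fraction Fraction of genomes that receive one mutated
#'   truncated near-duplicate contig (ANI ~ 97-99, AF of the duplicate 100).
#' @param completeness_na_fraction Fraction of contigs whose completeness
#'   estimate is unknown (`NA`).
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return List of class `virome_genomes`: `genomes` tibble (contig_id,
#'   molecule, length, completeness, is_duplicate, source_id, sequence) and
#'   `genes` tibble (gene_id, contig_id, start, end, strand, category).
#'   Coordinates are 1-based inclusive.
#' @export
#' @examples
#' sim <- sim_genomes(n = 3, length_range = c(5000, 8000), seed = 1)
#' sim$genomes[, 1:4]
sim_genomes <- function(n,
                        length_range = c(5000, 30000),
                        gene_density = 1,
                        rna_fraction = 0.3,
                        duplicate_fraction = 0,
                        completeness_na_fraction = 0.3,
                        seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  if (length(length_range) != 2 || any(!is.finite(length_range)) ||
      length_range[1] > length_range[2] ||
      length_range[1] < 1000 || length_range[2] > 200000) {
    abort_parameter("`length_range` must be two values within [1000, 200000]")
  }
  check_scalar_number(gene_density, "gene_density", lower = 1e-6)
  check_scalar_number(rna_fraction, "rna_fraction", lower = 0, upper = 1)
  check_scalar_number(duplicate_fraction, "duplicate_fraction", 0, 1)
  set_seed_if(seed)

  n <- as.integer(n)
  lens <- as.integer(length_range[1] +
                       floor(runif(n) *
                               (length_range[2] - length_range[1] + 1)))
  molecule <- ifelse(rbinom(n, 1, rna_fraction) == 1, "ssRNA", "DNA")
  ids <- sprintf("contig_%04d", seq_len(n))
  seqs <- vapply(lens, random_seq, character(1))
  completeness <- round(runif(n, 50, 100), 1)
  completeness[runif(n) < completeness_na_fraction] <- NA_real_

  genomes <- tibble(contig_id = ids, molecule = molecule, length = lens,
                    completeness = completeness,
                    is_duplicate = FALSE, source_id = NA_character_,
                    sequence = seqs)

  genes <- purrr::map2(ids, seq_len(n), function(id, i) {
    len <- lens[i]
    n_genes <- max(1L, as.integer(round(len / 1000 * gene_density)))
    block <- as.integer(floor(len / n_genes))
    g_len <- as.integer(floor(block * runif(n_genes, 0.6, 0.9)))
    g_len <- pmax(30L, pmin(g_len, block - 2L))
    offset <- as.integer(floor(runif(n_genes, 0, pmax(1, block - g_len))))
    start <- (seq_len(n_genes) - 1L) * block + offset + 1L
    end <- pmin(start + g_len - 1L, len)
    strand <- if (molecule[i] == "ssRNA") rep("+", n_genes) else
      sample(c("+", "-"), n_genes, replace = TRUE)
    tibble(gene_id = sprintf("%s_g%02d", id, seq_len(n_genes)),
           contig_id = id, start = start, end = end, strand = strand,
           category = sample(GENE_CATEGORIES, n_genes, replace = TRUE,
                             prob = c(0.12, 0.08, 0.10, 0.20, 0.10, 0.40)))
  }) |> bind_rows()

  if (duplicate_fraction > 0) {
    n_dup <- as.integer(round(n * duplicate_fraction))
    if (n_dup > 0) {
      src <- sample(ids, n_dup)
      dups <- purrr::map(src, function(s) {
        row <- genomes[genomes$contig_id == s, ]
        keep <- as.integer(floor(row$length * runif(1, 0.86, 0.95)))
        sq <- substr(row$sequence, 1, keep)
        ## ~1.5% point mutations: ANI stays well above the 95% threshold
        n_mut <- as.integer(ceiling(keep * 0.015))
        pos <- sample(keep, n_mut)
        chars <- strsplit(sq, "", fixed = TRUE)[[1]]
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        tibble(contig_id = paste0(s, "_dup"), molecule = row$molecule,
               length = keep,
               completeness = round(runif(1, 40, 90), 1),
               is_duplicate = TRUE, source_id = s,
               sequence = paste(chars, collapse = ""))
      }) |> bind_rows()
      genomes <- bind_rows(genomes, dups)
    }
  }

  structure(list(genomes = genomes, genes = genes), class = "virome_genomes")
}

#' @export
print.virome_genomes <- function(x, ...) {
  cat(sprintf("<virome_genomes> %d contigs (%d DNA, %d ssRNA, %d duplicates), %d genes\n",
              nrow(x$genomes), sum(x$genomes$molecule == "DNA"),
              sum(x$genomes$molecule == "ssRNA"),
              sum(x$genomes$is_duplicate), nrow(x$genes)))
  invisible(x)
}
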