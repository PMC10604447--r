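## File-format interfaces. Standard formats go through the standard
## packages (Biostrings, rtracklayer, Rsamtools, ape); the placement TSV
## dialect and the small metadata tables are plain readr TSVs.

#' Read and write the placement TSV dialect
#'
#' Placements are tab-separated with a mandatory header line and columns
#' read_id, contig_id, start, end, strand, library_id (1-based inclusive
#' coordinates, strand `+`/`-`).
#'
#' @param path File path.
#' @return A placements tibble.
#' @export
read_placements_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    contig_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    library_id = readr::col_character()))
  check_columns(df, c("read_id", "contig_id", "start", "end", "strand",
                      "library_id"), "placements")
  df
}

#' @rdname read_placements_tsv
#' @param placements A placements tibble.
#' @export
write_placements_tsv <- function(placements, path) {
  readr::write_tsv(placements, path)
  invisible(path)
}

#' Read read placements from a BAM file
#'
#' Converts primary alignments to the placement tibble, resolving the
#' strandedness protocol of the library: with `stranded_protocol = "rf"`
#' (dUTP-style, read 1 antisense to the transcript) the alignment strand
#' of read 1 (and of unpaired reads) is flipped to the coding-strand
#' sense, while read 2 keeps its alignment strand; `"fr"` is the mirror
#' image; `"unstranded"` keeps alignment strands as-is (appropriate for
#' metagenome libraries). Alignment end is `pos + qwidth - 1` (indel-free
#' span approximation).
#'
#' @param path BAM file path.
#' @param library_id Library identifier to stamp on the records.
#' @param stranded_protocol `"unstranded"`, `"rf"`, or `"fr"`.
#' @return A placements tibble.
#' @export
read_placements_bam <- function(path, library_id,
                                stranded_protocol = c("unstranded", "rf", "fr")) {
  stranded_protocol <- match.arg(stranded_protocol)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort_parameter("Rsamtools is required to read BAM files")
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "flag"),
    flag = flags)
  b <- Rsamtools::scanBam(path, param = par)[[1]]
  strand <- as.character(b$strand)
  if (stranded_protocol != "unstranded") {
    first <- bitwAnd(b$flag, 128L) == 0L   # read 1 or unpaired
    flip <- if (stranded_protocol == "rf") first else !first
    strand[flip] <- ifelse(strand[flip] == "+", "-", "+")
  }
  tibble(read_id = b$qname,
         contig_id = as.character(b$rname),
         start = b$pos,
         end = b$pos + b$qwidth - 1L,
         strand = strand,
         library_id = library_id)
}

#' Write genomes to FASTA (with a completeness side table)
#'
#' @param genomes Tibble with contig_id, sequence, and optionally
#'   molecule/completeness.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genomes_fasta <- function(genomes, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_parameter("Biostrings is required for FASTA output")
  }
  ## ssRNA genomes are represented as their cDNA for catalog purposes
  x <- Biostrings::DNAStringSet(setNames(genomes$sequence,
                                         genomes$contig_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genomes_fasta
#' @export
read_genomes_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_parameter("Biostrings is required for FASTA input")
  }
  x <- Biostrings::readDNAStringSet(path)
  tibble(contig_id = names(x),
         length = Biostrings::width(x),
         sequence = unname(as.character(x)))
}

#' Write and read gene features as GFF3
#'
#' Gene coordinates are 1-based inclusive; strand goes in column 7 and the
#' functional category travels in the attributes as `category=`.
#'
#' @param genes Tibble: gene_id, contig_id, start, end, strand, category.
#' @param path GFF3 path.
#' @return `path` / a genes tibble.
#' @export
write_genes_gff3 <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort_parameter("rtracklayer is required for GFF3 output")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$category <- genes$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort_parameter("rtracklayer is required for GFF3 input")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(gene_id = gr$ID,
         contig_id = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         category = if (!is.null(gr$category)) gr$category
                    else NA_character_)
}

#' Read a reference annotation table for a phylogeny
#'
#' Tab-separated with header: tip, class (reference/query), and optional
#' taxon, host, dataset columns.
#'
#' @param path TSV path.
#' @return Annotation tibble.
#' @export
read_tree_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  check_columns(df, c("tip", "class"), "tree annotations")
  df
}
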