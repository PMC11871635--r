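# Gene-model input: GTF gene records (via rtracklayer) or a BED6 of
# TSS-anchored gene bodies. Internally a gene is a GRanges row with gene_id,
# symbol and the absolute 1-based TSS coordinate (start on +, end on -).

gene_granges <- function(chrom, start, end, strand, gene_id, symbol) {
  strand <- as.character(strand)
  strand[!strand %in% c("+", "-")] <- "+"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    gene_id = gene_id, symbol = symbol)
  gr$tss <- ifelse(strand == "-", GenomicRanges::end(gr),
                   GenomicRanges::start(gr))
  sorted_granges(gr)
}

#' Read gene models from a GTF file
#'
#' Keeps records of the requested feature type and converts GTF 1-based
#' inclusive coordinates to the internal representation. The TSS is the
#' 5' end of the gene body (start on the + strand, end on the - strand).
#'
#' @param path Path to a GTF file with `gene_id` (and optionally
#'   `gene_name`) attributes.
#' @param feature Feature type to keep (default `"gene"`).
#' @return A `GRanges` with metadata columns `gene_id`, `symbol`, `tss`.
#' @export
read_gtf_genes <- function(path, feature = "gene") {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[as.character(g$type) == feature]
  if (!length(g)) {
    stop(sprintf("no '%s' records in %s", feature, path), call. = FALSE)
  }
  if (is.null(g$gene_id) || anyNA(g$gene_id)) {
    stop("GTF records lack a gene_id attribute", call. = FALSE)
  }
  symbol <- g$gene_name
  if (is.null(symbol)) symbol <- g$gene_id
  symbol[is.na(symbol)] <- g$gene_id[is.na(symbol)]
  gene_granges(as.character(GenomicRanges::seqnames(g)),
               GenomicRanges::start(g), GenomicRanges::end(g),
               as.character(GenomicRanges::strand(g)),
               g$gene_id, symbol)
}

#' Read gene models from a BED6 file
#'
#' The BED name column is used as both gene id and symbol.
#' @param path Path to a BED6 file of gene bodies.
#' @return A `GRanges` with metadata columns `gene_id`, `symbol`, `tss`.
#' @export
read_genes_bed <- function(path) {
  f <- split_fields(path)
  nf <- lengths(f$parts)
  if (!length(f$parts) || any(nf < 6)) {
    stop("gene BED must have 6 columns", call. = FALSE)
  }
  co <- parse_coords(f$parts, f$lineno)
  gene_granges(field_col(f$parts, 1), co$start0 + 1L, co$end0,
               field_col(f$parts, 6),
               field_col(f$parts, 4), field_col(f$parts, 4))
}

#' Write gene models as GTF gene records
#' @param genes A `GRanges` as produced by [read_gtf_genes()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf_genes <- function(genes, path, source = "crcscan") {
  lines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
    as.character(GenomicRanges::seqnames(genes)), source,
    GenomicRanges::start(genes), GenomicRanges::end(genes),
    as.character(GenomicRanges::strand(genes)),
    genes$gene_id, genes$symbol)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Soft-masked lowercase bases are uppercased; duplicate sequence names are
#' an error. Names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence names in FASTA", call. = FALSE)
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a genome FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
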