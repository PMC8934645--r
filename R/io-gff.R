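#' Write annotations as GFF3 plus a protein FASTA
#'
#' @param genes a [genome_annotation()].
#' @param gff_path output GFF3 file.
#' @param fasta_path output protein FASTA; headers are gene ids. Written
#'   only for genes whose `protein_seq` is available.
#' @return Invisibly, `gff_path`.
#' @export
write_gff_fasta <- function(genes, gff_path, fasta_path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$product <- genes$product
  gr$protein_length <- genes$protein_length
  rtracklayer::export(gr, gff_path, format = "GFF3")
  has_seq <- !is.na(genes$protein_seq)
  aa <- Biostrings::AAStringSet(stats::setNames(genes$protein_seq[has_seq],
                                                genes$gene_id[has_seq]))
  Biostrings::writeXStringSet(aa, fasta_path)
  invisible(gff_path)
}

#' Read a GFF3 annotation together with its protein FASTA
#'
#' CDS (or gene) features are matched to FASTA records by their `ID`
#' attribute; an error lists any orphan ids present on one side only.
#'
#' @param gff_path GFF3 file with CDS features carrying `ID` attributes.
#' @param fasta_path protein FASTA whose headers are the feature ids.
#' @return A [genome_annotation()].
#' @export
read_gff_fasta <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type %in% c("CDS", "gene")]
  if (length(gr) == 0L) {
    stop("read_gff_fasta: no CDS/gene features in ", gff_path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  ids <- as.character(gr$ID)
  orphan_feats <- setdiff(ids, names(aa))
  orphan_seqs <- setdiff(names(aa), ids)
  if (length(orphan_feats) > 0L || length(orphan_seqs) > 0L) {
    stop("read_gff_fasta: ID mismatch between GFF3 and FASTA; ",
         "features without sequence: [",
         paste(orphan_feats, collapse = ", "),
         "]; sequences without feature: [",
         paste(orphan_seqs, collapse = ", "), "]", call. = FALSE)
  }
  seqs <- as.character(aa)[ids]
  genome_annotation(data.frame(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_length = nchar(seqs),
    product = if (!is.null(gr$product)) as.character(gr$product) else "",
    protein_seq = seqs,
    stringsAsFactors = FALSE), source = "gff3")
}
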