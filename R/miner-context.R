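#' Build the genomic neighborhood context of a gene
#'
#' Collects up to `window_genes` neighbors on each side of the focal gene
#' on its replicon, ordered by genomic distance. Neighbors separated from
#' the focal gene by more than `max_intergenic_bp` of intergenic sequence
#' are excluded; replicon edges simply truncate a side.
#'
#' @param gene_id focal gene.
#' @param genes a [genome_annotation()].
#' @param window_genes neighbors per side.
#' @param max_intergenic_bp maximum focal-to-neighbor intergenic gap.
#' @return A `neighborhood_context`: list with `focal` (the gene row) and
#'   `neighbors` (data.frame: `gene_id`, `side` upstream/downstream,
#'   `distance_rank`, `same_strand`, `intergenic_bp`).
#' @export
build_context <- function(gene_id, genes, window_genes = 1L,
                          max_intergenic_bp = 1000L) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("build_context: unknown gene ", gene_id, call. = FALSE)
  rep_idx <- which(genes$replicon_id == genes$replicon_id[i])
  pos <- match(i, rep_idx)  # rank of focal gene within its sorted replicon
  rows <- list()
  for (side in c("upstream", "downstream")) {
    step <- if (side == "upstream") -1L else 1L
    for (k in seq_len(window_genes)) {
      j_rank <- pos + step * k
      if (j_rank < 1L || j_rank > length(rep_idx)) break
      j <- rep_idx[j_rank]
      gap <- intergenic_gap(genes$start[i], genes$end[i],
                            genes$start[j], genes$end[j])
      if (gap > max_intergenic_bp) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[j], side = side, distance_rank = k,
        same_strand = genes$strand[j] == genes$strand[i],
        intergenic_bp = gap, stringsAsFactors = FALSE)
    }
  }
  neighbors <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene_id = character(), side = character(),
               distance_rank = integer(), same_strand = logical(),
               intergenic_bp = integer(), stringsAsFactors = FALSE)
  structure(list(focal = genes[i, , drop = FALSE], neighbors = neighbors),
            class = "neighborhood_context")
}

# bp of intergenic sequence between two non-overlapping gene intervals
intergenic_gap <- function(a_start, a_end, b_start, b_end) {
  if (b_start > a_end) return(b_start - a_end - 1L)
  if (a_start > b_end) return(a_start - b_end - 1L)
  0L  # overlapping features
}

# Vectorized neighbor table for a whole corpus: one row per
# (focal gene, neighbor) within the window and intergenic cutoff.
neighbor_table <- function(genes, window_genes = 1L,
                           max_intergenic_bp = 1000L) {
  parts <- list()
  n <- nrow(genes)
  for (k in seq_len(window_genes)) {
    for (step in c(-k, k)) {
      i <- seq_len(n)
      j <- i + step
      ok <- j >= 1L & j <= n
      i <- i[ok]; j <- j[ok]
      ok2 <- genes$replicon_id[i] == genes$replicon_id[j]
      i <- i[ok2]; j <- j[ok2]
      if (length(i) == 0L) next
      gap <- ifelse(genes$start[j] > genes$end[i],
                    genes$start[j] - genes$end[i] - 1L,
                    ifelse(genes$start[i] > genes$end[j],
                           genes$start[i] - genes$end[j] - 1L, 0L))
      keep <- gap <= max_intergenic_bp
      if (!any(keep)) next
      parts[[length(parts) + 1L]] <- data.frame(
        focal = genes$gene_id[i][keep],
        neighbor = genes$gene_id[j][keep],
        side = if (step < 0L) "upstream" else "downstream",
        distance_rank = k,
        same_strand = (genes$strand[i] == genes$strand[j])[keep],
        intergenic_bp = gap[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0L) {
    return(data.frame(focal = character(), neighbor = character(),
                      side = character(), distance_rank = integer(),
                      same_strand = logical(), intergenic_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, parts)
}
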