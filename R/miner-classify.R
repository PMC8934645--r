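#' Detect an Acr-Aca fusion architecture on a protein
#'
#' Calls a fusion when an Aca-family evidence interval lies entirely
#' within the terminal `terminal_fraction` of the protein (either end)
#' and the remaining portion — the putative Acr — is at least
#' `min_remainder_aa` long. The remainder is measured from the far edge
#' of the Aca interval to the opposite protein end.
#'
#' @param gene_id gene to examine.
#' @param genes a [genome_annotation()].
#' @param aca_intervals data.frame with columns `start`, `end` (aa,
#'   1-based inclusive) of Aca-family hit or domain intervals on this
#'   protein.
#' @param params a [miner_params()].
#' @return A one-row data.frame (`gene_id`, `terminal_side`,
#'   `aca_start`, `aca_end`, `acr_remainder_length`) or `NULL` when no
#'   interval satisfies the geometry.
#' @export
detect_fusion <- function(gene_id, genes, aca_intervals, params = miner_params()) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("detect_fusion: unknown gene ", gene_id, call. = FALSE)
  L <- genes$protein_length[i]
  if (is.null(aca_intervals) || nrow(aca_intervals) == 0L) return(NULL)
  term <- floor(params$terminal_fraction * L)
  aca_intervals <- aca_intervals[order(aca_intervals$start), , drop = FALSE]
  for (r in seq_len(nrow(aca_intervals))) {
    s <- aca_intervals$start[r]; e <- aca_intervals$end[r]
    if (is.na(s) || is.na(e) || s < 1L || e > L || e < s) next
    if (e <= term) {                     # N-terminal
      remainder <- L - e
      if (remainder >= params$min_remainder_aa) {
        return(data.frame(gene_id = gene_id, terminal_side = "N",
                          aca_start = s, aca_end = e,
                          acr_remainder_length = remainder,
                          stringsAsFactors = FALSE))
      }
    } else if (s >= L - term + 1L) {     # C-terminal
      remainder <- s - 1L
      if (remainder >= params$min_remainder_aa) {
        return(data.frame(gene_id = gene_id, terminal_side = "C",
                          aca_start = s, aca_end = e,
                          acr_remainder_length = remainder,
                          stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

#' Build the Aca-family to Acr-family association graph
#'
#' For every gene, records which distinct marker Acr families occur among
#' its same-strand neighbors within the window, aggregated per family of
#' the focal gene across all loci. Genes without any hit-derived family
#' label form singleton families keyed `gene:<id>`, so the association
#' criterion is defined for every gene in the corpus.
#'
#' @param genes a [genome_annotation()].
#' @param labels passing hit labels from [map_hits_to_genes()].
#' @param markers a [marker_set()]; only its Acr families count as
#'   associated types.
#' @param params a [miner_params()].
#' @return An `association_graph`: list with `pairs` (data.frame
#'   `family`, `acr_family`, `n_loci`) and `counts` (named integer of
#'   distinct associated Acr families per family).
#' @export
build_association_graph <- function(genes, labels, markers,
                                    params = miner_params()) {
  nbr <- neighbor_table(genes, params$window_genes, params$max_intergenic_bp)
  graph_from_neighbors(genes, nbr, labels, markers)
}

graph_from_neighbors <- function(genes, nbr, labels, markers) {
  acr_fams <- marker_families(markers, "acr")
  label_rel <- unique(labels[, c("gene_id", "family")])
  fam_of <- split(label_rel$family, label_rel$gene_id)
  gene_families <- function(id) {
    f <- fam_of[[id]]
    if (is.null(f) || length(f) == 0L) paste0("gene:", id) else f
  }
  pairs <- list()
  if (nrow(nbr) > 0L) {
    nbr_ss <- nbr[nbr$same_strand, , drop = FALSE]
    for (r in seq_len(nrow(nbr_ss))) {
      nfams <- intersect(fam_of[[nbr_ss$neighbor[r]]], acr_fams)
      if (length(nfams) == 0L) next
      for (ff in gene_families(nbr_ss$focal[r])) {
        for (g in nfams) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            family = ff, acr_family = g, locus = nbr_ss$focal[r],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(pairs) == 0L) {
    pr <- data.frame(family = character(), acr_family = character(),
                     n_loci = integer(), stringsAsFactors = FALSE)
    return(structure(list(pairs = pr, counts = integer(0)),
                     class = "association_graph"))
  }
  pp <- do.call(rbind, pairs)
  agg <- stats::aggregate(locus ~ family + acr_family, data = pp,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "n_loci"
  counts <- tapply(agg$acr_family, agg$family,
                   function(x) length(unique(x)))
  structure(list(pairs = agg,
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "association_graph")
}

association_count <- function(assoc, families) {
  if (length(families) == 0L) return(0L)
  hit <- assoc$counts[intersect(families, names(assoc$counts))]
  if (length(hit) == 0L) 0L else max(hit)
}

#' @export
print.association_graph <- function(x, ...) {
  cat(sprintf("association_graph: %d famil%s with recorded Acr neighbors\n",
              length(x$counts), if (length(x$counts) == 1L) "y" else "ies"))
  print(utils::head(x$pairs, 15L))
  invisible(x)
}
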