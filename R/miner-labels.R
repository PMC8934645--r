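#' Map homology hits onto genes as family labels
#'
#' A gene carries family label F if and only if it has at least one hit
#' to F with `evalue < evalue_max` and `query_coverage > coverage_min`
#' (both strict, exactly as the screening thresholds are printed).
#' Multiple labels per gene are allowed (the Acr-Aca fusion case). Hits
#' to gene ids absent from the annotation are skipped with one warning
#' reporting the count.
#'
#' @param hits hit table (see [read_hit_table()]).
#' @param genes a [genome_annotation()].
#' @param evalue_max,coverage_min strict thresholds.
#' @return data.frame of passing labels with columns `gene_id`, `family`,
#'   `subject_start`, `subject_end` (one row per passing hit; use
#'   `unique(labels[c("gene_id","family")])` for the label relation).
#' @export
map_hits_to_genes <- function(hits, genes, evalue_max = 1e-3,
                              coverage_min = 0.70) {
  empty <- data.frame(gene_id = character(), family = character(),
                      subject_start = integer(), subject_end = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  unknown <- !(hits$subject_gene_id %in% genes$gene_id)
  if (any(unknown)) {
    warning("map_hits_to_genes: skipped ", sum(unknown),
            " hit(s) to unknown gene ids", call. = FALSE)
    hits <- hits[!unknown, , drop = FALSE]
  }
  pass <- hits$evalue < evalue_max & hits$query_coverage > coverage_min
  hits <- hits[pass, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(gene_id = hits$subject_gene_id,
                    family = hits$query_family,
                    subject_start = hits$subject_start,
                    subject_end = hits$subject_end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# labels including marker member genes known directly (adopted singletons)
labels_with_members <- function(labels, markers, genes) {
  extra <- list()
  for (f in names(markers$members)) {
    ids <- intersect(markers$members[[f]], genes$gene_id)
    if (length(ids) > 0L) {
      extra[[f]] <- data.frame(gene_id = ids, family = f,
                               subject_start = NA_integer_,
                               subject_end = NA_integer_,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(extra) > 0L) labels <- rbind(labels, do.call(rbind, extra))
  labels[!duplicated(labels[, c("gene_id", "family", "subject_start",
                                "subject_end")]), , drop = FALSE]
}
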