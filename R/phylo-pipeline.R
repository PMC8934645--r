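#' Filter homolog hits for tree building
#'
#' Applies the homolog retention rule used for distance trees: E-value
#' strictly below `evalue_max`, query coverage strictly above
#' `coverage_min`, and pairwise sequence difference (1 - q against the
#' family seed) at most `max_difference`. The first two comparisons are
#' strict as printed; the difference bound is inclusive, so a pair at
#' exactly the maximum difference is retained.
#'
#' @param hits hit table (see [read_hit_table()]). If it has a `q`
#'   column, that identity fraction is used directly; otherwise q is
#'   computed by [align_pair()] between each subject sequence and the
#'   seed.
#' @param seqs named character vector of subject protein sequences
#'   (required unless `hits$q` is present).
#' @param seed_seq seed protein sequence the difference is measured
#'   against.
#' @param evalue_max,coverage_min,max_difference thresholds.
#' @param ... alignment options passed to [align_pair()].
#' @return The retained hit rows with added `q` and `difference`
#'   columns.
#' @export
filter_homologs <- function(hits, seqs = NULL, seed_seq = NULL,
                            evalue_max = 0.001, coverage_min = 0.70,
                            max_difference = 0.85, ...) {
  if (nrow(hits) == 0L) {
    hits$q <- numeric(0); hits$difference <- numeric(0)
    return(hits)
  }
  keep <- hits$evalue < evalue_max & hits$query_coverage > coverage_min
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$q <- numeric(0); hits$difference <- numeric(0)
    return(hits)
  }
  if (is.null(hits$q)) {
    if (is.null(seqs) || is.null(seed_seq)) {
      stop("filter_homologs: need seqs and seed_seq (or a q column) to ",
           "evaluate the maximum-difference filter", call. = FALSE)
    }
    hits$q <- vapply(hits$subject_gene_id, function(id) {
      if (!id %in% names(seqs)) {
        stop("filter_homologs: no sequence for subject ", id, call. = FALSE)
      }
      align_pair(seqs[[id]], seed_seq, ...)$q
    }, numeric(1))
  }
  hits$difference <- 1 - hits$q
  out <- hits[hits$difference <= max_difference, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance-tree pipeline for an Acr homolog family
#'
#' Composes the family-tree stages: optional homolog filtering against
#' the seed, all-pairs global alignment, Grishin distance conversion,
#' fast minimum-evolution tree (NJ topology + OLS lengths), and Newick
#' serialization. Per-stage counts are reported in the audit.
#'
#' @param seqs named character vector of family protein sequences.
#' @param seed_id optional name of the seed sequence (used by the
#'   homolog filter).
#' @param hits optional hit table restricting the family to retained
#'   homologs (see [filter_homologs()]).
#' @param evalue_max,coverage_min,max_difference homolog filters.
#' @param d_cap Grishin distance cap.
#' @param ... alignment options passed to [align_pair()].
#' @return List with `distances` (the Grishin [grishin_matrix()]),
#'   `tree` (`ape::phylo`), `newick` (string) and `audit` (stage
#'   counts).
#' @export
family_tree_pipeline <- function(seqs, seed_id = NULL, hits = NULL,
                                 evalue_max = 0.001, coverage_min = 0.70,
                                 max_difference = 0.85, d_cap = 10, ...) {
  n_input <- length(seqs)
  if (!is.null(hits)) {
    if (is.null(seed_id) || !seed_id %in% names(seqs)) {
      stop("family_tree_pipeline: hits given but seed_id not found among seqs",
           call. = FALSE)
    }
    retained <- filter_homologs(hits, seqs, seqs[[seed_id]],
                                evalue_max = evalue_max,
                                coverage_min = coverage_min,
                                max_difference = max_difference, ...)
    keep_ids <- union(seed_id, retained$subject_gene_id)
    seqs <- seqs[names(seqs) %in% keep_ids]
  }
  if (length(seqs) < 3L) {
    stop("family_tree_pipeline: only ", length(seqs),
         " sequence(s) survive filtering; need at least 3 for a tree",
         call. = FALSE)
  }
  D <- grishin_matrix(seqs, d_cap = d_cap, ...)
  tree <- build_me_tree(D)
  list(distances = D,
       tree = tree,
       newick = ape::write.tree(tree),
       audit = list(n_input = n_input,
                    n_retained = length(seqs),
                    n_capped_pairs = sum(attr(D, "capped")) / 2,
                    tree_length = attr(tree, "tree_length")))
}
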