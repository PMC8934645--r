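#' Evolve a protein family along a phylogeny
#'
#' Simulates homolog sequences by dropping a root protein down a tree
#' under a uniform amino-acid replacement model: on a branch of length
#' `b` (substitutions/site) each site receives a Poisson(`rate * b`)
#' number of replacement events, each event drawing uniformly from the 19
#' alternative residues. The expected fraction of identical residues
#' between two leaves separated by path length `t` is
#' `1/20 + (19/20) * exp(-20 t / 19)`, which [expected_identity()]
#' evaluates for use as a closed-form check.
#'
#' @param tree an `ape::phylo` with branch lengths (rooted or unrooted;
#'   unrooted trees are traversed from an arbitrary internal node, which
#'   leaves all pairwise path lengths unchanged).
#' @param root_seq amino-acid string placed at the root.
#' @param rate substitution events per site per unit branch length.
#' @param seed integer seed.
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
simulate_family <- function(tree, root_seq, rate = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            nchar(root_seq) >= 1L)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- strsplit(root_seq, "")[[1]]
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    seqs[[child]] <- evolve_branch(seqs[[parent]], tree$edge.length[e] * rate)
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  stats::setNames(out, tree$tip.label)
}

evolve_branch <- function(chars, expected_subs_per_site) {
  if (expected_subs_per_site <= 0) return(chars)
  n_events <- stats::rpois(length(chars), expected_subs_per_site)
  for (p in which(n_events > 0L)) {
    for (k in seq_len(n_events[p])) {
      chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
    }
  }
  chars
}

#' Expected residue identity under the uniform replacement model
#'
#' @param path_length total substitutions/site separating two sequences.
#' @return Expected fraction of identical residues.
#' @export
expected_identity <- function(path_length) {
  1 / 20 + (19 / 20) * exp(-20 * path_length / 19)
}

#' Simulate Poisson colony counts for a plasmid-interference assay
#'
#' Generates replicate colony-forming-unit (cfu) counts for the
#' matching-spacer and mismatching-spacer transformations. The
#' mismatching count is Poisson with mean `mean_cfu`; the matching count
#' is Poisson with mean `mean_cfu * true_activity / 100`, so the
#' cfu-ratio estimator recovers `true_activity` in expectation.
#'
#' @param true_activity true inhibitory activity in percent (0-100).
#' @param n_replicates biological replicates (default 3).
#' @param mean_cfu expected mismatching-spacer colony count.
#' @param seed integer seed.
#' @param acr_label,cas9_label,assay labels copied into the table.
#' @return data.frame in assay-table layout with columns `acr_label`,
#'   `cas9_label`, `assay`, `replicate_id`, `cfu_matching`,
#'   `cfu_mismatching`.
#' @export
simulate_assay_counts <- function(true_activity, n_replicates = 3L,
                                  mean_cfu = 200, seed = 1L,
                                  acr_label = "AcrX", cas9_label = "SpyCas9",
                                  assay = "bacterial") {
  stopifnot(true_activity >= 0, true_activity <= 100, n_replicates >= 1L,
            mean_cfu >= 0)
  set.seed(seed)
  data.frame(acr_label = acr_label,
             cas9_label = cas9_label,
             assay = assay,
             replicate_id = seq_len(n_replicates),
             cfu_matching = stats::rpois(n_replicates,
                                         mean_cfu * true_activity / 100),
             cfu_mismatching = stats::rpois(n_replicates, mean_cfu),
             stringsAsFactors = FALSE)
}
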