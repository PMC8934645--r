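# Independent oracles used across the suite. These deliberately share no
# code with the package internals: classification is re-derived with plain
# per-gene loops over the sorted gene table, alignment scores with a
# stand-alone Gotoh dynamic program, and minimum-evolution trees by
# exhaustive topology enumeration are provided by the package itself and
# cross-checked here against NJ.

# Brute-force Acr/Aca classifier: applies the six printed criteria to every
# gene with naive loops.
oracle_mine <- function(genes, hits, domains, acr_fams, aca_fams,
                        p = miner_params()) {
  g <- as.data.frame(genes)
  g <- g[order(g$replicon_id, g$start), ]
  n <- nrow(g)

  labels_of <- function(id) {
    fams <- character(0)
    if (!is.null(hits) && nrow(hits) > 0) {
      for (r in seq_len(nrow(hits))) {
        if (hits$subject_gene_id[r] == id &&
            hits$evalue[r] < p$evalue_max &&
            hits$query_coverage[r] > p$coverage_min) {
          fams <- union(fams, hits$query_family[r])
        }
      }
    }
    fams
  }
  lab <- lapply(g$gene_id, labels_of)
  names(lab) <- g$gene_id

  neighbors_of <- function(i) {
    out <- list()
    for (j in seq_len(n)) {
      if (j == i || g$replicon_id[j] != g$replicon_id[i]) next
      same_rep <- which(g$replicon_id == g$replicon_id[i])
      rank_i <- match(i, same_rep); rank_j <- match(j, same_rep)
      if (abs(rank_i - rank_j) > p$window_genes) next
      gap <- if (g$start[j] > g$end[i]) g$start[j] - g$end[i] - 1
             else if (g$start[i] > g$end[j]) g$start[i] - g$end[j] - 1 else 0
      if (gap > p$max_intergenic_bp) next
      out[[length(out) + 1]] <- list(id = g$gene_id[j],
                                     same_strand = g$strand[j] == g$strand[i])
    }
    out
  }

  has_domain <- function(id) {
    if (is.null(domains) || nrow(domains) == 0) return(FALSE)
    any(domains$gene_id == id & domains$domain_label %in% c("HTH", "AP2") &
          domains$probability >= p$domain_prob_min)
  }

  # distinct marker Acr families adjacent (same strand) to any member of fam
  assoc_of_family <- function(fam) {
    fams_seen <- character(0)
    for (i in seq_len(n)) {
      my <- lab[[g$gene_id[i]]]
      mine <- if (length(my) == 0) paste0("gene:", g$gene_id[i]) else my
      if (!(fam %in% mine)) next
      for (nb in neighbors_of(i)) {
        if (!nb$same_strand) next
        fams_seen <- union(fams_seen, intersect(lab[[nb$id]], acr_fams))
      }
    }
    length(fams_seen)
  }

  acr_set <- character(0); aca_set <- character(0)
  for (i in seq_len(n)) {
    id <- g$gene_id[i]
    nbs <- neighbors_of(i)
    acr_nb <- any(vapply(nbs, function(nb)
      nb$same_strand && length(intersect(lab[[nb$id]], acr_fams)) > 0,
      logical(1)))
    any_nb <- any(vapply(nbs, function(nb)
      nb$same_strand &&
        length(intersect(lab[[nb$id]], c(acr_fams, aca_fams))) > 0,
      logical(1)))
    my <- lab[[id]]
    fams <- if (length(my) == 0) paste0("gene:", id) else my
    a_count <- if (length(fams) > 0) max(vapply(fams, assoc_of_family,
                                                numeric(1))) else 0
    if (acr_nb && has_domain(id) && a_count > p$association_threshold) {
      aca_set <- c(aca_set, id)
    }
    if (g$protein_length[i] < p$max_protein_aa && any_nb) {
      acr_set <- c(acr_set, id)
    }
  }
  list(acr = sort(acr_set), aca = sort(aca_set))
}

# candidate sets from mine_candidates() in comparable form
miner_sets <- function(cands) {
  list(acr = sort(unique(cands$gene_id[cands$candidate_class == "acr_candidate" &
                                         cands$qualifies])),
       aca = sort(unique(cands$gene_id[cands$candidate_class == "aca_candidate" &
                                         cands$qualifies])))
}

# small random corpus configuration used in oracle-equivalence checks; the
# no-domain variant trades the other decoys for the two-locus AcaND family
# to keep corpora at or below ~50 genes
small_corpus <- function(seed, with_nd = FALSE) {
  decoys <- if (with_nd) {
    c(oversize = 0L, wrong_strand = 0L, non_adjacent = 1L,
      no_domain_aca = 2L, low_association_aca = 0L)
  } else {
    c(oversize = 1L, wrong_strand = 1L, non_adjacent = 1L,
      no_domain_aca = 0L, low_association_aca = 1L)
  }
  cfg <- sim_config(seed = seed, n_replicons = 3L,
                    genes_per_replicon = c(6L, 9L),
                    n_operons = 3L,
                    decoy_spec = decoys,
                    n_fusions = if (with_nd) 0L else 1L,
                    acr_families = paste0("AcrF", 1:4),
                    aca_families = "AcaF1")
  sim <- generate_genomes(cfg)
  list(cfg = cfg, sim = sim,
       hits = generate_hit_table(sim, seed = seed + 1000L),
       domains = generate_domain_table(sim, seed = seed + 2000L))
}

# Stand-alone Gotoh global aligner (affine gaps; a gap of length k costs
# open + k * extend), returning the optimal score.
gotoh_score <- function(a, b, mat, open = 11, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# random unrooted binary tree with named tips and given branch-length range
random_bltree <- function(n_tips, bl_range = c(0.1, 1), tip_prefix = "t") {
  tr <- ape::rtree(n_tips, rooted = FALSE,
                   tip.label = paste0(tip_prefix, seq_len(n_tips)))
  tr$edge.length <- stats::runif(nrow(tr$edge), bl_range[1], bl_range[2])
  tr
}
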