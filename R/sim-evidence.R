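#' Simulate a homology hit table for a synthetic corpus
#'
#' Emulates the tabular evidence a protein BLAST search would provide:
#' every planted family member receives a hit to its family marker, with
#' E-value drawn log-uniformly from `[1e-50, 1e-5]` (safely inside the
#' strict `E < 0.001` filter) and query coverage drawn from
#' `coverage_range`. Fusion ORFs receive two hits: an Acr-family hit over
#' the non-terminal segment and an Aca-family hit confined to the planted
#' terminal interval. A configurable fraction of background genes receives
#' spurious hits with E-values log-uniform in `[1e-3, 10]`, which straddle
#' and always fail the strict threshold.
#'
#' @param sim an `acr_sim` from [generate_genomes()].
#' @param spurious_fraction fraction of background genes receiving a
#'   spurious hit (default 0.1).
#' @param coverage_range length-2 range for query coverage of true hits;
#'   `c(1, 1)` gives noiseless 100% coverage.
#' @param identity_range length-2 range (percent) for percent identity.
#' @param seed integer seed for this table's draws.
#' @return data.frame with columns `query_family`, `subject_gene_id`,
#'   `percent_identity`, `evalue`, `query_coverage` (fraction),
#'   `subject_start`, `subject_end`.
#' @export
generate_hit_table <- function(sim, spurious_fraction = 0.1,
                               coverage_range = c(0.75, 1),
                               identity_range = c(35, 95),
                               seed = sim$config$seed) {
  stopifnot(inherits(sim, "acr_sim"), nrow(sim$truth) > 0L)
  set.seed(seed)
  truth <- sim$truth
  rows <- list()
  hit_row <- function(family, gene_id, s_start, s_end, spurious = FALSE) {
    data.frame(
      query_family = family,
      subject_gene_id = gene_id,
      percent_identity = stats::runif(1, identity_range[1], identity_range[2]),
      evalue = if (spurious) 10^stats::runif(1, -3, 1)
               else 10^stats::runif(1, -50, -5),
      query_coverage = if (spurious) stats::runif(1)
                       else stats::runif(1, coverage_range[1], coverage_range[2]),
      subject_start = as.integer(s_start),
      subject_end = as.integer(s_end),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    if (is.na(tr$family)) next
    L <- tr$protein_length
    if (identical(tr$true_class, "fusion")) {
      # Acr-family hit over the non-terminal remainder
      if (tr$fusion_side == "N") {
        rows[[length(rows) + 1L]] <- hit_row(tr$family, tr$gene_id,
                                             tr$fusion_aca_end + 1L, L)
      } else {
        rows[[length(rows) + 1L]] <- hit_row(tr$family, tr$gene_id,
                                             1L, tr$fusion_aca_start - 1L)
      }
      # Aca-family hit confined to the planted terminal interval
      rows[[length(rows) + 1L]] <- hit_row(tr$family2, tr$gene_id,
                                           tr$fusion_aca_start, tr$fusion_aca_end)
    } else {
      rows[[length(rows) + 1L]] <- hit_row(tr$family, tr$gene_id, 1L, L)
    }
  }
  bg <- truth[truth$true_class == "background", ]
  if (spurious_fraction > 0 && nrow(bg) > 0L) {
    n_spur <- floor(spurious_fraction * nrow(bg))
    if (n_spur > 0L) {
      pick <- bg[sample.int(nrow(bg), n_spur), ]
      fams <- unique(stats::na.omit(truth$family))
      for (i in seq_len(nrow(pick))) {
        L <- pick$protein_length[i]
        s <- sample.int(max(1L, L - 10L), 1L)
        rows[[length(rows) + 1L]] <- hit_row(sample(fams, 1L),
                                             pick$gene_id[i],
                                             s, min(L, s + sample(10:60, 1L)),
                                             spurious = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a DNA-binding-domain annotation table
#'
#' Stands in for domain predictions over the corpus proteins: every
#' planted aca gene (including low-association decoys, which must satisfy
#' the domain criterion) receives one HTH or AP2 record with high
#' probability score; at `false_positive_rate` every other gene also
#' receives a record.
#'
#' @param sim an `acr_sim`.
#' @param false_positive_rate per-gene probability of a spurious domain
#'   record on genes without a planted domain (default 0).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `domain_label`
#'   (`HTH`/`AP2`), `probability`, `region_start`, `region_end`.
#' @export
generate_domain_table <- function(sim, false_positive_rate = 0,
                                  seed = sim$config$seed) {
  stopifnot(inherits(sim, "acr_sim"))
  set.seed(seed)
  truth <- sim$truth
  planted <- truth$true_class %in% c("aca", "decoy:low_association")
  domain_row <- function(gene_id, L, prob_range = c(0.85, 0.99)) {
    r_start <- min(5L, L)
    r_end <- min(r_start + 55L, L)
    data.frame(gene_id = gene_id,
               domain_label = sample(c("HTH", "AP2"), 1L, prob = c(0.8, 0.2)),
               probability = stats::runif(1, prob_range[1], prob_range[2]),
               region_start = r_start, region_end = r_end,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(which(planted), function(i) {
    domain_row(truth$gene_id[i], truth$protein_length[i])
  })
  if (false_positive_rate > 0) {
    others <- which(!planted)
    fp <- others[stats::runif(length(others)) < false_positive_rate]
    rows <- c(rows, lapply(fp, function(i) {
      domain_row(truth$gene_id[i], truth$protein_length[i],
                 prob_range = c(0.5, 0.95))
    }))
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), domain_label = character(),
                      probability = numeric(), region_start = integer(),
                      region_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
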