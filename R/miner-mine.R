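#' Classify every gene in a corpus against the Acr/Aca criteria
#'
#' Applies the guilt-by-association criteria to each gene:
#'
#' Aca candidate — all of: (i) at least one neighbor within the window
#' carrying an Acr marker-family label, on the same strand; (ii) a
#' DNA-binding-domain record (HTH or AP2) at or above the probability
#' floor; (iii) the gene's family associated with strictly more than
#' `association_threshold` distinct Acr families corpus-wide.
#'
#' Acr candidate — (i) protein shorter than 300 aa (strict) and (ii) at
#' least one same-strand neighbor within the window carrying an Acr or
#' Aca marker-family label. A detected Acr-Aca fusion architecture
#' raises the confidence tier to `fusion_boosted`; it is a booster, not
#' a requirement.
#'
#' @param genes a [genome_annotation()].
#' @param hits homology hit table (see [read_hit_table()]); may be `NULL`.
#' @param domains domain table (see [read_domain_table()]); may be `NULL`.
#' @param markers a [marker_set()] of current search markers.
#' @param params a [miner_params()].
#' @param audit if `TRUE`, return one row per gene and candidate class
#'   with all evidence flags (`qualifies` marks the candidates);
#'   otherwise only qualifying candidates are returned.
#' @return data.frame of candidate loci with per-criterion evidence
#'   columns.
#' @export
mine_candidates <- function(genes, hits, domains, markers,
                            params = miner_params(), audit = FALSE) {
  labels <- map_hits_to_genes(hits, genes, params$evalue_max,
                              params$coverage_min)
  labels <- labels_with_members(labels, markers, genes)
  nbr <- neighbor_table(genes, params$window_genes, params$max_intergenic_bp)
  assoc <- graph_from_neighbors(genes, nbr, labels, markers)

  acr_fams <- marker_families(markers, "acr")
  aca_fams <- marker_families(markers, "aca")
  label_rel <- unique(labels[, c("gene_id", "family")])
  fam_of <- split(label_rel$family, label_rel$gene_id)
  nbr_by_focal <- split(nbr, nbr$focal)

  domain_ok_ids <- character(0)
  if (!is.null(domains) && nrow(domains) > 0L) {
    sel <- domains$domain_label %in% c("HTH", "AP2") &
      domains$probability >= params$domain_prob_min
    domain_ok_ids <- unique(domains$gene_id[sel])
  }

  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    my_nbr <- nbr_by_focal[[gid]]
    if (is.null(my_nbr)) my_nbr <- nbr[0, , drop = FALSE]
    nbr_fams <- lapply(my_nbr$neighbor, function(id) fam_of[[id]])
    nbr_acr <- vapply(nbr_fams, function(f) length(intersect(f, acr_fams)) > 0L,
                      logical(1))
    nbr_any <- vapply(nbr_fams, function(f)
      length(intersect(f, c(acr_fams, aca_fams))) > 0L, logical(1))

    # --- Aca classification -------------------------------------------------
    aca_adj <- any(nbr_acr)
    aca_orient <- any(nbr_acr & my_nbr$same_strand)
    has_domain <- gid %in% domain_ok_ids
    fams <- fam_of[[gid]]
    if (is.null(fams) || length(fams) == 0L) fams <- paste0("gene:", gid)
    a_count <- association_count(assoc, fams)
    aca_ok <- aca_adj && aca_orient && has_domain &&
      a_count > params$association_threshold

    # --- Acr classification -------------------------------------------------
    size_ok <- genes$protein_length[i] < params$max_protein_aa
    acr_adj <- any(nbr_any)
    acr_orient <- any(nbr_any & my_nbr$same_strand)
    marker_nbr <- which(nbr_any & my_nbr$same_strand)
    marker_family <- if (length(marker_nbr) > 0L) {
      paste(unique(unlist(lapply(nbr_fams[marker_nbr], function(f)
        intersect(f, c(acr_fams, aca_fams))))), collapse = ",")
    } else NA_character_
    marker_side <- if (length(marker_nbr) > 0L) {
      paste(unique(my_nbr$side[marker_nbr]), collapse = ",")
    } else NA_character_
    aca_iv <- labels[labels$gene_id == gid & labels$family %in% aca_fams &
                       !is.na(labels$subject_start), , drop = FALSE]
    fusion <- detect_fusion(gid, genes,
                            data.frame(start = aca_iv$subject_start,
                                       end = aca_iv$subject_end), params)
    acr_ok <- size_ok && acr_adj && acr_orient

    base <- data.frame(
      gene_id = gid, replicon_id = genes$replicon_id[i],
      protein_length = genes$protein_length[i],
      families = paste(fams, collapse = ","),
      marker_families = marker_family, marker_side = marker_side,
      stringsAsFactors = FALSE)
    if (audit || aca_ok) {
      rows[[length(rows) + 1L]] <- cbind(base, data.frame(
        candidate_class = "aca_candidate", qualifies = aca_ok,
        size_ok = NA, adjacent_marker = aca_adj, orientation_ok = aca_orient,
        has_dna_binding_domain = has_domain, association_count = a_count,
        fusion = FALSE, fusion_side = NA_character_,
        fusion_aca_start = NA_integer_, fusion_aca_end = NA_integer_,
        acr_remainder_length = NA_integer_,
        confidence_tier = "standard", stringsAsFactors = FALSE))
    }
    if (audit || acr_ok) {
      rows[[length(rows) + 1L]] <- cbind(base, data.frame(
        candidate_class = "acr_candidate", qualifies = acr_ok,
        size_ok = size_ok, adjacent_marker = acr_adj,
        orientation_ok = acr_orient,
        has_dna_binding_domain = has_domain, association_count = a_count,
        fusion = !is.null(fusion),
        fusion_side = if (is.null(fusion)) NA_character_ else fusion$terminal_side,
        fusion_aca_start = if (is.null(fusion)) NA_integer_ else fusion$aca_start,
        fusion_aca_end = if (is.null(fusion)) NA_integer_ else fusion$aca_end,
        acr_remainder_length = if (is.null(fusion)) NA_integer_ else
          fusion$acr_remainder_length,
        confidence_tier = if (is.null(fusion)) "standard" else "fusion_boosted",
        stringsAsFactors = FALSE))
    }
  }
  if (length(rows) == 0L) {
    return(empty_candidates())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(gene_id = character(), replicon_id = character(),
             protein_length = integer(), families = character(),
             marker_families = character(), marker_side = character(),
             candidate_class = character(), qualifies = logical(),
             size_ok = logical(), adjacent_marker = logical(),
             orientation_ok = logical(), has_dna_binding_domain = logical(),
             association_count = integer(), fusion = logical(),
             fusion_side = character(), fusion_aca_start = integer(),
             fusion_aca_end = integer(), acr_remainder_length = integer(),
             confidence_tier = character(), stringsAsFactors = FALSE)
}

#' Classify a single gene as an Aca candidate
#'
#' Single-gene interface over the same predicates as [mine_candidates()];
#' the context must have been built with labels and markers attached (see
#' [build_labeled_context()]).
#'
#' @param context a labeled `neighborhood_context`.
#' @param domains domain table.
#' @param assoc an `association_graph` built over the full corpus.
#' @param params a [miner_params()].
#' @return A one-row evidence data.frame; `qualifies` indicates whether
#'   the gene is an Aca candidate.
#' @export
classify_aca <- function(context, domains, assoc, params = miner_params()) {
  gid <- context$focal$gene_id
  nbr_acr <- vapply(context$neighbors$acr_marker_families,
                    function(f) length(f) > 0L, logical(1))
  adjacent <- any(nbr_acr)
  orient <- any(nbr_acr & context$neighbors$same_strand)
  has_domain <- FALSE
  if (!is.null(domains) && nrow(domains) > 0L) {
    sel <- domains$gene_id == gid & domains$domain_label %in% c("HTH", "AP2") &
      domains$probability >= params$domain_prob_min
    has_domain <- any(sel)
  }
  a_count <- association_count(assoc, context$focal_families)
  data.frame(gene_id = gid, candidate_class = "aca_candidate",
             qualifies = adjacent && orient && has_domain &&
               a_count > params$association_threshold,
             adjacent_marker = adjacent, orientation_ok = orient,
             has_dna_binding_domain = has_domain,
             association_count = a_count, stringsAsFactors = FALSE)
}

#' Classify a single gene as an Acr candidate
#'
#' @param context a labeled `neighborhood_context` (see
#'   [build_labeled_context()]).
#' @param params a [miner_params()].
#' @param fusion optional fusion call from [detect_fusion()]; boosts the
#'   confidence tier but is never required.
#' @return A one-row evidence data.frame.
#' @export
classify_acr_candidate <- function(context, params = miner_params(),
                                   fusion = NULL) {
  gid <- context$focal$gene_id
  nbr_any <- vapply(seq_len(nrow(context$neighbors)), function(r) {
    length(context$neighbors$acr_marker_families[[r]]) > 0L ||
      length(context$neighbors$aca_marker_families[[r]]) > 0L
  }, logical(1))
  size_ok <- context$focal$protein_length < params$max_protein_aa
  adjacent <- any(nbr_any)
  orient <- any(nbr_any & context$neighbors$same_strand)
  data.frame(gene_id = gid, candidate_class = "acr_candidate",
             qualifies = size_ok && adjacent && orient,
             size_ok = size_ok, adjacent_marker = adjacent,
             orientation_ok = orient,
             confidence_tier = if (!is.null(fusion)) "fusion_boosted" else "standard",
             stringsAsFactors = FALSE)
}

#' Build a neighborhood context with marker labels attached
#'
#' Augments [build_context()] with, per neighbor, the Acr and Aca marker
#' families it carries, and with the focal gene's own families (its hit
#' labels, or a `gene:<id>` singleton when unlabeled).
#'
#' @param gene_id focal gene.
#' @param genes a [genome_annotation()].
#' @param labels passing hit labels from [map_hits_to_genes()].
#' @param markers a [marker_set()].
#' @param params a [miner_params()].
#' @return A labeled `neighborhood_context`.
#' @export
build_labeled_context <- function(gene_id, genes, labels, markers,
                                  params = miner_params()) {
  ctx <- build_context(gene_id, genes, params$window_genes,
                       params$max_intergenic_bp)
  label_rel <- unique(labels[, c("gene_id", "family")])
  fam_of <- split(label_rel$family, label_rel$gene_id)
  acr_fams <- marker_families(markers, "acr")
  aca_fams <- marker_families(markers, "aca")
  ctx$neighbors$acr_marker_families <- lapply(ctx$neighbors$gene_id, function(id)
    intersect(fam_of[[id]], acr_fams))
  ctx$neighbors$aca_marker_families <- lapply(ctx$neighbors$gene_id, function(id)
    intersect(fam_of[[id]], aca_fams))
  focal_f <- fam_of[[gene_id]]
  ctx$focal_families <- if (is.null(focal_f) || length(focal_f) == 0L)
    paste0("gene:", gene_id) else focal_f
  ctx
}
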