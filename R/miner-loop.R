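#' Iterative search-validation marker expansion
#'
#' Runs the guilt-by-association discovery loop: genes are labeled from
#' the current marker families, Aca then Acr candidates are classified,
#' new candidates are passed to a pluggable validator (standing in for
#' the experimental screen), and the families of accepted candidates
#' join the marker set for the next round. The loop stops at a fixed
#' point (no new family adopted) or after `max_iterations` rounds, and
#' never removes a marker, so marker sets grow monotonically.
#'
#' Accepted candidates contribute their hit-derived families (Aca
#' candidates as Aca markers, Acr candidates as Acr markers); accepted
#' genes without any hit label are adopted as singleton families named
#' `gene:<id>` whose only member is the gene itself.
#'
#' @param seed_markers nonempty [marker_set()] of initial families.
#' @param genes a [genome_annotation()].
#' @param hits,domains evidence tables.
#' @param validator function `(candidates, iteration) -> character` of
#'   accepted gene ids; see [validator_accept_all()].
#' @param params a [miner_params()].
#' @return List with `markers` (final [marker_set()], each family tagged
#'   with its adoption iteration), `candidates` (the candidate ledger
#'   from the final marker set) and `audit` (per-iteration data.frame:
#'   candidates seen, accepted, families added).
#' @export
search_validation_loop <- function(seed_markers, genes, hits, domains,
                                   validator = validator_accept_all(),
                                   params = miner_params()) {
  stopifnot(inherits(seed_markers, "marker_set"))
  if (nrow(seed_markers$families) == 0L) {
    stop("search_validation_loop: seed_markers must be nonempty", call. = FALSE)
  }
  markers <- seed_markers
  audit <- list()
  converged <- FALSE
  for (iter in seq_len(params$max_iterations)) {
    cands <- mine_candidates(genes, hits, domains, markers, params)
    known <- unlist(lapply(names(markers$members), function(f)
      markers$members[[f]]))
    fresh <- cands[!(cands$gene_id %in% known), , drop = FALSE]
    accepted_ids <- unique(validator(fresh, iter))
    acc <- fresh[fresh$gene_id %in% accepted_ids, , drop = FALSE]

    new_fams <- character(0)
    for (cls in c("aca_candidate", "acr_candidate")) {  # Aca first
      sub <- acc[acc$candidate_class == cls, , drop = FALSE]
      if (nrow(sub) == 0L) next
      type <- if (cls == "aca_candidate") "aca" else "acr"
      for (r in seq_len(nrow(sub))) {
        fams <- strsplit(sub$families[r], ",", fixed = TRUE)[[1]]
        adopt <- setdiff(fams, markers$families$family)
        if (length(adopt) > 0L) {
          members <- stats::setNames(
            lapply(adopt, function(f) sub$gene_id[r]), adopt)
          markers <- add_markers(markers, adopt, type, iter, members)
          new_fams <- c(new_fams, adopt)
        } else {
          # family already known: record the member gene
          markers$members[[fams[1]]] <- union(markers$members[[fams[1]]],
                                              sub$gene_id[r])
        }
      }
    }
    audit[[iter]] <- data.frame(
      iteration = iter,
      n_candidates = nrow(cands),
      n_accepted = nrow(acc),
      families_added = paste(unique(new_fams), collapse = ","),
      stringsAsFactors = FALSE)
    if (length(new_fams) == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("search_validation_loop: max_iterations (", params$max_iterations,
            ") reached without a fixed point; marker set so far: ",
            paste(markers$families$family, collapse = ", "), call. = FALSE)
  }
  list(markers = markers,
       candidates = mine_candidates(genes, hits, domains, markers, params),
       audit = do.call(rbind, audit))
}

#' Candidate validators for the search-validation loop
#'
#' The validation step is experimental in the field (plasmid-interference
#' screening); these helpers supply the standard stand-ins: accept
#' everything, reject everything, accept genes on a user list, or accept
#' exactly the planted acr/aca/fusion genes of a simulation truth ledger.
#'
#' @return A function `(candidates, iteration) -> character vector` of
#'   accepted gene ids.
#' @export
validator_accept_all <- function() {
  function(candidates, iteration) unique(candidates$gene_id)
}

#' @rdname validator_accept_all
#' @export
validator_reject_all <- function() {
  function(candidates, iteration) character(0)
}

#' @rdname validator_accept_all
#' @param gene_ids character vector of gene ids to accept.
#' @export
validator_from_list <- function(gene_ids) {
  force(gene_ids)
  function(candidates, iteration)
    intersect(unique(candidates$gene_id), gene_ids)
}

#' @rdname validator_accept_all
#' @param truth a truth ledger data.frame (from [generate_genomes()]).
#' @export
validator_from_truth <- function(truth) {
  ok <- truth$gene_id[truth$true_class %in% c("acr", "aca", "fusion")]
  validator_from_list(ok)
}
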