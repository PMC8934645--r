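#' Mining parameters
#'
#' Collects every threshold used by the candidate criteria. Defaults are
#' the published screening values where the protocol states them
#' (protein size < 300 aa, E-value < 0.001, query coverage > 70%,
#' association with more than two distinct Acr families); all comparisons
#' against these are strict, so boundary values fail. The neighborhood
#' window defaults to one gene per side ("directly upstream or
#' downstream"), with a wider `audit_window_genes` used only for
#' enumeration listings of relevant neighboring genes.
#'
#' @param evalue_max homology hits must satisfy `evalue < evalue_max`.
#' @param coverage_min hits must satisfy `query_coverage > coverage_min`.
#' @param max_protein_aa Acr candidates must be shorter than this (aa).
#' @param window_genes neighbors per side considered adjacent.
#' @param max_intergenic_bp neighbors farther than this are not adjacent.
#' @param association_threshold Aca candidates require strictly more
#'   distinct Acr families than this corpus-wide.
#' @param domain_prob_min minimum probability for a DNA-binding-domain
#'   record to count (HTH/AP2).
#' @param terminal_fraction fraction of the protein defining the N/C
#'   terminal region for fusion calls.
#' @param min_remainder_aa minimum Acr remainder outside the fused Aca
#'   segment.
#' @param max_iterations guard for the search-validation loop.
#' @param audit_window_genes wider window for audit enumerations.
#' @return A `miner_params` list.
#' @export
miner_params <- function(evalue_max = 1e-3,
                         coverage_min = 0.70,
                         max_protein_aa = 300L,
                         window_genes = 1L,
                         max_intergenic_bp = 1000L,
                         association_threshold = 2L,
                         domain_prob_min = 0.5,
                         terminal_fraction = 0.4,
                         min_remainder_aa = 40L,
                         max_iterations = 20L,
                         audit_window_genes = 5L) {
  stopifnot(evalue_max > 0, coverage_min >= 0, coverage_min <= 1,
            max_protein_aa >= 1, window_genes >= 1,
            max_intergenic_bp >= 0, association_threshold >= 0,
            domain_prob_min >= 0, domain_prob_min <= 1,
            terminal_fraction > 0, terminal_fraction < 1,
            min_remainder_aa >= 0, max_iterations >= 1)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 max_protein_aa = as.integer(max_protein_aa),
                 window_genes = as.integer(window_genes),
                 max_intergenic_bp = as.integer(max_intergenic_bp),
                 association_threshold = as.integer(association_threshold),
                 domain_prob_min = domain_prob_min,
                 terminal_fraction = terminal_fraction,
                 min_remainder_aa = as.integer(min_remainder_aa),
                 max_iterations = as.integer(max_iterations),
                 audit_window_genes = as.integer(audit_window_genes)),
            class = "miner_params")
}

#' Marker family set for guilt-by-association searches
#'
#' Holds the Acr and Aca families currently usable as search markers,
#' together with the loop iteration at which each was adopted (0 for
#' seeds) and any directly known member genes.
#'
#' @param acr,aca character vectors of family labels.
#' @param members optional named list family -> character vector of known
#'   member gene ids.
#' @return A `marker_set`.
#' @export
marker_set <- function(acr = character(), aca = character(),
                       members = list()) {
  if (length(intersect(acr, aca)) > 0L) {
    stop("marker_set: a family cannot be both acr and aca: ",
         paste(intersect(acr, aca), collapse = ", "), call. = FALSE)
  }
  fam <- data.frame(family = c(acr, aca),
                    type = c(rep("acr", length(acr)), rep("aca", length(aca))),
                    iteration = 0L, stringsAsFactors = FALSE)
  structure(list(families = fam, members = members), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d acr + %d aca families\n",
              sum(x$families$type == "acr"), sum(x$families$type == "aca")))
  print(x$families)
  invisible(x)
}

marker_families <- function(markers, type) {
  markers$families$family[markers$families$type == type]
}

add_markers <- function(markers, families, type, iteration,
                        members = list()) {
  new <- setdiff(families, markers$families$family)
  if (length(new) > 0L) {
    markers$families <- rbind(markers$families,
                              data.frame(family = new, type = type,
                                         iteration = as.integer(iteration),
                                         stringsAsFactors = FALSE))
  }
  for (f in names(members)) {
    markers$members[[f]] <- union(markers$members[[f]], members[[f]])
  }
  markers
}
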