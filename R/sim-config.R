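#' Configuration for the synthetic Acr/Aca genome simulator
#'
#' Describes a set of Streptococcus-like replicons (linear prophage/MGE
#' regions) carrying planted acr-aca operons, Acr-Aca fusion ORFs, and
#' decoy genes each engineered to violate exactly one candidate criterion.
#' A single integer seed fixes every downstream draw.
#'
#' Decoy classes and the criterion each violates:
#' * `oversize` — protein >= 300 aa, otherwise a perfect Acr candidate.
#' * `wrong_strand` — adjacent to a marker but on the opposite strand.
#' * `non_adjacent` — small protein with no marker gene in its neighborhood.
#' * `no_domain_aca` — Aca-like gene (adjacent Acr neighbors, high family
#'   association) lacking any DNA-binding-domain record.
#' * `low_association_aca` — Aca-like gene with an HTH domain whose family
#'   sits next to only one distinct Acr family corpus-wide.
#'
#' Aca-type decoy families need more than one locus to make their
#' association count meaningful with a one-gene neighborhood window, so
#' `no_domain_aca` must be 0 or >= 2; true aca families each receive at
#' least three operons so their association count exceeds two.
#'
#' @param seed integer; fixes all randomness end-to-end.
#' @param n_replicons number of linear replicons to simulate.
#' @param genes_per_replicon length-2 integer range of background gene
#'   counts per replicon (planted cassettes are inserted between them).
#' @param n_operons number of planted acr-aca cassettes.
#' @param acr_length_range length-2 aa range for planted Acr proteins;
#'   upper bound must stay below 300 aa.
#' @param aca_length_range length-2 aa range for planted Aca proteins.
#' @param decoy_spec named integer vector with entries `oversize`,
#'   `wrong_strand`, `non_adjacent`, `no_domain_aca`, `low_association_aca`.
#' @param n_fusions number of planted Acr-Aca fusion ORFs.
#' @param fusion_terminal_side `"N"`, `"C"` or `"random"`.
#' @param acr_families character vector of Acr family labels (>= 3).
#' @param aca_families character vector of Aca family labels.
#' @param intergenic_range length-2 bp range for intergenic gaps.
#' @param background_length_range length-2 aa range for background proteins.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_replicons = 20L,
                       genes_per_replicon = c(12L, 20L),
                       n_operons = 12L,
                       acr_length_range = c(50L, 250L),
                       aca_length_range = c(60L, 140L),
                       decoy_spec = c(oversize = 2L, wrong_strand = 2L,
                                      non_adjacent = 2L, no_domain_aca = 2L,
                                      low_association_aca = 2L),
                       n_fusions = 3L,
                       fusion_terminal_side = c("random", "N", "C"),
                       acr_families = paste0("AcrF", 1:6),
                       aca_families = paste0("AcaF", 1:3),
                       intergenic_range = c(20L, 200L),
                       background_length_range = c(80L, 500L)) {
  fusion_terminal_side <- match.arg(fusion_terminal_side)
  decoy_names <- c("oversize", "wrong_strand", "non_adjacent",
                   "no_domain_aca", "low_association_aca")
  full_spec <- stats::setNames(integer(length(decoy_names)), decoy_names)
  if (length(decoy_spec) > 0L) {
    unknown <- setdiff(names(decoy_spec), decoy_names)
    if (length(unknown) > 0L || is.null(names(decoy_spec))) {
      stop("sim_config: decoy_spec must be named with: ",
           paste(decoy_names, collapse = ", "), call. = FALSE)
    }
    full_spec[names(decoy_spec)] <- as.integer(decoy_spec)
  }
  cfg <- list(seed = as.integer(seed),
              n_replicons = as.integer(n_replicons),
              genes_per_replicon = as.integer(genes_per_replicon),
              n_operons = as.integer(n_operons),
              acr_length_range = as.integer(acr_length_range),
              aca_length_range = as.integer(aca_length_range),
              decoy_spec = full_spec,
              n_fusions = as.integer(n_fusions),
              fusion_terminal_side = fusion_terminal_side,
              acr_families = acr_families,
              aca_families = aca_families,
              intergenic_range = as.integer(intergenic_range),
              background_length_range = as.integer(background_length_range))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$n_replicons < 1L) {
    stop("sim_config: n_replicons must be >= 1", call. = FALSE)
  }
  if (length(cfg$genes_per_replicon) != 2L ||
      cfg$genes_per_replicon[1] > cfg$genes_per_replicon[2] ||
      cfg$genes_per_replicon[1] < 1L) {
    stop("sim_config: genes_per_replicon must be a valid range", call. = FALSE)
  }
  if (cfg$acr_length_range[2] >= 300L) {
    stop("sim_config: acr_length_range upper bound must be < 300 aa",
         call. = FALSE)
  }
  if (any(cfg$decoy_spec < 0L)) {
    stop("sim_config: decoy counts must be >= 0", call. = FALSE)
  }
  if (cfg$decoy_spec[["no_domain_aca"]] == 1L) {
    stop("sim_config: no_domain_aca must be 0 or >= 2 (a single locus ",
         "cannot exceed the association threshold with a one-gene window)",
         call. = FALSE)
  }
  if (cfg$n_operons > 0L && length(cfg$aca_families) > 0L &&
      cfg$n_operons < 3L * length(cfg$aca_families)) {
    stop("sim_config: need n_operons >= 3 * length(aca_families) so every ",
         "aca family associates with more than two distinct Acr families",
         call. = FALSE)
  }
  if (cfg$n_operons > 0L && length(cfg$acr_families) < 3L) {
    stop("sim_config: need at least 3 Acr families", call. = FALSE)
  }
  # every replicon must host its share of cassettes in non-adjacent
  # inter-gene slots (so no background gene flanks two cassettes):
  # k cassettes need at least 2k background genes
  n_cassettes <- cfg$n_operons + cfg$n_fusions + sum(cfg$decoy_spec)
  per_rep <- ceiling(n_cassettes / cfg$n_replicons)
  if (cfg$genes_per_replicon[1] < 2L * per_rep) {
    stop("sim_config: genes_per_replicon too small to host the planted ",
         "elements (need at least ", 2L * per_rep,
         " background genes per replicon)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  seed %d | %d replicons | %d operons | %d fusions\n",
              x$seed, x$n_replicons, x$n_operons, x$n_fusions))
  cat("  decoys:", paste(sprintf("%s=%d", names(x$decoy_spec), x$decoy_spec),
                         collapse = " "), "\n")
  cat("  families:", paste(x$acr_families, collapse = ","), "|",
      paste(x$aca_families, collapse = ","), "\n")
  invisible(x)
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# point-mutate a fraction of sites (substitution to a different residue)
mutate_protein <- function(seq, fraction) {
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(fraction * length(chars))
  if (n_mut == 0L) return(seq)
  pos <- sample.int(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
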