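#' Simulate annotated replicons with planted acr-aca loci
#'
#' Generates a set of linear Streptococcus-like replicons whose background
#' genes are interleaved with planted cassettes: acr-aca operons (small
#' same-strand adjacent gene pairs), Acr-Aca fusion ORFs next to a partner
#' acr, and decoy genes each violating exactly one candidate criterion.
#' Every emitted gene is recorded once in the truth ledger together with
#' its class and family, so downstream mining can be scored exactly.
#'
#' Cassette layouts (all genes on one strand unless noted):
#' * operon: `acr - aca`, order randomized per cassette.
#' * fusion: `fusion - acr` partner pair.
#' * oversize / wrong-strand decoys: `decoy - acr - aca` (the wrong-strand
#'   decoy sits on the opposite strand).
#' * non-adjacent decoy: a lone small gene surrounded by background.
#' * no-domain aca decoy: `acr - acr - decoy - acr - acr` so the decoy
#'   neighbors two distinct Acr families per locus.
#' * low-association aca decoy: `acr - acr - decoy` with a single fixed
#'   Acr family across all its loci.
#'
#' Background genes immediately flanking a cassette are forced onto the
#' opposite strand so that planted elements, not bystanders, carry the
#' candidate signal.
#'
#' @param config a [sim_config()].
#' @return An object of class `acr_sim`: list with `genes` (a
#'   [genome_annotation()]), `proteins` (named character vector of
#'   amino-acid sequences), `truth` (the truth ledger data.frame),
#'   `replicon_lengths` (named integer) and `config`.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  # --- family seed proteins -------------------------------------------------
  acr_seeds <- lapply(config$acr_families, function(f) {
    random_protein(sample(config$acr_length_range[1]:config$acr_length_range[2], 1L))
  })
  names(acr_seeds) <- config$acr_families
  aca_seeds <- lapply(config$aca_families, function(f) {
    random_protein(sample(config$aca_length_range[1]:config$aca_length_range[2], 1L))
  })
  names(aca_seeds) <- config$aca_families
  nd_count <- config$decoy_spec[["no_domain_aca"]]
  la_count <- config$decoy_spec[["low_association_aca"]]
  if (nd_count > 0L) {
    aca_seeds[["AcaND"]] <- random_protein(
      sample(config$aca_length_range[1]:config$aca_length_range[2], 1L))
  }
  if (la_count > 0L) {
    aca_seeds[["AcaLA"]] <- random_protein(
      sample(config$aca_length_range[1]:config$aca_length_range[2], 1L))
  }

  member_of <- function(seed_seq) mutate_protein(seed_seq, stats::runif(1, 0.02, 0.12))

  n_acr <- length(config$acr_families)
  n_aca <- length(config$aca_families)
  # round-robin counters guaranteeing >=3 distinct Acr families per aca family
  aca_counter <- stats::setNames(integer(n_aca), config$aca_families)
  next_pair <- function() {
    j <- which.min(aca_counter)  # least-served aca family
    ga <- config$aca_families[j]
    fa <- config$acr_families[(aca_counter[j] %% n_acr) + 1L]
    aca_counter[j] <<- aca_counter[j] + 1L
    list(acr = fa, aca = ga)
  }

  gene_spec <- function(class, family = NA_character_, family2 = NA_character_,
                        seq, rel_strand = "same",
                        fusion_side = NA_character_,
                        fusion_aca_start = NA_integer_,
                        fusion_aca_end = NA_integer_) {
    list(class = class, family = family, family2 = family2, seq = seq,
         rel_strand = rel_strand, fusion_side = fusion_side,
         fusion_aca_start = fusion_aca_start, fusion_aca_end = fusion_aca_end)
  }

  make_fusion <- function(acr_family, aca_family) {
    L <- sample(150:280, 1L)
    side <- switch(config$fusion_terminal_side,
                   random = sample(c("N", "C"), 1L),
                   config$fusion_terminal_side)
    seg <- floor(0.33 * L)
    aca_seed <- aca_seeds[[aca_family]]
    aca_piece <- substr(member_of(aca_seed), 1L,
                        min(seg, nchar(aca_seed)))
    m <- nchar(aca_piece)
    body <- member_of(acr_seeds[[acr_family]])
    # pad/trim the acr-derived body to full length, then stamp the terminal
    # aca segment in
    body <- paste0(body, random_protein(max(0L, L - nchar(body))))
    body <- substr(body, 1L, L)
    if (side == "N") {
      a_start <- 3L; a_end <- 2L + m
    } else {
      a_end <- L - 2L; a_start <- a_end - m + 1L
    }
    substr(body, a_start, a_end) <- aca_piece
    gene_spec("fusion", family = acr_family, family2 = aca_family,
              seq = body, fusion_side = side,
              fusion_aca_start = a_start, fusion_aca_end = a_end)
  }

  # --- cassettes ------------------------------------------------------------
  cassettes <- list()
  add_cassette <- function(genes) cassettes[[length(cassettes) + 1L]] <<- genes

  for (i in seq_len(config$n_operons)) {
    p <- next_pair()
    pair <- list(gene_spec("acr", p$acr, seq = member_of(acr_seeds[[p$acr]])),
                 gene_spec("aca", p$aca, seq = member_of(aca_seeds[[p$aca]])))
    if (stats::runif(1) < 0.5) pair <- rev(pair)
    add_cassette(pair)
  }
  for (i in seq_len(config$n_fusions)) {
    fa <- config$acr_families[((i - 1L) %% n_acr) + 1L]
    ga <- config$aca_families[((i - 1L) %% n_aca) + 1L]
    partner <- next_pair()$acr
    pair <- list(make_fusion(fa, ga),
                 gene_spec("acr", partner, seq = member_of(acr_seeds[[partner]])))
    if (stats::runif(1) < 0.5) pair <- rev(pair)
    add_cassette(pair)
  }
  for (i in seq_len(config$decoy_spec[["oversize"]])) {
    p <- next_pair()
    add_cassette(list(
      gene_spec("decoy:size", seq = random_protein(sample(300:450, 1L))),
      gene_spec("acr", p$acr, seq = member_of(acr_seeds[[p$acr]])),
      gene_spec("aca", p$aca, seq = member_of(aca_seeds[[p$aca]]))))
  }
  for (i in seq_len(config$decoy_spec[["wrong_strand"]])) {
    p <- next_pair()
    add_cassette(list(
      gene_spec("decoy:strand", rel_strand = "opposite",
                seq = random_protein(
                  sample(config$acr_length_range[1]:config$acr_length_range[2], 1L))),
      gene_spec("acr", p$acr, seq = member_of(acr_seeds[[p$acr]])),
      gene_spec("aca", p$aca, seq = member_of(aca_seeds[[p$aca]]))))
  }
  for (i in seq_len(config$decoy_spec[["non_adjacent"]])) {
    add_cassette(list(
      gene_spec("decoy:adjacency",
                seq = random_protein(
                  sample(config$acr_length_range[1]:config$acr_length_range[2], 1L)))))
  }
  # no-domain aca decoys: each locus sandwiches the decoy between two acr
  # pairs from two families new to the AcaND neighborhood
  nd_fam_idx <- 0L
  for (i in seq_len(nd_count)) {
    inner1 <- config$acr_families[(nd_fam_idx %% n_acr) + 1L]
    inner2 <- config$acr_families[((nd_fam_idx + 1L) %% n_acr) + 1L]
    nd_fam_idx <- nd_fam_idx + 2L
    outer1 <- next_pair()$acr
    outer2 <- next_pair()$acr
    add_cassette(list(
      gene_spec("acr", outer1, seq = member_of(acr_seeds[[outer1]])),
      gene_spec("acr", inner1, seq = member_of(acr_seeds[[inner1]])),
      gene_spec("decoy:no_domain", family = "AcaND",
                seq = member_of(aca_seeds[["AcaND"]])),
      gene_spec("acr", inner2, seq = member_of(acr_seeds[[inner2]])),
      gene_spec("acr", outer2, seq = member_of(acr_seeds[[outer2]]))))
  }
  # low-association aca decoys: single fixed Acr family across every locus
  la_partner <- config$acr_families[1]
  for (i in seq_len(la_count)) {
    add_cassette(list(
      gene_spec("acr", la_partner, seq = member_of(acr_seeds[[la_partner]])),
      gene_spec("acr", la_partner, seq = member_of(acr_seeds[[la_partner]])),
      gene_spec("decoy:low_association", family = "AcaLA",
                seq = member_of(aca_seeds[["AcaLA"]]))))
  }

  # --- place cassettes on replicons ----------------------------------------
  assign_rep <- rep(seq_len(config$n_replicons), length.out = length(cassettes))
  rows <- list()
  replicon_lengths <- stats::setNames(integer(config$n_replicons),
                                      sprintf("rep%02d", seq_len(config$n_replicons)))
  for (r in seq_len(config$n_replicons)) {
    rep_id <- sprintf("rep%02d", r)
    my_cassettes <- cassettes[assign_rep == r]
    k <- length(my_cassettes)
    n_bg <- sample(config$genes_per_replicon[1]:config$genes_per_replicon[2], 1L)
    # internal gaps between consecutive background genes; cassettes go into
    # non-adjacent gaps so no background gene flanks two cassettes
    if (k > 0L) {
      gaps_avail <- seq_len(n_bg - 1L)
      if (length(gaps_avail) < 2L * k - 1L) {
        stop("generate_genomes: genes_per_replicon too small to host the ",
             "planted elements on replicon ", rep_id, call. = FALSE)
      }
      slots <- sort(sample(seq_len(n_bg - 1L), k))
      tries <- 0L
      while (k > 1L && any(diff(slots) < 2L)) {
        slots <- sort(sample(seq_len(n_bg - 1L), k))
        tries <- tries + 1L
        if (tries > 1000L) {
          slots <- seq.int(1L, by = 2L, length.out = k)
          break
        }
      }
    } else {
      slots <- integer(0)
    }
    cassette_strand <- sample(c("+", "-"), max(k, 1L), replace = TRUE)

    # build the linear sequence of gene specs for this replicon; background
    # genes immediately flanking a cassette go on the opposite strand
    specs <- list()
    bg_lengths <- sample(config$background_length_range[1]:config$background_length_range[2],
                         n_bg, replace = TRUE)
    for (b in seq_len(n_bg)) {
      s <- gene_spec("background", seq = random_protein(bg_lengths[b]))
      ci_here <- match(b, slots)        # cassette right after this bg gene
      ci_prev <- match(b - 1L, slots)   # cassette right before it
      s$strand <- if (!is.na(ci_here)) {
        flip_strand(cassette_strand[ci_here])
      } else if (!is.na(ci_prev)) {
        flip_strand(cassette_strand[ci_prev])
      } else {
        sample(c("+", "-"), 1L)
      }
      specs[[length(specs) + 1L]] <- s
      if (!is.na(ci_here)) {
        cs <- cassette_strand[ci_here]
        for (g in my_cassettes[[ci_here]]) {
          g$strand <- if (identical(g$rel_strand, "opposite"))
            flip_strand(cs) else cs
          specs[[length(specs) + 1L]] <- g
        }
      }
    }
    pos <- 1L
    for (gi in seq_along(specs)) {
      g <- specs[[gi]]
      strand <- g$strand
      gap <- sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)
      start <- pos + gap
      aa <- nchar(g$seq)
      end <- start + 3L * aa + 2L  # CDS including stop codon
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = rep_id,
        gene_id = sprintf("%s_g%03d", rep_id, gi),
        start = start, end = end, strand = strand,
        protein_length = aa,
        product = switch(g$class,
                         acr = "anti-CRISPR protein",
                         aca = "Acr-associated HTH regulator",
                         fusion = "Acr-Aca fusion protein",
                         "hypothetical protein"),
        protein_seq = g$seq,
        true_class = g$class, family = g$family, family2 = g$family2,
        fusion_side = g$fusion_side,
        fusion_aca_start = g$fusion_aca_start,
        fusion_aca_end = g$fusion_aca_end,
        stringsAsFactors = FALSE)
      pos <- end
    }
    replicon_lengths[rep_id] <- pos +
      sample(config$intergenic_range[1]:config$intergenic_range[2], 1L)
  }

  all_rows <- do.call(rbind, rows)
  gene_cols <- c("replicon_id", "gene_id", "start", "end", "strand",
                 "protein_length", "product", "protein_seq")
  truth_cols <- c("gene_id", "replicon_id", "true_class", "family", "family2",
                  "start", "end", "strand", "protein_length",
                  "fusion_side", "fusion_aca_start", "fusion_aca_end")
  genes <- genome_annotation(all_rows[, gene_cols], source = "synthetic")
  truth <- all_rows[, truth_cols]
  rownames(truth) <- NULL
  structure(list(genes = genes,
                 proteins = stats::setNames(all_rows$protein_seq, all_rows$gene_id),
                 truth = truth,
                 replicon_lengths = replicon_lengths,
                 config = config),
            class = "acr_sim")
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' @export
print.acr_sim <- function(x, ...) {
  tab <- table(x$truth$true_class)
  cat(sprintf("acr_sim: %d genes on %d replicons (seed %d)\n",
              nrow(x$genes), length(x$replicon_lengths), x$config$seed))
  print(tab)
  invisible(x)
}
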