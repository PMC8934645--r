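#' Optimal global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (default BLOSUM62,
#' gap open 11, gap extend 1, so a gap of length k costs 11 + k). The
#' identity fraction q is computed over residue-residue columns only;
#' columns with a gap in either row are excluded from both the numerator
#' and the denominator.
#'
#' @param seq_a,seq_b amino-acid strings (standard 20-letter alphabet).
#' @param scoring `"BLOSUM62"` or a named substitution matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return A `pairwise_alignment`: list with `aligned_a`, `aligned_b`,
#'   `score`, `n_identical`, `n_aligned_pairs` and `q` (fraction
#'   identical).
#' @export
align_pair <- function(seq_a, seq_b, scoring = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  mat <- if (is.matrix(scoring)) {
    scoring
  } else {
    get(data(list = scoring, package = "Biostrings",
             envir = environment())[1], envir = environment())
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- a != "-" & b != "-"
  n_aligned <- sum(both)
  n_id <- sum(a[both] == b[both])
  structure(list(aligned_a = paste(a, collapse = ""),
                 aligned_b = paste(b, collapse = ""),
                 score = Biostrings::score(pa),
                 n_identical = n_id,
                 n_aligned_pairs = n_aligned,
                 q = if (n_aligned > 0L) n_id / n_aligned else 0),
            class = "pairwise_alignment")
}

check_protein <- function(seq, label) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("align_pair: ", label, " must be a nonempty amino-acid string",
         call. = FALSE)
  }
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET20)
  if (length(bad) > 0L) {
    stop("align_pair: invalid residue(s) in ", label, ": ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: score %.1f, q = %d/%d = %.3f\n",
              x$score, x$n_identical, x$n_aligned_pairs, x$q))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Identity substitution matrix
#'
#' Simple match/mismatch scoring over the 20-residue alphabet, useful
#' for tests and didactic examples.
#'
#' @param match,mismatch scores.
#' @return A 20x20 named numeric matrix.
#' @export
identity_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  diag(m) <- match
  m
}
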