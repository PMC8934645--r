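#' Grishin protein distance
#'
#' The Grishin model relates the fraction of identical residues q to the
#' evolutionary distance d (substitutions/site, with among-site rate
#' variation) through q = ln(1 + 2d) / (2d). The function is strictly
#' decreasing in d, so the inverse is found by bracketed root-finding to
#' |change in q| <= 1e-10. q = 1 maps to d = 0 exactly. Because d
#' diverges as q approaches 0, distances are capped at `d_cap`
#' (default 10 substitutions/site) and capped values are flagged via the
#' `"capped"` attribute.
#'
#' @param q fraction of identical residues, in (0, 1]; vectorized.
#' @param d_cap distance cap for near-saturated pairs.
#' @return Numeric vector of distances with a logical `"capped"`
#'   attribute.
#' @export
grishin_distance <- function(q, d_cap = 10) {
  if (any(is.na(q)) || any(q <= 0 | q > 1)) {
    stop("grishin_distance: q must lie in (0, 1]", call. = FALSE)
  }
  q_cap <- grishin_q(d_cap)
  out <- numeric(length(q))
  capped <- logical(length(q))
  for (i in seq_along(q)) {
    if (q[i] == 1) {
      out[i] <- 0
    } else if (q[i] < q_cap) {
      out[i] <- d_cap
      capped[i] <- TRUE
    } else {
      f <- function(d) grishin_q(d) - q[i]
      r <- stats::uniroot(f, lower = 1e-12, upper = d_cap,
                          tol = .Machine$double.eps^0.75, maxiter = 2000L)
      d <- r$root
      # polish with a few Newton steps until |q(d) - q| <= 1e-10
      for (it in 1:50) {
        err <- grishin_q(d) - q[i]
        if (abs(err) <= 1e-12) break
        slope <- (grishin_q(d + 1e-8) - grishin_q(d - 1e-8)) / 2e-8
        d <- d - err / slope
      }
      out[i] <- d
    }
  }
  attr(out, "capped") <- capped
  out
}

#' Forward Grishin model: expected identity at distance d
#'
#' @param d distance in substitutions/site (>= 0); vectorized.
#' @return q = ln(1 + 2d) / (2d), with q(0) = 1 (the limit).
#' @export
grishin_q <- function(d) {
  if (any(d < 0)) stop("grishin_q: d must be >= 0", call. = FALSE)
  ifelse(d == 0, 1, log1p(2 * d) / (2 * d))
}

#' All-pairs Grishin distance matrix for a protein family
#'
#' Aligns every sequence pair globally, converts identity fractions to
#' Grishin distances, and assembles a symmetric matrix with zero
#' diagonal.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param d_cap distance cap passed to [grishin_distance()].
#' @param ... alignment options passed to [align_pair()].
#' @return A `dist_matrix`: symmetric numeric matrix with taxon
#'   dimnames, `"capped"` logical matrix attribute, and `"q"` attribute
#'   holding the identity fractions.
#' @export
grishin_matrix <- function(seqs, d_cap = 10, ...) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  Q <- matrix(1, n, n, dimnames = dimnames(D))
  capped <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      q <- align_pair(seqs[[i]], seqs[[j]], ...)$q
      q <- max(q, .Machine$double.eps)  # fully dissimilar pairs hit the cap
      d <- grishin_distance(q, d_cap = d_cap)
      D[i, j] <- D[j, i] <- as.numeric(d)
      Q[i, j] <- Q[j, i] <- q
      capped[i, j] <- capped[j, i] <- attr(d, "capped")
    }
  }
  structure(D, q = Q, capped = capped, class = c("dist_matrix", "matrix"))
}
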