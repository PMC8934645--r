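#' Fast minimum-evolution tree from a distance matrix
#'
#' Realizes the fast minimum-evolution method as neighbor joining (the
#' standard greedy ME heuristic) for the topology, followed by
#' ordinary-least-squares branch lengths; negative fitted lengths are
#' clamped to zero and the tree length recomputed. Taxa are sorted
#' lexicographically before NJ, so the result is invariant to input
#' order. On an additive matrix NJ recovers the generating topology and
#' the OLS lengths are exact.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa,
#'   finite entries, zero diagonal).
#' @return An unrooted `ape::phylo` with non-negative branch lengths and
#'   attribute `"tree_length"` (sum of branch lengths).
#' @export
build_me_tree <- function(D) {
  D <- validate_dist_matrix(D)
  taxa <- sort(rownames(D))
  D <- D[taxa, taxa]
  if (length(taxa) == 3L) {
    # three-point formulas give the unique (star) tree exactly
    x <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    x <- pmax(x, 0)
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                                        taxa[1], x[1], taxa[2], x[2],
                                        taxa[3], x[3]))
    attr(tr, "tree_length") <- sum(tr$edge.length)
    return(tr)
  }
  tr <- ape::nj(D)
  tr <- ols_branch_lengths(tr, D)
  tr
}

validate_dist_matrix <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames",
                                 call. = FALSE)
  if (nrow(D) < 3L) stop("build_me_tree: need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(D))) stop("build_me_tree: non-finite distances",
                               call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero",
                                      call. = FALSE)
  D
}

#' Fit OLS branch lengths on a fixed topology
#'
#' Solves the ordinary least-squares problem matching path lengths on
#' the tree to the pairwise distances; negative estimates are clamped to
#' zero and the tree length recomputed after clamping.
#'
#' @param tree an `ape::phylo` (its `tip.label`s must match `D`).
#' @param D distance matrix.
#' @return `tree` with `edge.length` set and attribute `"tree_length"`.
#' @export
ols_branch_lengths <- function(tree, D) {
  taxa <- tree$tip.label
  D <- as.matrix(D)[taxa, taxa]
  n <- length(taxa)
  m <- nrow(tree$edge)
  # leaves on the child side of each edge
  adj <- vector("list", n + tree$Nnode)
  for (e in seq_len(m)) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  side_leaves <- function(v, banned) {
    seen <- v; queue <- v
    while (length(queue) > 0L) {
      x <- queue[1L]; queue <- queue[-1L]
      for (y in adj[[x]]) {
        if (y != banned && !(y %in% seen)) {
          seen <- c(seen, y); queue <- c(queue, y)
        }
      }
      banned <- -1L  # only the first step is banned
    }
    seen[seen <= n]
  }
  pairs <- utils::combn(n, 2L)
  A <- matrix(0, ncol(pairs), m)
  for (e in seq_len(m)) {
    leaves_v <- side_leaves(tree$edge[e, 2L], tree$edge[e, 1L])
    in_v <- seq_len(n) %in% leaves_v
    A[, e] <- xor(in_v[pairs[1L, ]], in_v[pairs[2L, ]])
  }
  dvec <- D[cbind(pairs[1L, ], pairs[2L, ])]
  fit <- stats::lm.fit(A, dvec)
  len <- pmax(fit$coefficients, 0)
  len[is.na(len)] <- 0
  tree$edge.length <- as.numeric(len)
  attr(tree, "tree_length") <- sum(tree$edge.length)
  tree
}

#' Exhaustive minimum-evolution search over all topologies
#'
#' Enumerates every unrooted binary topology on the taxa (105 for six,
#' 945 for seven), fits OLS branch lengths with clamping on each, and
#' returns the topology of minimum total tree length. Intended as a
#' validation mode for [build_me_tree()] at small n.
#'
#' @param D distance matrix (3 to 8 taxa).
#' @return List with `tree` (best `ape::phylo`), `tree_length`, and
#'   `n_topologies` examined.
#' @export
me_exhaustive <- function(D) {
  D <- validate_dist_matrix(D)
  taxa <- sort(rownames(D))
  if (length(taxa) > 8L) {
    stop("me_exhaustive: enumeration supported for <= 8 taxa", call. = FALSE)
  }
  topos <- enumerate_topologies(taxa)
  best <- NULL
  best_len <- Inf
  for (tr in topos) {
    fitted <- if (length(taxa) == 3L) build_me_tree(D) else
      ols_branch_lengths(tr, D)
    if (attr(fitted, "tree_length") < best_len) {
      best <- fitted
      best_len <- attr(fitted, "tree_length")
    }
  }
  list(tree = best, tree_length = best_len, n_topologies = length(topos))
}

#' Enumerate unrooted leaf-labeled topologies
#'
#' Recursive leaf insertion: each topology on k taxa spawns one child
#' per edge when the (k+1)-th taxon is attached, yielding the standard
#' (2k-5)!! count.
#'
#' @param taxa character vector of 3 to 8 taxon labels.
#' @return List of unrooted `ape::phylo` objects without branch lengths.
#' @export
enumerate_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3L, length(taxa) <= 8L)
  n <- length(taxa)
  # edge lists over arbitrary node ids; leaves are 1..n, internal ids count
  # down from -1
  start <- list(edges = rbind(c(-1L, 1L), c(-1L, 2L), c(-1L, 3L)),
                next_internal = -2L)
  grow <- function(state, leaf) {
    out <- list()
    for (e in seq_len(nrow(state$edges))) {
      u <- state$edges[e, 1L]; v <- state$edges[e, 2L]
      w <- state$next_internal
      edges <- rbind(state$edges[-e, , drop = FALSE],
                     c(u, w), c(w, v), c(w, leaf))
      out[[length(out) + 1L]] <- list(edges = edges,
                                      next_internal = w - 1L)
    }
    out
  }
  states <- list(start)
  for (leaf in seq.int(4L, length.out = max(0L, n - 3L))) {
    states <- unlist(lapply(states, grow, leaf = leaf), recursive = FALSE)
  }
  lapply(states, function(s) edge_list_to_phylo(s$edges, taxa))
}

edge_list_to_phylo <- function(edges, taxa) {
  n <- length(taxa)
  adj <- list()
  key <- function(x) as.character(x)
  for (e in seq_len(nrow(edges))) {
    u <- key(edges[e, 1L]); v <- key(edges[e, 2L])
    adj[[u]] <- c(adj[[u]], edges[e, 2L])
    adj[[v]] <- c(adj[[v]], edges[e, 1L])
  }
  newick <- function(node, parent) {
    if (node >= 1L) return(taxa[node])
    kids <- setdiff(adj[[key(node)]], parent)
    paste0("(", paste(vapply(kids, newick, character(1), parent = node),
                      collapse = ","), ")")
  }
  root <- edges[edges[, 1L] < 0L, 1L][1L]
  ape::read.tree(text = paste0(newick(root, NA), ";"))
}
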