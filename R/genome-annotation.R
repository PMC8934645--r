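#' Construct a genome annotation table
#'
#' The central substrate of neighborhood mining: an ordered, stranded gene
#' table covering one or more replicons. Coordinates are 1-based, fully
#' closed intervals (the GenBank/GFF3 convention); conversions to other
#' conventions happen only inside parsers/writers.
#'
#' @param genes data.frame with columns `replicon_id`, `gene_id`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`), `protein_length` (aa) and optionally
#'   `product` and `protein_seq`.
#' @param source character scalar recorded as the annotation source label
#'   (e.g. `"genome"`, `"phage"`, `"prophage"`, `"synthetic"`).
#'
#' @return A `genome_annotation`: the validated data.frame sorted by
#'   `(replicon_id, start)`, with a `source` attribute.
#' @export
genome_annotation <- function(genes, source = "genome") {
  required <- c("replicon_id", "gene_id", "start", "end", "strand",
                "protein_length")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0L) {
    stop("genome_annotation: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"product" %in% names(genes)) genes$product <- ""
  if (!"protein_seq" %in% names(genes)) genes$protein_seq <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$protein_length <- as.integer(genes$protein_length)
  if (anyDuplicated(genes$gene_id)) {
    stop("genome_annotation: duplicated gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(genes$end < genes$start)) {
    stop("genome_annotation: end < start for gene(s): ",
         paste(genes$gene_id[genes$end < genes$start], collapse = ", "),
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("genome_annotation: strand must be '+' or '-'", call. = FALSE)
  }
  if (any(genes$protein_length < 1L)) {
    stop("genome_annotation: protein_length must be >= 1", call. = FALSE)
  }
  has_seq <- !is.na(genes$protein_seq)
  if (any(has_seq & nchar(genes$protein_seq) != genes$protein_length)) {
    bad <- genes$gene_id[has_seq & nchar(genes$protein_seq) != genes$protein_length]
    stop("genome_annotation: protein_seq length != protein_length for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  genes <- genes[order(genes$replicon_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(genes,
            source = source,
            class = c("genome_annotation", "data.frame"))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d replicon(s) [source: %s]\n",
              nrow(x), length(unique(x$replicon_id)),
              attr(x, "source") %||% "genome"))
  print(utils::head(as.data.frame(x)[, c("replicon_id", "gene_id", "start",
                                         "end", "strand", "protein_length")],
                    10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more genes\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a replicon's annotation
#'
#' Flips coordinates and strands of every gene on one replicon, as if the
#' replicon sequence had been reverse-complemented. Neighborhood mining must
#' be invariant under this operation (adjacency and strand-equality are
#' symmetric), which makes it a useful consistency probe.
#'
#' @param genes a `genome_annotation`.
#' @param replicon_id replicon to flip.
#' @param replicon_length length in bp of that replicon; defaults to the
#'   maximum gene end coordinate.
#' @return A `genome_annotation` with the chosen replicon flipped.
#' @export
flip_replicon <- function(genes, replicon_id,
                          replicon_length = NULL) {
  sel <- genes$replicon_id == replicon_id
  if (!any(sel)) stop("flip_replicon: unknown replicon ", replicon_id,
                      call. = FALSE)
  L <- replicon_length %||% max(genes$end[sel])
  new_start <- L - genes$end[sel] + 1L
  new_end <- L - genes$start[sel] + 1L
  genes$start[sel] <- new_start
  genes$end[sel] <- new_end
  genes$strand[sel] <- ifelse(genes$strand[sel] == "+", "-", "+")
  genome_annotation(as.data.frame(genes), source = attr(genes, "source"))
}
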