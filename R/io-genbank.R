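#' Write annotations as a GenBank feature table
#'
#' Emits one GenBank record per replicon with a CDS feature per gene
#' (location, strand via `complement(..)`, `/locus_tag`, `/product` and
#' `/translation` when the protein sequence is available). Records carry
#' the feature table only; no nucleotide ORIGIN block is written, which
#' is sufficient for annotation-level round-trips.
#'
#' @param genes a [genome_annotation()].
#' @param path output file.
#' @param replicon_lengths optional named integer vector of replicon
#'   lengths; defaults to each replicon's maximum gene end.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(genes, path, replicon_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rep_id in unique(genes$replicon_id)) {
    sub <- genes[genes$replicon_id == rep_id, , drop = FALSE]
    L <- if (!is.null(replicon_lengths) && rep_id %in% names(replicon_lengths)) {
      replicon_lengths[[rep_id]]
    } else {
      max(sub$end)
    }
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   PHG",
                       rep_id, L), con)
    writeLines(sprintf("DEFINITION  %s.", rep_id), con)
    writeLines(sprintf("ACCESSION   %s", rep_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    for (i in seq_len(nrow(sub))) {
      loc <- sprintf("%d..%d", sub$start[i], sub$end[i])
      if (sub$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", sub$gene_id[i]), con)
      writeLines(sprintf("                     /product=\"%s\"", sub$product[i]), con)
      if (!is.na(sub$protein_seq[i])) {
        tr <- sub$protein_seq[i]
        chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(44, nchar(tr) + 43, 44), nchar(tr)))
        writeLines(sprintf("                     /translation=\"%s", chunks[1]), con)
        if (length(chunks) > 1L) {
          for (ch in chunks[-1]) writeLines(sprintf("                     %s", ch), con)
        }
        writeLines("                     \"", con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a GenBank feature table
#'
#' Parses CDS features (location, strand, `/locus_tag`, `/product`,
#' `/translation`) from a (possibly multi-record) GenBank flat file into
#' the internal gene table. Nucleotide sequence blocks are skipped.
#'
#' @param path GenBank file.
#' @return A [genome_annotation()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  rows <- list()
  rep_id <- NA_character_
  cds <- NULL
  qual_key <- NULL
  flush_cds <- function() {
    if (is.null(cds)) return()
    seq <- cds$translation
    plen <- if (!is.na(seq)) nchar(seq) else max(1L, (cds$end - cds$start + 1L) %/% 3L - 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      replicon_id = cds$replicon_id, gene_id = cds$locus_tag,
      start = cds$start, end = cds$end, strand = cds$strand,
      protein_length = plen, product = cds$product,
      protein_seq = seq, stringsAsFactors = FALSE)
    cds <<- NULL
  }
  for (ln in lines) {
    if (grepl("^LOCUS ", ln)) {
      flush_cds()
      rep_id <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^\\s{5}CDS\\s", ln)) {
      flush_cds()
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", ln))
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      loc <- gsub("complement\\(|\\)", "", loc)
      parts <- strsplit(loc, "\\.\\.")[[1]]
      if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
        stop("read_genbank: malformed CDS location '", loc, "' in record ",
             rep_id, call. = FALSE)
      }
      cds <- list(replicon_id = rep_id, start = as.integer(parts[1]),
                  end = as.integer(parts[2]), strand = strand,
                  locus_tag = NA_character_, product = "",
                  translation = NA_character_)
      qual_key <- NULL
    } else if (!is.null(cds) && grepl("^\\s{21}/", ln)) {
      q <- trimws(ln)
      m <- regmatches(q, regexec('^/([a-z_]+)="?([^"]*)"?', q))[[1]]
      if (length(m) == 3L) {
        qual_key <- m[2]
        val <- m[3]
        if (qual_key == "locus_tag") cds$locus_tag <- val
        if (qual_key == "product") cds$product <- val
        if (qual_key == "translation") cds$translation <- val
        if (grepl('"\\s*$', q) && qual_key == "translation" &&
            grepl('".*"', q)) qual_key <- NULL
      }
    } else if (!is.null(cds) && !is.null(qual_key) &&
               qual_key == "translation" && grepl("^\\s{21}", ln)) {
      val <- trimws(ln)
      if (identical(val, "\"")) { qual_key <- NULL; next }
      cds$translation <- paste0(cds$translation, gsub('"', "", val))
      if (grepl('"\\s*$', val)) qual_key <- NULL
    } else if (grepl("^//", ln)) {
      flush_cds()
    }
  }
  flush_cds()
  if (length(rows) == 0L) {
    stop("read_genbank: no CDS features found in ", path, call. = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$gene_id)) {
    stop("read_genbank: CDS without /locus_tag in record ",
         paste(unique(out$replicon_id[is.na(out$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  genome_annotation(out, source = "genbank")
}
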