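#' Read a homology hit table
#'
#' Accepts a TSV in the spirit of BLAST tabular output with named
#' columns. Required: `query_family`, `subject_gene_id`,
#' `percent_identity`, `evalue`, `query_coverage`, `subject_start`,
#' `subject_end`. Extra columns are carried through silently; columns are
#' matched by name, not position. Coverage given in percent (values > 1)
#' is normalized to a fraction.
#'
#' @param path TSV file.
#' @return data.frame of typed hit rows (possibly empty, with a warning).
#' @export
read_hit_table <- function(path) {
  required <- c("query_family", "subject_gene_id", "percent_identity",
                "evalue", "query_coverage", "subject_start", "subject_end")
  df <- read_typed_tsv(path, required, "read_hit_table")
  if (nrow(df) == 0L) return(df)
  df$percent_identity <- as.numeric(df$percent_identity)
  df$evalue <- as.numeric(df$evalue)
  df$query_coverage <- normalize_coverage(as.numeric(df$query_coverage))
  df$subject_start <- as.integer(df$subject_start)
  df$subject_end <- as.integer(df$subject_end)
  if (any(df$evalue < 0, na.rm = TRUE)) {
    stop("read_hit_table: negative E-values in ", path, call. = FALSE)
  }
  if (any(df$subject_end < df$subject_start, na.rm = TRUE)) {
    stop("read_hit_table: subject_end < subject_start in ", path, call. = FALSE)
  }
  df
}

#' Read a protein domain annotation table
#'
#' Required columns: `gene_id`, `domain_label`, `probability`,
#' `region_start`, `region_end`.
#'
#' @param path TSV file.
#' @return data.frame of typed domain rows.
#' @export
read_domain_table <- function(path) {
  required <- c("gene_id", "domain_label", "probability",
                "region_start", "region_end")
  df <- read_typed_tsv(path, required, "read_domain_table")
  if (nrow(df) == 0L) return(df)
  df$probability <- as.numeric(df$probability)
  df$region_start <- as.integer(df$region_start)
  df$region_end <- as.integer(df$region_end)
  df
}

#' Read an assay count table
#'
#' Required columns: `acr_label`, `cas9_label`, `assay`, `replicate_id`;
#' measurement columns (any subset): `cfu_matching`/`cfu_mismatching`,
#' `cleaved_fraction`, `efficiency_no4HT`/`efficiency_4HT`.
#'
#' @param path TSV file.
#' @return data.frame of typed assay rows.
#' @export
read_assay_table <- function(path) {
  required <- c("acr_label", "cas9_label", "assay", "replicate_id")
  df <- read_typed_tsv(path, required, "read_assay_table")
  for (col in intersect(c("cfu_matching", "cfu_mismatching"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("read_assay_table: negative counts in column ", col, call. = FALSE)
    }
  }
  for (col in intersect(c("cleaved_fraction", "efficiency_no4HT",
                          "efficiency_4HT"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("cleaved_fraction" %in% names(df) &&
      any(df$cleaved_fraction < 0 | df$cleaved_fraction > 1, na.rm = TRUE)) {
    stop("read_assay_table: cleaved_fraction outside [0, 1]", call. = FALSE)
  }
  df
}

read_typed_tsv <- function(path, required, caller) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t",
                          comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(caller, ": schema error, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(caller, ": ", path, " has a header but no rows", call. = FALSE)
  }
  df
}

normalize_coverage <- function(x) ifelse(!is.na(x) & x > 1, x / 100, x)

#' Write a candidate report as TSV and JSON
#'
#' The TSV carries one row per candidate with its per-criterion evidence
#' columns; the JSON mirrors it and conforms to the schema shipped at
#' `system.file("extdata", "candidates.schema.json", package = "acrmine")`.
#'
#' @param candidates data.frame of candidate loci (see [mine_candidates()]).
#' @param tsv_path output TSV path.
#' @param json_path optional output JSON path (default: TSV path with a
#'   `.json` extension).
#' @return Invisibly, `tsv_path`.
#' @export
write_candidates <- function(candidates, tsv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tsv$", ".json", tsv_path)
  utils::write.table(candidates, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(candidates = candidates), json_path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tsv_path)
}

#' Write a phylogeny in Newick format
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}
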