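sim_for_io <- generate_genomes(sim_config(seed = 21, n_replicons = 3,
                                          n_operons = 3,
                                          aca_families = "AcaF1",
                                          n_fusions = 1,
                                          decoy_spec = c(oversize = 1)))

test_that("genome_annotation validates its invariants", {
  df <- data.frame(replicon_id = "r1", gene_id = c("g1", "g2"),
                   start = c(10, 200), end = c(100, 300),
                   strand = c("+", "-"), protein_length = c(30, 33))
  ga <- genome_annotation(df)
  expect_s3_class(ga, "genome_annotation")
  expect_error(genome_annotation(transform(df, gene_id = "g1")), "duplicated")
  expect_error(genome_annotation(transform(df, end = c(5, 300))), "end < start")
  expect_error(genome_annotation(transform(df, strand = "*")), "strand")
  bad <- df; bad$protein_seq <- c("MK", "MKL")
  expect_error(genome_annotation(bad), "protein_seq length")
})

test_that("GenBank write-then-read preserves coordinates, strands, proteins", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(sim_for_io$genes, gb, sim_for_io$replicon_lengths)
  back <- read_genbank(gb)
  expect_equal(back$gene_id, sim_for_io$genes$gene_id)
  expect_equal(back$start, sim_for_io$genes$start)
  expect_equal(back$end, sim_for_io$genes$end)
  expect_equal(back$strand, sim_for_io$genes$strand)
  expect_equal(back$protein_seq, sim_for_io$genes$protein_seq)
  # complement-strand CDS parse to "-"
  expect_true(any(back$strand == "-"))
})

test_that("malformed GenBank records fail with the locus named", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       repX  500 bp",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..x",
               "//"), gb)
  expect_error(read_genbank(gb), "repX")
})

test_that("GFF3+FASTA round-trips and flags orphan ids", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  write_gff_fasta(sim_for_io$genes, gff, faa)
  back <- read_gff_fasta(gff, faa)
  expect_equal(back$gene_id, sim_for_io$genes$gene_id)
  expect_equal(back$start, sim_for_io$genes$start)
  expect_equal(back$strand, sim_for_io$genes$strand)
  expect_equal(back$protein_seq, sim_for_io$genes$protein_seq)
  # drop one FASTA record -> orphan feature reported by id
  aa <- Biostrings::readAAStringSet(faa)
  missing_id <- names(aa)[1]
  Biostrings::writeXStringSet(aa[-1], faa)
  expect_error(read_gff_fasta(gff, faa), missing_id)
})

test_that("hit tables parse outfmt-6-style columns and normalize coverage", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("query_family", "subject_gene_id", "percent_identity",
                     "evalue", "query_coverage", "subject_start",
                     "subject_end", "bitscore", sep = "\t"),
               "AcrF1\tg1\t85.3\t1e-30\t85\t1\t100\t210",
               "AcrF2\tg2\t44.0\t0.5\t0.85\t5\t60\t33"), tsv)
  h <- read_hit_table(tsv)
  expect_equal(h$query_coverage, c(0.85, 0.85))  # "85" and "0.85" agree
  expect_equal(h$evalue, c(1e-30, 0.5))
  expect_true("bitscore" %in% names(h))  # extra columns pass through
  # missing column -> schema error
  writeLines(c("query_family\tsubject_gene_id", "A\tg1"), tsv)
  expect_error(read_hit_table(tsv), "missing column")
  # empty table -> empty with warning
  writeLines(paste("query_family", "subject_gene_id", "percent_identity",
                   "evalue", "query_coverage", "subject_start",
                   "subject_end", sep = "\t"), tsv)
  expect_warning(h0 <- read_hit_table(tsv), "no rows")
  expect_equal(nrow(h0), 0)
})

test_that("assay and domain tables parse with type checks", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("acr_label\tcas9_label\tassay\treplicate_id\tcfu_matching\tcfu_mismatching",
               "AcrA\tSpyCas9\tbacterial\t1\t90\t120"), tsv)
  a <- read_assay_table(tsv)
  expect_equal(a$cfu_matching, 90L)
  writeLines(c("acr_label\tcas9_label\tassay\treplicate_id\tcleaved_fraction",
               "AcrA\tSpyCas9\thuman\t1\t1.5"), tsv)
  expect_error(read_assay_table(tsv), "cleaved_fraction")
  writeLines(c("gene_id\tdomain_label\tprobability\tregion_start\tregion_end",
               "g1\tHTH\t0.97\t3\t58"), tsv)
  d <- read_domain_table(tsv)
  expect_equal(d$domain_label, "HTH")
})

test_that("candidate reports write TSV+JSON matching the shipped schema", {
  out <- withr::local_tempfile(fileext = ".tsv")
  empty <- acrmine:::empty_candidates()
  write_candidates(empty, out)
  expect_equal(readLines(out)[1],
               paste(names(empty), collapse = "\t"))
  expect_equal(length(readLines(out)), 1)  # header-only
  schema <- jsonlite::read_json(system.file("extdata",
                                            "candidates.schema.json",
                                            package = "acrmine"))
  required <- unlist(schema$properties$candidates$items$required)
  expect_true(all(required %in% names(empty)))
  json <- jsonlite::read_json(sub("\\.tsv$", ".json", out))
  expect_true("candidates" %in% names(json))
})

test_that("Newick write-then-read preserves topology and branch lengths", {
  set.seed(77)
  tr <- random_bltree(5)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(ape::dist.topo(tr, back), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-12)
})

test_that("reverse-complementing a replicon preserves gene geometry", {
  genes <- sim_for_io$genes
  flipped <- flip_replicon(genes, "rep01", sim_for_io$replicon_lengths[["rep01"]])
  sel <- genes$replicon_id == "rep01"
  expect_setequal(flipped$gene_id[flipped$replicon_id == "rep01"],
                  genes$gene_id[sel])
  # double flip is the identity
  twice <- flip_replicon(flipped, "rep01", sim_for_io$replicon_lengths[["rep01"]])
  expect_equal(as.data.frame(twice), as.data.frame(genes))
})
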