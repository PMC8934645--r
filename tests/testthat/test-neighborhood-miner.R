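# shared fixture: mid-size corpus with every planted element class
fix <- local({
  cfg <- sim_config(seed = 31)
  sim <- generate_genomes(cfg)
  list(cfg = cfg, sim = sim,
       hits = generate_hit_table(sim),
       domains = generate_domain_table(sim),
       markers = marker_set(acr = cfg$acr_families, aca = cfg$aca_families),
       params = miner_params())
})

test_that("hit-to-gene labeling applies strict thresholds", {
  genes <- genome_annotation(data.frame(
    replicon_id = "r", gene_id = c("g1", "g2", "g3"),
    start = c(1, 500, 1000), end = c(300, 800, 1300),
    strand = "+", protein_length = 99))
  hits <- data.frame(
    query_family = c("F", "F", "F", "F"),
    subject_gene_id = c("g1", "g2", "g3", "ghost"),
    percent_identity = 50,
    evalue = c(1e-6, 0.001, 1e-6, 1e-6),     # g2 sits exactly on the boundary
    query_coverage = c(0.9, 0.9, 0.70, 0.9), # g3 sits exactly on the boundary
    subject_start = 1, subject_end = 99)
  expect_warning(lab <- map_hits_to_genes(hits, genes), "unknown gene")
  expect_equal(lab$gene_id, "g1")  # boundaries fail strict < and >
})

test_that("labeling matches a brute-force row filter on mixed tables", {
  for (seed in c(101, 102, 103)) {
    cp <- small_corpus(seed)
    lab <- map_hits_to_genes(cp$hits, cp$sim$genes)
    got <- unique(lab[, c("gene_id", "family")])
    got <- got[order(got$gene_id, got$family), ]
    h <- cp$hits
    keep <- h$evalue < 1e-3 & h$query_coverage > 0.70 &
      h$subject_gene_id %in% cp$sim$genes$gene_id
    want <- unique(data.frame(gene_id = h$subject_gene_id[keep],
                              family = h$query_family[keep]))
    want <- want[order(want$gene_id, want$family), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("neighborhood contexts respect window, gaps and replicon edges", {
  g <- as.data.frame(fix$sim$genes)
  first <- g$gene_id[g$replicon_id == "rep01"][1]
  ctx <- build_context(first, fix$sim$genes)
  expect_equal(sum(ctx$neighbors$side == "upstream"), 0)
  # window=1 -> at most one neighbor per side
  any_mid <- g$gene_id[g$replicon_id == "rep01"][3]
  ctx2 <- build_context(any_mid, fix$sim$genes, window_genes = 1)
  expect_lte(sum(ctx2$neighbors$side == "upstream"), 1)
  expect_lte(sum(ctx2$neighbors$side == "downstream"), 1)
  # a tight intergenic cutoff empties the context
  ctx3 <- build_context(any_mid, fix$sim$genes, max_intergenic_bp = 0)
  expect_equal(nrow(ctx3$neighbors), 0)
  # contexts equal a brute-force scan over the sorted gene list
  set.seed(55)
  for (id in sample(g$gene_id, 20)) {
    ctx <- build_context(id, fix$sim$genes, window_genes = 2,
                         max_intergenic_bp = 1000)
    i <- match(id, g$gene_id)
    same_rep <- which(g$replicon_id == g$replicon_id[i])
    rank_i <- match(i, same_rep)
    expected <- character(0)
    for (j in same_rep) {
      if (j == i || abs(match(j, same_rep) - rank_i) > 2) next
      gap <- if (g$start[j] > g$end[i]) g$start[j] - g$end[i] - 1
             else if (g$start[i] > g$end[j]) g$start[i] - g$end[j] - 1 else 0
      if (gap <= 1000) expected <- c(expected, g$gene_id[j])
    }
    expect_setequal(ctx$neighbors$gene_id, expected)
  }
})

test_that("single-gene classifiers reproduce the printed criteria", {
  genes <- genome_annotation(data.frame(
    replicon_id = "r",
    gene_id = c("acr1", "aca1", "acr2", "opp", "big", "acr3"),
    start = c(100, 600, 1100, 1600, 2100, 3400),
    end = c(400, 900, 1400, 1900, 3200, 3700),
    strand = c("+", "+", "+", "-", "+", "+"),
    protein_length = c(90, 100, 85, 80, 300, 95)))
  hits <- data.frame(query_family = c("FA", "FB", "GA", "FA"),
                     subject_gene_id = c("acr1", "acr2", "aca1", "acr3"),
                     percent_identity = 60, evalue = 1e-9,
                     query_coverage = 0.92, subject_start = 1,
                     subject_end = 80)
  domains <- data.frame(gene_id = "aca1", domain_label = "HTH",
                        probability = 0.95, region_start = 5, region_end = 60)
  markers <- marker_set(acr = c("FA", "FB", "FC"), aca = "GA")
  p <- miner_params()
  labels <- map_hits_to_genes(hits, genes)
  assoc3 <- structure(list(pairs = data.frame(), counts = c(GA = 3L)),
                      class = "association_graph")
  ctx <- build_labeled_context("aca1", genes, labels, markers, p)
  res <- classify_aca(ctx, domains, assoc3, p)
  expect_true(res$qualifies)  # HTH + same-strand Acr neighbors + 3 > 2
  # same gene with association 2 is rejected (strictly more than two)
  assoc2 <- structure(list(pairs = data.frame(), counts = c(GA = 2L)),
                      class = "association_graph")
  expect_false(classify_aca(ctx, domains, assoc2, p)$qualifies)
  # opposite-strand neighbor fails orientation
  ctx_opp <- build_labeled_context("opp", genes, labels, markers, p)
  res_opp <- classify_aca(ctx_opp, domains, assoc3, p)
  expect_false(res_opp$qualifies)
  # acr candidate: small protein next to an Aca marker, standard tier
  res_acr <- classify_acr_candidate(
    build_labeled_context("acr1", genes, labels, markers, p), p)
  expect_true(res_acr$qualifies)
  expect_equal(res_acr$confidence_tier, "standard")
  # 300-aa protein otherwise perfect is rejected: strict < 300
  res_big <- classify_acr_candidate(
    build_labeled_context("big", genes, labels, markers, p), p)
  expect_false(res_big$qualifies)
  expect_false(res_big$size_ok)
  expect_true(res_big$adjacent_marker)
})

test_that("fusion geometry calls match the terminal rule", {
  genes <- genome_annotation(data.frame(
    replicon_id = "r", gene_id = "f1", start = 1, end = 603,
    strand = "+", protein_length = 200))
  p <- miner_params()  # terminal_fraction 0.4 -> N-terminal 80 aa
  call <- detect_fusion("f1", genes, data.frame(start = 5, end = 60), p)
  expect_equal(call$terminal_side, "N")
  expect_equal(call$acr_remainder_length, 140)
  # interval straddling the midpoint -> no call
  expect_null(detect_fusion("f1", genes, data.frame(start = 70, end = 130), p))
  # C-terminal call
  cc <- detect_fusion("f1", genes, data.frame(start = 150, end = 195), p)
  expect_equal(cc$terminal_side, "C")
  expect_equal(cc$acr_remainder_length, 149)
  # remainder below the floor -> no call
  p2 <- miner_params(min_remainder_aa = 150)
  expect_null(detect_fusion("f1", genes, data.frame(start = 5, end = 60), p2))
})

test_that("planted fusions are recovered with no false fusion calls", {
  n_checked <- 0
  for (seed in 1:20) {
    cp <- small_corpus(seed)
    cands <- mine_candidates(cp$sim$genes, cp$hits, cp$domains,
                             marker_set(acr = cp$cfg$acr_families,
                                        aca = cp$cfg$aca_families),
                             miner_params(), audit = TRUE)
    acr_rows <- cands[cands$candidate_class == "acr_candidate", ]
    tr <- cp$sim$truth
    fus_ids <- tr$gene_id[tr$true_class == "fusion"]
    called <- acr_rows$gene_id[acr_rows$fusion]
    expect_setequal(called, fus_ids)
    sides <- acr_rows$fusion_side[match(fus_ids, acr_rows$gene_id)]
    expect_equal(sides, tr$fusion_side[match(fus_ids, tr$gene_id)])
    n_checked <- n_checked + length(fus_ids)
  }
  expect_gte(n_checked, 20)
})

test_that("association graph equals brute-force pair enumeration", {
  labels <- map_hits_to_genes(fix$hits, fix$sim$genes)
  assoc <- build_association_graph(fix$sim$genes, labels, fix$markers,
                                   fix$params)
  expect_true(all(assoc$pairs$n_loci >= 1))
  # brute force: for every family, union of acr families among same-strand
  # direct neighbors of its members
  g <- as.data.frame(fix$sim$genes)
  acr_fams <- fix$cfg$acr_families
  rel <- unique(labels[, c("gene_id", "family")])
  for (fam in unique(rel$family)) {
    members <- rel$gene_id[rel$family == fam]
    seen <- character(0)
    for (id in members) {
      i <- match(id, g$gene_id)
      same_rep <- which(g$replicon_id == g$replicon_id[i])
      rank_i <- match(i, same_rep)
      for (dr in c(-1, 1)) {
        j <- same_rep[rank_i + dr]
        if (is.na(j)) next
        gap <- if (g$start[j] > g$end[i]) g$start[j] - g$end[i] - 1
               else g$start[i] - g$end[j] - 1
        if (gap > 1000 || g$strand[i] != g$strand[j]) next
        seen <- union(seen, intersect(rel$family[rel$gene_id == g$gene_id[j]],
                                      acr_fams))
      }
    }
    got <- if (fam %in% names(assoc$counts)) assoc$counts[[fam]] else 0L
    expect_equal(got, length(seen), info = fam)
  }
})

test_that("corpus mining matches the brute-force criteria oracle", {
  for (seed in c(201, 202, 203, 204, 205)) {
    cp <- small_corpus(seed, with_nd = seed %% 2 == 0)
    markers <- marker_set(acr = cp$cfg$acr_families,
                          aca = cp$cfg$aca_families)
    got <- miner_sets(mine_candidates(cp$sim$genes, cp$hits, cp$domains,
                                      markers, miner_params()))
    want <- oracle_mine(cp$sim$genes, cp$hits, cp$domains,
                        cp$cfg$acr_families, cp$cfg$aca_families)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("candidate sets are invariant under replicon reverse-complement", {
  cands0 <- miner_sets(mine_candidates(fix$sim$genes, fix$hits, fix$domains,
                                       fix$markers, fix$params))
  genes_f <- fix$sim$genes
  for (rep_id in c("rep01", "rep05", "rep11")) {
    genes_f <- flip_replicon(genes_f, rep_id,
                             fix$sim$replicon_lengths[[rep_id]])
  }
  cands1 <- miner_sets(mine_candidates(genes_f, fix$hits, fix$domains,
                                       fix$markers, fix$params))
  expect_identical(cands0, cands1)
})

test_that("the search-validation loop expands markers monotonically", {
  chain <- local({
    genes <- genome_annotation(data.frame(
      replicon_id = "r1",
      gene_id = c("gA1", "gB1", "gA2", "gB2", "gA3", "gB3", "gC1"),
      start = seq(100, by = 500, length.out = 7),
      end = seq(400, by = 500, length.out = 7),
      strand = "+", protein_length = 90))
    hits <- data.frame(
      query_family = c("A1", "B", "A2", "B", "A3", "B", "C"),
      subject_gene_id = c("gA1", "gB1", "gA2", "gB2", "gA3", "gB3", "gC1"),
      percent_identity = 50, evalue = 1e-20, query_coverage = 0.9,
      subject_start = 1, subject_end = 90)
    domains <- data.frame(gene_id = c("gB1", "gB2", "gB3"),
                          domain_label = "HTH", probability = 0.95,
                          region_start = 5, region_end = 60)
    list(genes = genes, hits = hits, domains = domains,
         seeds = marker_set(acr = c("A1", "A2", "A3")))
  })
  # reject-all validator: fixed point after one iteration, seeds only
  rej <- search_validation_loop(chain$seeds, chain$genes, chain$hits,
                                chain$domains, validator_reject_all())
  expect_equal(nrow(rej$audit), 1)
  expect_equal(sort(rej$markers$families$family), c("A1", "A2", "A3"))
  # accept-all on a 2-hop chain: aca family B at iteration 1, second acr
  # family C at iteration 2
  acc <- search_validation_loop(chain$seeds, chain$genes, chain$hits,
                                chain$domains, validator_accept_all())
  fam <- acc$markers$families
  expect_equal(fam$iteration[fam$family == "B"], 1L)
  expect_equal(fam$type[fam$family == "B"], "aca")
  expect_equal(fam$iteration[fam$family == "C"], 2L)
  expect_equal(fam$type[fam$family == "C"], "acr")
  # monotonicity on the synthetic corpus with a truth validator
  seeds <- marker_set(acr = fix$cfg$acr_families[1])
  res <- search_validation_loop(seeds, fix$sim$genes, fix$hits, fix$domains,
                                validator_from_truth(fix$sim$truth),
                                fix$params)
  it <- res$markers$families$iteration
  expect_true(all(diff(sort(it)) >= 0))
  expect_lte(max(it), length(unique(na.omit(fix$sim$truth$family))))
  # every seed family is retained
  expect_true(all(c(fix$cfg$acr_families[1]) %in%
                    res$markers$families$family))
})
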