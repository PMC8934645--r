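test_that("a minimal simulation plants one adjacent same-strand operon", {
  cfg <- sim_config(seed = 1, n_replicons = 1, genes_per_replicon = c(6, 8),
                    n_operons = 3, n_fusions = 0,
                    decoy_spec = c(oversize = 0, wrong_strand = 0,
                                   non_adjacent = 0, no_domain_aca = 0,
                                   low_association_aca = 0),
                    aca_families = "AcaF1")
  sim <- generate_genomes(cfg)
  truth <- sim$truth
  expect_setequal(unique(truth$true_class), c("acr", "aca", "background"))
  acrs <- truth[truth$true_class == "acr", ]
  acas <- truth[truth$true_class == "aca", ]
  expect_equal(nrow(acrs), 3)
  expect_equal(nrow(acas), 3)
  expect_true(all(acrs$protein_length < 300))
  # each aca is immediately adjacent (by gene rank) and same strand as an acr
  g <- as.data.frame(sim$genes)
  for (i in seq_len(nrow(acas))) {
    rank_aca <- match(acas$gene_id[i], g$gene_id)
    nb <- g[abs(seq_len(nrow(g)) - rank_aca) == 1 &
              g$replicon_id == acas$replicon_id[i], ]
    partner <- nb[nb$gene_id %in% acrs$gene_id, ]
    expect_gte(nrow(partner), 1)
    expect_true(any(partner$strand == acas$strand[i]))
  }
})

test_that("simulation output is byte-identical under a fixed seed", {
  s1 <- generate_genomes(sim_config(seed = 11))
  s2 <- generate_genomes(sim_config(seed = 11))
  expect_identical(s1, s2)
  expect_identical(generate_hit_table(s1, seed = 5),
                   generate_hit_table(s2, seed = 5))
  expect_identical(generate_domain_table(s1, seed = 5),
                   generate_domain_table(s2, seed = 5))
})

test_that("every gene appears exactly once in the truth ledger", {
  sim <- generate_genomes(sim_config(seed = 4))
  expect_setequal(sim$truth$gene_id, sim$genes$gene_id)
  expect_equal(anyDuplicated(sim$truth$gene_id), 0)
  # decoys name exactly the criterion they violate
  decoys <- sim$truth$true_class[startsWith(sim$truth$true_class, "decoy:")]
  expect_true(all(decoys %in% c("decoy:size", "decoy:strand",
                                "decoy:adjacency", "decoy:no_domain",
                                "decoy:low_association")))
  oversize <- sim$truth[sim$truth$true_class == "decoy:size", ]
  expect_true(all(oversize$protein_length >= 300))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(acr_length_range = c(50, 300)), "< 300")
  expect_error(sim_config(decoy_spec = c(no_domain_aca = 1)), "no_domain_aca")
  expect_error(sim_config(n_operons = 2, aca_families = "A1"), "3 \\*")
  expect_error(sim_config(n_replicons = 1, genes_per_replicon = c(3, 4)),
               "too small")
})

test_that("hit tables cover planted members and respect fusion geometry", {
  sim <- generate_genomes(sim_config(seed = 9))
  hits0 <- generate_hit_table(sim, spurious_fraction = 0,
                              coverage_range = c(1, 1))
  planted <- sim$truth[!is.na(sim$truth$family), ]
  expect_setequal(unique(hits0$subject_gene_id), planted$gene_id)
  expect_true(all(hits0$query_coverage == 1))
  expect_true(all(hits0$evalue < 1e-5))
  fus <- sim$truth[sim$truth$true_class == "fusion", ]
  for (i in seq_len(nrow(fus))) {
    h <- hits0[hits0$subject_gene_id == fus$gene_id[i], ]
    expect_equal(nrow(h), 2)
    aca_hit <- h[h$query_family == fus$family2[i], ]
    expect_equal(aca_hit$subject_start, fus$fusion_aca_start[i])
    expect_equal(aca_hit$subject_end, fus$fusion_aca_end[i])
    # the aca-matching segment is confined to the terminal 40%
    L <- fus$protein_length[i]
    term <- floor(0.4 * L)
    expect_true(aca_hit$subject_end <= term ||
                  aca_hit$subject_start >= L - term + 1)
  }
  # spurious hits never pass the strict E-value filter
  hits <- generate_hit_table(sim, spurious_fraction = 0.5)
  spurious <- hits[!(hits$subject_gene_id %in% planted$gene_id), ]
  expect_gt(nrow(spurious), 0)
  expect_true(all(spurious$evalue >= 1e-3))
})

test_that("domain tables mark planted acas and honor the FP rate", {
  sim <- generate_genomes(sim_config(seed = 13))
  d0 <- generate_domain_table(sim, false_positive_rate = 0)
  expected <- sim$truth$gene_id[sim$truth$true_class %in%
                                  c("aca", "decoy:low_association")]
  expect_setequal(d0$gene_id, expected)
  expect_true(all(d0$domain_label %in% c("HTH", "AP2")))
  d1 <- generate_domain_table(sim, false_positive_rate = 1)
  expect_setequal(d1$gene_id, sim$genes$gene_id)
})

test_that("family simulation matches the closed-form expected identity", {
  # identical under zero branch lengths
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  root <- random_protein_str(120)
  s0 <- simulate_family(tr0, root, seed = 2)
  expect_true(all(s0 == root))
  # Monte-Carlo mean identity vs closed form at two path lengths
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.2,(c:0.05,d:0.3):0.2);")
  paths <- ape::cophenetic.phylo(tr)
  ident <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    mean(cx == cy)
  }
  obs_ab <- obs_ad <- numeric(200)
  set.seed(99)
  root2 <- random_protein_str(150)
  for (r in 1:200) {
    s <- simulate_family(tr, root2, seed = 10000 + r)
    obs_ab[r] <- ident(s[["a"]], s[["b"]])
    obs_ad[r] <- ident(s[["a"]], s[["d"]])
  }
  expect_lt(mean(obs_ad), mean(obs_ab))  # longer path, lower identity
  expect_equal(mean(obs_ab), expected_identity(paths["a", "b"]),
               tolerance = 0.02)
  expect_equal(mean(obs_ad), expected_identity(paths["a", "d"]),
               tolerance = 0.02)
  # seeded reproducibility
  expect_identical(simulate_family(tr, root2, seed = 5),
                   simulate_family(tr, root2, seed = 5))
})

test_that("assay count simulation matches its Poisson contract", {
  t0 <- simulate_assay_counts(0, n_replicates = 10, mean_cfu = 300, seed = 1)
  expect_true(all(t0$cfu_matching == 0))
  t100 <- simulate_assay_counts(100, n_replicates = 2000, mean_cfu = 200,
                                seed = 2)
  expect_equal(mean(t100$cfu_matching), mean(t100$cfu_mismatching),
               tolerance = 0.02)
  expect_identical(simulate_assay_counts(60, seed = 3),
                   simulate_assay_counts(60, seed = 3))
})
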