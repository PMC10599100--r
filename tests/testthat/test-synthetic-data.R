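test_that("generated proteins carry their class's diagnostic features", {
  set.seed(2)
  wxlip <- generate_protein("WXLIP_FULL")
  expect_true(nchar(wxlip$sequence) >= 337 && nchar(wxlip$sequence) <= 365)
  expect_equal(nrow(scan_pgbd_anchor(wxlip$sequence)), 1)
  expect_setequal(wxlip$hits$domain, c("PGBD", "HBD"))
  expect_true(nrow(detect_tmh(wxlip$sequence)) >= 1)

  small <- generate_protein("WXL_SMALL")
  expect_gte(nrow(scan_wxl_motifs(small$sequence)), 1)

  large <- generate_protein("WXL_LARGE")
  m <- scan_wxl_motifs(large$sequence)
  expect_gte(nrow(m), 1)
  expect_gte(max(m$end), nchar(large$sequence) - 15)

  decoy <- generate_protein("DECOY")
  expect_equal(nrow(scan_wxl_motifs(decoy$sequence)), 0)
  expect_equal(nrow(scan_pgbd_anchor(decoy$sequence)), 0)

  expect_error(generate_protein("NOT_A_CLASS"), "class")
})

test_that("the same seed reproduces byte-identical genome bundles", {
  cfg <- synthetic_config(seed = 99, genes_per_replicon = 30)
  g1 <- generate_genome(cfg, dir = withr::local_tempdir())
  g2 <- generate_genome(cfg, dir = withr::local_tempdir())
  expect_identical(readLines(g1$genbank_path), readLines(g2$genbank_path))
  expect_identical(readLines(g1$domtblout_path),
                   readLines(g2$domtblout_path))
  expect_equal(g1$truth$proteins, g2$truth$proteins)
  g3 <- generate_genome(synthetic_config(seed = 100,
                                         genes_per_replicon = 30),
                        dir = withr::local_tempdir())
  expect_false(identical(readLines(g1$genbank_path),
                         readLines(g3$genbank_path)))
})

test_that("truth manifests encode the adjacency rule on the planted gaps", {
  # gaps of 0 and 4 chain: one simple qualifying cluster
  g <- generate_genome(synthetic_config(
    seed = 3, genes_per_replicon = 35,
    planted_clusters = list(cluster_spec(gaps = c(0, 4)))))
  expect_equal(sum(g$truth$clusters$qualifies), 1)
  expect_equal(sum(g$truth$clusters$simple), 1)

  # a gap of 5 splits the plant; neither fragment has 1 WxLIP + 2 WxL
  g2 <- generate_genome(synthetic_config(
    seed = 3, genes_per_replicon = 35,
    planted_clusters = list(
      cluster_spec(c("WXLIP_FULL", "WXL_SMALL", "WXL_LARGE"),
                   gaps = c(0, 5)))))
  expect_equal(sum(g2$truth$clusters$qualifies), 0)

  # capacity is enforced
  expect_error(generate_genome(synthetic_config(
    seed = 1, genes_per_replicon = 10)), "capacity")
})

test_that("spurious domain rows above the cutoff never alter a call", {
  cfg_clean <- synthetic_config(seed = 41, genes_per_replicon = 30,
                                n_spurious_hits = 0L)
  cfg_noisy <- synthetic_config(seed = 41, genes_per_replicon = 30,
                                n_spurious_hits = 40L)
  g_clean <- generate_genome(cfg_clean, dir = withr::local_tempdir())
  g_noisy <- generate_genome(cfg_noisy, dir = withr::local_tempdir())
  classify <- function(g) {
    p <- read_genbank(g$genbank_path, genome_id = "g")
    classify_architecture(p, merge_hits(parse_domtblout(g$domtblout_path)))
  }
  c1 <- classify(g_clean)
  c2 <- classify(g_noisy)
  expect_equal(c1$arch_class, c2$arch_class)
  # and all spurious rows really are above the cutoff
  all_rows <- parse_domtblout(g_noisy$domtblout_path, evalue_max = Inf)
  expect_equal(sum(all_rows$evalue >= 1e-10), 40)
})

test_that("planted MSA columns are recovered exactly at the threshold", {
  msa <- generate_msa(n_seqs = 175, n_cols = 40, conserved_cols = c(3, 7),
                      threshold_count = 60, seed = 6)
  prof <- column_conservation(msa$alignment, threshold = 60)
  expect_equal(which(prof$conserved), c(3, 7))
  expect_true(all(prof$majority_count[c(3, 7)] == 60))

  # planting at count 59 recovers nothing at threshold 60
  msa59 <- generate_msa(n_seqs = 175, n_cols = 40, conserved_cols = c(3, 7),
                        threshold_count = 59, seed = 6)
  prof59 <- column_conservation(msa59$alignment, threshold = 60)
  expect_equal(sum(prof59$conserved), 0)

  # determinism
  m1 <- generate_msa(n_seqs = 30, n_cols = 10, conserved_cols = 2,
                     threshold_count = 10, seed = 12)
  m2 <- generate_msa(n_seqs = 30, n_cols = 10, conserved_cols = 2,
                     threshold_count = 10, seed = 12)
  expect_equal(m1$alignment, m2$alignment)

  # infeasible configurations are refused
  expect_error(generate_msa(n_seqs = 175, n_cols = 5, conserved_cols = 1,
                            threshold_count = 8), "infeasible")
})

test_that("the full pipeline reproduces the planted truth end to end", {
  cfgs <- list(
    synthetic_config(seed = 201, genes_per_replicon = 35,
                     planted_clusters = list(cluster_spec(gaps = c(1, 3)))),
    synthetic_config(seed = 202, n_replicons = 2, genes_per_replicon = 40,
                     planted_clusters = list(
                       cluster_spec(),
                       cluster_spec(c("WXLIP_FULL", "WXLIP_FULL", "WXL_SMALL",
                                      "WXL_SMALL", "WXL_LARGE"),
                                    gaps = c(2, 0, 4, 1)))),
    synthetic_config(seed = 203, genes_per_replicon = 40,
                     planted_clusters = list(
                       cluster_spec(c("WXLIP_FULL", "WXL_SMALL"), gaps = 0),
                       cluster_spec(c("PGBD_ONLY", "HBD_ONLY"), gaps = 6))))
  for (cfg in cfgs) {
    g <- generate_genome(cfg, dir = withr::local_tempdir())
    p <- read_genbank(g$genbank_path, genome_id = cfg$genome_id)
    calls <- classify_architecture(
      p, merge_hits(parse_domtblout(g$domtblout_path)))
    truth_p <- g$truth$proteins
    cmp <- dplyr::left_join(calls,
                            truth_p[, c("protein_id", "true_class")],
                            by = "protein_id")
    expect_true(all(
      (cmp$true_class == "DECOY" & cmp$arch_class == "OTHER") |
        cmp$arch_class == cmp$true_class))
    clusters <- evaluate_clusters(find_candidates(calls))
    got_q <- dplyr::arrange(clusters[clusters$qualifies, ],
                            replicon_id, ordinal_min)
    exp_q <- dplyr::arrange(g$truth$clusters[g$truth$clusters$qualifies, ],
                            replicon_id, ordinal_min)
    expect_equal(got_q$ordinal_min, exp_q$ordinal_min)
    expect_equal(got_q$ordinal_max, exp_q$ordinal_max)
    expect_equal(got_q$simple, exp_q$simple)
  }
})
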