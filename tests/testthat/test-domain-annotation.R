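test_that("domtblout rows are kept only below the E-value cutoff", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment",
               domtbl_row("prot1", "WxL", "PF13731.8", 1e-9, 10, 60),
               domtbl_row("prot1", "WxL", "PF13731.8", 1e-11, 100, 150)),
             f)
  h <- parse_domtblout(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$evalue, 1e-11)
  expect_equal(h$env_start, 99)   # 1-based inclusive -> 0-based half-open
  expect_equal(h$env_end, 150)
})

test_that("comment-only files give an empty hit table", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# target name ...", "#"), f)
  expect_equal(nrow(parse_domtblout(f)), 0)
})

test_that("coordinate conversion and filtering match a hand oracle on mixed rows", {
  set.seed(5)
  ev <- c(1e-20, 5e-3, 1e-15, 2e-9, 1e-50, 0.5, 1e-12, 1e-4, 3e-11, 1)
  from <- sample(1:200, 10)
  to <- from + sample(30:120, 10)
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(vapply(1:10, function(i) {
    domtbl_row(sprintf("p%02d", i), "DUF916", "PF06040.14", ev[i],
               from[i], to[i])
  }, ""), f)
  h <- parse_domtblout(f)
  keep <- which(ev < 1e-10)
  expect_setequal(h$protein_id, sprintf("p%02d", keep))
  h <- h[order(match(h$protein_id, sprintf("p%02d", keep))), ]
  expect_equal(h$env_start, from[keep] - 1L)
  expect_equal(h$env_end, to[keep])
  expect_true(all(h$domain == "PGBD"))
})

test_that("unmapped models are ignored with a warning; malformed rows error", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(domtbl_row("p1", "PF99999", "PF99999.1", 1e-30, 5, 80),
               domtbl_row("p2", "DUF3324", "PF11797.10", 1e-30, 5, 80)), f)
  expect_warning(h <- parse_domtblout(f), "unmapped")
  expect_equal(h$domain, "HBD")

  f2 <- withr::local_tempfile(fileext = ".domtblout")
  writeLines("p1 WxL too few fields", f2)
  expect_error(parse_domtblout(f2), "line 1")
})

test_that("E-value filtering is monotone in the threshold", {
  set.seed(9)
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(vapply(1:40, function(i) {
    domtbl_row(sprintf("p%02d", i), "WxL", "PF13731.8",
               10^runif(1, -40, 0), 1, 100)
  }, ""), f)
  thresholds <- c(1e-30, 1e-20, 1e-10, 1e-5, 1)
  counts <- vapply(thresholds, function(t) {
    nrow(parse_domtblout(f, evalue_max = t))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  # subset relation, not just counts
  lo <- parse_domtblout(f, evalue_max = 1e-20)
  hi <- parse_domtblout(f, evalue_max = 1e-5)
  expect_true(all(lo$protein_id %in% hi$protein_id))
})

test_that("merge_hits keeps the best of heavily overlapping same-domain hits", {
  one <- tibble::tibble(protein_id = "p", domain = "PGBD",
                        env_start = 10L, env_end = 150L,
                        evalue = 1e-20, source = "hmmer")
  expect_equal(merge_hits(one), one)

  two <- tibble::tibble(protein_id = "p", domain = "PGBD",
                        env_start = c(10L, 20L), env_end = c(150L, 155L),
                        evalue = c(1e-20, 1e-12), source = "hmmer")
  m <- merge_hits(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$evalue, 1e-20)

  # different domains are never merged even at full overlap
  mixed <- dplyr::mutate(two, domain = c("PGBD", "HBD"))
  expect_equal(nrow(merge_hits(mixed)), 2)
})

test_that("merge_hits agrees with the subset fixed-point oracle on random inputs", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    d <- tibble::tibble(
      protein_id = "p", domain = "WXL",
      env_start = as.integer(sample(0:150, n)),
      evalue = 10^runif(n, -40, -11), source = "hmmer")
    d$env_end <- d$env_start + as.integer(sample(20:100, n, replace = TRUE))
    surv <- merge_hits(d)
    idx <- oracle_suppress(d)
    expected <- dplyr::arrange(d[idx, ], env_start)
    expect_equal(surv$env_start, expected$env_start)
    expect_equal(surv$evalue, expected$evalue)
  }
})

test_that("WxL pair scanner matches enumeration and the domain-length envelope", {
  expect_equal(nrow(scan_wxl_motifs("AAAA")), 0)
  expect_equal(nrow(scan_wxl_motifs("WA")), 0)   # shorter than a motif

  s <- strrep("A", 200)
  plant <- function(s, i) {  # 0-based W.L
    substr(s, i + 1, i + 1) <- "W"; substr(s, i + 3, i + 3) <- "L"; s
  }
  s <- plant(plant(s, 10), 150)
  hits <- scan_wxl_motifs(s)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$pos1, hits$pos2), c(10, 150))
  expect_equal(c(hits$start, hits$end), c(10, 153))

  # span 243 exceeds the 190-residue domain envelope
  s2 <- plant(plant(strrep("A", 300), 10), 250)
  expect_equal(nrow(scan_wxl_motifs(s2)), 0)
  # separation below the adjacency floor
  s3 <- plant(plant(strrep("A", 100), 10), 30)
  expect_equal(nrow(scan_wxl_motifs(s3)), 0)
})

test_that("motif scanners equal brute-force enumeration on random sequences", {
  set.seed(77)
  for (rep in 1:300) {
    s <- random_aa(sample(3:260, 1))
    got <- scan_wxl_motifs(s)
    exp <- oracle_wxl_pairs(s)
    expect_equal(nrow(got), length(exp))
    if (length(exp)) {
      em <- do.call(rbind, exp)
      em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
      gm <- as.matrix(got[order(got$pos1, got$pos2), c("pos1", "pos2")])
      expect_equal(unname(gm), unname(em))
    }
    expect_equal(scan_pgbd_anchor(s)$start, oracle_anchor_offsets(s))
  }
  # seed the anchor explicitly since it is vanishingly rare at random
  s <- paste0(random_aa(50), "NQIDKGHTYFDLK", random_aa(50))
  expect_equal(scan_pgbd_anchor(s)$start, oracle_anchor_offsets(s))
  expect_equal(scan_pgbd_anchor(s)$start, 50L)
})

test_that("PGBD anchor requires every fixed position", {
  expect_equal(scan_pgbd_anchor("NQIDKAAAYFDLK")$start, 0L)
  expect_equal(nrow(scan_pgbd_anchor("NQIDKAAAYFDLA")), 0)
  # overlapping occurrences are all reported
  s <- "NQIDKNQIDKAAAYFDLKAAYFDLK"
  expect_equal(scan_pgbd_anchor(s)$start,
               oracle_anchor_offsets(s))
})

test_that("TMH detector fires on a C-terminal hydrophobic tract only", {
  expect_equal(nrow(detect_tmh(strrep("D", 150))), 0)
  expect_equal(nrow(detect_tmh("LLL")), 0)  # shorter than the window

  cterm <- paste0(strrep("S", 100), strrep("L", 22))
  span <- detect_tmh(cterm)
  expect_equal(nrow(span), 1)
  expect_true(span$start <= 100 && span$end >= 122 - 1)
  expect_gte(span$hydropathy, 1.6)

  nterm <- paste0(strrep("L", 22), strrep("S", 100))
  expect_equal(nrow(detect_tmh(nterm)), 0)
})

test_that("TMH spans never overlap and each carries a window above threshold", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(60:300, 1)
    s <- random_aa(n)
    # occasionally splice in a hydrophobic tract near the C-terminus
    if (rep %% 2 == 0) {
      tract <- paste(sample(c("L", "I", "V", "F"), 22, replace = TRUE),
                     collapse = "")
      s <- paste0(substr(s, 1, n - 30), tract, substr(s, n - 7, n))
    }
    spans <- detect_tmh(s)
    if (nrow(spans) > 1) {
      expect_true(all(spans$start[-1] >= spans$end[-nrow(spans)]))
    }
    if (nrow(spans) > 0) {
      kd <- wxlsurvey:::kd_values(s)
      for (i in seq_len(nrow(spans))) {
        w <- 19
        starts <- (spans$start[i] + 1):(spans$end[i] - w + 1)
        means <- vapply(starts, function(p) mean(kd[p:(p + w - 1)]), 0)
        expect_gte(max(means), 1.6)
        expect_equal(spans$hydropathy[i], max(means))
      }
    }
  }
})

test_that("signal-peptide heuristic follows the n-region/h-region rule", {
  pos <- paste0("MKKLLLLLLLL", "AAS", strrep("A", 50))
  call <- detect_signal_peptide(pos)
  expect_true(call$present)
  expect_lte(call$cleavage_hint, 45)

  expect_false(detect_signal_peptide(strrep("E", 80))$present)
  expect_false(detect_signal_peptide("MKL")$present)  # too short

  # output depends only on the first 45 residues
  tail1 <- paste0(substr(pos, 1, 45), strrep("D", 100))
  tail2 <- paste0(substr(pos, 1, 45), strrep("L", 100))
  expect_equal(detect_signal_peptide(tail1), detect_signal_peptide(tail2))
})

test_that("motif evidence flows through the shared filter pathway", {
  g <- generate_protein("WXL_SMALL")
  hits <- motif_hits_as_domain_hits("p1", g$sequence)
  expect_true(all(hits$evalue < 1e-10))
  expect_true(all(hits$source == "motif"))
  expect_true("WXL" %in% hits$domain)
})
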