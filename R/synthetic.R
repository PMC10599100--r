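# Seeded synthetic genomes with planted WxL clusters and known truth.
#
# The generator emulates the statistical structure of the genome survey:
# replicons carry decoy genes plus planted clusters of relevant proteins
# (default: the common simple arrangement of 1 WxLIP + 2 WxL), with
# configurable intervening-decoy gaps. Background residues are sampled
# uniformly over the 19 standard residues excluding tryptophan, so WxL
# motif pairs occur only where planted; decoy genes are motif-scrubbed
# the same way. It makes no attempt to mimic real codon usage, GC
# content, or phylogenetic correlation.

#' Specify one planted gene cluster
#'
#' @param members Character vector of architecture classes in gene order,
#'   e.g. `c("WXLIP_FULL", "WXL_SMALL", "WXL_LARGE")`.
#' @param gaps Integer vector of intervening decoy-gene counts between
#'   consecutive members; length `length(members) - 1`, each at most 10.
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(members = c("WXLIP_FULL", "WXL_SMALL", "WXL_LARGE"),
                         gaps = rep(0L, length(members) - 1L)) {
  if (!all(members %in% RELEVANT_CLASSES)) {
    abort("cluster_spec members must be relevant architecture classes")
  }
  if (length(gaps) != length(members) - 1L) {
    abort("cluster_spec: length(gaps) must equal length(members) - 1")
  }
  if (length(gaps) && any(gaps < 0 | gaps > 10)) {
    abort("cluster_spec: gaps must be in [0, 10]")
  }
  structure(list(members = members, gaps = as.integer(gaps)),
            class = "cluster_spec")
}

#' Configuration for the synthetic genome generator
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_id Genome identifier.
#' @param n_replicons Number of replicons.
#' @param genes_per_replicon Annotated genes per replicon (planted plus
#'   decoys).
#' @param planted_clusters List of [cluster_spec()]s, distributed
#'   round-robin across replicons.
#' @param n_spurious_hits Number of extra domtblout rows with E-values in
#'   `[1e-9, 1]` (above the survey cutoff; they must never alter a call).
#' @param max_gap Adjacency-rule parameter used to compute the truth
#'   manifest's qualifies/simple flags, default 4.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, genome_id = sprintf("synth%04d", seed),
                             n_replicons = 1L, genes_per_replicon = 40L,
                             planted_clusters = list(cluster_spec()),
                             n_spurious_hits = 5L, max_gap = 4L) {
  structure(list(seed = as.integer(seed), genome_id = genome_id,
                 n_replicons = as.integer(n_replicons),
                 genes_per_replicon = as.integer(genes_per_replicon),
                 planted_clusters = planted_clusters,
                 n_spurious_hits = as.integer(n_spurious_hits),
                 max_gap = as.integer(max_gap)),
            class = "synthetic_config")
}

# Background residues: uniform over the standard residues minus W.
BACKGROUND_AA <- setdiff(AA20, "W")

random_background <- function(n) {
  paste(sample(BACKGROUND_AA, n, replace = TRUE), collapse = "")
}

# "MKK" + leucine-rich h-region + background, 25 residues; trips the
# signal-peptide heuristic by construction.
random_signal <- function() {
  paste0("MKK", strrep("L", 12), random_background(10))
}

splice <- function(base, at, insert) {
  # replace substring of base starting at 0-based `at` with `insert`
  paste0(str_sub(base, 1, at), insert,
         str_sub(base, at + nchar(insert) + 1))
}

#' Generate one synthetic protein of a given architecture class
#'
#' Builds a sequence of background residues with the class's diagnostic
#' features planted: WxL proteins get two Trp-x-Leu motifs spaced within
#' the 160-190-residue domain envelope (C-terminal for the large class);
#' full WxLIP gets a signal-like N-terminus, a ~148-residue PGBD carrying
#' the NQIDKxxxYFDLK anchor, a 112-residue HBD, and a 22-residue
#' hydrophobic (L/I/V/F) C-terminal transmembrane tract, with total
#' length drawn from 337-365; PGBD-only and HBD-only proteins carry the
#' single domain. Draws from the ambient RNG stream.
#'
#' @param arch_class One of `WXLIP_FULL`, `WXL_SMALL`, `WXL_LARGE`,
#'   `PGBD_ONLY`, `HBD_ONLY`, or `DECOY`.
#' @return A list with `sequence` and `hits` (true domain spans, 0-based
#'   half-open, columns `domain`, `env_start`, `env_end`).
#' @export
generate_protein <- function(arch_class) {
  no_hits <- tibble(domain = character(), env_start = integer(),
                    env_end = integer())
  plant_wxl_pair <- function(s, i, j) {
    s <- splice(s, i, paste0("W", str_sub(s, i + 2, i + 2), "L"))
    splice(s, j, paste0("W", str_sub(s, j + 2, j + 2), "L"))
  }
  if (arch_class == "DECOY") {
    len <- sample(100:300, 1)
    return(list(sequence = random_background(len), hits = no_hits))
  }
  sig <- random_signal()
  if (arch_class == "WXL_SMALL") {
    len <- sample(195:225, 1)
    s <- paste0(sig, random_background(len - 25))
    i <- 30L
    j <- i + sample(120:150, 1)
    s <- plant_wxl_pair(s, i, j)
    hits <- tibble(domain = "WXL", env_start = i, env_end = j + 3L)
  } else if (arch_class == "WXL_LARGE") {
    len <- sample(400:480, 1)
    s <- paste0(sig, random_background(len - 25))
    j <- len - 11L
    i <- j - sample(120L:150L, 1)
    s <- plant_wxl_pair(s, i, j)
    hits <- tibble(domain = "WXL", env_start = i, env_end = j + 3L)
  } else if (arch_class == "WXLIP_FULL") {
    len <- sample(337:365, 1)
    pad1 <- sample(0:2, 1)
    s <- paste0(sig, random_background(len - 25 - 22),
                paste(sample(c("L", "I", "V", "F"), 22, replace = TRUE),
                      collapse = ""))
    pgbd <- c(25L, 173L)
    anchor <- paste0("NQIDK", random_background(3), "YFDLK")
    s <- splice(s, 30L, anchor)
    hbd <- c(173L + pad1, 173L + pad1 + 112L)
    hits <- tibble(domain = c("PGBD", "HBD"),
                   env_start = c(pgbd[1], hbd[1]),
                   env_end = c(pgbd[2], hbd[2]))
  } else if (arch_class == "PGBD_ONLY") {
    len <- sample(200:260, 1)
    s <- paste0(sig, random_background(len - 25))
    anchor <- paste0("NQIDK", random_background(3), "YFDLK")
    s <- splice(s, 30L, anchor)
    hits <- tibble(domain = "PGBD", env_start = 25L, env_end = 173L)
  } else if (arch_class == "HBD_ONLY") {
    len <- sample(160:200, 1)
    s <- paste0(sig, random_background(len - 25))
    hits <- tibble(domain = "HBD", env_start = 25L, env_end = 137L)
  } else {
    abort(sprintf("unknown architecture class: %s", arch_class))
  }
  list(sequence = s, hits = hits)
}

#' Generate a synthetic annotated genome with planted WxL clusters
#'
#' Writes a GenBank flat file, an hmmsearch-style domtblout with one row
#' per true domain (E-values log-uniform in `[1e-50, 1e-11]`, below the
#' survey cutoff) plus `n_spurious_hits` rows with E-values in
#' `[1e-9, 1]` (above it), and a ground-truth manifest. Each planted
#' cluster is placed at a random locus of its replicon with its stated
#' decoy gaps; cluster blocks are separated by at least `max_gap + 3`
#' decoy genes so distinct plants never merge under the adjacency rule.
#' The truth manifest's qualifies/simple flags are computed directly from
#' the definitional rule on the planted gap lists (a within-cluster gap
#' exceeding `max_gap` splits the plant into fragments that are judged
#' separately).
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory, created if needed; default a fresh
#'   tempdir subdirectory.
#' @return A list: `genbank_path`, `domtblout_path`, `truth` (list of
#'   tibbles `proteins`, `hits`, `clusters`), and the `config`.
#' @export
generate_genome <- function(config, dir = tempfile("synthgenome")) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  buffer <- config$max_gap + 3L
  rep_ids <- sprintf("%s_r%d", config$genome_id, seq_len(config$n_replicons))
  cluster_rep <- if (length(config$planted_clusters)) {
    rep_len <- rep(seq_len(config$n_replicons),
                   length.out = length(config$planted_clusters))
    rep_len
  } else integer(0)

  all_proteins <- list()
  truth_hits <- list()
  truth_clusters <- list()
  cluster_idx <- 0L

  for (r in seq_len(config$n_replicons)) {
    specs <- config$planted_clusters[cluster_rep == r]
    footprints <- map_int(specs, function(sp) {
      length(sp$members) + sum(sp$gaps)
    })
    n_genes <- config$genes_per_replicon
    needed <- sum(footprints) + (length(specs) + 1L) * buffer
    if (needed > n_genes) {
      abort(sprintf("planted clusters exceed replicon capacity (%d genes needed, %d available)",
                    needed, n_genes))
    }
    # distribute the slack randomly among the buffer regions
    slack <- n_genes - needed
    extra <- if (length(specs)) {
      tabulate(sample.int(length(specs) + 1L, slack, replace = TRUE),
               nbins = length(specs) + 1L)
    } else c(slack)

    classes <- rep("DECOY", n_genes)
    cursor <- 0L
    for (k in seq_along(specs)) {
      cursor <- cursor + buffer + extra[k]
      sp <- specs[[k]]
      ords <- integer(length(sp$members))
      pos <- cursor
      for (m in seq_along(sp$members)) {
        ords[m] <- pos
        pos <- pos + 1L + if (m < length(sp$members)) sp$gaps[m] else 0L
      }
      classes[ords + 1L] <- sp$members
      cursor <- cursor + footprints[k]
      cluster_idx <- cluster_idx + 1L
      truth_clusters[[cluster_idx]] <- truth_eval_plant(
        sp, ords, rep_ids[r], cluster_idx, config$max_gap)
    }

    nt_cursor <- 100L
    genes <- map(seq_len(n_genes), function(g) {
      p <- generate_protein(classes[g])
      pid <- sprintf("%s_p%04d", rep_ids[r], g)
      ntlen <- 3L * (nchar(p$sequence) + 1L)
      row <- tibble(replicon_id = rep_ids[r], protein_id = pid,
                    ordinal = g - 1L, true_class = classes[g],
                    length = nchar(p$sequence), sequence = p$sequence)
      list(row = row, hits = if (nrow(p$hits)) {
        mutate(p$hits, protein_id = pid, .before = 1)
      } else NULL, ntlen = ntlen)
    })
    tab <- bind_rows(map(genes, "row"))
    ntlens <- map_int(genes, "ntlen")
    spacers <- sample(20:200, n_genes, replace = TRUE)
    starts <- 100L + cumsum(c(0L, (ntlens + spacers)[-n_genes]))
    tab$start <- starts
    tab$end <- starts + ntlens
    tab$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    all_proteins[[r]] <- tab
    truth_hits[[r]] <- bind_rows(purrr::compact(map(genes, "hits")))
  }

  proteins <- bind_rows(all_proteins) |>
    mutate(genome_id = config$genome_id, .before = 1)
  hits <- bind_rows(truth_hits)
  clusters <- bind_rows(truth_clusters)

  gb_path <- file.path(dir, paste0(config$genome_id, ".gbk"))
  write_genbank(proteins, gb_path)
  dt_path <- file.path(dir, paste0(config$genome_id, ".domtblout"))
  write_domtblout(hits, proteins, dt_path,
                  n_spurious = config$n_spurious_hits)
  readr::write_tsv(select(proteins, -"sequence"),
                   file.path(dir, "truth_proteins.tsv"), progress = FALSE)
  if (nrow(clusters)) {
    readr::write_tsv(clusters, file.path(dir, "truth_clusters.tsv"),
                     progress = FALSE)
  }

  list(genbank_path = gb_path, domtblout_path = dt_path,
       truth = list(proteins = proteins, hits = hits, clusters = clusters),
       config = config, dir = dir)
}

# Judge a planted cluster under the adjacency rule: chain members whose
# intervening-gap is <= max_gap, then census each fragment.
truth_eval_plant <- function(sp, ords, replicon_id, idx, max_gap) {
  frag <- cumsum(c(1L, as.integer(sp$gaps > max_gap)))
  out <- list()
  for (f in unique(frag)) {
    mem <- sp$members[frag == f]
    n_wxlip <- sum(mem == "WXLIP_FULL")
    n_wxl <- sum(mem %in% c("WXL_SMALL", "WXL_LARGE"))
    out[[length(out) + 1L]] <- tibble(
      plant = idx, fragment = f, replicon_id = replicon_id,
      ordinals = paste(ords[frag == f], collapse = ","),
      ordinal_min = min(ords[frag == f]),
      ordinal_max = max(ords[frag == f]),
      classes = paste(mem, collapse = ","),
      n_wxlip = n_wxlip, n_wxl = n_wxl,
      qualifies = n_wxlip >= 1L & n_wxl >= 2L,
      simple = n_wxlip == 1L & n_wxl == 2L & n_wxlip >= 1L)
  }
  bind_rows(out)
}

# Emit an hmmsearch --domtblout file for the true hits plus spurious rows.
write_domtblout <- function(hits, proteins, path, n_spurious = 0L) {
  model_info <- list(
    WXL = c(name = "WxL", acc = "PF13731.8", qlen = 170L),
    PGBD = c(name = "DUF916", acc = "PF06040.14", qlen = 125L),
    HBD = c(name = "DUF3324", acc = "PF11797.10", qlen = 112L))
  lens <- stats::setNames(nchar(proteins$sequence), proteins$protein_id)

  rows <- character(0)
  emit <- function(pid, domain, from0, to, evalue) {
    mi <- model_info[[domain]]
    sprintf(paste0("%-20s -          %6d %-10s %-12s %6s %9.2g %6.1f %5.1f",
                   "   1   1 %9.2g %9.2g %6.1f %5.1f     1 %5s %6d %6d %6d %6d 0.90 -"),
            pid, lens[[pid]], mi[["name"]], mi[["acc"]], mi[["qlen"]],
            evalue, 200 - log10(evalue), 0.1,
            evalue, evalue, 180 - log10(evalue), 0.1, mi[["qlen"]],
            from0 + 1L, to, from0 + 1L, to)
  }
  if (nrow(hits)) {
    ev <- 10^stats::runif(nrow(hits), -50, -11)
    rows <- c(rows, map_chr(seq_len(nrow(hits)), function(i) {
      emit(hits$protein_id[i], hits$domain[i],
           hits$env_start[i], hits$env_end[i], ev[i])
    }))
  }
  if (n_spurious > 0 && nrow(proteins) > 0) {
    pick <- sample(proteins$protein_id, n_spurious, replace = TRUE)
    doms <- sample(names(model_info), n_spurious, replace = TRUE)
    ev <- 10^stats::runif(n_spurious, -9, 0)
    rows <- c(rows, map_chr(seq_len(n_spurious), function(i) {
      plen <- lens[[pick[i]]]
      from0 <- sample.int(max(1L, plen - 30L), 1) - 1L
      emit(pick[i], doms[i], from0, min(plen, from0 + 30L), ev[i])
    }))
  }
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Generate an alignment with planted invariant columns
#'
#' At each planted column exactly `threshold_count` rows share one
#' residue while the remaining rows receive a balanced spread of the
#' other residues (so no residue can reach the threshold); every other
#' column receives a balanced spread of all twenty residues. The planted
#' column set is therefore exactly what [column_conservation()] should
#' recover at `threshold = threshold_count`.
#'
#' @param n_seqs Number of rows, default 175.
#' @param n_cols Number of columns.
#' @param conserved_cols Integer vector of planted column indices
#'   (1-based).
#' @param threshold_count Number of rows sharing the invariant residue,
#'   default 60.
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @return A list: `alignment` (tibble `id`, `sequence`) and
#'   `truth_columns`.
#' @export
generate_msa <- function(n_seqs = 175, n_cols = 50, conserved_cols = integer(0),
                         threshold_count = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(conserved_cols) && (min(conserved_cols) < 1 ||
                                 max(conserved_cols) > n_cols)) {
    abort("conserved_cols out of range")
  }
  if (ceiling(n_seqs / 20) >= threshold_count) {
    abort("infeasible: background columns would reach the threshold")
  }
  if (threshold_count > n_seqs) abort("threshold_count exceeds n_seqs")
  n_rest <- n_seqs - threshold_count
  if (n_rest > 0 && ceiling(n_rest / 19) >= threshold_count) {
    abort("infeasible: non-invariant rows would reach the threshold")
  }
  mat <- matrix("", nrow = n_seqs, ncol = n_cols)
  for (j in seq_len(n_cols)) {
    if (j %in% conserved_cols) {
      res <- sample(AA20, 1)
      rows_in <- sample.int(n_seqs, threshold_count)
      mat[rows_in, j] <- res
      others <- setdiff(AA20, res)
      fill <- sample(rep(others, length.out = n_rest))
      mat[-rows_in, j] <- fill
    } else {
      mat[, j] <- sample(rep(AA20, length.out = n_seqs))
    }
  }
  aln <- tibble(id = sprintf("seq%04d", seq_len(n_seqs)),
                sequence = apply(mat, 1, paste, collapse = ""))
  list(alignment = aln, truth_columns = sort(as.integer(conserved_cols)))
}
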