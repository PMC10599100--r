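# Independent brute-force oracles used across the suite. These are written
# from the definitions, not from the implementation paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All W.L motif offsets (0-based), by direct position-by-position check.
oracle_wxl_offsets <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(integer(0))
  which(ch[1:(n - 2)] == "W" & ch[3:n] == "L") - 1L
}

# All qualifying ordered motif pairs by enumeration.
oracle_wxl_pairs <- function(s, min_sep = 40, max_span = 190) {
  off <- oracle_wxl_offsets(s)
  out <- list()
  for (i in off) for (j in off) {
    if (j > i && j - i >= min_sep && j + 3 - i <= max_span) {
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

# NQIDKxxxYFDLK offsets (0-based), position-by-position.
oracle_anchor_offsets <- function(s) {
  ch <- strsplit(s, "")[[1]]
  pat <- strsplit("NQIDK...YFDLK", "")[[1]]
  n <- length(ch)
  hits <- integer(0)
  if (n < 13) return(hits)
  for (p in 1:(n - 12)) {
    ok <- TRUE
    for (k in 1:13) {
      if (pat[k] != "." && ch[p + k - 1] != pat[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p - 1L)
  }
  hits
}

# Hit-suppression fixed point by exhaustive subset search: the surviving
# set S is the unique subset with h in S iff no better-ranked member of S
# overlaps h by more than min_overlap of the shorter interval.
oracle_suppress <- function(d, min_overlap = 0.5) {
  n <- nrow(d)
  rank_of <- order(order(d$evalue, -(d$env_end - d$env_start), d$env_start))
  overlaps <- function(i, k) {
    ov <- min(d$env_end[i], d$env_end[k]) - max(d$env_start[i], d$env_start[k])
    shorter <- min(d$env_end[i] - d$env_start[i], d$env_end[k] - d$env_start[k])
    ov > min_overlap * shorter
  }
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    for (h in seq_len(n)) {
      suppressed <- any(vapply(S, function(k) {
        k != h && rank_of[k] < rank_of[h] && overlaps(h, k)
      }, logical(1)))
      if ((h %in% S) == suppressed) { ok <- FALSE; break }
    }
    if (ok) return(sort(S))
  }
  stop("no fixed point found")
}

# Single-linkage partition of ordinals by brute-force transitive closure
# (all-pairs union-find). Returns a list of sorted integer vectors.
oracle_partition <- function(ordinals, max_gap = 4) {
  n <- length(ordinals)
  parent <- seq_len(n)
  find2 <- function(i, p) { while (p[i] != i) i <- p[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(ordinals[i] - ordinals[j]) <= max_gap + 1) {
      ri <- find2(i, parent); rj <- find2(j, parent)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find2, integer(1), p = parent)
  unname(lapply(split(ordinals, roots), function(v) sort(v)))
}

# Vectorized Henderson-Hasselbalch charge for the grid-search pI oracle.
oracle_charge_curve <- function(sequence, pH, pka = wxlsurvey::emboss_pka()) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  cnt <- function(r) sum(ch == r)
  pos <- c(Nterm = 1, K = cnt("K"), R = cnt("R"), H = cnt("H"))
  neg <- c(Cterm = 1, D = cnt("D"), E = cnt("E"), C = cnt("C"), Y = cnt("Y"))
  q <- rep(0, length(pH))
  for (g in names(pos)) q <- q + pos[[g]] / (1 + 10^(pH - pka[[g]]))
  for (g in names(neg)) q <- q - neg[[g]] / (1 + 10^(pka[[g]] - pH))
  q
}

oracle_grid_pi <- function(sequence, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- oracle_charge_curve(sequence, grid)
  grid[which.min(abs(q))]
}

# Toy GenBank record builder for parser tests.
toy_genbank <- function(cds, locus = "TESTLOC", origin = NULL) {
  lines <- c(sprintf("LOCUS       %s 99999 bp    DNA     linear   BCT", locus),
             "DEFINITION  toy record.",
             "FEATURES             Location/Qualifiers")
  for (c_ in cds) {
    span <- sprintf("%d..%d", c_$from, c_$to)
    if (isTRUE(c_$complement)) span <- sprintf("complement(%s)", span)
    lines <- c(lines, sprintf("     CDS             %s", span))
    if (!is.null(c_$protein_id)) {
      lines <- c(lines, sprintf("                     /protein_id=\"%s\"",
                                c_$protein_id))
    }
    if (!is.null(c_$translation)) {
      lines <- c(lines, sprintf("                     /translation=\"%s\"",
                                c_$translation))
    }
  }
  if (!is.null(origin)) {
    lines <- c(lines, "ORIGIN")
    # 60 bases per line, GenBank style
    starts <- seq(1, nchar(origin), by = 60)
    for (s in starts) {
      chunk <- substr(origin, s, min(nchar(origin), s + 59))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
      lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
    }
  }
  c(lines, "//")
}

# Minimal domtblout row with controllable fields (1-based env coords).
domtbl_row <- function(target, model, acc, evalue, env_from, env_to,
                       ievalue = evalue) {
  paste(target, "-", 500, model, acc, 150,
        format(evalue, scientific = TRUE), 55.0, 0.1, 1, 1,
        format(ievalue, scientific = TRUE), format(ievalue, scientific = TRUE),
        50.0, 0.1, 1, 150, env_from, env_to, env_from, env_to, 0.9, "-")
}

# A minimal classified-calls tibble for cluster tests.
make_calls <- function(ordinals, classes, replicon = "r1",
                       protein_ids = sprintf("%s_p%03d", replicon, ordinals)) {
  tibble::tibble(replicon_id = replicon, protein_id = protein_ids,
                 ordinal = as.integer(ordinals), arch_class = classes)
}
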