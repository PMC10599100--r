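#' Parse and filter HMMER3 per-domain tabular output
#'
#' Reads an `hmmsearch --domtblout` file, maps query-model names to the
#' three survey domains and keeps only hits whose full-sequence E-value is
#' below `evalue_max` (the survey cutoff is 1e-10). Envelope coordinates
#' are converted from HMMER's 1-based inclusive convention to 0-based
#' half-open. Rows whose model is not in the name map are dropped with a
#' warning; the filter uses the full-sequence E-value column, not the
#' per-domain conditional E-value (`use_domain_evalue = TRUE` switches to
#' the independent per-domain i-Evalue).
#'
#' @param path Path to a domtblout file.
#' @param evalue_max Inclusion threshold; a hit is kept iff its E-value is
#'   strictly below this. Default `1e-10`.
#' @param name_map Named character vector mapping model names
#'   (Pfam accession with the version stripped, or plain model name) to
#'   domain labels. Default `c(PF13731 = "WXL", PF06040 = "PGBD",
#'   PF11797 = "HBD")`.
#' @param use_domain_evalue Filter on the per-domain independent E-value
#'   instead of the full-sequence E-value. Default `FALSE`.
#' @return A tibble of domain hits: `protein_id`, `domain`, `env_start`,
#'   `env_end` (0-based half-open residue coordinates), `evalue`, `source`
#'   (`"hmmer"`).
#' @export
parse_domtblout <- function(path, evalue_max = 1e-10,
                            name_map = default_name_map(),
                            use_domain_evalue = FALSE) {
  stopifnot_scalar_file(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(str_trim(lines))
  rows <- lines[keep]
  if (length(rows) == 0) return(empty_hits())
  fields <- str_split(str_trim(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22)) {
    bad <- which(keep)[which(nf < 22)[1]]
    abort(sprintf("malformed domtblout row at line %d of %s (%d fields, need >= 22)",
                  bad, path, min(nf)))
  }
  tab <- tibble(
    protein_id = map_chr(fields, 1),
    model = map_chr(fields, 4),
    model_acc = map_chr(fields, 5),
    seq_evalue = as.numeric(map_chr(fields, 7)),
    dom_ievalue = as.numeric(map_chr(fields, 13)),
    env_from = as.integer(map_chr(fields, 20)),
    env_to = as.integer(map_chr(fields, 21))
  )
  if (anyNA(tab$seq_evalue) || anyNA(tab$env_from) || anyNA(tab$env_to)) {
    bad <- which(keep)[which(is.na(tab$seq_evalue) | is.na(tab$env_from) |
                               is.na(tab$env_to))[1]]
    abort(sprintf("malformed domtblout row at line %d of %s", bad, path))
  }
  # model key: try the query name, then the accession, version stripped
  key1 <- sub("\\.\\d+$", "", tab$model)
  key2 <- sub("\\.\\d+$", "", tab$model_acc)
  dom <- unname(name_map[key1])
  dom[is.na(dom)] <- unname(name_map[key2])[is.na(dom)]
  if (anyNA(dom)) {
    warn(sprintf("ignoring %d domtblout row(s) for unmapped model(s): %s",
                 sum(is.na(dom)),
                 paste(unique(tab$model[is.na(dom)]), collapse = ", ")))
  }
  ev <- if (use_domain_evalue) tab$dom_ievalue else tab$seq_evalue
  out <- tibble(protein_id = tab$protein_id, domain = dom,
                env_start = tab$env_from - 1L, env_end = tab$env_to,
                evalue = ev, source = "hmmer") |>
    filter(!is.na(.data$domain), .data$evalue < evalue_max) |>
    arrange(.data$protein_id, .data$env_start)
  out
}

#' @rdname parse_domtblout
#' @export
default_name_map <- function() {
  c(PF13731 = "WXL", PF06040 = "PGBD", PF11797 = "HBD",
    WxL = "WXL", DUF916 = "PGBD", DUF3324 = "HBD")
}

empty_hits <- function() {
  tibble(protein_id = character(), domain = character(),
         env_start = integer(), env_end = integer(),
         evalue = double(), source = character())
}

#' Collapse redundant same-domain hits on each protein
#'
#' Among hits of the same domain on the same protein that overlap by more
#' than 50% of the shorter interval, only the lowest-E-value hit survives
#' (ties broken toward the longer, then the more N-terminal hit). Hits of
#' different domains are never merged. Output is sorted by protein and
#' envelope start.
#'
#' @param hits A domain-hit tibble as from [parse_domtblout()] or
#'   [motif_hits_as_domain_hits()].
#' @param min_overlap Fraction of the shorter interval above which two
#'   same-domain hits are considered redundant. Default 0.5.
#' @return A tibble with the same columns, containing the surviving hits.
#' @export
merge_hits <- function(hits, min_overlap = 0.5) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    group_by(.data$protein_id, .data$domain) |>
    dplyr::group_modify(function(d, key) {
      suppress_redundant(d, min_overlap)
    }) |>
    ungroup() |>
    arrange(.data$protein_id, .data$env_start) |>
    select(dplyr::all_of(names(hits)))
}

# Greedy suppression: rank by (evalue, -length, start); keep a hit unless it
# overlaps a kept hit by > min_overlap of the shorter interval.
suppress_redundant <- function(d, min_overlap) {
  o <- order(d$evalue, -(d$env_end - d$env_start), d$env_start)
  d <- d[o, ]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    redundant <- FALSE
    for (k in kept) {
      ov <- min(d$env_end[i], d$env_end[k]) - max(d$env_start[i], d$env_start[k])
      shorter <- min(d$env_end[i] - d$env_start[i],
                     d$env_end[k] - d$env_start[k])
      if (ov > min_overlap * shorter) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  d[sort(kept), ]
}

#' Scan a protein sequence for WxL motif pairs
#'
#' The WxL domain is 160-190 residues long and carries two Trp-x-Leu
#' motifs. This scanner finds every offset `i` (0-based) with `W` at `i`
#' and `L` at `i + 2`, and reports one candidate domain per ordered motif
#' pair `(i, j)` that a WxL domain could contain: the pair span
#' `j + 3 - i` must not exceed `max_span` (190) and the motifs must be at
#' least `min_sep` residues apart (40, to exclude adjacent spurious
#' motifs). The reported span is `(i, j + 3)`, 0-based half-open.
#'
#' @param sequence Amino-acid string.
#' @param min_sep Minimum motif separation `j - i`, default 40.
#' @param max_span Maximum span `j + 3 - i`, default 190.
#' @return A tibble with columns `motif` (`"WxL_pair"`), `pos1`, `pos2`
#'   (0-based motif offsets), `start`, `end` (the pair span).
#' @export
scan_wxl_motifs <- function(sequence, min_sep = 40, max_span = 190) {
  s <- toupper(sequence)
  n <- nchar(s)
  empty <- tibble(motif = character(), pos1 = integer(), pos2 = integer(),
                  start = integer(), end = integer())
  if (n < 3) return(empty)
  ch <- seq_chars(s)
  idx <- which(ch[1:(n - 2)] == "W" & ch[3:n] == "L") - 1L  # 0-based
  if (length(idx) < 2) return(empty)
  pairs <- expand.grid(i = idx, j = idx)
  pairs <- pairs[pairs$j - pairs$i >= min_sep &
                   pairs$j + 3 - pairs$i <= max_span, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  tibble(motif = "WxL_pair",
         pos1 = as.integer(pairs$i), pos2 = as.integer(pairs$j),
         start = as.integer(pairs$i), end = as.integer(pairs$j + 3L)) |>
    arrange(.data$pos1, .data$pos2)
}

#' Scan a protein sequence for the conserved PGBD N-terminal anchor
#'
#' Finds all occurrences of the 13-residue pattern `NQIDKxxxYFDLK`
#' (`x` = any residue, matched as exactly three arbitrary residues) that
#' is highly conserved near the N-terminus of the peptidoglycan-binding
#' domain of WxLIP proteins.
#'
#' @param sequence Amino-acid string.
#' @return A tibble with columns `motif` (`"NQIDK_anchor"`), `start`, `end`
#'   (0-based half-open).
#' @export
scan_pgbd_anchor <- function(sequence) {
  s <- toupper(sequence)
  m <- gregexpr("(?=NQIDK...YFDLK)", s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(motif = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  tibble(motif = "NQIDK_anchor", start = start, end = start + 13L)
}

#' Detect a C-terminal transmembrane helix by sliding-window hydropathy
#'
#' Slides a Kyte-Doolittle hydropathy window along the sequence; window
#' start positions whose mean is at least `threshold` are merged into
#' maximal spans, and only spans starting within the final `cterm_zone`
#' residues are returned (the WxLIP transmembrane helix is C-terminal).
#' The reported `hydropathy` is the peak window mean inside the span, so
#' it always satisfies the threshold.
#'
#' @param sequence Amino-acid string.
#' @param window Window length in residues, default 19.
#' @param threshold Minimum mean hydropathy, default 1.6.
#' @param cterm_zone Size of the C-terminal acceptance zone, default 60.
#' @return A tibble with columns `start`, `end` (0-based half-open residue
#'   span) and `hydropathy`; zero rows if the sequence is shorter than the
#'   window or no span qualifies.
#' @export
detect_tmh <- function(sequence, window = 19, threshold = 1.6,
                       cterm_zone = 60) {
  empty <- tibble(start = integer(), end = integer(), hydropathy = double())
  n <- nchar(sequence)
  if (n < window) return(empty)
  kd <- kd_values(sequence)
  means <- roll_mean(kd, window)
  hit <- which(means >= threshold)            # window start, 1-based
  if (length(hit) == 0) return(empty)
  # merge in residue space: union of qualifying windows, maximal runs
  covered <- logical(n)
  for (p in hit) covered[p:(p + window - 1L)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spans <- map(which(runs$values), function(k) {
    in_span <- hit[hit >= starts[k] & hit + window - 1L <= ends[k]]
    tibble(start = starts[k] - 1L, end = ends[k],
           hydropathy = max(means[in_span]))
  })
  bind_rows(spans) |>
    filter(.data$start >= n - cterm_zone) |>
    arrange(.data$start)
}

#' Heuristic N-terminal signal-peptide call
#'
#' A light secretion-signal heuristic: present when the first 10 residues
#' contain at least one positive residue (K/R, the n-region) and some
#' 8-residue window inside residues 5-30 has mean Kyte-Doolittle
#' hydropathy >= 1.5 (the h-region). The cleavage hint is the end of the
#' first such window plus 5 residues, capped at 45. The call is advisory
#' metadata only: architecture classification never depends on it.
#'
#' @param sequence Amino-acid string.
#' @return A one-row tibble with `present` (logical) and `cleavage_hint`
#'   (integer residue offset or `NA`).
#' @export
detect_signal_peptide <- function(sequence) {
  n <- nchar(sequence)
  absent <- tibble(present = FALSE, cleavage_hint = NA_integer_)
  if (n < 25) return(absent)
  ch <- seq_chars(toupper(sequence))
  if (!any(ch[1:10] %in% c("K", "R"))) return(absent)
  zone <- kd_values(sequence)[5:min(30, n)]
  if (length(zone) < 8) return(absent)
  means <- roll_mean(zone, 8)
  hit <- which(means >= 1.5)
  if (length(hit) == 0) return(absent)
  win_end <- 4L + hit[1] + 8L - 1L             # 1-based end within sequence
  tibble(present = TRUE, cleavage_hint = min(45L, win_end + 5L))
}

#' Convert motif-scanner evidence to domain hits
#'
#' In motif-only mode (no HMMER output available) the WxL pair scanner and
#' the PGBD anchor scanner provide domain evidence. Each motif hit becomes
#' a domain hit with a fixed pseudo-E-value so it flows through the same
#' filter and merge pathway as HMMER hits. The anchor marks only the PGBD
#' N-terminus, so the PGBD hit is extended to a nominal domain length.
#' No sequence motif exists for HBD, so motif-only evidence cannot
#' distinguish a full WxLIP from an isolated PGBD protein.
#'
#' @param protein_id Protein identifier for the emitted hits.
#' @param sequence Amino-acid string.
#' @param pseudo_evalue E-value assigned to motif evidence, default 1e-12
#'   (passes the survey filter).
#' @param pgbd_nominal_length Length to which an anchor-based PGBD hit is
#'   extended, default 148.
#' @return A domain-hit tibble (`source = "motif"`).
#' @export
motif_hits_as_domain_hits <- function(protein_id, sequence,
                                      pseudo_evalue = 1e-12,
                                      pgbd_nominal_length = 148) {
  n <- nchar(sequence)
  wxl <- scan_wxl_motifs(sequence)
  anchor <- scan_pgbd_anchor(sequence)
  out <- empty_hits()
  if (nrow(wxl)) {
    out <- bind_rows(out, tibble(
      protein_id = protein_id, domain = "WXL",
      env_start = wxl$start, env_end = wxl$end,
      evalue = pseudo_evalue, source = "motif"))
  }
  if (nrow(anchor)) {
    out <- bind_rows(out, tibble(
      protein_id = protein_id, domain = "PGBD",
      env_start = pmax(0L, anchor$start - 5L),
      env_end = pmin(n, anchor$start - 5L + as.integer(pgbd_nominal_length)),
      evalue = pseudo_evalue, source = "motif"))
  }
  out
}
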