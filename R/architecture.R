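#' Classify proteins into WxL-cluster architecture classes
#'
#' Applies the survey's architecture grammar to each protein's merged
#' domain evidence:
#'
#' * `WXLIP_FULL` — PGBD and HBD both present, PGBD starting before HBD
#'   (the order the two domains always take in full-length WxLIP);
#' * `PGBD_ONLY` / `HBD_ONLY` — exactly one of the pair present;
#' * `OTHER` with an order-violation flag — both present but HBD first;
#' * `WXL_SMALL` — a WxL hit and no PGBD/HBD, where the longest WxL hit
#'   covers at least `small_coverage` of the mature length (sequence minus
#'   the first 25 residues, a nominal signal peptide);
#' * `WXL_LARGE` — a WxL hit that fails the coverage test but whose most
#'   C-terminal hit ends within `cterm_tol` residues of the C-terminus
#'   (large WxL proteins carry the WxL domain at the C-terminus);
#' * `OTHER` — anything else.
#'
#' A protein carrying both PGBD/HBD and WxL evidence is classed by the
#' PGBD/HBD branch; the survey treats WxLIP and WxL proteins as disjoint
#' sets. The signal-peptide call is recorded but never gates a class.
#'
#' @param proteins A proteins tibble ([read_genbank()]): `protein_id`,
#'   `sequence`, plus any bookkeeping columns, which are carried through.
#' @param hits Merged domain-hit tibble ([merge_hits()]).
#' @param tmh Optional precomputed TMH tibble with a `protein_id` column;
#'   by default [detect_tmh()] runs on each sequence.
#' @param signal Optional precomputed signal tibble (`protein_id`,
#'   `present`); by default [detect_signal_peptide()] runs per sequence.
#' @param small_coverage Mature-length coverage above which a WxL protein
#'   is "small", default 0.6.
#' @param cterm_tol C-terminal tolerance (residues) for the large-WxL
#'   test, default 15.
#' @param signal_clip Nominal signal-peptide length subtracted to get the
#'   mature length, default 25.
#' @return The input tibble with columns `arch_class`, `has_tmh`,
#'   `has_signal`, `order_violation`, and per-domain hit spans
#'   (`wxl_start`, `wxl_end`, `pgbd_start`, `pgbd_end`, `hbd_start`,
#'   `hbd_end`, `pgbd_len`).
#' @export
classify_architecture <- function(proteins, hits,
                                  tmh = NULL, signal = NULL,
                                  small_coverage = 0.6, cterm_tol = 15,
                                  signal_clip = 25) {
  stray <- setdiff(unique(hits$protein_id), proteins$protein_id)
  if (length(stray)) {
    abort(sprintf("domain hits reference unknown protein(s): %s",
                  paste(utils::head(stray, 3), collapse = ", ")))
  }
  if (anyDuplicated(proteins$protein_id)) {
    abort("duplicate protein_id in proteins table")
  }

  per <- split(hits, factor(hits$protein_id, levels = proteins$protein_id))
  calls <- pmap(list(proteins$protein_id, proteins$sequence, per),
                function(pid, seqs, h) {
    classify_one(pid, seqs, h, tmh, signal,
                 small_coverage, cterm_tol, signal_clip)
  })
  bind_rows(calls) |>
    (\(d) dplyr::bind_cols(proteins, select(d, -"protein_id")))()
}

classify_one <- function(pid, sequence, h, tmh, signal,
                         small_coverage, cterm_tol, signal_clip) {
  n <- nchar(sequence)
  dom_span <- function(d) {
    hd <- h[h$domain == d, , drop = FALSE]
    if (nrow(hd) == 0) return(c(NA_integer_, NA_integer_))
    # representative hit: the lowest E-value (ties: longest)
    i <- order(hd$evalue, -(hd$env_end - hd$env_start))[1]
    c(hd$env_start[i], hd$env_end[i])
  }
  pgbd <- dom_span("PGBD"); hbd <- dom_span("HBD")
  wxl_hits <- h[h$domain == "WXL", , drop = FALSE]

  order_violation <- FALSE
  if (!is.na(pgbd[1]) && !is.na(hbd[1])) {
    if (pgbd[1] < hbd[1]) {
      cls <- "WXLIP_FULL"
    } else {
      cls <- "OTHER"; order_violation <- TRUE
    }
  } else if (!is.na(pgbd[1])) {
    cls <- "PGBD_ONLY"
  } else if (!is.na(hbd[1])) {
    cls <- "HBD_ONLY"
  } else if (nrow(wxl_hits) > 0) {
    mature <- max(1L, n - signal_clip)
    longest <- which.max(wxl_hits$env_end - wxl_hits$env_start)
    cov <- (wxl_hits$env_end[longest] - wxl_hits$env_start[longest]) / mature
    if (cov >= small_coverage) {
      cls <- "WXL_SMALL"
    } else if (max(wxl_hits$env_end) >= n - cterm_tol) {
      cls <- "WXL_LARGE"
    } else {
      cls <- "OTHER"
    }
  } else {
    cls <- "OTHER"
  }

  tm <- if (is.null(tmh)) detect_tmh(sequence) else
    tmh[tmh$protein_id == pid, , drop = FALSE]
  sg <- if (is.null(signal)) detect_signal_peptide(sequence) else
    signal[signal$protein_id == pid, , drop = FALSE]
  wxl_span <- if (nrow(wxl_hits)) {
    i <- which.max(wxl_hits$env_end - wxl_hits$env_start)
    c(wxl_hits$env_start[i], wxl_hits$env_end[i])
  } else c(NA_integer_, NA_integer_)

  tibble(protein_id = pid, arch_class = cls,
         has_tmh = nrow(tm) > 0,
         has_signal = isTRUE(nrow(sg) > 0 && sg$present[1]),
         order_violation = order_violation,
         wxl_start = wxl_span[1], wxl_end = wxl_span[2],
         pgbd_start = pgbd[1], pgbd_end = pgbd[2],
         hbd_start = hbd[1], hbd_end = hbd[2],
         pgbd_len = if (is.na(pgbd[1])) NA_integer_ else
           as.integer(pgbd[2] - pgbd[1]))
}

#' Flag the buttressing-loop insert in PGBD domains
#'
#' In-cluster peptidoglycan-binding domains carry a ~20-residue insert (a
#' buttressing loop) absent from Pfam's DUF916 definition, making the
#' domain ~148 residues instead of ~125. A PGBD hit at least
#' `length_threshold` residues long (default 140, the midpoint between the
#' two lengths) is flagged as carrying the insert.
#'
#' @param calls A classified-protein tibble from [classify_architecture()];
#'   every row must have a PGBD hit (`pgbd_len` non-missing).
#' @param length_threshold Inclusive length cutoff, default 140.
#' @return The input with columns `pgbd_length` and `insert_present`.
#' @export
detect_buttressing_insert <- function(calls, length_threshold = 140) {
  if (any(is.na(calls$pgbd_len))) {
    abort("detect_buttressing_insert: some proteins have no PGBD hit")
  }
  calls |>
    mutate(pgbd_length = .data$pgbd_len,
           insert_present = .data$pgbd_len >= length_threshold)
}

#' Census of architecture classes
#'
#' Tallies classified proteins the way the survey reports them: small and
#' large WxL proteins are pooled into a single WxL count, and the total is
#' the sum over the five relevant classes (`OTHER` is excluded).
#'
#' @param calls A classified-protein tibble from [classify_architecture()].
#' @return A one-row tibble: `n_wxlip`, `n_wxl`, `n_wxl_small`,
#'   `n_wxl_large`, `n_pgbd_only`, `n_hbd_only`, `total`.
#' @export
proteome_census <- function(calls) {
  if (anyDuplicated(calls$protein_id)) {
    abort("duplicate protein_id in calls")
  }
  cnt <- function(cls) sum(calls$arch_class %in% cls)
  tibble(
    n_wxlip = cnt("WXLIP_FULL"),
    n_wxl_small = cnt("WXL_SMALL"),
    n_wxl_large = cnt("WXL_LARGE"),
    n_wxl = cnt(c("WXL_SMALL", "WXL_LARGE")),
    n_pgbd_only = cnt("PGBD_ONLY"),
    n_hbd_only = cnt("HBD_ONLY"),
    total = cnt(RELEVANT_CLASSES)
  )
}
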