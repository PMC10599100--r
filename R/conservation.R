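#' Read a protein multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal text (auto-detected from the header
#' line). Rows are upper-cased; `.` gaps are normalized to `-`; ragged
#' alignments are rejected with the offending id named.
#'
#' @param path Path to the alignment file.
#' @return A tibble with columns `id` and `sequence` (gapped, equal
#'   lengths), carrying attributes `n_seqs` and `n_cols`.
#' @export
read_alignment <- function(path) {
  stopifnot_scalar_file(path)
  first <- readLines(path, n = 1, warn = FALSE)
  fmt <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  if (fmt == "clustal") {
    # normalize header spacing (strict readers expect two blank lines)
    rows <- readLines(path, warn = FALSE)
    body <- rows[-1][cumsum(nzchar(str_trim(rows[-1]))) > 0]
    tmp <- tempfile(fileext = ".aln")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(rows[1], "", "", body), tmp)
    aln <- Biostrings::readAAMultipleAlignment(tmp, format = "clustal")
    ids <- names(Biostrings::unmasked(aln))
    seqs <- as.character(aln)
  } else {
    tab <- read_fasta(path, alignment = TRUE)
    ids <- tab$id
    seqs <- tab$sequence
  }
  seqs <- gsub(".", "-", toupper(unname(seqs)), fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    off <- ids[lens != lens[1]][1]
    abort(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                  off, nchar(seqs[ids == off][1]), lens[1]))
  }
  out <- tibble(id = ids, sequence = seqs)
  attr(out, "n_seqs") <- length(ids)
  attr(out, "n_cols") <- if (length(lens)) lens[1] else 0L
  out
}

#' Per-column conservation profile of an alignment
#'
#' For each alignment column, finds the most frequent non-gap residue
#' (ties broken alphabetically) and flags the column as conserved when
#' that residue's count reaches the threshold. This realizes the
#' "invariant in at least N sequences" statistic used to annotate the
#' PGBD and HBD alignments (N = 60 of 175 sequences there). Gaps never
#' count toward the majority. Alternatively a fractional threshold
#' (`threshold_frac`) may be given for alignments of other depths.
#'
#' @param aln An alignment tibble from [read_alignment()] (columns `id`,
#'   `sequence`).
#' @param threshold Absolute count threshold, default 60.
#' @param threshold_frac If non-`NULL`, overrides `threshold` with
#'   `ceiling(threshold_frac * n_seqs)`.
#' @return A tibble with one row per column: `column` (1-based),
#'   `majority_residue`, `majority_count`, `conserved`; class
#'   `"conservation_profile"` with the threshold stored as an attribute.
#' @export
column_conservation <- function(aln, threshold = 60, threshold_frac = NULL) {
  n_seqs <- nrow(aln)
  if (n_seqs < 1) abort("alignment has no sequences")
  if (!is.null(threshold_frac)) {
    threshold <- as.integer(ceiling(threshold_frac * n_seqs))
  }
  if (threshold < 1) abort("conservation threshold must be >= 1")
  mat <- do.call(rbind, strsplit(toupper(aln$sequence), "", fixed = TRUE))
  n_cols <- ncol(mat)
  prof <- map(seq_len(n_cols), function(j) {
    col <- mat[, j]
    col <- col[!(col %in% c("-", "."))]
    if (length(col) == 0) {
      return(tibble(column = j, majority_residue = NA_character_,
                    majority_count = 0L))
    }
    tab <- table(col)
    top <- max(tab)
    res <- sort(names(tab)[tab == top])[1]   # alphabetical tie-break
    tibble(column = j, majority_residue = res, majority_count = as.integer(top))
  })
  out <- bind_rows(prof) |>
    mutate(conserved = .data$majority_count >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "n_seqs") <- n_seqs
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Map conserved alignment columns onto a reference sequence
#'
#' Translates conserved column indices into 1-based residue positions of
#' the ungapped reference row, for downstream structure annotation.
#' Conserved columns where the reference carries a gap cannot be mapped
#' and are reported separately.
#'
#' @param profile A [column_conservation()] profile.
#' @param aln The alignment the profile was computed from.
#' @param ref_id Id of the reference row.
#' @return A list with `positions` (integer vector of 1-based ungapped
#'   reference positions of conserved columns) and `gap_columns` (the
#'   conserved column indices at which the reference is gapped).
#' @export
map_to_reference <- function(profile, aln, ref_id) {
  if (!ref_id %in% aln$id) {
    abort(sprintf("reference id '%s' not in alignment", ref_id))
  }
  ref <- seq_chars(aln$sequence[aln$id == ref_id][1])
  is_res <- !(ref %in% c("-", "."))
  ref_pos <- cumsum(is_res)                 # 1-based ungapped index per column
  cons <- profile$column[profile$conserved]
  mapped <- cons[is_res[cons]]
  list(positions = as.integer(ref_pos[mapped]),
       gap_columns = as.integer(cons[!is_res[cons]]))
}

#' Write an alignment tibble as aligned FASTA
#'
#' @param aln Alignment tibble (`id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(aln, path)
}
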