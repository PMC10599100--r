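#' Read an annotated bacterial genome from a GenBank flat file
#'
#' Parses every `LOCUS` record (replicon) in a GenBank flat file and returns
#' one row per annotated CDS, ordered along each replicon. Coordinates are
#' converted from GenBank's 1-based inclusive convention to 0-based
#' half-open at this boundary, so all downstream interval arithmetic is
#' uniform. Gene ordinals (0-based rank in start-coordinate order, the unit
#' of the cluster adjacency rule) are assigned after sorting, regardless of
#' strand.
#'
#' Translations are taken from the `/translation` qualifier when present;
#' otherwise they are derived from the nucleotide span under genetic code
#' table 11 (bacterial). A CDS with neither a translation nor extractable
#' nucleotides is skipped with a warning, as are `/pseudo` features: only
#' translated CDS count as "annotated genes" here.
#'
#' @param path Path to a GenBank flat file containing one or more records.
#' @param genome_id Identifier for the genome; defaults to the file name
#'   without extension.
#' @return A tibble with columns `genome_id`, `replicon_id`, `protein_id`,
#'   `ordinal`, `start`, `end` (0-based half-open nucleotide coordinates),
#'   `strand` (`"+"`/`"-"`) and `sequence` (amino acids, stop trimmed,
#'   ambiguity codes mapped to `X`).
#' @examples
#' gb <- generate_genome(synthetic_config(seed = 1))
#' proteins <- read_genbank(gb$genbank_path)
#' head(proteins)
#' @export
read_genbank <- function(path, genome_id = NULL) {
  stopifnot_scalar_file(path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(startsWith(lines, "LOCUS"))) {
    abort(sprintf("not a GenBank flat file (no LOCUS line): %s", path))
  }
  genome_id <- genome_id %||% sub("\\.(gb|gbk|gbff|genbank)$", "",
                                  basename(path))
  rec_starts <- which(startsWith(lines, "LOCUS"))
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))

  replicons <- map2(rec_starts, rec_ends, function(a, b) {
    parse_genbank_record(lines[a:b], path)
  })
  ids <- map_chr(replicons, "replicon_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate replicon id in %s: %s", path,
                  ids[duplicated(ids)][1]))
  }
  proto <- tibble(replicon_id = character(), protein_id = character(),
                  ordinal = integer(), start = integer(), end = integer(),
                  strand = character(), sequence = character())
  out <- bind_rows(proto, map(replicons, "genes"))
  out <- out |>
    group_by(.data$replicon_id) |>
    arrange(.data$start, .data$end, .by_group = TRUE) |>
    mutate(ordinal = row_number() - 1L) |>
    ungroup() |>
    mutate(genome_id = genome_id) |>
    select("genome_id", "replicon_id", "protein_id", "ordinal",
           "start", "end", "strand", "sequence")
  attr(out, "replicons") <- ids
  out
}

# Parse one LOCUS..// block into replicon_id + gene tibble.
parse_genbank_record <- function(lines, path) {
  locus_tokens <- strsplit(str_trim(lines[1]), "\\s+")[[1]]
  if (length(locus_tokens) < 2) {
    abort(sprintf("malformed LOCUS line in %s", path))
  }
  replicon_id <- locus_tokens[2]

  feat_i <- which(startsWith(lines, "FEATURES"))
  origin_i <- which(startsWith(lines, "ORIGIN"))
  end_i <- which(startsWith(lines, "//"))
  stop_i <- min(c(origin_i, end_i, length(lines) + 1L))

  origin_seq <- NULL
  if (length(origin_i) == 1 && origin_i < stop_i + 1) {
    oend <- if (length(end_i)) min(end_i[end_i > origin_i]) - 1L else length(lines)
    if (oend > origin_i) {
      origin_seq <- toupper(gsub("[^A-Za-z]", "",
                                 paste(lines[(origin_i + 1L):oend], collapse = "")))
    }
  }

  genes <- tibble(replicon_id = character(), protein_id = character(),
                  ordinal = integer(), start = integer(), end = integer(),
                  strand = character(), sequence = character())
  if (length(feat_i) != 1 || feat_i + 1 > stop_i - 1) {
    return(list(replicon_id = replicon_id, genes = genes))
  }
  flines <- lines[(feat_i + 1L):(stop_i - 1L)]
  # a new feature starts with exactly 5 spaces then a key
  is_key <- grepl("^ {5}\\S", flines)
  key <- ifelse(is_key, str_trim(str_sub(flines, 6, 20)), NA_character_)
  grp <- cumsum(is_key)
  keep <- grp > 0
  flines <- flines[keep]; key <- key[keep]; grp <- grp[keep]

  cds <- list()
  for (g in unique(grp)) {
    block <- flines[grp == g]
    k <- str_trim(str_sub(block[1], 6, 20))
    if (k != "CDS") next
    cds[[length(cds) + 1L]] <- parse_cds_block(block, replicon_id, origin_seq)
  }
  genes <- bind_rows(cds)
  list(replicon_id = replicon_id, genes = genes)
}

parse_cds_block <- function(block, replicon_id, origin_seq) {
  body <- str_trim(str_sub(block, 22))
  qual_start <- which(startsWith(body, "/"))
  loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(body)
  location <- paste(body[1:loc_end], collapse = "")

  quals <- list()
  if (length(qual_start)) {
    qgrp <- cumsum(startsWith(body, "/"))
    for (q in unique(qgrp[qgrp > 0])) {
      txt <- paste(body[qgrp == q & seq_along(body) >= qual_start[1]],
                   collapse = "")
      m <- str_match(txt, "^/([A-Za-z_0-9]+)(=(.*))?$")
      if (!is.na(m[1, 2])) {
        val <- m[1, 4]
        if (!is.na(val)) val <- gsub("^\"|\"$", "", val)
        quals[[m[1, 2]]] <- if (is.na(val)) TRUE else val
      }
    }
  }
  if (isTRUE(quals$pseudo)) return(NULL)

  loc <- parse_genbank_location(location)
  if (is.null(loc)) {
    warn(sprintf("%s: unparsable CDS location '%s'; skipped",
                 replicon_id, location))
    return(NULL)
  }
  pid <- quals$protein_id %||% quals$locus_tag %||%
    sprintf("%s_%d_%d", replicon_id, loc$start, loc$end)

  aa <- quals$translation
  if (is.null(aa)) {
    aa <- translate_from_origin(loc, origin_seq)
    if (is.null(aa)) {
      warn(sprintf("%s %s: no /translation and no extractable nucleotides; skipped",
                   replicon_id, pid))
      return(NULL)
    }
  }
  aa <- gsub("\\*$", "", gsub(" ", "", aa))
  aa <- gsub("\\*", "X", aa)
  if (nchar(aa) == 0) return(NULL)
  aa <- sanitize_protein(aa, context = pid)

  tibble(replicon_id = replicon_id, protein_id = pid, ordinal = NA_integer_,
         start = loc$start - 1L, end = loc$end,
         strand = loc$strand, sequence = aa)
}

# Returns list(start, end (1-based inclusive), strand, parts) or NULL.
parse_genbank_location <- function(location) {
  strand <- if (grepl("complement", location)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", location)
  parts <- strsplit(inner, ",")[[1]]
  m <- str_match(parts, "^(\\d+)(\\.\\.(\\d+))?$")
  if (any(is.na(m[, 2]))) return(NULL)
  from <- as.integer(m[, 2])
  to <- ifelse(is.na(m[, 4]), m[, 2], m[, 4])
  to <- as.integer(to)
  list(start = min(from), end = max(to), strand = strand,
       parts = cbind(from, to))
}

translate_from_origin <- function(loc, origin_seq) {
  if (is.null(origin_seq)) return(NULL)
  if (max(loc$parts[, 2]) > nchar(origin_seq)) return(NULL)
  pieces <- apply(loc$parts, 1, function(p) {
    substr(origin_seq, p[1], p[2])
  })
  nt <- paste(pieces, collapse = "")
  dna <- Biostrings::DNAString(gsub("[^ACGTN]", "N", nt))
  if (loc$strand == "-") dna <- Biostrings::reverseComplement(dna)
  if (length(dna) < 3) return(NULL)
  dna <- dna[1:(3 * (length(dna) %/% 3))]
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  aa
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header and
#' sequences are upper-cased. Gap characters (`-`, `.`) are stripped unless
#' `alignment = TRUE`, in which case they are preserved for use with
#' [read_alignment()]-style consumers.
#'
#' @param path Path to a FASTA file.
#' @param alignment Keep gap characters? Default `FALSE`.
#' @return A tibble with columns `id` and `sequence`; zero rows for an
#'   empty file.
#' @export
read_fasta <- function(path, alignment = FALSE) {
  stopifnot_scalar_file(path)
  txt <- readLines(path, warn = FALSE)
  if (!any(startsWith(txt, ">"))) {
    if (all(str_trim(txt) == "")) return(tibble(id = character(),
                                                sequence = character()))
    abort(sprintf("not FASTA (no '>' header): %s", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- map_chr(str_split(names(set), "\\s+"), 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  if (!alignment) seqs <- gsub("[-.]", "", seqs)
  tibble(id = ids, sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' Sequences are wrapped at a fixed column width; `read_fasta()` of the
#' written file reproduces the input exactly.
#'
#' @param records A tibble (or data frame) with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (nrow(records) > 0 && any(!nzchar(records$id))) {
    abort("FASTA ids must be nonempty")
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a proteins table as a GenBank flat file
#'
#' The inverse of [read_genbank()] for annotation-level information: one
#' `LOCUS` record per replicon, one CDS feature per protein with its
#' coordinates (converted back to GenBank 1-based inclusive), strand and
#' `/translation`. Nucleotide `ORIGIN` sections are not emitted; the
#' translations carry the sequence information. Used by the synthetic
#' genome generator and for round-trip testing.
#'
#' @param proteins A proteins tibble as returned by [read_genbank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(proteins, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rep_id in unique(proteins$replicon_id)) {
    genes <- proteins |> filter(.data$replicon_id == rep_id) |>
      arrange(.data$start)
    len <- if (nrow(genes)) max(genes$end) + 50L else 1000L
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                       rep_id, len), con)
    writeLines(sprintf("DEFINITION  synthetic replicon %s.", rep_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      span <- sprintf("%d..%d", g$start + 1L, g$end)
      if (g$strand == "-") span <- sprintf("complement(%s)", span)
      writeLines(sprintf("     CDS             %s", span), con)
      writeLines(sprintf("                     /protein_id=\"%s\"", g$protein_id),
                 con)
      tr <- sprintf("/translation=\"%s\"", g$sequence)
      wrapped <- substring(tr, seq(1, nchar(tr), 58),
                           pmin(nchar(tr), seq(58, nchar(tr) + 57, 58)))
      writeLines(paste0(strrep(" ", 21), wrapped), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
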