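#' Pipeline configuration
#'
#' Assembles the thresholds and paths driving [run_survey()]. All
#' defaults mirror the survey's stated parameters: domain hits kept below
#' E-value 1e-10, clusters chained across at most 4 intervening annotated
#' genes, alignment columns conserved at 60 invariant sequences.
#'
#' @param genomes_dir Directory of GenBank files (`.gb`, `.gbk`, `.gbff`).
#' @param domtblout_dir Directory of HMMER domtblout files, or `NULL`
#'   with `motif_only = TRUE` to use the built-in motif scanners.
#' @param alignments_dir Optional directory of alignments for the
#'   conservation report.
#' @param out_dir Optional output directory for the TSV tables; `NULL`
#'   keeps results in memory only.
#' @param motif_only Use motif-scanner evidence instead of HMMER output.
#'   Lower fidelity: no sequence motif exists for HBD, so full WxLIP
#'   proteins class as PGBD-only in this mode.
#' @param evalue_max,max_gap,conservation_threshold,insert_threshold
#'   Survey thresholds (defaults 1e-10, 4, 60, 140).
#' @param tmh_window,tmh_threshold,tmh_cterm_zone Hydropathy TMH
#'   detector settings (defaults 19, 1.6, 60).
#' @param small_coverage,cterm_tol Small/large WxL classification knobs
#'   (defaults 0.6, 15).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes_dir, domtblout_dir = NULL,
                            alignments_dir = NULL, out_dir = NULL,
                            motif_only = is.null(domtblout_dir),
                            evalue_max = 1e-10, max_gap = 4,
                            conservation_threshold = 60,
                            insert_threshold = 140,
                            tmh_window = 19, tmh_threshold = 1.6,
                            tmh_cterm_zone = 60,
                            small_coverage = 0.6, cterm_tol = 15) {
  cfg <- list(genomes_dir = genomes_dir, domtblout_dir = domtblout_dir,
              alignments_dir = alignments_dir, out_dir = out_dir,
              motif_only = motif_only, evalue_max = evalue_max,
              max_gap = max_gap,
              conservation_threshold = conservation_threshold,
              insert_threshold = insert_threshold,
              tmh_window = tmh_window, tmh_threshold = tmh_threshold,
              tmh_cterm_zone = tmh_cterm_zone,
              small_coverage = small_coverage, cterm_tol = cterm_tol)
  num <- c("evalue_max", "max_gap", "conservation_threshold",
           "insert_threshold", "tmh_window", "tmh_threshold",
           "tmh_cterm_zone", "small_coverage", "cterm_tol")
  if (any(unlist(cfg[num]) <= 0)) abort("all thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines are `key = value`; `#` starts a comment. Keys are the arguments
#' of [pipeline_config()]; unknown keys raise an error.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stopifnot_scalar_file(path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(str_trim(lines))]
  kv <- str_match(lines, "^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$")
  if (anyNA(kv[, 1])) abort("malformed config line")
  args <- as.list(kv[, 3])
  names(args) <- kv[, 2]
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) abort(sprintf("unknown config key(s): %s",
                                 paste(bad, collapse = ", ")))
  numeric_keys <- c("evalue_max", "max_gap", "conservation_threshold",
                    "insert_threshold", "tmh_window", "tmh_threshold",
                    "tmh_cterm_zone", "small_coverage", "cterm_tol")
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  if ("motif_only" %in% names(args)) {
    args$motif_only <- tolower(args$motif_only) %in% c("true", "yes", "1")
  }
  do.call(pipeline_config, args)
}

#' Run the full WxL genome survey
#'
#' Executes every stage in order: read the annotated genomes, gather and
#' filter domain evidence (HMMER domtblout or motif scanners), merge
#' redundant hits, classify each protein's architecture, chain relevant
#' genes into adjacency clusters, evaluate and type the clusters,
#' summarize each genome, and compute the property table for the
#' relevant proteins (plus conservation profiles when alignments are
#' supplied). Deterministic given inputs and configuration.
#'
#' @param config A [pipeline_config()] (or path to a config file).
#' @return A `wxl_survey` object: a list of tibbles `proteins`,
#'   `clusters`, `summaries`, `physchem`, `conservation`, plus the
#'   `config` and run metadata. TSV tables are written to
#'   `config$out_dir` when set.
#' @export
run_survey <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$genomes_dir) || !dir.exists(config$genomes_dir)) {
    abort(sprintf("genomes_dir does not exist: %s",
                  config$genomes_dir %||% "<missing>"))
  }
  gb_files <- list.files(config$genomes_dir,
                         pattern = "\\.(gb|gbk|gbff|genbank)$",
                         full.names = TRUE)
  if (length(gb_files) == 0) abort("no GenBank files in genomes_dir")

  hmmer_hits <- NULL
  if (!config$motif_only) {
    if (is.null(config$domtblout_dir) || !dir.exists(config$domtblout_dir)) {
      abort("domtblout_dir does not exist (or set motif_only)")
    }
    dt_files <- list.files(config$domtblout_dir,
                           pattern = "\\.(domtblout|tbl|txt)$",
                           full.names = TRUE)
    if (length(dt_files) == 0) abort("no domtblout files in domtblout_dir")
    hmmer_hits <- bind_rows(map(dt_files, parse_domtblout,
                                evalue_max = config$evalue_max))
  }

  all_calls <- list()
  all_clusters <- list()
  for (f in gb_files) {
    proteins <- read_genbank(f)
    hits <- if (config$motif_only) {
      bind_rows(map2(proteins$protein_id, proteins$sequence,
                     motif_hits_as_domain_hits))
    } else {
      filter(hmmer_hits, .data$protein_id %in% proteins$protein_id)
    }
    hits <- merge_hits(hits)
    tmh <- bind_rows(map2(proteins$protein_id, proteins$sequence,
                          function(pid, s) {
      d <- detect_tmh(s, window = config$tmh_window,
                      threshold = config$tmh_threshold,
                      cterm_zone = config$tmh_cterm_zone)
      if (nrow(d)) mutate(d, protein_id = pid, .before = 1) else NULL
    }))
    if (nrow(tmh) == 0) {
      tmh <- tibble(protein_id = character(), start = integer(),
                    end = integer(), hydropathy = double())
    }
    calls <- classify_architecture(proteins, hits, tmh = tmh,
                                   small_coverage = config$small_coverage,
                                   cterm_tol = config$cterm_tol)
    cand <- find_candidates(calls, max_gap = config$max_gap)
    all_calls[[f]] <- calls
    all_clusters[[f]] <- evaluate_clusters(cand)
  }
  calls <- bind_rows(all_calls)
  clusters <- bind_rows(all_clusters)
  summaries <- summarize_genomes(calls, clusters)

  relevant <- filter(calls, .data$arch_class %in% RELEVANT_CLASSES)
  physchem <- if (nrow(relevant)) physchem_profile(relevant) else
    physchem_profile(tibble(protein_id = character(),
                            sequence = character()))

  conservation <- NULL
  if (!is.null(config$alignments_dir) && dir.exists(config$alignments_dir)) {
    aln_files <- list.files(config$alignments_dir,
                            pattern = "\\.(fa|fasta|afa|aln|clustal)$",
                            full.names = TRUE)
    conservation <- bind_rows(map(aln_files, function(af) {
      prof <- column_conservation(read_alignment(af),
                                  threshold = config$conservation_threshold)
      mutate(as_tibble(prof), alignment = basename(af), .before = 1)
    }))
  }

  result <- structure(list(
    proteins = select(calls, -"sequence"),
    clusters = clusters, summaries = summaries,
    physchem = physchem, conservation = conservation,
    config = config,
    meta = list(version = as.character(utils::packageVersion("wxlsurvey")),
                n_genomes = length(gb_files), timestamp = Sys.time())
  ), class = "wxl_survey")

  if (!is.null(config$out_dir)) write_survey_tables(result, config$out_dir)
  result
}

#' Write the survey tables as TSV files
#'
#' @param result A `wxl_survey` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$proteins, file.path(dir, "proteins.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$clusters, file.path(dir, "clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$summaries, file.path(dir, "genome_summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$physchem, file.path(dir, "physchem.tsv"),
                   progress = FALSE)
  if (!is.null(result$conservation)) {
    readr::write_tsv(result$conservation, file.path(dir, "conservation.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Consistency checks on a survey result
#'
#' Verifies the structural invariants every pipeline run must satisfy:
#' each cluster member appears in the protein table; per-class census
#' counts sum to the reported total in every genome summary; each
#' qualifying cluster meets the at-least-1-WxLIP-and-2-WxL definition;
#' simple clusters never outnumber qualifying clusters.
#'
#' @param result A `wxl_survey` object.
#' @return A tibble of findings (`check`, `detail`); zero rows means the
#'   result is internally consistent.
#' @export
validate_result <- function(result) {
  findings <- list()
  note <- function(check, detail) {
    findings[[length(findings) + 1L]] <<- tibble(check = check,
                                                 detail = detail)
  }
  if (nrow(result$clusters)) {
    members <- unlist(str_split(result$clusters$members, ","))
    missing <- setdiff(members, result$proteins$protein_id)
    if (length(missing)) {
      note("cluster_membership",
           sprintf("cluster member(s) absent from protein table: %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    bad <- filter(result$clusters,
                  .data$qualifies & (.data$n_wxlip < 1 | .data$n_wxl < 2))
    if (nrow(bad)) {
      note("cluster_definition",
           sprintf("%d qualifying cluster(s) violate the census thresholds",
                   nrow(bad)))
    }
  }
  s <- result$summaries
  if (nrow(s)) {
    mism <- s$total != s$n_wxlip + s$n_wxl + s$n_pgbd_only + s$n_hbd_only
    if (any(mism)) {
      note("census_sum", sprintf("census does not sum to total for: %s",
                                 paste(s$genome_id[mism], collapse = ", ")))
    }
    if (any(s$n_simple > s$n_clusters)) {
      note("simple_count", "n_simple exceeds n_clusters")
    }
    if (any(s$sparse & s$n_clusters > 0)) {
      note("sparse_flag", "sparse genome reports a qualifying cluster")
    }
  }
  if (length(findings)) bind_rows(findings) else
    tibble(check = character(), detail = character())
}

#' @export
print.wxl_survey <- function(x, ...) {
  g <- glance(x)
  cat("<wxl_survey>\n")
  cat(sprintf("  genomes: %d   proteins: %d (relevant %d)\n",
              g$n_genomes, g$n_proteins, g$n_relevant))
  cat(sprintf("  census:  %d WxLIP, %d WxL, %d PGBD-only, %d HBD-only\n",
              g$n_wxlip, g$n_wxl, g$n_pgbd_only, g$n_hbd_only))
  cat(sprintf("  clusters: %d qualifying (%d simple), %d sparse genome(s)\n",
              g$n_clusters, g$n_simple, g$n_sparse))
  invisible(x)
}
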