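#' Group relevant genes into adjacency cluster candidates
#'
#' Applies the survey's adjacency rule per replicon: two relevant genes
#' (WxL, WxLIP, isolated PGBD or HBD) belong to the same candidate when
#' they are separated by no more than `max_gap` intervening annotated
#' genes, i.e. their ordinal difference is at most `max_gap + 1`. The rule
#' is applied transitively (single linkage), so candidates are the maximal
#' chained groups; every relevant gene lands in exactly one candidate,
#' singletons included. Genes on different replicons never share a
#' candidate, and adjacency does not wrap around the origin of circular
#' replicons.
#'
#' @param calls A classified-protein tibble ([classify_architecture()])
#'   with `replicon_id`, `ordinal`, `protein_id`, `arch_class`. Rows whose
#'   class is not one of the five relevant classes are ignored.
#' @param max_gap Maximum number of intervening annotated genes, default 4.
#' @return The relevant rows with an added `cluster_id` column
#'   (`<replicon>:c<k>`, numbered along each replicon), sorted by replicon
#'   and ordinal.
#' @export
find_candidates <- function(calls, max_gap = 4) {
  rel <- calls |>
    filter(.data$arch_class %in% RELEVANT_CLASSES) |>
    arrange(.data$replicon_id, .data$ordinal)
  if (nrow(rel) == 0) return(mutate(rel, cluster_id = character(0)))
  dup <- rel |> count(.data$replicon_id, .data$ordinal) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate ordinal %d on replicon %s",
                  dup$ordinal[1], dup$replicon_id[1]))
  }
  rel |>
    group_by(.data$replicon_id) |>
    mutate(cluster_id = sprintf(
      "%s:c%d", .data$replicon_id,
      cumsum(c(1L, as.integer(diff(.data$ordinal) > max_gap + 1L))))) |>
    ungroup()
}

#' Evaluate adjacency candidates against the WxL-cluster definition
#'
#' A candidate qualifies as a WxL cluster when it contains at least one
#' full-length WxLIP and at least two WxL proteins (small or large); it is
#' "simple" when it contains exactly one WxLIP and exactly two WxL.
#' Isolated PGBD or HBD members co-occur in clusters but count toward
#' neither tally.
#'
#' @param candidates Output of [find_candidates()].
#' @return One row per candidate: `genome_id` (when present),
#'   `replicon_id`, `cluster_id`, `n_members`, `n_wxlip`, `n_wxl`,
#'   `ordinal_min`, `ordinal_max`, `members` (comma-joined protein ids),
#'   `member_classes`, `qualifies`, `simple`.
#' @export
evaluate_clusters <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble(replicon_id = character(), cluster_id = character(),
                  n_members = integer(), n_wxlip = integer(),
                  n_wxl = integer(), ordinal_min = integer(),
                  ordinal_max = integer(), members = character(),
                  member_classes = character(), qualifies = logical(),
                  simple = logical()))
  }
  grp_cols <- intersect(c("genome_id", "replicon_id", "cluster_id"),
                        names(candidates))
  candidates |>
    arrange(.data$replicon_id, .data$ordinal) |>
    group_by(across(dplyr::all_of(grp_cols))) |>
    summarise(
      n_members = n(),
      n_wxlip = sum(.data$arch_class == "WXLIP_FULL"),
      n_wxl = sum(.data$arch_class %in% c("WXL_SMALL", "WXL_LARGE")),
      ordinal_min = min(.data$ordinal),
      ordinal_max = max(.data$ordinal),
      members = paste(.data$protein_id, collapse = ","),
      member_classes = paste(.data$arch_class, collapse = ","),
      .groups = "drop"
    ) |>
    mutate(qualifies = .data$n_wxlip >= 1L & .data$n_wxl >= 2L,
           simple = .data$qualifies & .data$n_wxlip == 1L & .data$n_wxl == 2L) |>
    arrange(.data$replicon_id, .data$ordinal_min)
}

#' Summarize one genome's WxL content
#'
#' Combines the proteome census with the cluster tally: how many
#' qualifying clusters, how many of the simple 1-WxLIP + 2-WxL type, and
#' whether the genome is "sparse" (only one or two relevant proteins in
#' total and no qualifying cluster — the pattern the survey found in only
#' 59 of 5482 genomes).
#'
#' @param genome_id Genome identifier.
#' @param calls Classified proteins of this genome.
#' @param clusters Evaluated clusters of this genome
#'   ([evaluate_clusters()]).
#' @return A one-row tibble with the census columns plus `n_clusters`,
#'   `n_simple`, `sparse`.
#' @export
summarize_genome <- function(genome_id, calls, clusters) {
  census <- proteome_census(calls)
  n_clusters <- sum(clusters$qualifies)
  n_simple <- sum(clusters$simple)
  dplyr::bind_cols(
    tibble(genome_id = genome_id),
    census,
    tibble(n_clusters = n_clusters, n_simple = n_simple,
           sparse = census$total %in% c(1L, 2L) & n_clusters == 0L)
  )
}

#' @describeIn summarize_genome Summarize every genome in a multi-genome
#'   calls table (requires a `genome_id` column).
#' @export
summarize_genomes <- function(calls, clusters) {
  gids <- unique(calls$genome_id)
  bind_rows(map(gids, function(g) {
    cl <- if ("genome_id" %in% names(clusters)) {
      filter(clusters, .data$genome_id == g)
    } else clusters
    summarize_genome(g, filter(calls, .data$genome_id == g), cl)
  }))
}
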