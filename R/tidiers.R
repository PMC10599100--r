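#' Tidy and glance methods for survey results
#'
#' `tidy()` returns the requested table of a `wxl_survey` (the per-protein
#' classification by default); `glance()` returns a one-row summary of
#' the whole run.
#'
#' @param x A `wxl_survey` object from [run_survey()].
#' @param table Which table to return: `"proteins"`, `"clusters"`,
#'   `"summaries"`, `"physchem"` or `"conservation"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wxl_survey
#' @export
tidy.wxl_survey <- function(x, table = c("proteins", "clusters", "summaries",
                                         "physchem", "conservation"), ...) {
  table <- match.arg(table)
  out <- x[[table]]
  if (is.null(out)) {
    abort(sprintf("survey result has no '%s' table", table))
  }
  as_tibble(out)
}

#' @rdname tidy.wxl_survey
#' @method glance wxl_survey
#' @export
glance.wxl_survey <- function(x, ...) {
  s <- x$summaries
  tibble(
    n_genomes = nrow(s),
    n_proteins = nrow(x$proteins),
    n_relevant = sum(x$proteins$arch_class %in% RELEVANT_CLASSES),
    n_wxlip = sum(s$n_wxlip), n_wxl = sum(s$n_wxl),
    n_pgbd_only = sum(s$n_pgbd_only), n_hbd_only = sum(s$n_hbd_only),
    total = sum(s$total),
    n_clusters = sum(s$n_clusters), n_simple = sum(s$n_simple),
    n_sparse = sum(s$sparse)
  )
}

#' @rdname tidy.wxl_survey
#' @method tidy conservation_profile
#' @export
tidy.conservation_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "conservation_profile")
  as_tibble(out)
}

#' @rdname tidy.wxl_survey
#' @method glance conservation_profile
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(n_cols = nrow(x), n_conserved = sum(x$conserved),
         threshold = attr(x, "threshold"),
         n_seqs = attr(x, "n_seqs"))
}

#' Plot a conservation profile
#'
#' Column bar chart of the majority-residue count per alignment column,
#' with conserved columns highlighted and the invariance threshold drawn
#' as a dashed line.
#'
#' @param object A `conservation_profile` from [column_conservation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$column, y = .data$majority_count,
                               fill = .data$conserved)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "alignment column", y = "majority-residue count",
                  fill = sprintf("invariant in ≥ %d", thr)) +
    ggplot2::theme_minimal()
}

#' Plot the gene-cluster map of a survey
#'
#' One horizontal track per replicon with each relevant gene drawn at its
#' ordinal, coloured by architecture class; qualifying clusters are
#' underlined. A compact view of where the WxL loci sit in each genome.
#'
#' @param object A `wxl_survey` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wxl_survey
#' @export
autoplot.wxl_survey <- function(object, ...) {
  rel <- filter(object$proteins, .data$arch_class %in% RELEVANT_CLASSES)
  cl <- filter(object$clusters, .data$qualifies)
  p <- ggplot2::ggplot(rel,
                       ggplot2::aes(x = .data$ordinal, y = .data$replicon_id,
                                    colour = .data$arch_class)) +
    ggplot2::geom_point(size = 3, shape = 15) +
    ggplot2::labs(x = "gene ordinal", y = NULL, colour = "class") +
    ggplot2::theme_minimal()
  if (nrow(cl)) {
    p <- p + ggplot2::geom_segment(
      data = cl,
      ggplot2::aes(x = .data$ordinal_min - 0.4, xend = .data$ordinal_max + 0.4,
                   y = .data$replicon_id, yend = .data$replicon_id),
      inherit.aes = FALSE, linewidth = 0.4, colour = "grey40")
  }
  if ("genome_id" %in% names(rel) && length(unique(rel$genome_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~genome_id, scales = "free")
  }
  p
}

#' @rdname autoplot.wxl_survey
#' @export
plot_cluster_map <- function(object, ...) autoplot.wxl_survey(object, ...)
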