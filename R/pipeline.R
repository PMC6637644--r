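#' Run the full differential-regulation analysis for one comparison
#'
#' Orchestrates the pipeline over two biological replicates of one
#' comparison: quality filtering, per-replicate population statistics and
#' z-scores, dual-criterion classification, two-replicate combination,
#' top-N ranking, and (when a gene-set collection is supplied) one-sided
#' over-representation testing with BH FDR control against the quantified
#' background. Deterministic given inputs and configuration.
#'
#' @param tables list of exactly two [quant_table]s (the two replicates),
#'   unfiltered or filtered.
#' @param thresholds a [silac_thresholds()].
#' @param sets optional [gene_set_collection()] for enrichment.
#' @param enrichment_id identifier space used for enrichment matching:
#'   `"gene_name"` or `"accession"`.
#' @param q_cut FDR significance cutoff for reporting enriched sets.
#' @param top_n number of top up/down proteins to report.
#' @param robust passed to [population_stats()].
#' @param out_dir optional directory; when given, the call table, top-N
#'   tables, enrichment table, replicate scatter plot (PDF), and a run log
#'   are written there.
#' @return list with `calls`, `top_up`, `top_down`, `enrichment` (or
#'   `NULL`), per-replicate `stats`, and `counts` (parsed, filtered per
#'   replicate, called up/down).
#' @export
run_coculture_analysis <- function(tables,
                                   thresholds = silac_thresholds(),
                                   sets = NULL,
                                   enrichment_id = c("gene_name", "accession"),
                                   q_cut = 0.05,
                                   top_n = 10L,
                                   robust = FALSE,
                                   out_dir = NULL) {
  enrichment_id <- match.arg(enrichment_id)
  if (!is.list(tables) || length(tables) != 2L ||
      !all(vapply(tables, inherits, logical(1L), "quant_table"))) {
    stop("run_coculture_analysis requires a list of exactly 2 quant_tables",
         call. = FALSE)
  }
  parsed <- vapply(tables, nrow, integer(1L))
  filtered <- lapply(tables, filter_quality)
  n_filtered <- vapply(filtered, nrow, integer(1L))
  per_rep <- lapply(filtered, replicate_calls, thresholds = thresholds,
                    robust = robust)
  calls <- combine_replicates(per_rep)
  top_up <- rank_top(calls, "up", top_n)
  top_down <- rank_top(calls, "down", top_n)
  enrichment <- NULL
  if (!is.null(sets)) {
    universe <- unique(toupper(calls[[enrichment_id]]))
    hit_rows <- calls$direction != "unchanged"
    hit_ids <- unique(toupper(calls[[enrichment_id]][hit_rows]))
    enrichment <- fisher_enrichment(hit_ids, universe, sets)
    enrichment <- direction_summary(enrichment, calls, sets,
                                    id_column = enrichment_id)
    enrichment$significant <- enrichment$q_value < q_cut
  }
  counts <- list(parsed = parsed, filtered = n_filtered,
                 quantified_in_both = sum(!is.na(calls$average_ratio)),
                 called_up = sum(calls$direction == "up"),
                 called_down = sum(calls$direction == "down"))
  result <- list(calls = calls, top_up = top_up, top_down = top_down,
                 enrichment = enrichment,
                 stats = lapply(per_rep, attr, "stats"),
                 thresholds = thresholds, counts = counts,
                 comparison = attr(tables[[1L]], "comparison"))
  if (!is.null(out_dir)) write_result_bundle(result, out_dir)
  result
}

write_result_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(result$calls, file.path(out_dir, "calls.tsv"))
  write_table(result$top_up, file.path(out_dir, "top_up.tsv"))
  write_table(result$top_down, file.path(out_dir, "top_down.tsv"))
  if (!is.null(result$enrichment)) {
    write_table(result$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  plot_ok <- sum(!is.na(result$calls$log2_rep1) &
                 !is.na(result$calls$log2_rep2)) > 0L
  if (plot_ok) {
    scatter_plot(result$calls, thresholds = result$thresholds,
                 path = file.path(out_dir, "scatter.pdf"))
  }
  log_lines <- c(
    sprintf("silacdiff %s", as.character(utils::packageVersion("silacdiff"))),
    sprintf("comparison: %s", result$comparison),
    sprintf("thresholds: z_cut=%g z_tier99=%g z_tier999=%g log2_cut=%g",
            result$thresholds$z_cut, result$thresholds$z_tier99,
            result$thresholds$z_tier999, result$thresholds$log2_cut),
    sprintf("parsed: %s", paste(result$counts$parsed, collapse = ", ")),
    sprintf("filtered: %s", paste(result$counts$filtered, collapse = ", ")),
    sprintf("quantified in both replicates: %d",
            result$counts$quantified_in_both),
    sprintf("called up: %d", result$counts$called_up),
    sprintf("called down: %d", result$counts$called_down))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Replicate-vs-replicate scatter plot of log2 ratios
#'
#' Plots replicate 1 against replicate 2 log2 ratios, colored by final
#' regulation call, with dashed guide lines at the fold cutoffs
#' (+/- log2_cut). Proteins quantified in only one replicate are omitted.
#'
#' @param calls data.frame from [combine_replicates()].
#' @param thresholds a [silac_thresholds()] (for the guide lines).
#' @param path optional output file (`.pdf`, `.png`, `.svg`); when `NULL`
#'   the ggplot object is returned unsaved.
#' @param width,height device size in inches.
#' @return The ggplot object, invisibly when saved.
#' @export
scatter_plot <- function(calls, thresholds = silac_thresholds(),
                         path = NULL, width = 5, height = 5) {
  df <- calls[!is.na(calls$log2_rep1) & !is.na(calls$log2_rep2), ,
              drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no proteins with log2 ratios in both replicates; nothing to plot",
         call. = FALSE)
  }
  df$direction <- factor(df$direction, levels = c("down", "unchanged", "up"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_rep1,
                                        y = .data$log2_rep2,
                                        colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * thresholds$log2_cut,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$log2_cut,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(down = "#2166AC", unchanged = "grey55", up = "#B2182B"),
      drop = FALSE) +
    ggplot2::labs(x = "log2 ratio, replicate 1",
                  y = "log2 ratio, replicate 2",
                  colour = "call") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
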