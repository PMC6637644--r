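#' One-sided gene-set over-representation test
#'
#' For each gene set, tests whether the hit list contains more set members
#' than expected by chance within the background universe, using the
#' one-sided Fisher's exact / hypergeometric upper-tail probability
#' `P(X >= overlap)`. Identifier matching is case-insensitive exact string
#' match; set members are intersected with the universe before testing, and
#' sets with no member in the universe are dropped. Benjamini-Hochberg
#' q-values over the tested sets are appended.
#'
#' @param hit_ids character vector of significant identifiers (gene names or
#'   accessions); must be a subset of `universe_ids`.
#' @param universe_ids character vector: the background, typically all
#'   quality-filtered quantified proteins of the experiment.
#' @param sets a [gene_set_collection()]; its explicit `universe`, when set,
#'   replaces `universe_ids`.
#' @return data.frame with one row per tested set: `set_name`, `overlap`,
#'   `set_size_in_universe`, `hits`, `universe`, `p_value`, `q_value`,
#'   ordered by increasing p-value.
#' @export
fisher_enrichment <- function(hit_ids, universe_ids, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!is.null(sets$universe)) universe_ids <- sets$universe
  universe <- unique(toupper(as.character(universe_ids)))
  hits <- unique(toupper(as.character(hit_ids)))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  stray <- setdiff(hits, universe)
  if (length(stray) > 0L) {
    stop("hit identifiers not in universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(unique(toupper(sets$sets[[nm]])), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    x <- length(intersect(members, hits))
    # P(X >= x) for X ~ Hypergeometric(N, K, n_hits)
    p <- stats::phyper(x - 1L, K, N - K, n_hits, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = x, set_size_in_universe = K,
               hits = n_hits, universe = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no gene set has any member in the universe", call. = FALSE)
  }
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, clipped to 1;
#' output order matches input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Annotate enrichment results with hit directions
#'
#' Counts up- and down-called proteins among each set's overlapping hits and
#' labels the set `"up"` when every overlapping member is up-regulated,
#' `"down"` when every one is down-regulated, `"mixed"` otherwise (and `NA`
#' for sets with no overlap).
#'
#' @param enrichment data.frame from [fisher_enrichment()].
#' @param calls data.frame from [combine_replicates()].
#' @param sets the same [gene_set_collection()] used for the test.
#' @param id_column column of `calls` the set members refer to
#'   (`"gene_name"` or `"accession"`).
#' @return `enrichment` with `n_up`, `n_down`, and `direction_label` columns
#'   appended.
#' @export
direction_summary <- function(enrichment, calls, sets,
                              id_column = c("gene_name", "accession")) {
  id_column <- match.arg(id_column)
  stopifnot(inherits(sets, "gene_set_collection"))
  ids <- toupper(calls[[id_column]])
  hit_dir <- calls$direction[calls$direction != "unchanged"]
  hit_ids <- ids[calls$direction != "unchanged"]
  n_up <- integer(nrow(enrichment))
  n_down <- integer(nrow(enrichment))
  label <- character(nrow(enrichment))
  for (i in seq_len(nrow(enrichment))) {
    members <- toupper(sets$sets[[enrichment$set_name[[i]]]])
    in_set <- hit_ids %in% members
    n_up[[i]] <- sum(in_set & hit_dir == "up")
    n_down[[i]] <- sum(in_set & hit_dir == "down")
    label[[i]] <- if (n_up[[i]] + n_down[[i]] == 0L) NA_character_
      else if (n_down[[i]] == 0L) "up"
      else if (n_up[[i]] == 0L) "down"
      else "mixed"
  }
  enrichment$n_up <- n_up
  enrichment$n_down <- n_down
  enrichment$direction_label <- label
  enrichment
}
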