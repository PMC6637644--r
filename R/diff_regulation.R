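#' Decision thresholds for the dual fold-change / z-score criterion
#'
#' Defaults are the two-sided standard-normal quantiles at 95% / 99% / 99.9%
#' confidence (1.960, 2.576, 3.291 sigma) together with the fold cutoffs
#' 1.5-fold up and 0.67-fold down, i.e. `|log2 ratio| > 0.58`. A protein is
#' significantly regulated when it passes both the fold and the z criterion
#' with consistent sign; the z tiers grade the confidence of the call.
#'
#' @param z_cut first-tier z cutoff in sigma units (95% confidence).
#' @param z_tier99 second-tier cutoff (99%).
#' @param z_tier999 third-tier cutoff (99.9%).
#' @param log2_cut magnitude cutoff on the log2 ratio; the fold criterion is
#'   strict (`|log2 ratio| > log2_cut`) while the z criterion is inclusive
#'   (`|z| >= z_cut`).
#' @param fold_up,fold_down raw-ratio equivalents of the fold cutoffs, kept
#'   for reporting.
#' @return A `silac_thresholds` list.
#' @export
silac_thresholds <- function(z_cut = 1.960, z_tier99 = 2.576,
                             z_tier999 = 3.291, log2_cut = 0.58,
                             fold_up = 1.5, fold_down = 0.67) {
  if (!(0 < z_cut && z_cut < z_tier99 && z_tier99 < z_tier999)) {
    stop("need 0 < z_cut < z_tier99 < z_tier999", call. = FALSE)
  }
  if (log2_cut <= 0) stop("log2_cut must be > 0", call. = FALSE)
  if (!(fold_down < 1 && 1 < fold_up)) {
    stop("need fold_down < 1 < fold_up", call. = FALSE)
  }
  structure(list(z_cut = z_cut, z_tier99 = z_tier99, z_tier999 = z_tier999,
                 log2_cut = log2_cut, fold_up = fold_up,
                 fold_down = fold_down),
            class = "silac_thresholds")
}

#' Log2-transform the ratios of a quantification table
#'
#' @param table a quality-filtered [quant_table] (all ratios present and
#'   positive).
#' @return data.frame with columns `accession`, `gene_name`, `log2_ratio`.
#' @export
log2_ratios <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  bad <- is.na(table$ratio) | table$ratio <= 0
  if (any(bad)) {
    stop("non-positive or missing ratio for accession(s): ",
         paste(utils::head(table$accession[bad], 5L), collapse = ", "),
         "; run filter_quality() first", call. = FALSE)
  }
  data.frame(accession = table$accession,
             gene_name = table$gene_name,
             log2_ratio = log2(table$ratio),
             stringsAsFactors = FALSE)
}

#' Population mean and standard deviation of log2 ratios
#'
#' The mean of the log2 ratios equals the log2 of the geometric mean of the
#' raw ratios; the whole quantified population of one replicate is used, with
#' no trimming. The sample (n-1) standard deviation is the default; a robust
#' median/MAD mode is available for populations with extreme spike ratios.
#'
#' @param log2_values numeric vector of log2 ratios (length >= 2, finite).
#' @param robust if `TRUE`, use median and `stats::mad()` (scaled to be
#'   consistent with the normal SD) instead of mean/SD.
#' @return A `population_stats` list: `mean_log2`, `sd_log2`, `n`.
#' @export
population_stats <- function(log2_values, robust = FALSE) {
  log2_values <- as.numeric(log2_values)
  if (length(log2_values) < 2L) {
    stop("population_stats needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(log2_values))) {
    stop("all log2 values must be finite", call. = FALSE)
  }
  if (robust) {
    m <- stats::median(log2_values)
    s <- stats::mad(log2_values)
  } else {
    m <- mean(log2_values)
    s <- stats::sd(log2_values)
  }
  structure(list(mean_log2 = m, sd_log2 = s, n = length(log2_values)),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("population_stats: n = %d, mean log2 = %.4f, sd log2 = %.4f\n",
              x$n, x$mean_log2, x$sd_log2))
  invisible(x)
}

#' Standardize log2 ratios to z-scores
#'
#' `z = (log2_ratio - mean_log2) / sd_log2`: the number of population
#' standard deviations (sigma) a protein's log2 ratio lies from the
#' population mean.
#'
#' @param log2_table data.frame from [log2_ratios()] (columns `accession`,
#'   `log2_ratio`, optionally `gene_name`).
#' @param stats a [population_stats()] computed from the same population.
#' @return The input data.frame with a `z` column appended.
#' @export
z_scores <- function(log2_table, stats) {
  stopifnot(inherits(stats, "population_stats"))
  if (!is.finite(stats$sd_log2) || stats$sd_log2 <= 0) {
    stop("degenerate population: sd of log2 ratios is zero, z-scores undefined",
         call. = FALSE)
  }
  log2_table$z <- (log2_table$log2_ratio - stats$mean_log2) / stats$sd_log2
  log2_table
}

#' Classify proteins by the dual fold-change / z-score criterion
#'
#' Direction: `up` when `log2_ratio > log2_cut` and `z >= z_cut`; `down`
#' when `log2_ratio < -log2_cut` and `z <= -z_cut`; otherwise `unchanged`.
#' The fold criterion is strict and the z criterion inclusive, exactly as
#' the decision rule states. Tier grades `|z|` against the three confidence
#' cutoffs and is reported as `"none"` for unchanged proteins.
#'
#' @param log2_ratio,z numeric vectors (recycled to common length).
#' @param thresholds a [silac_thresholds()].
#' @return data.frame with character columns `direction`
#'   (`up`/`down`/`unchanged`) and `tier` (`none`/`ci95`/`ci99`/`ci999`).
#' @export
classify_regulation <- function(log2_ratio, z,
                                thresholds = silac_thresholds()) {
  stopifnot(inherits(thresholds, "silac_thresholds"))
  n <- max(length(log2_ratio), length(z))
  log2_ratio <- rep_len(log2_ratio, n)
  z <- rep_len(z, n)
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  up <- log2_ratio > thresholds$log2_cut & z >= thresholds$z_cut
  down <- log2_ratio < -thresholds$log2_cut & z <= -thresholds$z_cut
  direction <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  az <- abs(z)
  tier <- ifelse(az >= thresholds$z_tier999, "ci999",
          ifelse(az >= thresholds$z_tier99, "ci99",
          ifelse(az >= thresholds$z_cut, "ci95", "none")))
  tier[direction == "unchanged"] <- "none"
  data.frame(direction = direction, tier = tier, stringsAsFactors = FALSE)
}

#' Score and classify one replicate
#'
#' Convenience wrapper: log2-transform, compute population statistics over
#' the whole filtered replicate, standardize, and classify every protein.
#'
#' @param table a quality-filtered [quant_table].
#' @param thresholds a [silac_thresholds()].
#' @param robust passed to [population_stats()].
#' @return data.frame with columns `accession`, `gene_name`, `ratio`,
#'   `log2_ratio`, `z`, `direction`, `tier`; the `population_stats` used are
#'   attached as attribute `"stats"`.
#' @export
replicate_calls <- function(table, thresholds = silac_thresholds(),
                            robust = FALSE) {
  lt <- log2_ratios(table)
  st <- population_stats(lt$log2_ratio, robust = robust)
  zt <- z_scores(lt, st)
  cls <- classify_regulation(zt$log2_ratio, zt$z, thresholds)
  out <- data.frame(accession = zt$accession,
                    gene_name = zt$gene_name,
                    ratio = table$ratio[match(zt$accession, table$accession)],
                    log2_ratio = zt$log2_ratio,
                    z = zt$z,
                    direction = cls$direction,
                    tier = cls$tier,
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- st
  attr(out, "replicate") <- attr(table, "replicate")
  out
}

tier_levels <- c("none", "ci95", "ci99", "ci999")

#' Combine regulation calls from two biological replicates
#'
#' A protein's final direction is `up` (or `down`) only when it is
#' quantified in both replicates and called `up` (or `down`) in both; any
#' disagreement, including presence in only one replicate or opposite
#' directions, yields `unchanged`. The reported average ratio is the
#' geometric mean of the two replicate ratios (consistent with the log-space
#' analysis); the combined confidence tier is the weaker of the two
#' replicate tiers.
#'
#' @param calls_by_replicate list of exactly two data.frames from
#'   [replicate_calls()].
#' @return data.frame of final calls, one row per protein in the union of
#'   the replicates, with per-replicate ratio/log2/z/direction columns,
#'   final `direction`, `tier`, and `average_ratio` (`NA` for proteins seen
#'   in only one replicate).
#' @export
combine_replicates <- function(calls_by_replicate) {
  if (!is.list(calls_by_replicate) || length(calls_by_replicate) != 2L ||
      inherits(calls_by_replicate, "data.frame")) {
    stop("combine_replicates requires a list of exactly 2 replicate call tables",
         call. = FALSE)
  }
  r1 <- calls_by_replicate[[1L]]
  r2 <- calls_by_replicate[[2L]]
  acc <- union(r1$accession, r2$accession)
  i1 <- match(acc, r1$accession)
  i2 <- match(acc, r2$accession)
  gene <- ifelse(is.na(i1), r2$gene_name[i2], r1$gene_name[i1])
  both <- !is.na(i1) & !is.na(i2)
  dir1 <- r1$direction[i1]
  dir2 <- r2$direction[i2]
  direction <- rep("unchanged", length(acc))
  agree <- both & dir1 == dir2 & dir1 != "unchanged"
  direction[agree] <- dir1[agree]
  t1 <- match(r1$tier[i1], tier_levels)
  t2 <- match(r2$tier[i2], tier_levels)
  tier <- rep("none", length(acc))
  tier[agree] <- tier_levels[pmin(t1, t2)[agree]]
  average_ratio <- rep(NA_real_, length(acc))
  average_ratio[both] <- sqrt(r1$ratio[i1][both] * r2$ratio[i2][both])
  data.frame(accession = acc,
             gene_name = gene,
             ratio_rep1 = r1$ratio[i1],
             log2_rep1 = r1$log2_ratio[i1],
             z_rep1 = r1$z[i1],
             direction_rep1 = dir1,
             ratio_rep2 = r2$ratio[i2],
             log2_rep2 = r2$log2_ratio[i2],
             z_rep2 = r2$z[i2],
             direction_rep2 = dir2,
             direction = direction,
             tier = tier,
             average_ratio = average_ratio,
             stringsAsFactors = FALSE)
}

#' Rank the top regulated proteins
#'
#' For `direction = "up"`: the `n` up-called proteins with the largest
#' average ratio, descending. For `"down"`: the `n` down-called proteins
#' with the smallest average ratio, ascending. Ties are broken by accession
#' in lexicographic order; fewer than `n` available returns all of them.
#'
#' @param calls data.frame from [combine_replicates()].
#' @param direction `"up"` or `"down"`.
#' @param n number of proteins to report (default 10).
#' @return data.frame subset of `calls`, ordered.
#' @export
rank_top <- function(calls, direction = c("up", "down"), n = 10L) {
  direction <- match.arg(direction)
  stopifnot(n >= 1L)
  sub <- calls[calls$direction == direction, , drop = FALSE]
  ord <- order(if (direction == "up") -sub$average_ratio else sub$average_ratio,
               sub$accession)
  out <- sub[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}
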