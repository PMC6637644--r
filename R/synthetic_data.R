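#' Configuration for the synthetic SILAC experiment generator
#'
#' Defaults emulate the scale and structure of a two-replicate SILAC
#' co-culture screen: ~5,500 quantified proteins per comparison, a small
#' fraction of truly regulated proteins (roughly 0.75% up and 1.2% down,
#' matching the ~41/65 calls out of ~5,500 such screens report), an
#' approximately log-normal null ratio distribution centered on ratio 1, a
#' few percent missing values, and contaminant/reverse decoy rows.
#'
#' The noise model: a null protein's per-replicate log2 ratio is drawn from
#' `Normal(0, null_sd_log2)` — this is the spread of the unregulated
#' population. A regulated protein carries a fixed biological effect
#' `delta` (identical in both replicates) observed with independent
#' per-replicate measurement noise `Normal(0, replicate_noise_sd_log2)`.
#' Keeping the effect shared and the noise independent is what makes the
#' two-replicate intersection rule informative.
#'
#' @param n_proteins number of biological proteins per comparison.
#' @param frac_up,frac_down fractions of truly up-/down-regulated proteins;
#'   `frac_up + frac_down < 1`. Counts are `round(n_proteins * frac)`.
#' @param effect_log2_mean,effect_log2_sd true effect magnitudes are
#'   `|Normal(effect_log2_mean, effect_log2_sd)|` (sign by direction).
#' @param null_sd_log2 SD of null-protein log2 ratios (per replicate).
#' @param replicate_noise_sd_log2 SD of per-replicate measurement noise on
#'   regulated proteins.
#' @param missing_rate probability each ratio cell is blanked, independently.
#' @param contaminant_rate,reverse_rate decoy rows appended as fractions of
#'   `n_proteins`; decoys draw ratios from the null distribution so failing
#'   to filter them perturbs the population statistics measurably.
#' @param n_replicates fixed at 2.
#' @param extreme_spikes optionally force this many up-regulated proteins to
#'   an extreme effect `extreme_log2` (e.g. 7.4, i.e. ratio ~170) to stress
#'   SD-inflation robustness.
#' @param extreme_log2 log2 effect used for spiked proteins.
#' @param comparison comparison label for the emitted tables.
#' @param seed RNG seed; identical configurations give identical output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 5500L,
                              frac_up = 0.0075,
                              frac_down = 0.012,
                              effect_log2_mean = 1.5,
                              effect_log2_sd = 0.5,
                              null_sd_log2 = 0.3,
                              replicate_noise_sd_log2 = 0.3,
                              missing_rate = 0.02,
                              contaminant_rate = 0.02,
                              reverse_rate = 0.01,
                              n_replicates = 2L,
                              extreme_spikes = 0L,
                              extreme_log2 = 7.4,
                              comparison = "KG1a H/M",
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), frac_up = frac_up,
              frac_down = frac_down, effect_log2_mean = effect_log2_mean,
              effect_log2_sd = effect_log2_sd, null_sd_log2 = null_sd_log2,
              replicate_noise_sd_log2 = replicate_noise_sd_log2,
              missing_rate = missing_rate,
              contaminant_rate = contaminant_rate,
              reverse_rate = reverse_rate,
              n_replicates = as.integer(n_replicates),
              extreme_spikes = as.integer(extreme_spikes),
              extreme_log2 = extreme_log2,
              comparison = comparison, seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_proteins < 1L) bad <- c(bad, "n_proteins")
  if (cfg$frac_up < 0 || cfg$frac_up >= 1) bad <- c(bad, "frac_up")
  if (cfg$frac_down < 0 || cfg$frac_down >= 1) bad <- c(bad, "frac_down")
  if (cfg$frac_up + cfg$frac_down >= 1) bad <- c(bad, "frac_up+frac_down")
  if (cfg$effect_log2_mean < 0) bad <- c(bad, "effect_log2_mean")
  if (cfg$effect_log2_sd < 0) bad <- c(bad, "effect_log2_sd")
  if (cfg$null_sd_log2 <= 0) bad <- c(bad, "null_sd_log2")
  if (cfg$replicate_noise_sd_log2 < 0) bad <- c(bad, "replicate_noise_sd_log2")
  for (f in c("missing_rate", "contaminant_rate", "reverse_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) bad <- c(bad, f)
  }
  if (cfg$n_replicates != 2L) bad <- c(bad, "n_replicates")
  if (cfg$extreme_spikes < 0L) bad <- c(bad, "extreme_spikes")
  if (length(bad) > 0L) {
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a two-replicate SILAC co-culture experiment
#'
#' Generates protein-group style quantification tables with known ground
#' truth under the model described in [simulation_config()]. Truly regulated
#' proteins receive a fixed log2 effect applied identically in both
#' replicates; every cell may be blanked at `missing_rate`; decoy rows
#' (contaminant and reverse) are appended with flags set.
#'
#' @param config a [simulation_config()].
#' @return list with `tables` (list of two [quant_table]s, `rep1`/`rep2`),
#'   `truth` (data.frame: `accession`, `true_direction` in
#'   `up`/`down`/`null`, `true_log2_effect`), and `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    n <- config$n_proteins
    n_up <- round(n * config$frac_up)
    n_down <- round(n * config$frac_down)
    if (config$extreme_spikes > n_up) {
      stop("extreme_spikes exceeds the number of up-regulated proteins",
           call. = FALSE)
    }
    direction <- c(rep("up", n_up), rep("down", n_down),
                   rep("null", n - n_up - n_down))
    effect <- numeric(n)
    effect[direction == "up"] <-
      abs(stats::rnorm(n_up, config$effect_log2_mean, config$effect_log2_sd))
    effect[direction == "down"] <-
      -abs(stats::rnorm(n_down, config$effect_log2_mean, config$effect_log2_sd))
    if (config$extreme_spikes > 0L) {
      effect[which(direction == "up")[seq_len(config$extreme_spikes)]] <-
        config$extreme_log2
    }
    accession <- sprintf("SYN%05d", seq_len(n))
    gene_name <- sprintf("GENE%05d", seq_len(n))
    truth <- data.frame(accession = accession,
                        true_direction = direction,
                        true_log2_effect = effect,
                        stringsAsFactors = FALSE)
    noise_sd <- ifelse(direction == "null",
                       config$null_sd_log2, config$replicate_noise_sd_log2)
    n_con <- round(n * config$contaminant_rate)
    n_rev <- round(n * config$reverse_rate)
    tables <- lapply(seq_len(config$n_replicates), function(r) {
      log2_obs <- effect + stats::rnorm(n, 0, noise_sd)
      ratio <- 2^log2_obs
      if (config$missing_rate > 0) {
        ratio[stats::runif(n) < config$missing_rate] <- NA_real_
      }
      decoy_ratio <- 2^stats::rnorm(n_con + n_rev, 0, config$null_sd_log2)
      records <- data.frame(
        accession = c(accession,
                      sprintf("CON__SYNC%04d", seq_len(n_con)),
                      sprintf("REV__SYNR%04d", seq_len(n_rev))),
        gene_name = c(gene_name,
                      sprintf("CONG%04d", seq_len(n_con)),
                      sprintf("REVG%04d", seq_len(n_rev))),
        description = c(sprintf("Synthetic protein %d", seq_len(n)),
                        rep("Synthetic contaminant", n_con),
                        rep("Synthetic reverse decoy", n_rev)),
        ratio = c(ratio, decoy_ratio),
        is_contaminant = c(rep(FALSE, n), rep(TRUE, n_con), rep(FALSE, n_rev)),
        is_reverse = c(rep(FALSE, n + n_con), rep(TRUE, n_rev)),
        stringsAsFactors = FALSE)
      quant_table(records, comparison = config$comparison,
                  replicate = paste0("rep", r),
                  provenance = sprintf("simulate_experiment(seed = %d)",
                                       config$seed))
    })
    names(tables) <- paste0("rep", seq_len(config$n_replicates))
    list(tables = tables, truth = truth, config = config)
  })
}

#' Benchmark regulation calls against simulated ground truth
#'
#' Decoy rows are excluded automatically (they carry no truth entry). A call
#' counts as a true positive only when its direction matches the true
#' direction.
#'
#' @param calls data.frame from [combine_replicates()] (needs `accession`
#'   and `direction`).
#' @param truth truth data.frame from [simulate_experiment()].
#' @return list of metrics: `sensitivity` (correct-direction calls among
#'   truly regulated), `specificity` (truly null proteins left uncalled),
#'   `fdp` (truly null among all called; 0 when nothing is called),
#'   `direction_accuracy` (correct direction among truly regulated proteins
#'   that were called at all), and the underlying counts.
#' @export
evaluate_calls <- function(calls, truth) {
  m <- merge(calls[c("accession", "direction")],
             truth, by = "accession")
  if (nrow(m) == 0L) {
    stop("no accession overlap between calls and truth", call. = FALSE)
  }
  called <- m$direction != "unchanged"
  regulated <- m$true_direction != "null"
  correct <- called & regulated & m$direction == m$true_direction
  n_called <- sum(called)
  sensitivity <- if (sum(regulated) == 0L) NA_real_
    else sum(correct) / sum(regulated)
  specificity <- if (sum(!regulated) == 0L) NA_real_
    else sum(!called & !regulated) / sum(!regulated)
  fdp <- if (n_called == 0L) 0 else sum(called & !regulated) / n_called
  called_regulated <- called & regulated
  direction_accuracy <- if (sum(called_regulated) == 0L) NA_real_
    else sum(correct) / sum(called_regulated)
  list(sensitivity = sensitivity, specificity = specificity, fdp = fdp,
       direction_accuracy = direction_accuracy,
       n_called = n_called, n_regulated = sum(regulated),
       n_null = sum(!regulated), n_evaluated = nrow(m))
}
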