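#!/usr/bin/env Rscript
# Gene-set over-representation on the combined calls: construct synthetic
# "pathways" from the simulation ground truth (two sets seeded with truly
# regulated proteins, several background sets), write them as GMT, and test
# the called protein lists against the quantified-protein universe with the
# one-sided hypergeometric test and BH FDR control.

suppressPackageStartupMessages(library(silacdiff))

stopifnot(dir.exists("results/kg1a"))  # run analysis/02 first

for (nm in c("kg1a", "hs5")) {
  calls <- read.delim(file.path("results", nm, "calls.tsv"))
  truth <- read.delim(file.path("results/sim", sprintf("%s_truth.tsv", nm)))
  up <- truth$accession[truth$true_direction == "up"]
  down <- truth$accession[truth$true_direction == "down"]
  null <- truth$accession[truth$true_direction == "null"]

  set.seed(7)
  sets <- list(
    "induced pathway" = c(sample(up, min(12, length(up))), sample(null, 8)),
    "suppressed pathway" = c(sample(down, min(15, length(down))), sample(null, 10)))
  for (i in 1:6) {
    sets[[sprintf("background set %d", i)]] <- sample(null, 40)
  }
  gmt <- file.path("results", nm, "sets.gmt")
  writeLines(vapply(names(sets), function(s)
    paste(c(s, "synthetic set", sets[[s]]), collapse = "\t"), character(1)),
    gmt)
  gsc <- read_gmt(gmt)

  universe <- calls$accession[!is.na(calls$average_ratio)]
  hits <- calls$accession[calls$direction != "unchanged"]
  enr <- fisher_enrichment(hits, universe, gsc)
  enr <- direction_summary(enr, calls, gsc, id_column = "accession")
  enr$significant <- enr$q_value < 0.05
  write_table(enr, file.path("results", nm, "enrichment.tsv"))

  sig <- enr[enr$significant, ]
  cat(sprintf("%s: %d/%d sets significant at FDR < 0.05\n",
              nm, nrow(sig), nrow(enr)))
  for (i in seq_len(nrow(sig))) {
    cat(sprintf("  %-20s overlap %d/%d, q = %.2e, direction %s\n",
                sig$set_name[i], sig$overlap[i], sig$set_size_in_universe[i],
                sig$q_value[i], sig$direction_label[i]))
  }
}
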