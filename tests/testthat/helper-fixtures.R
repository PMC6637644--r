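# Shared fixture builders: everything is constructed in code at test time.

make_records <- function(ratios, accession = sprintf("P%03d", seq_along(ratios)),
                         contaminant = FALSE, reverse = FALSE) {
  data.frame(accession = accession,
             gene_name = sprintf("G%03d", seq_along(ratios)),
             description = sprintf("protein %d", seq_along(ratios)),
             ratio = ratios,
             is_contaminant = rep_len(contaminant, length(ratios)),
             is_reverse = rep_len(reverse, length(ratios)),
             stringsAsFactors = FALSE)
}

make_table <- function(ratios, comparison = "KG1a H/M", replicate = "rep1",
                       ...) {
  quant_table(make_records(ratios, ...), comparison = comparison,
              replicate = replicate)
}

# Minimal MaxQuant-style proteinGroups file writer.
write_pg_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste("Majority protein IDs", "Gene names", "Protein names",
                  "Ratio H/M normalized", "Potential contaminant", "Reverse",
                  sep = "\t")
  writeLines(c(header, rows), path)
  path
}

# Replicate-call rows for combine_replicates tests.
make_calls <- function(accession, ratio, direction, tier = "ci95",
                       z = ifelse(direction == "up", 3,
                                  ifelse(direction == "down", -3, 0))) {
  data.frame(accession = accession,
             gene_name = paste0("G_", accession),
             ratio = ratio,
             log2_ratio = log2(ratio),
             z = z,
             direction = direction,
             tier = ifelse(direction == "unchanged", "none", tier),
             stringsAsFactors = FALSE)
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "silacdiff", mustWork = TRUE)
}
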