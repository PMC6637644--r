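#' Construct a protein quantification table
#'
#' A `quant_table` holds one comparison's protein-level SILAC ratio
#' measurements for a single biological replicate: one row per protein group,
#' with the heavy-over-light (H/L) or heavy-over-medium (H/M) ratio, gene
#' annotation, and the contaminant/reverse-decoy flags carried over from the
#' upstream search-engine output.
#'
#' @param records data.frame with columns `accession`, `gene_name`,
#'   `description`, `ratio`, `is_contaminant`, `is_reverse`. `ratio` may be
#'   `NA` (not quantified) but any present value must be finite and positive.
#' @param comparison label of the comparison, e.g. `"KG1a H/M"` or
#'   `"HS5 H/L"`.
#' @param replicate replicate identifier (e.g. `"rep1"`).
#' @param channel_scheme `"heavy_over_medium"` or `"heavy_over_light"`. If
#'   `NULL`, inferred from `comparison` (a label containing `"H/M"` maps to
#'   heavy-over-medium, `"H/L"` to heavy-over-light).
#' @param provenance free-text origin note kept as metadata.
#'
#' @return A `quant_table`: a data.frame with attributes `comparison`,
#'   `replicate`, `channel_scheme`, `provenance`.
#' @export
quant_table <- function(records, comparison, replicate,
                        channel_scheme = NULL, provenance = "") {
  required <- c("accession", "gene_name", "description", "ratio",
                "is_contaminant", "is_reverse")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("quant_table records lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  records$accession <- as.character(records$accession)
  if (any(!nzchar(records$accession)) || anyNA(records$accession)) {
    stop("every accession must be a non-empty string", call. = FALSE)
  }
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0L) {
    stop("duplicate accession(s) in table: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  present <- !is.na(records$ratio)
  if (any(present & (!is.finite(records$ratio) | records$ratio <= 0))) {
    stop("present ratios must be finite and > 0", call. = FALSE)
  }
  if (is.null(channel_scheme)) channel_scheme <- infer_channel_scheme(comparison)
  channel_scheme <- match.arg(channel_scheme,
                              c("heavy_over_medium", "heavy_over_light"))
  check_channel_scheme(comparison, channel_scheme)
  structure(records,
            comparison = comparison,
            replicate = replicate,
            channel_scheme = channel_scheme,
            provenance = provenance,
            class = c("quant_table", "data.frame"))
}

infer_channel_scheme <- function(comparison) {
  if (grepl("H/M", comparison, fixed = TRUE)) return("heavy_over_medium")
  if (grepl("H/L", comparison, fixed = TRUE)) return("heavy_over_light")
  stop("cannot infer channel scheme from comparison label ",
       sQuote(comparison), "; pass channel_scheme explicitly", call. = FALSE)
}

check_channel_scheme <- function(comparison, channel_scheme) {
  other <- switch(channel_scheme,
                  heavy_over_medium = "H/L",
                  heavy_over_light = "H/M")
  if (grepl(other, comparison, fixed = TRUE)) {
    stop("channel_scheme ", sQuote(channel_scheme),
         " is inconsistent with comparison label ", sQuote(comparison),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %s, replicate %s (%s), %d proteins\n",
              attr(x, "comparison"), attr(x, "replicate"),
              attr(x, "channel_scheme"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Default MaxQuant-style column mapping
#'
#' Column headers follow MaxQuant 1.5-era proteinGroups conventions. The
#' ratio column is picked by channel scheme; `use_normalized = FALSE`
#' switches to the raw (un-normalized) ratio columns.
#'
#' @param use_normalized use `"Ratio H/x normalized"` columns (default) or
#'   the raw `"Ratio H/x"` columns.
#' @return Named character vector mapping logical fields to column headers.
#' @export
default_column_map <- function(use_normalized = TRUE) {
  c(accession = "Majority protein IDs",
    gene_name = "Gene names",
    description = "Protein names",
    ratio_hm = if (use_normalized) "Ratio H/M normalized" else "Ratio H/M",
    ratio_hl = if (use_normalized) "Ratio H/L normalized" else "Ratio H/L",
    contaminant = "Potential contaminant",
    reverse = "Reverse")
}

#' Read a protein-groups quantification table
#'
#' Parses a tab-separated protein-group table (MaxQuant proteinGroups
#' dialect) into a [quant_table] for one comparison/replicate. Unparsable or
#' non-positive ratio cells become missing values; rows are never dropped
#' here (see [filter_quality()]). For multi-accession cells such as
#' `"P1;P2"` the first accession is the canonical key and the full string is
#' retained in the description. Contaminant/reverse flags are considered set
#' for any non-empty cell other than `"0"` (MaxQuant marks them `"+"`).
#'
#' @param path path to a tab-separated file with a header row.
#' @param comparison comparison label, e.g. `"KG1a H/M"`.
#' @param replicate replicate identifier.
#' @param column_map named vector overriding [default_column_map()] entries.
#' @param channel_scheme see [quant_table()]; inferred from `comparison` when
#'   `NULL`.
#'
#' @return A [quant_table], row order as in the file.
#' @export
read_protein_groups <- function(path, comparison, replicate,
                                column_map = default_column_map(),
                                channel_scheme = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  if (is.null(channel_scheme)) channel_scheme <- infer_channel_scheme(comparison)
  ratio_field <- switch(channel_scheme,
                        heavy_over_medium = "ratio_hm",
                        heavy_over_light = "ratio_hl")
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, quote = "")
  needed <- map[c("accession", "gene_name", "description", ratio_field,
                  "contaminant", "reverse")]
  absent <- needed[!needed %in% names(raw)]
  if (length(absent) > 0L) {
    stop("mapped column(s) not present in ", path, ": ",
         paste(sQuote(absent), collapse = ", "), call. = FALSE)
  }
  full_acc <- raw[[map[["accession"]]]]
  accession <- vapply(strsplit(full_acc, ";", fixed = TRUE),
                      function(x) x[1L], character(1L))
  description <- raw[[map[["description"]]]]
  multi <- grepl(";", full_acc, fixed = TRUE)
  description[multi] <- paste0(description[multi],
                               " [protein IDs: ", full_acc[multi], "]")
  ratio <- suppressWarnings(as.numeric(raw[[needed[[ratio_field]]]]))
  ratio[!is.finite(ratio) | ratio <= 0] <- NA_real_
  flag_set <- function(x) nzchar(trimws(x)) & trimws(x) != "0"
  records <- data.frame(accession = accession,
                        gene_name = raw[[map[["gene_name"]]]],
                        description = description,
                        ratio = ratio,
                        is_contaminant = flag_set(raw[[map[["contaminant"]]]]),
                        is_reverse = flag_set(raw[[map[["reverse"]]]]),
                        stringsAsFactors = FALSE)
  quant_table(records, comparison = comparison, replicate = replicate,
              channel_scheme = channel_scheme,
              provenance = paste0("read_protein_groups: ", path))
}

#' Remove decoy, contaminant, and unquantified entries
#'
#' Drops records flagged as contaminant or reverse decoy, and records whose
#' ratio for this table's comparison/replicate is missing. These entries
#' exist for search-engine FDR control and must not enter the population
#' statistics. Removal counts are reported via [message()].
#'
#' @param table a [quant_table].
#' @return A [quant_table] containing only quantified biological proteins.
#' @export
filter_quality <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  n0 <- nrow(table)
  flagged <- table$is_contaminant | table$is_reverse
  unquantified <- is.na(table$ratio)
  keep <- !flagged & !unquantified
  message(sprintf(
    "filter_quality [%s %s]: %d records in; removed %d contaminant, %d reverse, %d unquantified; %d retained",
    attr(table, "comparison"), attr(table, "replicate"), n0,
    sum(table$is_contaminant), sum(table$is_reverse & !table$is_contaminant),
    sum(unquantified & !flagged), sum(keep)))
  if (!any(keep)) {
    stop("no quantifiable proteins remain after quality filtering",
         call. = FALSE)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("comparison", "replicate", "channel_scheme",
                    "provenance")] <-
    attributes(table)[c("comparison", "replicate", "channel_scheme",
                        "provenance")]
  class(out) <- c("quant_table", "data.frame")
  out
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are collapsed.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   member vectors) and `universe` (optional explicit background, `NULL`
#'   here).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields",
                   i), call. = FALSE)
    }
    nms[[i]] <- fields[[1L]]
    members <- unique(fields[-(1:2)])
    sets[[i]] <- members[nzchar(members)]
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set names in GMT file: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("GMT file contains an empty set", call. = FALSE)
  }
  names(sets) <- nms
  gene_set_collection(sets)
}

#' Build a gene-set collection
#'
#' @param sets named list of character vectors (set members); names unique,
#'   every set non-empty.
#' @param universe optional explicit background identifier vector.
#' @return A `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets))) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("every set must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(x) unique(as.character(x)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a quant_table in the protein-groups dialect
#'
#' Emits the same MaxQuant-style tab-separated dialect that
#' [read_protein_groups()] consumes, so simulated experiments round-trip
#' through the file interface. The ratio lands in the column matching the
#' table's channel scheme; flags are written as `"+"`.
#'
#' @param table a [quant_table].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_protein_groups <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  map <- default_column_map()
  ratio_col <- switch(attr(table, "channel_scheme"),
                      heavy_over_medium = map[["ratio_hm"]],
                      heavy_over_light = map[["ratio_hl"]])
  out <- data.frame(a = table$accession,
                    b = table$gene_name,
                    c = table$description,
                    d = table$ratio,
                    e = ifelse(table$is_contaminant, "+", ""),
                    f = ifelse(table$is_reverse, "+", ""),
                    stringsAsFactors = FALSE)
  names(out) <- c(map[["accession"]], map[["gene_name"]],
                  map[["description"]], ratio_col,
                  map[["contaminant"]], map[["reverse"]])
  write_table(out, path)
}

#' Write a result table as tab-separated text
#'
#' Numeric columns are rendered with `%.17g` so that writing and re-reading
#' preserves values exactly; column order is the data.frame order; missing
#' values are written as empty cells.
#'
#' @param records a data.frame (a [quant_table] works too).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write table to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
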