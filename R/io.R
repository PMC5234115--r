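#' Read an OTU table from TSV
#'
#' On-disk dialect: tab-separated, header row `otu_id` followed by sample
#' ids, one row per OTU, optional trailing `taxonomy` column with a
#' semicolon-delimited ranked lineage. The in-memory object is transposed to
#' sample-major orientation.
#'
#' @param path file path.
#' @param mode `"counts"` or `"relative"`; entries are validated accordingly.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  if (!length(lines)) stop("empty OTU table file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "otu_id")
    stop("OTU table must start with an 'otu_id' header column")
  has_tax <- header[length(header)] == "taxonomy"
  sample_cols <- header[-c(1, if (has_tax) length(header))]
  if (!length(sample_cols)) stop("OTU table has no sample columns")
  n_field <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_field)) {
    bad <- which(widths != n_field)[1]
    stop(sprintf("ragged row %d (OTU '%s'): expected %d fields, found %d",
                 bad + 1L, body[[bad]][1], n_field, widths[bad]))
  }
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  val_cols <- seq(2L, length.out = length(sample_cols))
  vals <- vapply(body, function(f) as.numeric(f[val_cols]),
                 numeric(length(sample_cols)))
  vals <- matrix(vals, nrow = length(sample_cols),
                 dimnames = list(sample_cols, ids))
  if (anyNA(vals)) {
    bad <- ids[apply(is.na(t(vals)), 1, any)][1]
    stop("non-numeric abundance in row for OTU '", bad, "'")
  }
  if (any(vals < 0)) {
    bad <- ids[apply(t(vals) < 0, 1, any)][1]
    stop("negative abundance in row for OTU '", bad, "'")
  }
  taxonomy <- NULL
  if (has_tax)
    taxonomy <- setNames(vapply(body, `[`, character(1), n_field), ids)
  otu_table(vals, mode = mode, taxonomy = taxonomy)
}

#' Write an OTU table to TSV
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  v <- t(table$values)  # OTUs in rows on disk
  df <- data.frame(otu_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy))
    df$taxonomy <- unname(table$taxonomy[rownames(v)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample metadata TSV
#'
#' Columns: `sample_id`, `type`, `residence`, `site`, `individual`, `season`.
#' Empty strings are read as `NA`.
#'
#' @param path file path.
#' @return a validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  meta$residence <- as.character(meta$residence)
  meta$site <- as.character(meta$site)
  meta$individual <- as.character(meta$individual)
  sample_metadata(meta)
}

#' @param meta a metadata data.frame.
#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a generated study to a directory
#'
#' Writes `otu_table.tsv` (OTUs in rows, taxonomy column), `metadata.tsv`,
#' `tree.nwk` (newick) and, when ground truth is present, `truth.json`
#' (OTU classes, owners, per-surface-sample mixing proportions and the
#' deposition/loss schedules) as a machine-readable sidecar.
#'
#' @param study the list returned by [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(study$table, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(study$meta, file.path(dir, "metadata.tsv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  if (!is.null(study$truth)) {
    tr <- study$truth
    sidecar <- list(
      otu_class = as.list(tr$otu_class),
      otu_owner = as.list(tr$otu_owner),
      mixing = tr$mixing,
      deposition_schedule = tr$deposition_schedule,
      loss_schedule = tr$loss_schedule)
    jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
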