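#' Construct an OTU table
#'
#' An `otu_table` holds a samples-by-OTUs abundance matrix together with its
#' mode (`"counts"` or `"relative"`) and optional taxonomy annotations.
#' In memory the orientation is sample-major (rows are samples); on disk the
#' conventional amplicon orientation (rows are OTUs) is used, see
#' [write_otu_table()].
#'
#' @param values numeric matrix, samples in rows, OTUs in columns; both
#'   dimnames must be set and unique.
#' @param mode `"counts"` (non-negative integers) or `"relative"` (each row
#'   sums to 1 or is all zero).
#' @param taxonomy optional named character vector mapping OTU ids to
#'   semicolon-delimited ranked lineages
#'   (e.g. `"k__Bacteria;...;f__Moraxellaceae;g__Acinetobacter"`).
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(values, mode = c("counts", "relative"), taxonomy = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(values < 0)) {
    bad <- rownames(values)[apply(values < 0, 1, any)]
    stop("negative abundances in sample(s): ", paste(bad, collapse = ", "))
  }
  if (mode == "counts" && any(abs(values - round(values)) > 1e-9))
    stop("mode 'counts' requires integer entries")
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- abs(rs - 1) > 1e-9 & rs > 0
    if (any(bad))
      stop("relative-mode rows must sum to 1 (or be all zero); offending sample(s): ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("'taxonomy' must be a named character vector (names = OTU ids)")
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(values))]
  }
  structure(list(values = values, mode = mode, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (%s%s)\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

sample_ids <- function(table) rownames(table$values)
otu_ids <- function(table) colnames(table$values)

#' Convert counts to relative abundances
#'
#' Each sample (row) is divided by its total; all-zero samples stay zero.
#'
#' @param table an [otu_table()].
#' @return an `otu_table` in `"relative"` mode.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$mode == "relative") return(table)
  v <- table$values
  tot <- rowSums(v)
  tot[tot == 0] <- 1
  otu_table(v / tot, mode = "relative", taxonomy = table$taxonomy)
}

#' Subset an OTU table
#'
#' @param table an [otu_table()].
#' @param samples,otus character vectors of ids to keep (default all).
#' @return an `otu_table` restricted to the requested ids, order preserved.
#' @export
subset_table <- function(table, samples = NULL, otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  v <- table$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing))
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(otus)) {
    missing <- setdiff(otus, colnames(v))
    if (length(missing))
      stop("unknown OTU id(s): ", paste(missing, collapse = ", "))
    v <- v[, otus, drop = FALSE]
  }
  tab <- table
  tab$values <- v
  if (!is.null(tab$taxonomy))
    tab$taxonomy <- tab$taxonomy[intersect(names(tab$taxonomy), colnames(v))]
  tab
}

#' Extract the family rank from taxonomy annotations
#'
#' Lineages use the common `k__...;p__...;...;f__Family;g__...` convention;
#' the `f__` entry is returned without its prefix, `NA` when absent or empty.
#'
#' @param table an [otu_table()] with taxonomy.
#' @return named character vector, OTU id -> family (or `NA`).
#' @export
otu_families <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy)) stop("table has no taxonomy annotations")
  vapply(table$taxonomy, function(lin) {
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    fam <- parts[startsWith(parts, "f__")]
    if (!length(fam)) return(NA_character_)
    fam <- sub("^f__", "", fam[1])
    if (!nzchar(fam)) NA_character_ else fam
  }, character(1))
}

#' Validate sample metadata
#'
#' Metadata is a plain data frame with columns `sample_id`, `type`
#' (`skin`, `surface`, `air` or `control`), `residence`, `site`,
#' `individual` (skin samples only) and `season` (ordinal, 1 = winter;
#' absent/NA for controls).
#'
#' @param meta a data.frame.
#' @return the validated data.frame (invisibly classed for provenance).
#' @export
sample_metadata <- function(meta) {
  required <- c("sample_id", "type", "residence", "site", "individual", "season")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  bad_type <- setdiff(unique(meta$type), c("skin", "surface", "air", "control"))
  if (length(bad_type))
    stop("unknown sample type(s): ", paste(bad_type, collapse = ", "))
  skin <- meta$type == "skin"
  if (any(skin & (is.na(meta$individual) | !nzchar(meta$individual))))
    stop("skin samples must carry an individual label")
  if (any(!skin & meta$type != "control" & !is.na(meta$individual)))
    stop("only skin samples may carry an individual label")
  noncontrol <- meta$type != "control"
  if (any(noncontrol & is.na(meta$season)))
    stop("season required for all non-control samples")
  meta$season <- as.integer(meta$season)
  meta
}

meta_for <- function(meta, ids) meta[match(ids, meta$sample_id), , drop = FALSE]
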