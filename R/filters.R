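#' Flag likely kit-control contaminants
#'
#' An OTU is designated a likely contaminant when it reaches at least
#' `threshold` relative abundance in at least one kit-control sample
#' (boundary inclusive). Controls with zero reads contribute nothing.
#'
#' @param table an [otu_table()] in counts mode.
#' @param control_ids sample ids of the kit controls (non-empty, all present
#'   in the table).
#' @param threshold relative-abundance cutoff in (0, 1]; default 0.05.
#' @return character vector of flagged OTU ids (possibly empty).
#' @export
flag_contaminants <- function(table, control_ids, threshold = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  if (table$mode != "counts") stop("contaminant rule applies to count tables")
  if (!length(control_ids)) stop("cannot apply contaminant rule: no control samples")
  missing <- setdiff(control_ids, sample_ids(table))
  if (length(missing))
    stop("control sample(s) not in table: ", paste(missing, collapse = ", "))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  ctrl <- table$values[control_ids, , drop = FALSE]
  tot <- rowSums(ctrl)
  keep <- tot > 0
  if (!any(keep)) return(character(0))
  rel <- ctrl[keep, , drop = FALSE] / tot[keep]
  colnames(ctrl)[apply(rel >= threshold, 2, any)]
}

#' Rarefy a count table to even depth
#'
#' Each sample's reads are subsampled uniformly without replacement to a
#' common depth. The default depth is the total of the most depauperate
#' sample, so no sample is dropped; with an explicit depth, samples below it
#' are dropped with a warning naming them.
#'
#' @param table an [otu_table()] in counts mode.
#' @param depth target reads per sample (>= 1); default `min(rowSums)`.
#' @param seed optional integer; when given the subsampling is reproducible
#'   and the caller's RNG state is left untouched.
#' @return a rarefied counts `otu_table`; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (table$mode != "counts") stop("rarefaction applies to count tables")
  totals <- rowSums(table$values)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) stop("'depth' must be at least 1")
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(sample_ids(table)[drop], collapse = ", "))
  }
  v <- table$values[!drop, , drop = FALSE]
  do_sub <- function() {
    out <- v
    resample <- rowSums(v) > depth
    if (any(resample))
      out[resample, ] <- withCallingHandlers(
        vegan::rrarefy(v[resample, , drop = FALSE], depth),
        # vegan warns whenever the smallest count exceeds 1; these are
        # genuine integer counts, so the heuristic does not apply
        warning = function(w) {
          if (grepl("observed counts", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    out
  }
  out <- if (is.null(seed)) do_sub() else withr::with_seed(seed, do_sub())
  otu_table(out, mode = "counts", taxonomy = table$taxonomy)
}

#' Drop low-prevalence OTUs
#'
#' Keeps OTUs present (abundance > 0) in at least `min_fraction` of the
#' table's samples; OTUs present in fewer are excluded. With the default
#' 0.10 this is the "present in < 10% of samples are excluded" rule applied
#' per matching input table.
#'
#' @param table an [otu_table()].
#' @param min_fraction prevalence cutoff in \[0, 1\]; default 0.10.
#' @return the filtered `otu_table` (sample set unchanged).
#' @export
prevalence_filter <- function(table, min_fraction = 0.10) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must be in [0, 1]")
  prev <- colMeans(table$values > 0)
  subset_table(table, otus = otu_ids(table)[prev >= min_fraction])
}

#' Per-sample abundance share of indicator families by source
#'
#' Given lists of bacterial families indicative of candidate household
#' sources (human skin, oral cavity, leaf, stool, soil, ...), sums the
#' relative abundance of OTUs whose family belongs to each list. Overlapping
#' lists are counted independently; OTUs without a family annotation never
#' match.
#'
#' @param table an [otu_table()] with taxonomy.
#' @param family_lists named list, source -> character vector of family
#'   names (may be empty).
#' @return numeric matrix samples x sources of relative-abundance sums.
#' @export
family_source_composition <- function(table, family_lists) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$taxonomy)) stop("table has no taxonomy; cannot map families")
  if (!is.list(family_lists) || is.null(names(family_lists)))
    stop("'family_lists' must be a named list of family-name vectors")
  fam <- otu_families(table)
  rel <- relative_abundance(table)$values
  out <- matrix(0, nrow(rel), length(family_lists),
                dimnames = list(rownames(rel), names(family_lists)))
  for (src in names(family_lists)) {
    hit <- names(fam)[!is.na(fam) & fam %in% family_lists[[src]]]
    hit <- intersect(hit, colnames(rel))
    if (length(hit))
      out[, src] <- rowSums(rel[, hit, drop = FALSE])
  }
  out
}
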