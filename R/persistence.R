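## Persistence contexts: skin OTUs live on (individual, body site),
## surface OTUs on (residence, surface site).
context_key <- function(meta) {
  ifelse(meta$type == "skin",
         paste("skin", meta$individual, meta$site, sep = "|"),
         paste("surface", meta$residence, meta$site, sep = "|"))
}

#' Season of first observation per (context, OTU)
#'
#' Maps every OTU in every skin or surface context to the first season in
#' which it was observed (count > 0) there. OTUs never observed in a
#' context do not appear.
#'
#' @param table rarefied counts [otu_table()].
#' @param meta sample metadata with ordered seasons.
#' @return data.frame with `context` (composite key `kind|key1|key2`),
#'   `otu`, `first_season`; also a `seasons_observed` column with the number
#'   of distinct seasons the OTU was seen in that context.
#' @export
first_observation_map <- function(table, meta) {
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[meta$sample_id %in% sample_ids(table) &
                 meta$type %in% c("skin", "surface"), , drop = FALSE]
  meta$context <- context_key(meta)
  out <- list()
  for (ctx in unique(meta$context)) {
    rows <- meta[meta$context == ctx, , drop = FALSE]
    seasons <- sort(unique(rows$season))
    pres <- vapply(seasons, function(s) {
      ids <- rows$sample_id[rows$season == s]
      colSums(table$values[ids, , drop = FALSE] > 0) > 0
    }, logical(ncol(table$values)))
    pres <- matrix(pres, ncol = length(seasons),
                   dimnames = list(otu_ids(table), seasons))
    seen <- rowSums(pres) > 0
    if (!any(seen)) next
    first <- seasons[apply(pres[seen, , drop = FALSE], 1, which.max)]
    out[[ctx]] <- data.frame(context = ctx, otu = otu_ids(table)[seen],
                             first_season = first,
                             seasons_observed = rowSums(pres[seen, , drop = FALSE]),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample composition by season of first observation
#'
#' For each skin or surface sample, the fraction of its OTUs (`richness`
#' weighting) or of its reads (`abundance` weighting) attributable to OTUs
#' first observed in each season of the sample's context. Fractions sum to
#' 1 for non-empty samples, and no mass can be attributed to a season after
#' the sample's own.
#'
#' @inheritParams first_observation_map
#' @param weighting `"richness"` or `"abundance"`.
#' @param fmap optional precomputed [first_observation_map()].
#' @return data.frame `sample_id`, `type`, `season`, `origin_season`,
#'   `fraction`.
#' @export
seasonal_origin_fractions <- function(table, meta,
                                      weighting = c("abundance", "richness"),
                                      fmap = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(fmap)) fmap <- first_observation_map(table, meta)
  meta <- meta[meta$sample_id %in% sample_ids(table) &
                 meta$type %in% c("skin", "surface"), , drop = FALSE]
  meta$context <- context_key(meta)
  out <- list()
  for (k in seq_len(nrow(meta))) {
    id <- meta$sample_id[k]
    v <- table$values[id, ]
    present <- names(v)[v > 0]
    if (!length(present)) next
    fm <- fmap[fmap$context == meta$context[k], , drop = FALSE]
    origin <- setNames(fm$first_season, fm$otu)[present]
    w <- if (weighting == "abundance") v[present] else rep(1, length(present))
    frac <- tapply(w, origin, sum) / sum(w)
    out[[id]] <- data.frame(sample_id = id, type = meta$type[k],
                            season = meta$season[k],
                            origin_season = as.integer(names(frac)),
                            fraction = as.numeric(frac),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative-abundance share of persistent OTUs per sample
#'
#' An OTU is persistent in a context when it was observed there in at least
#' `min_seasons` distinct seasons (gaps allowed). Returns, per sample, the
#' share of reads carried by persistent OTUs.
#'
#' @inheritParams seasonal_origin_fractions
#' @param min_seasons minimum number of distinct seasons (e.g. 2 for
#'   "persisted for more than one season").
#' @return data.frame `sample_id`, `type`, `season`, `share` in \[0, 1\].
#' @export
persistence_share <- function(table, meta, min_seasons = 2, fmap = NULL) {
  if (is.null(fmap)) fmap <- first_observation_map(table, meta)
  meta <- meta[meta$sample_id %in% sample_ids(table) &
                 meta$type %in% c("skin", "surface"), , drop = FALSE]
  meta$context <- context_key(meta)
  share <- numeric(nrow(meta))
  for (k in seq_len(nrow(meta))) {
    v <- table$values[meta$sample_id[k], ]
    present <- names(v)[v > 0]
    if (!length(present)) { share[k] <- NA_real_; next }
    fm <- fmap[fmap$context == meta$context[k], , drop = FALSE]
    pers <- fm$otu[fm$seasons_observed >= min_seasons]
    share[k] <- sum(v[intersect(present, pers)]) / sum(v[present])
  }
  data.frame(sample_id = meta$sample_id, type = meta$type,
             season = meta$season, share = share, stringsAsFactors = FALSE)
}
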