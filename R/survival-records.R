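## Covariate binning -------------------------------------------------------

## Abundance percentile bins among the OTUs present in one context-season:
## 0-69th, 70-89th, 90-98th and 99th percentile of the within-sample
## relative-abundance ranks (percentile = 100 * rank / n, ties by mid-rank).
abundance_bins <- function(relab) {
  pct <- 100 * rank(relab, ties.method = "average") / length(relab)
  cut_bin <- ifelse(pct >= 99, "p99",
                    ifelse(pct >= 90, "p90_98",
                           ifelse(pct >= 70, "p70_89", "p0_69")))
  setNames(cut_bin, names(relab))
}

## IndVal value bins: [0,0.2), [0.2,0.6), [0.6,0.9), [0.9,1].
indval_bin <- function(v) {
  ifelse(v >= 0.9, "v09_1",
         ifelse(v >= 0.6, "v06_09",
                ifelse(v >= 0.2, "v02_06", "v0_02")))
}

ABUND_LEVELS <- c("p0_69", "p70_89", "p90_98", "p99")
INDVAL_LEVELS <- c("v0_02", "v02_06", "v06_09", "v09_1")

#' Precompute per-season covariate annotations for the survival models
#'
#' Computes, for every season: masked indicator values per (OTU,
#' individual) via [indval()], and per-individual per-site hitting sets via
#' [cohort_hitting_sets()]. These feed the abundance/IndVal/hitting-set
#' covariates of [build_loss_records()] and [build_deposition_records()].
#'
#' @param table rarefied counts [otu_table()].
#' @param meta sample metadata.
#' @param n_perm permutations for IndVal significance.
#' @param seed optional integer seed.
#' @param detect_threshold,demotion_factor hitting-set parameters.
#' @return list with `indval` (per season: matrix individuals x OTUs of
#'   masked values) and `hitting_sets` (per season: named list from
#'   [cohort_hitting_sets()] with site scope).
#' @export
survival_annotations <- function(table, meta, n_perm = 199, seed = NULL,
                                 detect_threshold = 1e-3, demotion_factor = 2) {
  seasons <- sort(unique(meta$season[meta$type == "skin"]))
  iv <- list(); hs <- list()
  for (s in seasons) {
    entries <- indval(table, meta, s, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + s)
    inds <- sort(unique(entries$individual))
    m <- matrix(0, length(inds), length(unique(entries$otu)),
                dimnames = list(inds, unique(entries$otu)))
    m[cbind(match(entries$individual, rownames(m)),
            match(entries$otu, colnames(m)))] <- entries$masked
    iv[[as.character(s)]] <- m
    hs[[as.character(s)]] <- cohort_hitting_sets(table, meta, s, scope = "site",
                                                 detect_threshold, demotion_factor)
  }
  list(indval = iv, hitting_sets = hs)
}

lookup_indval <- function(ann, season, individual, otus) {
  m <- ann$indval[[as.character(season)]]
  out <- setNames(numeric(length(otus)), otus)
  if (is.null(m) || !individual %in% rownames(m)) return(out)
  common <- intersect(otus, colnames(m))
  out[common] <- m[individual, common]
  out
}

hs_members <- function(ann, season, individual, site = NULL) {
  sets <- ann$hitting_sets[[as.character(season)]]
  if (is.null(sets)) return(character(0))
  keys <- if (is.null(site)) {
    names(sets)[startsWith(names(sets), paste0(individual, "|"))]
  } else paste(individual, site, sep = "|")
  unique(unlist(lapply(sets[intersect(keys, names(sets))], `[[`, "otus")))
}

## Shared interval expansion: subject observed first in season f, event (or
## censoring) closing the record at season `end_season`; intervals are the
## season transitions (s, s+1] for s in f..end_season-1.
interval_seq <- function(first, end_season) {
  if (end_season <= first) return(NULL)
  data.frame(start = first:(end_season - 1), stop = (first + 1):end_season)
}

#' Counting-format records of OTU loss
#'
#' One subject per (OTU, context): body site of an individual for
#' `kind = "skin"`, surface site of a residence for `kind = "surface"`.
#' The observation period starts in the season of first observation and
#' ends either on the transition out of the last observed season (loss
#' event) or in the final season (right-censoring). Interim absent seasons
#' are not loss events and take the lowest abundance bin. Subjects first
#' observed in the final season have no transition and contribute no
#' record.
#'
#' Surface mode includes only OTUs also found in at least one skin sample
#' of an occupant of the modelled residence (any season); its IndVal
#' covariate is the maximum masked value among occupants and hitting-set
#' membership means membership in any occupant's hitting set. Hitting-set
#' membership is fixed at the subject's first-observed season.
#'
#' @param table rarefied counts [otu_table()].
#' @param meta sample metadata with ordered seasons.
#' @param kind `"skin"` or `"surface"`.
#' @param annotations from [survival_annotations()].
#' @param loss_at `"first_absence"` (default: the loss interval is the
#'   transition out of the last observed season) or `"last_observed"` (the
#'   record ends with the last observed season, so single-season subjects
#'   contribute no interval).
#' @return data.frame with `subject`, `otu`, context columns, `start`,
#'   `stop`, `abund_bin`, `indval_bin`, `indval`, `hs_member`, `event`.
#' @export
build_loss_records <- function(table, meta, kind = c("skin", "surface"),
                               annotations,
                               loss_at = c("first_absence", "last_observed")) {
  kind <- match.arg(kind)
  loss_at <- match.arg(loss_at)
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  sub <- meta[meta$type == kind, , drop = FALSE]
  if (is.unsorted(sort(unique(sub$season)))) stop("unordered seasons")
  S <- max(meta$season[meta$type %in% c("skin", "surface")], na.rm = TRUE)
  rel <- relative_abundance(table)$values
  out <- list()

  contexts <- if (kind == "skin") unique(sub[, c("individual", "site")])
              else unique(sub[, c("residence", "site")])
  for (ci in seq_len(nrow(contexts))) {
    if (kind == "skin") {
      ind <- contexts$individual[ci]; site <- contexts$site[ci]
      rows <- sub[sub$individual == ind & sub$site == site, , drop = FALSE]
      res <- rows$residence[1]
      occupants <- ind
    } else {
      res <- contexts$residence[ci]; site <- contexts$site[ci]
      rows <- sub[sub$residence == res & sub$site == site, , drop = FALSE]
      occupants <- unique(meta$individual[meta$type == "skin" &
                                            meta$residence == res])
      occupants <- occupants[!is.na(occupants)]
    }
    rows <- rows[order(rows$season), , drop = FALSE]
    seasons <- rows$season
    pres <- table$values[rows$sample_id, , drop = FALSE] > 0
    seen <- colSums(pres) > 0
    otus <- colnames(pres)[seen]
    if (kind == "surface") {
      skin_ids <- meta$sample_id[meta$type == "skin" & meta$residence == res]
      on_skin <- colSums(table$values[skin_ids, , drop = FALSE] > 0) > 0
      otus <- otus[on_skin[otus]]
    }
    if (!length(otus)) next

    ## per-season abundance bins among present OTUs (within this context)
    season_bins <- list(); season_rel <- list()
    for (k in seq_along(seasons)) {
      v <- colMeans(rel[rows$sample_id[rows$season == seasons[k]], ,
                        drop = FALSE])
      pv <- v[v > 0]
      season_bins[[as.character(seasons[k])]] <-
        if (length(pv)) abundance_bins(pv) else character(0)
    }

    pres_otus <- pres[, otus, drop = FALSE]
    first <- seasons[apply(pres_otus, 2, which.max)]
    last <- seasons[nrow(pres_otus) + 1 - apply(pres_otus[rev(seq_len(nrow(pres_otus))), ,
                                                          drop = FALSE], 2, which.max)]
    for (j in seq_along(otus)) {
      o <- otus[j]
      f <- first[j]; L <- last[j]
      censored <- L >= S
      end_season <- if (censored) S
                    else if (loss_at == "first_absence") L + 1 else L
      iv <- interval_seq(f, end_season)
      if (is.null(iv)) next
      n_int <- nrow(iv)
      ab <- vapply(iv$start, function(s) {
        b <- season_bins[[as.character(s)]]
        if (o %in% names(b)) b[[o]] else "p0_69"
      }, character(1))
      ivals <- vapply(iv$start, function(s) {
        vals <- vapply(occupants, function(i)
          lookup_indval(annotations, s, i, o), numeric(1))
        if (length(vals)) max(vals) else 0
      }, numeric(1))
      member <- any(vapply(occupants, function(i)
        o %in% hs_members(annotations, f, i,
                          site = if (kind == "skin") site else NULL),
        logical(1)))
      ctx_cols <- if (kind == "skin")
        data.frame(individual = ind, site = site, residence = res)
      else data.frame(individual = NA_character_, site = site, residence = res)
      out[[length(out) + 1L]] <- cbind(
        data.frame(subject = paste(kind, res, site,
                                   if (kind == "skin") ind else "", o, sep = "|"),
                   otu = o, stringsAsFactors = FALSE),
        ctx_cols[rep(1, n_int), , drop = FALSE],
        iv,
        data.frame(abund_bin = ab, indval_bin = indval_bin(ivals),
                   indval = ivals, hs_member = member,
                   event = c(rep(0L, n_int - 1), as.integer(!censored)),
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(out)) stop("no survival records could be constructed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$abund_bin <- factor(res$abund_bin, levels = ABUND_LEVELS)
  res$indval_bin <- factor(res$indval_bin, levels = INDVAL_LEVELS)
  res
}

#' Counting-format records of skin-to-surface deposition
#'
#' Subjects are (OTU, individual body site) skin observations; the event is
#' the first observation of the OTU on any surface of the individual's
#' residence in the same or a later season than its first skin observation.
#' Same-season depositions are recorded on the subject's first interval.
#' OTUs present on a surface of the residence before their first skin
#' observation are excluded; subjects never deposited are censored in the
#' final season. Covariates are as in the skin loss model.
#'
#' @inheritParams build_loss_records
#' @return data.frame as in [build_loss_records()].
#' @export
build_deposition_records <- function(table, meta, annotations) {
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  skin <- meta[meta$type == "skin", , drop = FALSE]
  S <- max(meta$season[meta$type %in% c("skin", "surface")], na.rm = TRUE)
  rel <- relative_abundance(table)$values
  out <- list()

  ## per (residence, season): surface presence of each OTU
  surf <- meta[meta$type == "surface", , drop = FALSE]
  surf_pres <- list()
  for (r in unique(surf$residence)) for (s in unique(surf$season[surf$residence == r])) {
    ids <- surf$sample_id[surf$residence == r & surf$season == s]
    surf_pres[[paste(r, s)]] <- colSums(table$values[ids, , drop = FALSE] > 0) > 0
  }
  surf_first <- function(r, o) {
    ss <- sort(unique(surf$season[surf$residence == r]))
    for (s in ss) {
      p <- surf_pres[[paste(r, s)]]
      if (!is.null(p) && isTRUE(p[[o]])) return(s)
    }
    NA_integer_
  }

  contexts <- unique(skin[, c("individual", "site")])
  for (ci in seq_len(nrow(contexts))) {
    ind <- contexts$individual[ci]; site <- contexts$site[ci]
    rows <- skin[skin$individual == ind & skin$site == site, , drop = FALSE]
    rows <- rows[order(rows$season), , drop = FALSE]
    res <- rows$residence[1]
    seasons <- rows$season
    pres <- table$values[rows$sample_id, , drop = FALSE] > 0
    otus <- colnames(pres)[colSums(pres) > 0]
    if (!length(otus)) next
    season_bins <- list()
    for (k in seq_along(seasons)) {
      v <- colMeans(rel[rows$sample_id[rows$season == seasons[k]], , drop = FALSE])
      pv <- v[v > 0]
      season_bins[[as.character(seasons[k])]] <-
        if (length(pv)) abundance_bins(pv) else character(0)
    }
    pres_otus <- pres[, otus, drop = FALSE]
    first <- seasons[apply(pres_otus, 2, which.max)]
    for (j in seq_along(otus)) {
      o <- otus[j]; f <- first[j]
      d <- surf_first(res, o)
      if (!is.na(d) && d < f) next          # surface before skin: excluded
      deposited <- !is.na(d)
      if (deposited && d == f) {
        if (f >= S) next                    # no transition available
        iv <- interval_seq(f, f + 1)
        events <- 1L
      } else if (deposited) {
        iv <- interval_seq(f, d)
        events <- c(rep(0L, nrow(iv) - 1), 1L)
      } else {
        iv <- interval_seq(f, S)
        if (is.null(iv)) next
        events <- rep(0L, nrow(iv))
      }
      ab <- vapply(iv$start, function(s) {
        b <- season_bins[[as.character(s)]]
        if (o %in% names(b)) b[[o]] else "p0_69"
      }, character(1))
      ivals <- vapply(iv$start, function(s)
        lookup_indval(annotations, s, ind, o), numeric(1))
      member <- o %in% hs_members(annotations, f, ind, site = site)
      out[[length(out) + 1L]] <- data.frame(
        subject = paste("deposition", res, site, ind, o, sep = "|"),
        otu = o, individual = ind, site = site, residence = res,
        start = iv$start, stop = iv$stop,
        abund_bin = ab, indval_bin = indval_bin(ivals), indval = ivals,
        hs_member = member, event = events, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no survival records could be constructed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$abund_bin <- factor(res$abund_bin, levels = ABUND_LEVELS)
  res$indval_bin <- factor(res$indval_bin, levels = INDVAL_LEVELS)
  res
}
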