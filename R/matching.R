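#' Build per (residence, season) matching input tables
#'
#' One input table per pairwise combination of target residence and source
#' season: sinks are the surface samples of the target residence from all
#' seasons; sources are the skin samples of every residence in the source
#' season, grouped into candidate environments (one per residence occupant
#' group by default, or one per individual). Low-prevalence OTUs are
#' excluded within each input table.
#'
#' @param table rarefied, contaminant-filtered counts [otu_table()].
#' @param meta sample metadata.
#' @param group_by `"residence"` (occupant group per residence) or
#'   `"individual"`.
#' @param min_prevalence per-input-table prevalence cutoff (default 0.10).
#' @return list of inputs, each a list with `residence`, `season`, `table`
#'   (the filtered sub-table), `sink_ids`, and `sources` (named list,
#'   environment -> skin sample ids). Residences without surface samples
#'   are skipped with a warning.
#' @export
build_matching_inputs <- function(table, meta, group_by = c("residence", "individual"),
                                  min_prevalence = 0.10) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  residences <- sort(unique(meta$residence[meta$type == "surface"]))
  skipped <- setdiff(unique(meta$residence[!is.na(meta$residence)]), residences)
  if (length(skipped))
    warning("residence(s) without surface samples skipped: ",
            paste(skipped, collapse = ", "))
  seasons <- sort(unique(meta$season[meta$type == "skin"]))
  inputs <- list()
  for (r in residences) for (s in seasons) {
    sink_ids <- meta$sample_id[meta$type == "surface" & meta$residence == r]
    skin <- meta[meta$type == "skin" & meta$season == s, , drop = FALSE]
    if (!nrow(skin)) next
    env <- if (group_by == "residence") skin$residence else skin$individual
    sources <- split(skin$sample_id, env)
    sub <- subset_table(table, samples = c(sink_ids, skin$sample_id))
    sub <- prevalence_filter(sub, min_prevalence)
    inputs[[length(inputs) + 1L]] <-
      list(residence = r, season = s, table = sub,
           sink_ids = sink_ids, sources = sources)
  }
  inputs
}

#' Score matches from estimated source proportions
#'
#' A sink is an accurate match when the source contribution of its true
#' environment is strictly greater than that of every other candidate
#' environment; the Unknown source never wins, and exact ties are scored
#' incorrect.
#'
#' @param props numeric matrix sinks x environments (an `Unknown` column is
#'   ignored for the argmax).
#' @param truth named character vector, sink id -> true environment.
#' @return data.frame with `sink_id`, `predicted`, `correct`.
#' @export
score_matches <- function(props, truth) {
  envs <- setdiff(colnames(props), "Unknown")
  if (length(envs) < 2) stop("need at least 2 candidate environments")
  p <- props[, envs, drop = FALSE]
  if (any(rowSums(p) == 0))
    stop("all-zero candidate proportions for sink(s): ",
         paste(rownames(p)[rowSums(p) == 0], collapse = ", "))
  pred <- envs[apply(p, 1, which.max)]
  correct <- vapply(seq_len(nrow(p)), function(i) {
    tr <- truth[[rownames(p)[i]]]
    if (!tr %in% envs) return(FALSE)
    p[i, tr] > max(p[i, setdiff(envs, tr)])
  }, logical(1))
  data.frame(sink_id = rownames(p), predicted = pred, correct = correct,
             stringsAsFactors = FALSE)
}

## Score a single sink's proportions; a sink whose known-source proportions
## are all zero (everything assigned to Unknown) has no strictly greatest
## environment and counts as an incorrect match rather than an error.
score_one <- function(proportions, true_env) {
  envs <- setdiff(names(proportions), "Unknown")
  p <- proportions[envs]
  if (all(p == 0))
    return(list(predicted = NA_character_, correct = FALSE))
  pred <- envs[which.max(p)]
  correct <- true_env %in% envs &&
    p[[true_env]] > max(p[setdiff(envs, true_env)])
  list(predicted = pred, correct = correct)
}

#' Run the full delay-resolved matching experiment
#'
#' For every (residence, season) input table from
#' [build_matching_inputs()], apportions each surface sink over the pooled
#' candidate skin environments and scores the match. The sampling delay of
#' a result is `sink season - source season`, an integer between -(S-1) and
#' S-1; positive delays mean the surface was sampled after the skin.
#'
#' @inheritParams build_matching_inputs
#' @param params sampler settings, see [st_params()].
#' @param seed optional integer; per-sink seeds are derived from it.
#' @return data.frame of match results: `sink_id`, `sink_residence`,
#'   `sink_season`, `source_season`, `delay`, `predicted`, `correct`.
#' @export
run_matching <- function(table, meta, params = st_params(), seed = NULL,
                         group_by = c("residence", "individual"),
                         min_prevalence = 0.10) {
  group_by <- match.arg(group_by)
  inputs <- build_matching_inputs(table, meta, group_by, min_prevalence)
  res <- list()
  counter <- 0L
  for (inp in inputs) {
    v <- inp$table$values
    sources <- lapply(inp$sources, function(ids)
      colSums(v[ids, , drop = FALSE]))
    smeta <- meta_for(meta, inp$sink_ids)
    for (k in seq_along(inp$sink_ids)) {
      sid <- inp$sink_ids[k]
      counter <- counter + 1L
      est <- gibbs_apportion(v[sid, ], sources, params,
                             seed = if (is.null(seed)) NULL else seed + counter,
                             sink_id = sid)
      sc <- score_one(est$proportions, inp$residence)
      res[[counter]] <- data.frame(
        sink_id = sid, sink_residence = inp$residence,
        sink_season = smeta$season[k], source_season = inp$season,
        delay = smeta$season[k] - inp$season,
        predicted = sc$predicted, correct = sc$correct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Accuracy rate by sampling delay
#'
#' @param results match results from [run_matching()].
#' @return data.frame `delay`, `n`, `accuracy` (fraction of sinks with an
#'   accurate match at that delay); delays with no results are omitted.
#' @export
accuracy_by_delay <- function(results) {
  if (!nrow(results)) stop("no match results")
  agg <- aggregate(correct ~ delay, data = results,
                   FUN = function(x) c(n = length(x), acc = mean(x)))
  data.frame(delay = agg$delay, n = as.integer(agg$correct[, "n"]),
             accuracy = agg$correct[, "acc"])
}

#' Candidate-subset-size matching experiment
#'
#' Repeats same-season (delay 0) matching against random subsets of
#' candidate environments of the given sizes, always including the correct
#' match. Accuracy per size is averaged over sinks and repeats.
#'
#' @inheritParams run_matching
#' @param sizes candidate-pool sizes (each >= 2, at most the number of
#'   candidate groups).
#' @param n_repeats random subsets drawn per size.
#' @param seed integer seed for subset draws and sampler chains.
#' @return data.frame `size`, `n` (scored sinks x repeats), `accuracy`.
#' @export
subset_size_experiment <- function(table, meta, sizes = c(2, 4, 6, 8),
                                   n_repeats = 50, seed = 1L,
                                   params = st_params(),
                                   group_by = c("residence", "individual"),
                                   min_prevalence = 0.10) {
  group_by <- match.arg(group_by)
  if (any(sizes < 2)) stop("subset sizes must be at least 2")
  inputs <- build_matching_inputs(table, meta, group_by, min_prevalence)
  ## delay-0 sinks only: surface season equals the input's source season
  n_groups <- length(unique(unlist(lapply(inputs, function(i) names(i$sources)))))
  if (any(sizes > n_groups))
    stop("subset size exceeds the number of candidate groups (", n_groups, ")")
  draws <- list()
  counter <- 0L
  withr::with_seed(seed, {
    for (k in sizes) {
      hits <- logical(0)
      for (rep in seq_len(n_repeats)) {
        for (inp in inputs) {
          smeta <- meta_for(meta, inp$sink_ids)
          d0 <- inp$sink_ids[smeta$season == inp$season]
          if (!length(d0)) next
          envs <- names(inp$sources)
          correct_env <- inp$residence
          if (!correct_env %in% envs) next
          cand <- c(correct_env,
                    sample(setdiff(envs, correct_env), k - 1))
          v <- inp$table$values
          sources <- lapply(inp$sources[cand], function(ids)
            colSums(v[ids, , drop = FALSE]))
          for (sid in d0) {
            counter <- counter + 1L
            est <- gibbs_apportion(v[sid, ], sources, params, sink_id = sid)
            hits <- c(hits, score_one(est$proportions, correct_env)$correct)
          }
        }
      }
      draws[[as.character(k)]] <- hits
    }
  })
  data.frame(size = sizes,
             n = vapply(draws, length, integer(1)),
             accuracy = vapply(draws, mean, numeric(1)))
}
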