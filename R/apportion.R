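#' Sampler settings for source apportionment
#'
#' Defaults follow the v1.0 defaults of the community-standard Bayesian
#' source-tracking tool: Dirichlet smoothing `alpha1 = 0.001` on known
#' sources, `alpha2 = 0.1` on the Unknown source, assignment prior
#' `beta = 10`, 10 independent restarts, 100 burn-in sweeps and one retained
#' draw per restart.
#'
#' @param alpha1,alpha2,beta Dirichlet/assignment smoothing parameters.
#' @param restarts independent chains averaged into the estimate.
#' @param burnin full Gibbs sweeps discarded before the first draw.
#' @param ndraws retained draws per restart.
#' @param delay sweeps between consecutive retained draws.
#' @return a list of sampler settings.
#' @export
st_params <- function(alpha1 = 0.001, alpha2 = 0.1, beta = 10,
                      restarts = 10, burnin = 100, ndraws = 1, delay = 10) {
  stopifnot(alpha1 > 0, alpha2 > 0, beta > 0, restarts >= 1,
            burnin >= 0, ndraws >= 1, delay >= 1)
  list(alpha1 = alpha1, alpha2 = alpha2, beta = beta, restarts = restarts,
       burnin = burnin, ndraws = ndraws, delay = delay)
}

#' Bayesian source apportionment of one sink sample
#'
#' Collapsed Gibbs sampling over per-read latent source labels: each sink
#' read is assigned to one of the known source environments or to a latent
#' Unknown source; known-source read likelihoods come from the pooled
#' (summed) source count vectors with Dirichlet smoothing, the Unknown
#' source learns its composition from the reads currently assigned to it.
#' The estimate is the posterior-mean occupancy fraction per source,
#' averaged over retained draws and restarts.
#'
#' @param sink named count vector over OTUs (at least one read).
#' @param sources named list of pooled count vectors (one per source
#'   environment), or a matrix with environments in rows; names/rownames
#'   are the environment labels. Zero-total sources are excluded with a
#'   warning.
#' @param params see [st_params()].
#' @param seed optional integer seed (restores the caller's RNG state).
#' @param sink_id optional label stored in the result.
#' @return a `source_estimate`: list with `sink_id`, `proportions` (named,
#'   includes `Unknown`, sums to 1) and `draws` (matrix of per-draw raw
#'   proportions).
#' @export
gibbs_apportion <- function(sink, sources, params = st_params(), seed = NULL,
                            sink_id = NULL) {
  if (is.matrix(sources)) {
    if (is.null(rownames(sources))) stop("source matrix needs rownames")
    sources <- setNames(lapply(seq_len(nrow(sources)),
                               function(i) sources[i, ]), rownames(sources))
  }
  if (!length(sources)) stop("at least one source environment required")
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("sources must be named")
  if (sum(sink) <= 0) stop("sink has zero reads")

  ## canonical (sorted) source order: the estimate is then exactly
  ## invariant to permutations of the input order under a fixed seed
  sources <- sources[order(names(sources))]
  totals <- vapply(sources, sum, numeric(1))
  if (any(totals <= 0)) {
    warning("excluding zero-total source(s): ",
            paste(names(sources)[totals <= 0], collapse = ", "))
    sources <- sources[totals > 0]
    if (!length(sources)) stop("no non-empty source environments remain")
  }

  otus <- Reduce(union, c(list(names(sink)), lapply(sources, names)))
  if (is.null(otus)) {  # unnamed vectors: positional alignment
    len <- unique(c(length(sink), lengths(sources)))
    if (length(len) != 1) stop("unnamed sink/sources must have equal length")
    otus <- paste0("t", seq_len(len))
    names(sink) <- otus
    sources <- lapply(sources, function(s) setNames(s, otus))
  }
  svec <- setNames(numeric(length(otus)), otus)
  svec[names(sink)] <- sink
  smat <- matrix(0, length(sources), length(otus),
                 dimnames = list(names(sources), otus))
  for (v in names(sources)) smat[v, names(sources[[v]])] <- sources[[v]]

  run <- function() gibbs_sink_cpp(as.integer(round(svec)), smat,
                                   params$alpha1, params$alpha2, params$beta,
                                   params$restarts, params$burnin,
                                   params$ndraws, params$delay)
  draws <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(draws) <- c(names(sources), "Unknown")
  props <- colMeans(draws)
  props <- props / sum(props)
  structure(list(sink_id = sink_id, proportions = props, draws = draws),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("source_estimate", if (!is.null(x$sink_id)) paste0("for ", x$sink_id),
      "\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Surface source decomposition for one season
#'
#' For every surface sample of the given season, estimates the mixing
#' proportions over three pooled source environments: occupant skin of the
#' same residence and season, household air of the same residence and
#' season, and the kit-control samples (a negative control), plus the
#' latent Unknown source.
#'
#' @param table a rarefied, contaminant-filtered counts [otu_table()].
#' @param meta sample metadata.
#' @param season target season (integer).
#' @param params see [st_params()].
#' @param seed optional integer; per-sink seeds are derived from it.
#' @return named list of [gibbs_apportion()] results, one per surface
#'   sample, with environments `skin`, `air`, `control`, `Unknown`.
#' @export
surface_source_decomposition <- function(table, meta, season,
                                         params = st_params(), seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[meta$sample_id %in% sample_ids(table), , drop = FALSE]
  surf <- meta[meta$type == "surface" & meta$season == season, , drop = FALSE]
  if (!nrow(surf)) stop("no surface samples in season ", season)
  ctrl_ids <- meta$sample_id[meta$type == "control"]
  if (!length(ctrl_ids)) stop("missing source class: control")
  pool <- function(ids) colSums(table$values[ids, , drop = FALSE])
  out <- list()
  for (k in seq_len(nrow(surf))) {
    r <- surf$residence[k]
    skin_ids <- meta$sample_id[meta$type == "skin" & meta$season == season &
                                 meta$residence == r]
    air_ids <- meta$sample_id[meta$type == "air" & meta$season == season &
                                meta$residence == r]
    if (!length(skin_ids))
      stop("missing source class: skin (residence ", r, ", season ", season, ")")
    if (!length(air_ids))
      stop("missing source class: air (residence ", r, ", season ", season, ")")
    sid <- surf$sample_id[k]
    sources <- list(skin = pool(skin_ids), air = pool(air_ids),
                    control = pool(ctrl_ids))
    out[[sid]] <- gibbs_apportion(table$values[sid, ], sources, params,
                                  seed = if (is.null(seed)) NULL else seed + k,
                                  sink_id = sid)
  }
  out
}

#' Collect source estimates into a matrix
#'
#' @param estimates list of `source_estimate` objects.
#' @return numeric matrix sinks x environments of mixing proportions.
#' @export
proportions_matrix <- function(estimates) {
  stopifnot(length(estimates) > 0)
  envs <- names(estimates[[1]]$proportions)
  t(vapply(estimates, function(e) e$proportions[envs], numeric(length(envs))))
}
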