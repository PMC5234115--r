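#' Indicator values of OTUs for individuals
#'
#' For each OTU o and individual i within one season's skin samples:
#' specificity is the mean relative abundance of o across i's body-site
#' samples divided by the sum of those means over all individuals; fidelity
#' is the fraction of i's site samples containing o; the indicator value is
#' their product. Significance is assessed by permuting individual labels
#' over site samples; p-values use the add-one estimator `(b + 1)/(B + 1)`,
#' and `masked` is the indicator value where `p < 0.05`, else 0.
#'
#' @param table counts or relative [otu_table()].
#' @param meta sample metadata; the season must hold skin samples for at
#'   least 2 individuals, each with at least one site sample.
#' @param season target season.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @return data.frame with `otu`, `individual`, `specificity`, `fidelity`,
#'   `indval`, `p`, `masked`.
#' @export
indval <- function(table, meta, season, n_perm = 999, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  skin <- meta[meta$type == "skin" & meta$season == season &
                 meta$sample_id %in% sample_ids(table), , drop = FALSE]
  inds <- sort(unique(skin$individual))
  if (length(inds) < 2) stop("need skin samples for at least 2 individuals")
  rel <- relative_abundance(subset_table(table, samples = skin$sample_id))$values
  labels <- factor(skin$individual, levels = inds)

  compute <- function(lab) {
    G <- t(vapply(inds, function(i) as.numeric(lab == i), numeric(nrow(rel))))
    G <- G / rowSums(G)                     # individuals x samples, row-mean weights
    A <- G %*% rel                          # mean relab per individual
    colsum <- colSums(A)
    spec <- sweep(A, 2, ifelse(colsum > 0, colsum, 1), "/")
    Fg <- G %*% (rel > 0)                   # fidelity (row-mean of presence)
    list(spec = spec, fid = Fg, iv = spec * Fg)
  }
  obs <- compute(labels)

  run_perms <- function() {
    cnt <- matrix(0, length(inds), ncol(rel))
    for (b in seq_len(n_perm)) {
      perm <- compute(sample(labels))
      cnt <- cnt + (perm$iv >= obs$iv - 1e-12)
    }
    cnt
  }
  cnt <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
  p <- (cnt + 1) / (n_perm + 1)

  data.frame(otu = rep(colnames(rel), each = length(inds)),
             individual = rep(inds, ncol(rel)),
             specificity = as.vector(obs$spec),
             fidelity = as.vector(obs$fid),
             indval = as.vector(obs$iv),
             p = as.vector(p),
             masked = as.vector(obs$iv * (p < 0.05)),
             stringsAsFactors = FALSE)
}

#' Greedy minimal hitting set for one individual
#'
#' Builds an ordered OTU set whose joint presence distinguishes the target
#' individual from every other (confounder) profile. An OTU is a candidate
#' when the target carries it at relative abundance >= `detect_threshold`;
#' it resolves a confounder whose abundance is below
#' `detect_threshold / demotion_factor`. Greedily adds the candidate
#' resolving the most unresolved confounders, breaking ties by higher
#' target abundance and then lexicographic OTU id.
#'
#' @param profiles numeric matrix individuals x OTUs of relative abundances
#'   (rownames = individuals).
#' @param target rowname of the individual to identify.
#' @param detect_threshold presence cutoff (default 1e-3).
#' @param demotion_factor absence margin divisor (default 2).
#' @return a `hitting_set`: list with `individual`, `otus` (ordered),
#'   `status` (`complete`, `partial` or `failed`).
#' @export
build_hitting_set <- function(profiles, target, detect_threshold = 1e-3,
                              demotion_factor = 2) {
  if (!target %in% rownames(profiles)) stop("target '", target, "' not in profiles")
  others <- setdiff(rownames(profiles), target)
  if (!length(others)) stop("need at least 2 individuals")
  tp <- profiles[target, ]
  candidates <- colnames(profiles)[tp >= detect_threshold]
  absent_cut <- detect_threshold / demotion_factor
  resolves <- matrix(profiles[others, candidates, drop = FALSE] < absent_cut,
                     nrow = length(others),
                     dimnames = list(others, candidates))
  unresolved <- others
  chosen <- character(0)
  while (length(unresolved)) {
    gains <- colSums(resolves[unresolved, , drop = FALSE])
    gains <- gains[setdiff(names(gains), chosen)]
    if (!length(gains) || max(gains) == 0) break
    best <- names(gains)[gains == max(gains)]
    if (length(best) > 1) {
      ab <- tp[best]
      best <- best[ab == max(ab)]
      best <- sort(best)[1]
    }
    chosen <- c(chosen, best)
    unresolved <- unresolved[!resolves[unresolved, best]]
  }
  status <- if (!length(unresolved)) "complete"
            else if (length(chosen)) "partial" else "failed"
  structure(list(individual = target, otus = chosen, status = status),
            class = "hitting_set")
}

#' @export
print.hitting_set <- function(x, ...) {
  cat(sprintf("hitting_set for %s [%s]: %s\n", x$individual, x$status,
              if (length(x$otus)) paste(x$otus, collapse = ", ") else "<empty>"))
  invisible(x)
}

#' Hitting sets for a cohort of individuals
#'
#' Convenience wrapper building one hitting set per individual from one
#' season's skin samples, either per body site (each individual's profile
#' is that site's sample) or pooled across sites (mean relative abundance).
#'
#' @inheritParams indval
#' @param scope `"pooled"` (one set per individual) or `"site"` (one per
#'   individual and body site).
#' @param detect_threshold,demotion_factor see [build_hitting_set()].
#' @return named list of `hitting_set` objects (names `individual` or
#'   `individual|site`).
#' @export
cohort_hitting_sets <- function(table, meta, season,
                                scope = c("pooled", "site"),
                                detect_threshold = 1e-3, demotion_factor = 2) {
  scope <- match.arg(scope)
  skin <- meta[meta$type == "skin" & meta$season == season &
                 meta$sample_id %in% sample_ids(table), , drop = FALSE]
  if (!nrow(skin)) stop("no skin samples in season ", season)
  rel <- relative_abundance(subset_table(table, samples = skin$sample_id))$values
  out <- list()
  if (scope == "pooled") {
    prof <- individual_profiles(rel, skin$individual)
    for (i in rownames(prof))
      out[[i]] <- build_hitting_set(prof, i, detect_threshold, demotion_factor)
    for (i in names(out)) { out[[i]]$season <- season; out[[i]]$scope <- "pooled" }
  } else {
    for (b in unique(skin$site)) {
      sub <- skin[skin$site == b, , drop = FALSE]
      prof <- rel[sub$sample_id, , drop = FALSE]
      rownames(prof) <- sub$individual
      for (i in rownames(prof)) {
        key <- paste(i, b, sep = "|")
        out[[key]] <- build_hitting_set(prof, i, detect_threshold, demotion_factor)
        out[[key]]$season <- season; out[[key]]$scope <- b
      }
    }
  }
  out
}

individual_profiles <- function(rel, individuals) {
  inds <- sort(unique(individuals))
  t(vapply(inds, function(i)
    colMeans(rel[individuals == i, , drop = FALSE]), numeric(ncol(rel))))
}

#' Re-identify individuals from previously built hitting sets
#'
#' A hitting set matches a profile when every member OTU is present at
#' relative abundance >= `detect_threshold`. For each complete set:
#' true positive when it matches its owner, false negative when it fails
#' the owner, and the false-positive count is the number of non-owners
#' matched.
#'
#' @param sets list of `hitting_set` objects (incomplete sets are skipped).
#' @param profiles numeric matrix individuals x OTUs of relative abundances
#'   for the target season.
#' @param detect_threshold presence cutoff, as at build time.
#' @return data.frame `individual`, `true_positive`, `false_negative`,
#'   `false_positives`.
#' @export
reidentify <- function(sets, profiles, detect_threshold = 1e-3) {
  sets <- Filter(function(s) s$status == "complete", sets)
  if (!length(sets)) stop("no complete hitting sets to evaluate")
  rows <- lapply(sets, function(s) {
    otus <- intersect(s$otus, colnames(profiles))
    hit <- if (length(otus) < length(s$otus)) rep(FALSE, nrow(profiles))
           else rowSums(profiles[, otus, drop = FALSE] >= detect_threshold) ==
             length(otus)
    names(hit) <- rownames(profiles)
    owner_hit <- isTRUE(hit[[s$individual]])
    data.frame(individual = s$individual,
               true_positive = owner_hit,
               false_negative = !owner_hit,
               false_positives = sum(hit[setdiff(names(hit), s$individual)]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
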