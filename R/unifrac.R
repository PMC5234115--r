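## Branch bookkeeping: for each edge of the rooted tree, which tips lie in
## the subtree below it. Computed once per tree by a postorder sweep and
## reused for every pairwise distance.
branch_structure <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  nn <- max(tree$edge)
  desc <- matrix(FALSE, nn, nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  list(incidence = desc[tree$edge[, 2], , drop = FALSE],  # edges x tips
       lengths = tree$edge.length,
       tips = tree$tip.label)
}

align_to_tips <- function(x, tips, label) {
  if (is.null(names(x))) {
    if (length(x) != length(tips))
      stop("unnamed ", label, " vector must match the number of tree leaves")
    return(setNames(as.numeric(x), tips))
  }
  extra <- setdiff(names(x)[x > 0], tips)
  if (length(extra))
    stop("OTU(s) absent from tree: ", paste(head(extra, 5), collapse = ", "))
  out <- setNames(numeric(length(tips)), tips)
  common <- intersect(names(x), tips)
  out[common] <- x[common]
  out
}

#' Unweighted UniFrac distance between two samples
#'
#' Fraction of total branch length leading exclusively to leaves present in
#' one of the two samples: `sum(l_b * |1A - 1B|) / sum(l_b * 1(A or B))`,
#' where a branch "carries" a sample when its subtree contains a leaf with
#' positive abundance.
#'
#' @param a,b abundance (or presence) vectors named by tree leaves, each
#'   with at least one positive entry.
#' @param tree rooted `phylo` with branch lengths.
#' @return distance in \[0, 1\].
#' @export
unweighted_unifrac <- function(a, b, tree) {
  bs <- branch_structure(tree)
  pa <- align_to_tips(a, bs$tips, "sample") > 0
  pb <- align_to_tips(b, bs$tips, "sample") > 0
  if (!any(pa) || !any(pb)) stop("both samples must contain at least one OTU")
  under_a <- bs$incidence %*% pa > 0
  under_b <- bs$incidence %*% pb > 0
  num <- sum(bs$lengths * (under_a != under_b))
  den <- sum(bs$lengths * (under_a | under_b))
  num / den
}

#' Weighted UniFrac distance between two samples
#'
#' `sum(l_b * |pA(b) - pB(b)|)` where `pX(b)` is the fraction of sample X's
#' reads at leaves below branch b. The raw (non-normalised) form is the
#' default; with `normalized = TRUE` the sum is divided by
#' `sum(l_b * (pA(b) + pB(b)))`, making the result invariant to uniform
#' branch-length scaling.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized logical flag.
#' @return non-negative distance (in \[0, 1\] when normalised).
#' @export
weighted_unifrac <- function(a, b, tree, normalized = FALSE) {
  bs <- branch_structure(tree)
  va <- align_to_tips(a, bs$tips, "sample")
  vb <- align_to_tips(b, bs$tips, "sample")
  if (sum(va) <= 0 || sum(vb) <= 0)
    stop("both samples must contain at least one read")
  pa <- drop(bs$incidence %*% (va / sum(va)))
  pb <- drop(bs$incidence %*% (vb / sum(vb)))
  d <- sum(bs$lengths * abs(pa - pb))
  if (normalized) d <- d / sum(bs$lengths * (pa + pb))
  d
}

#' All-pairs UniFrac distance matrix
#'
#' @param table an [otu_table()]; all its OTUs must be leaves of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param method `"weighted"` or `"unweighted"`.
#' @param normalized for the weighted variant only.
#' @return symmetric distance matrix with zero diagonal, dimnames = sample
#'   ids.
#' @export
unifrac <- function(table, tree, method = c("weighted", "unweighted"),
                    normalized = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(table, "otu_table"))
  bs <- branch_structure(tree)
  extra <- setdiff(otu_ids(table), bs$tips)
  if (length(extra))
    stop("OTU(s) absent from tree: ", paste(head(extra, 5), collapse = ", "))
  v <- matrix(0, nrow(table$values), length(bs$tips),
              dimnames = list(sample_ids(table), bs$tips))
  v[, otu_ids(table)] <- table$values
  n <- nrow(v)
  if (method == "weighted") {
    tot <- rowSums(v); tot[tot == 0] <- 1
    bp <- (v / tot) %*% t(bs$incidence)       # samples x edges
    dm <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
    for (i in seq_len(n - 1)) {
      diffs <- abs(bp[(i + 1):n, , drop = FALSE] -
                     rep(1, n - i) %o% bp[i, ])
      d <- diffs %*% bs$lengths
      if (normalized) {
        sums <- (bp[(i + 1):n, , drop = FALSE] +
                   rep(1, n - i) %o% bp[i, ]) %*% bs$lengths
        d <- d / sums
      }
      dm[i, (i + 1):n] <- d
      dm[(i + 1):n, i] <- d
    }
  } else {
    bp <- (v > 0) %*% t(bs$incidence) > 0     # samples x edges, logical
    mode(bp) <- "numeric"
    dm <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
    for (i in seq_len(n - 1)) {
      other <- bp[(i + 1):n, , drop = FALSE]
      this <- rep(1, n - i) %o% bp[i, ]
      num <- abs(other - this) %*% bs$lengths
      den <- pmax(other, this) %*% bs$lengths
      d <- ifelse(den > 0, num / den, 0)
      dm[i, (i + 1):n] <- d
      dm[(i + 1):n, i] <- d
    }
  }
  dm
}

#' Skin-surface distance profile by sampling delay
#'
#' Sampling delay is the signed number of seasons between collection of the
#' surface (sink) and skin (source) samples: positive when the surface was
#' sampled after the skin. For each delay, aggregates all pairwise
#' combinations of one skin and one surface sample from the same residence.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @param meta sample metadata covering the matrix's samples.
#' @return data.frame with columns `delay`, `n` (pair count), `mean`, `sd`;
#'   delays in range with no pairs appear with `n = 0` and `NA` statistics.
#' @export
delay_distance_profile <- function(dm, meta) {
  meta <- meta[meta$sample_id %in% rownames(dm), , drop = FALSE]
  skin <- meta[meta$type == "skin", , drop = FALSE]
  surf <- meta[meta$type == "surface", , drop = FALSE]
  if (!nrow(skin) || !nrow(surf))
    stop("distance matrix must cover skin and surface samples")
  smax <- max(c(skin$season, surf$season)) - min(c(skin$season, surf$season))
  delays <- seq(-smax, smax)
  vals <- lapply(delays, function(d) {
    out <- numeric(0)
    for (r in intersect(unique(skin$residence), unique(surf$residence))) {
      sk <- skin[skin$residence == r, , drop = FALSE]
      sf <- surf[surf$residence == r, , drop = FALSE]
      for (ss in unique(sk$season)) {
        f_ids <- sf$sample_id[sf$season == ss + d]
        k_ids <- sk$sample_id[sk$season == ss]
        if (length(f_ids) && length(k_ids))
          out <- c(out, as.vector(dm[k_ids, f_ids, drop = FALSE]))
      }
    }
    out
  })
  data.frame(delay = delays,
             n = vapply(vals, length, integer(1)),
             mean = vapply(vals, function(x) if (length(x)) mean(x) else NA_real_,
                           numeric(1)),
             sd = vapply(vals, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                         numeric(1)))
}

#' Rank-based comparison of grouped values
#'
#' Two-group comparisons use the Mann-Whitney (Wilcoxon rank-sum) test with
#' the normal approximation and mid-rank tie handling; k-group comparisons
#' use Kruskal-Wallis with the chi-square approximation.
#'
#' @param values numeric vector.
#' @param grouping factor or vector of group labels, same length.
#' @param test `"mann_whitney"` (exactly 2 groups) or `"kruskal_wallis"`.
#' @return list with `statistic`, `p.value`, `method`, `n`.
#' @export
group_compare <- function(values, grouping,
                          test = c("mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  grouping <- as.factor(as.vector(grouping))
  if (length(values) != length(grouping))
    stop("'values' and 'grouping' lengths differ")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes == 0)) stop("empty group(s): ",
                            paste(names(sizes)[sizes == 0], collapse = ", "))
  if (test == "mann_whitney") {
    if (length(sizes) != 2) stop("mann_whitney requires exactly 2 groups")
    g <- levels(grouping)
    ht <- wilcox.test(values[grouping == g[1]], values[grouping == g[2]],
                      exact = FALSE, correct = TRUE)
  } else {
    ht <- kruskal.test(values, grouping)
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = test, n = length(values))
}
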