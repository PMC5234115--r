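#' Configuration for the synthetic household study generator
#'
#' Defaults mirror the dimensions of the emulated study: 9 residences with
#' occupant groups of sizes {1,1,2,2,2,2,3,3,3} (19 individuals), 4 ordered
#' seasons (winter..autumn), 5 skin sites per individual, 8 surface and 4
#' air sites per residence, and 9 kit controls, yielding 380 skin, 288
#' surface and 144 air samples. The default mixing weights (0.6 skin, 0.17
#' air, 0.23 residual) correspond to the source proportions the emulated
#' study reports for household surfaces.
#'
#' OTU classes: `core` (each individual permanently carries
#' `n_core_otus_per_individual` OTUs drawn from a cohort-wide pool of twice
#' that size, so core membership overlaps between individuals), `shared`
#' (always on all occupants of a residence), `transient` (acquired each
#' season, retained
#' season-to-season with `skin_retention_prob`), `identifying` (private to
#' one individual, drawn at low-to-mid abundance and subject to the same
#' seasonal retention as transients, so that identifying features are
#' preferentially lost as a generator regime), `environment` (air) and
#' `contaminant` (kit controls, plus a small presence in the residual
#' component of surface samples).
#'
#' @param n_residences number of residences.
#' @param occupants_per_residence integer vector, one entry per residence.
#' @param n_seasons number of ordered seasons (>= 2).
#' @param skin_sites,surface_sites,air_sites site name vectors (non-empty).
#' @param n_controls number of kit-control samples.
#' @param read_depth_range inclusive (min, max) reads per sample.
#' @param n_core_otus_per_individual,n_shared_household_otus,n_transient_otus_per_season,n_identifying_otus_per_individual,n_environment_otus,n_contaminant_otus
#'   class sizes; transients are per individual per season.
#' @param skin_retention_prob per-season survival probability of non-core
#'   OTUs on skin.
#' @param surface_retention_prob per-season survival probability of
#'   deposited OTUs on a surface.
#' @param deposition_prob_base base per-season probability that a skin OTU
#'   is deposited onto a given surface site.
#' @param deposition_abundance_exponent exponent e in the deposition
#'   probability `deposition_prob_base * relab^e` (0 removes the abundance
#'   effect).
#' @param mix_weights named numeric (skin, air, residual) surface mixture
#'   weights summing to 1.
#' @param abundance_lognormal (mu, sigma) of the log-normal base abundance.
#' @param rng_seed integer master seed.
#' @return a validated `generator_config` list.
#' @export
household_config <- function(n_residences = 9,
                             occupants_per_residence = c(1, 1, 2, 2, 2, 2, 3, 3, 3),
                             n_seasons = 4,
                             skin_sites = c("forehead", "left_forearm", "left_palm",
                                            "right_forearm", "right_palm"),
                             surface_sites = c("bed_headboard", "blanket",
                                               "fridge_door_seal", "kitchen_ventilator",
                                               "remote_control", "shower_curtain",
                                               "toilet_flush_button", "tv_screen"),
                             air_sites = c("bedroom_air", "kitchen_air",
                                           "living_room_air", "toilet_air"),
                             n_controls = 9,
                             read_depth_range = c(1381, 3000),
                             n_core_otus_per_individual = 25,
                             n_shared_household_otus = 15,
                             n_transient_otus_per_season = 12,
                             n_identifying_otus_per_individual = 8,
                             n_environment_otus = 120,
                             n_contaminant_otus = 25,
                             skin_retention_prob = 0.85,
                             surface_retention_prob = 0.5,
                             deposition_prob_base = 1,
                             deposition_abundance_exponent = 0.05,
                             mix_weights = c(skin = 0.6, air = 0.17, residual = 0.23),
                             abundance_lognormal = c(mu = 0, sigma = 1.5),
                             rng_seed = 1L) {
  cfg <- list(n_residences = n_residences,
              occupants_per_residence = as.integer(occupants_per_residence),
              n_seasons = as.integer(n_seasons),
              skin_sites = skin_sites, surface_sites = surface_sites,
              air_sites = air_sites, n_controls = as.integer(n_controls),
              read_depth_range = as.integer(read_depth_range),
              n_core_otus_per_individual = n_core_otus_per_individual,
              n_shared_household_otus = n_shared_household_otus,
              n_transient_otus_per_season = n_transient_otus_per_season,
              n_identifying_otus_per_individual = n_identifying_otus_per_individual,
              n_environment_otus = n_environment_otus,
              n_contaminant_otus = n_contaminant_otus,
              skin_retention_prob = skin_retention_prob,
              surface_retention_prob = surface_retention_prob,
              deposition_prob_base = deposition_prob_base,
              deposition_abundance_exponent = deposition_abundance_exponent,
              mix_weights = mix_weights,
              abundance_lognormal = abundance_lognormal,
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (length(occupants_per_residence) != n_residences)
      stop("occupants_per_residence must have one entry per residence")
    if (any(occupants_per_residence < 1))
      stop("every residence needs at least one occupant")
    if (n_seasons < 2) stop("n_seasons must be at least 2")
    for (nm in c("skin_sites", "surface_sites", "air_sites"))
      if (!length(cfg[[nm]])) stop(nm, " must be non-empty")
    if (read_depth_range[1] > read_depth_range[2])
      stop("read_depth_range: min exceeds max")
    if (read_depth_range[1] < 1) stop("read depth must be positive")
    probs <- c(skin_retention_prob, surface_retention_prob, deposition_prob_base)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (abs(sum(mix_weights) - 1) > 1e-9)
      stop("mix_weights must sum to 1")
    if (any(mix_weights < 0)) stop("mix_weights must be non-negative")
    if (n_core_otus_per_individual + n_identifying_otus_per_individual +
        n_transient_otus_per_season < 1)
      stop("at least one skin OTU class must be non-empty")
  })
  invisible(cfg)
}

season_names <- function(n) {
  base <- c("winter", "spring", "summer", "autumn")
  if (n <= 4) base[seq_len(n)] else paste0("season", seq_len(n))
}

#' Generate a synthetic multi-season household microbiome study
#'
#' Produces an OTU count table, sample metadata, a rooted OTU phylogeny with
#' branch lengths, and the generator's latent ground truth. Skin profiles
#' are built from per-individual core, household-shared, identifying and
#' seasonally acquired transient OTUs with log-normal base abundances and
#' per-sample multiplicative noise; surface profiles are mixtures of pooled
#' occupant skin (restricted to OTUs that have been deposited and retained),
#' the residence air profile, and a residual component; air samples draw
#' from an environmental pool; kit controls carry contaminant OTUs at high
#' relative abundance. All randomness derives from `config$rng_seed`.
#'
#' @param config a [household_config()].
#' @return a list with elements `table` ([otu_table()], counts with
#'   taxonomy), `meta` (metadata data.frame), `tree` (an `ape` `phylo` over
#'   all OTU ids), and `truth` (see Details).
#' @details `truth` records `otu_class`, `otu_owner` (identifying OTUs),
#'   per-surface-sample mixing proportions, the deposition and loss
#'   schedules, and per-sample latent supports (`support`): the OTU set of
#'   the underlying mixture before multinomial read sampling, which at
#'   finite depth may drop rare members from the realised counts.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$rng_seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  S <- cfg$n_seasons
  residences <- sprintf("R%d", seq_len(cfg$n_residences))
  individuals <- unlist(lapply(seq_len(cfg$n_residences), function(r)
    paste0(residences[r], "_", letters[seq_len(cfg$occupants_per_residence[r])])))
  ind_res <- setNames(rep(residences, cfg$occupants_per_residence), individuals)

  ## ---- OTU pools -----------------------------------------------------
  counter <- 0L
  new_otus <- function(n) {
    if (n <= 0) return(character(0))
    ids <- sprintf("OTU_%05d", counter + seq_len(n))
    counter <<- counter + as.integer(n)
    ids
  }
  ## cores are drawn from a cohort-wide pool (twice the per-individual
  ## count), so individuals overlap in core membership and private features
  ## are predominantly identifying/transient OTUs
  core_pool <- new_otus(2L * cfg$n_core_otus_per_individual)
  core <- lapply(individuals, function(i)
    sort(sample(core_pool, cfg$n_core_otus_per_individual)))
  names(core) <- individuals
  shared <- lapply(residences, function(r) new_otus(cfg$n_shared_household_otus))
  names(shared) <- residences
  identifying <- lapply(individuals, function(i)
    new_otus(cfg$n_identifying_otus_per_individual))
  names(identifying) <- individuals
  transients <- lapply(individuals, function(i)
    lapply(seq_len(S), function(s) new_otus(cfg$n_transient_otus_per_season)))
  names(transients) <- individuals
  environment_pool <- new_otus(cfg$n_environment_otus)
  contaminant_pool <- new_otus(cfg$n_contaminant_otus)

  all_otus <- sprintf("OTU_%05d", seq_len(counter))
  otu_class <- setNames(rep(NA_character_, counter), all_otus)
  otu_class[core_pool] <- "core"
  otu_owner <- character(0)
  for (i in individuals) {
    otu_class[identifying[[i]]] <- "identifying"
    otu_owner[identifying[[i]]] <- i
    for (s in seq_len(S)) otu_class[transients[[i]][[s]]] <- "transient"
  }
  for (r in residences) otu_class[shared[[r]]] <- "shared"
  otu_class[environment_pool] <- "environment"
  otu_class[contaminant_pool] <- "contaminant"

  ## base abundances: log-normal, shared across seasons. Identifying and
  ## transient OTUs are drawn lower (low-to-mid abundance): established
  ## residents dominate skin abundance while seasonal acquisitions are
  ## numerous but individually minor, giving the heavy-tailed
  ## rank-abundance shape with stable taxa carrying most of the mass
  mu <- cfg$abundance_lognormal[[1]]; sg <- cfg$abundance_lognormal[[2]]
  base <- setNames(rlnorm(counter, mu, sg), all_otus)
  low <- otu_class %in% c("identifying", "transient")
  base[low] <- rlnorm(sum(low), mu - 1, sg / 2)

  taxonomy <- synthetic_taxonomy(all_otus, otu_class)

  ## ---- skin presence dynamics ---------------------------------------
  ## skin_present[[i]][[s]]: OTU set on individual i's skin in season s
  skin_present <- list()
  loss_schedule <- list()
  for (i in individuals) {
    always <- c(core[[i]], shared[[ind_res[i]]])
    cur <- c(always, identifying[[i]], transients[[i]][[1]])
    sets <- vector("list", S)
    sets[[1]] <- cur
    if (S > 1) for (s in 2:S) {
      nonpermanent <- setdiff(sets[[s - 1]], always)
      keep <- nonpermanent[runif(length(nonpermanent)) < cfg$skin_retention_prob]
      lost <- setdiff(nonpermanent, keep)
      if (length(lost))
        loss_schedule[[length(loss_schedule) + 1L]] <-
          data.frame(otu = lost, context = paste0("skin:", i), season = s,
                     stringsAsFactors = FALSE)
      sets[[s]] <- c(always, keep, transients[[i]][[s]])
    }
    skin_present[[i]] <- sets
  }

  depth_draw <- function() {
    r <- cfg$read_depth_range
    if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  }

  samples <- list()     # named list sample_id -> counts vector (sparse, named)
  meta_rows <- list()
  support <- list()
  noise_sd <- 0.5       # per-sample multiplicative log-noise

  profile_counts <- function(otus, weights, depth) {
    p <- weights / sum(weights)
    cnt <- rmultinom(1, depth, p)[, 1]
    setNames(cnt, otus)
  }

  ## ---- skin samples ---------------------------------------------------
  for (i in individuals) for (b in cfg$skin_sites) for (s in seq_len(S)) {
    id <- paste(i, b, paste0("S", s), sep = "_")
    otus <- skin_present[[i]][[s]]
    w <- base[otus] * rlnorm(length(otus), 0, noise_sd)
    samples[[id]] <- profile_counts(otus, w, depth_draw())
    support[[id]] <- otus
    meta_rows[[id]] <- data.frame(sample_id = id, type = "skin",
                                  residence = ind_res[[i]], site = b,
                                  individual = i, season = s,
                                  stringsAsFactors = FALSE)
  }

  ## ---- surface samples ------------------------------------------------
  mixing <- list()
  surf_skin_support <- list()
  deposition_schedule <- list()
  e <- cfg$deposition_abundance_exponent
  for (r in residences) {
    pooled <- lapply(seq_len(S), function(s) pooled_skin_fast(
      individuals[ind_res == r], skin_present, base, s))
    for (f in cfg$surface_sites) {
      deposited <- character(0)          # currently retained deposits
      trace_w <- numeric(0)              # last known pooled abundance
      for (s in seq_len(S)) {
        if (s > 1 && length(deposited)) {
          keep <- deposited[runif(length(deposited)) < cfg$surface_retention_prob]
          lost <- setdiff(deposited, keep)
          if (length(lost))
            loss_schedule[[length(loss_schedule) + 1L]] <-
              data.frame(otu = lost, context = paste0("surface:", r, ":", f),
                         season = s, stringsAsFactors = FALSE)
          deposited <- keep
        }
        q <- pooled[[s]]
        candidates <- setdiff(names(q), deposited)
        if (length(candidates)) {
          pdep <- pmin(1, cfg$deposition_prob_base * q[candidates]^e)
          hit <- candidates[runif(length(candidates)) < pdep]
          if (length(hit)) {
            deposited <- c(deposited, hit)
            deposition_schedule[[length(deposition_schedule) + 1L]] <-
              data.frame(otu = hit, residence = r, site = f, season = s,
                         stringsAsFactors = FALSE)
          }
        }
        ## refresh trace weights for OTUs still on occupant skin
        on_skin <- intersect(deposited, names(q))
        trace_w[on_skin] <- q[on_skin]
        trace_w <- trace_w[names(trace_w) %in% deposited]
        new_dep <- setdiff(deposited, names(trace_w))
        if (length(new_dep)) trace_w[new_dep] <- q[new_dep]

        id <- paste(r, f, paste0("S", s), sep = "_")
        w_mix <- cfg$mix_weights
        parts <- list()
        if (length(trace_w) && w_mix[["skin"]] > 0)
          parts$skin <- w_mix[["skin"]] * trace_w / sum(trace_w)
        if (w_mix[["air"]] > 0) {
          air_w <- base[seasonal_window(environment_pool, s, S)]
          parts$air <- w_mix[["air"]] * air_w / sum(air_w)
        }
        if (w_mix[["residual"]] > 0) {
          ## the residual pool is seasonal: outdoor-derived input turns over
          ## with the seasons, so each season draws from a rotating window
          ## covering half the environment pool (50% carryover between
          ## consecutive seasons); kit contaminants stay available year-round
          res_pool <- c(seasonal_window(environment_pool, s, S),
                        contaminant_pool)
          pick <- sample(res_pool, min(30L, length(res_pool)))
          rw <- rlnorm(length(pick), 0, 1)
          parts$residual <- w_mix[["residual"]] * setNames(rw / sum(rw), pick)
        }
        nm <- unlist(lapply(parts, names), use.names = FALSE)
        val <- unlist(parts, use.names = FALSE)
        combined <- vapply(split(val, nm), sum, numeric(1))
        eff <- vapply(parts, sum, numeric(1))
        mixing[[id]] <- c(skin = unname(eff["skin"] %||% 0) / sum(eff),
                          air = unname(eff["air"] %||% 0) / sum(eff),
                          residual = unname(eff["residual"] %||% 0) / sum(eff))
        samples[[id]] <- profile_counts(names(combined), combined, depth_draw())
        support[[id]] <- names(combined)
        surf_skin_support[[id]] <- if (is.null(parts$skin)) character(0)
                                   else names(parts$skin)
        meta_rows[[id]] <- data.frame(sample_id = id, type = "surface",
                                      residence = r, site = f,
                                      individual = NA_character_, season = s,
                                      stringsAsFactors = FALSE)
      }
    }
  }

  ## ---- air samples ----------------------------------------------------
  ## the environmental pool is seasonal: each season's air draws from a
  ## rotating window covering half the pool (50% carryover), emulating
  ## seasonal turnover of outdoor-derived communities
  for (r in residences) for (a in cfg$air_sites) for (s in seq_len(S)) {
    id <- paste(r, a, paste0("S", s), sep = "_")
    env_s <- seasonal_window(environment_pool, s, S)
    w <- base[env_s] * rlnorm(length(env_s), 0, noise_sd)
    samples[[id]] <- profile_counts(env_s, w, depth_draw())
    support[[id]] <- env_s
    meta_rows[[id]] <- data.frame(sample_id = id, type = "air",
                                  residence = r, site = a,
                                  individual = NA_character_, season = s,
                                  stringsAsFactors = FALSE)
  }

  ## ---- kit controls ---------------------------------------------------
  for (k in seq_len(cfg$n_controls)) {
    id <- sprintf("CTRL_%02d", k)
    w <- base[contaminant_pool] * rlnorm(length(contaminant_pool), 0, noise_sd)
    samples[[id]] <- profile_counts(contaminant_pool, w, depth_draw())
    support[[id]] <- contaminant_pool
    meta_rows[[id]] <- data.frame(sample_id = id, type = "control",
                                  residence = NA_character_, site = "kit",
                                  individual = NA_character_, season = NA_integer_,
                                  stringsAsFactors = FALSE)
  }

  ## ---- assemble -------------------------------------------------------
  ids <- names(samples)
  counts <- matrix(0, length(ids), counter, dimnames = list(ids, all_otus))
  for (id in ids) counts[id, names(samples[[id]])] <- samples[[id]]
  table <- otu_table(counts, mode = "counts", taxonomy = taxonomy)
  meta <- sample_metadata(do.call(rbind, meta_rows))
  rownames(meta) <- NULL

  tree <- ape::rtree(counter, tip.label = sample(all_otus))
  tree$edge.length <- rexp(nrow(tree$edge))

  truth <- structure(list(
    otu_class = otu_class,
    otu_owner = otu_owner,
    mixing = mixing,
    deposition_schedule = if (length(deposition_schedule))
      do.call(rbind, deposition_schedule) else NULL,
    loss_schedule = if (length(loss_schedule))
      do.call(rbind, loss_schedule) else NULL,
    support = support,
    surface_skin_support = surf_skin_support,
    skin_present = skin_present,
    config = cfg), class = "synthetic_truth")

  list(table = table, meta = meta, tree = tree, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

## rotating half-pool window: consecutive seasons share 50% of the pool
seasonal_window <- function(pool, s, n_seasons) {
  L <- length(pool)
  if (L < 4 || n_seasons < 2) return(pool)
  half <- ceiling(L / 2)
  offset <- (s - 1L) * max(1L, floor(L / n_seasons))
  pool[((offset + seq_len(half) - 1L) %% L) + 1L]
}

## pooled occupant-skin latent relative profile (mean of occupants'
## normalised base-abundance profiles)
pooled_skin_fast <- function(occ, skin_present, base, s) {
  nm <- character(0); val <- numeric(0)
  for (i in occ) {
    otus <- skin_present[[i]][[s]]
    nm <- c(nm, otus)
    val <- c(val, base[otus] / sum(base[otus]))
  }
  acc <- vapply(split(val, nm), sum, numeric(1))
  acc / length(occ)
}

synthetic_taxonomy <- function(otus, otu_class) {
  skin_fams <- c("Moraxellaceae", "Staphylococcaceae", "Micrococcaceae",
                 "Corynebacteriaceae", "Streptococcaceae")
  env_fams <- c("Sphingomonadaceae", "Methylobacteriaceae", "Pseudomonadaceae",
                "Rhodobacteraceae", "Xanthomonadaceae")
  ctam_fams <- c("Comamonadaceae", "Bradyrhizobiaceae")
  fam <- character(length(otus))
  skin_classes <- otu_class %in% c("core", "shared", "transient", "identifying")
  fam[skin_classes] <- sample(skin_fams, sum(skin_classes), replace = TRUE)
  fam[otu_class == "environment"] <- sample(env_fams, sum(otu_class == "environment"),
                                            replace = TRUE)
  fam[otu_class == "contaminant"] <- sample(ctam_fams, sum(otu_class == "contaminant"),
                                            replace = TRUE)
  setNames(sprintf("k__Bacteria;p__Proteobacteria;c__;o__;f__%s;g__", fam), otus)
}

#' Apply an extra season-to-season retention process to a table
#'
#' Isolates the turnover mechanism for persistence tests: independently per
#' context (individual x site for skin, residence x site for surfaces), each
#' non-core OTU present in season s survives to season s+1 with probability
#' `retention`; failures are zeroed from season s+1 onward of the survival
#' chain (an OTU absent at s cannot be lost at s+1). Core and
#' household-shared OTUs always survive. Rows whose totals changed are
#' rescaled to their original depths by largest-remainder rounding, which
#' preserves presence/absence.
#'
#' @param truth `synthetic_truth` from [generate_study()] (for OTU classes).
#' @param table the counts [otu_table()] to degrade.
#' @param meta the matching sample metadata.
#' @param retention per-season survival probability in \[0, 1\].
#' @param seed optional integer for reproducibility.
#' @return a degraded counts `otu_table`.
#' @export
degrade_over_seasons <- function(truth, table, meta, retention, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(table, "otu_table"))
  if (!is.numeric(retention) || retention < 0 || retention > 1)
    stop("'retention' must be in [0, 1]")
  run <- function() degrade_impl(truth, table, meta, retention)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

degrade_impl <- function(truth, table, meta, retention) {
  v <- table$values
  permanent <- names(truth$otu_class)[truth$otu_class %in% c("core", "shared")]
  meta <- meta[meta$type %in% c("skin", "surface"), , drop = FALSE]
  key <- ifelse(meta$type == "skin",
                paste("skin", meta$individual, meta$site, sep = ":"),
                paste("surface", meta$residence, meta$site, sep = ":"))
  for (ctx in unique(key)) {
    rows <- meta[key == ctx, , drop = FALSE]
    rows <- rows[order(rows$season), , drop = FALSE]
    if (nrow(rows) < 2) next
    for (si in seq_len(nrow(rows) - 1)) {
      cur <- rows$sample_id[si]; nxt <- rows$sample_id[si + 1]
      present <- colnames(v)[v[cur, ] > 0]
      mortal <- setdiff(present, permanent)
      dead <- mortal[runif(length(mortal)) >= retention]
      if (length(dead)) v[nxt, dead] <- 0
    }
  }
  ## re-normalise changed rows to original depths, preserving presence
  orig <- rowSums(table$values)
  now <- rowSums(v)
  for (id in rownames(v)[now != orig & now > 0]) {
    scaled <- v[id, ] * orig[id] / now[id]
    fl <- floor(scaled)
    rem <- orig[id] - sum(fl)
    if (rem > 0) {
      frac <- scaled - fl
      topup <- order(frac, decreasing = TRUE)[seq_len(rem)]
      fl[topup] <- fl[topup] + 1
    }
    v[id, ] <- fl
  }
  otu_table(v, mode = "counts", taxonomy = table$taxonomy)
}
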