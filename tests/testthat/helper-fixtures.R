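# Shared fixtures: small study configurations and hand-built toy tables.

# Compact household design used across modules: 3 residences, 5 occupants,
# 4 seasons, modest OTU pools, read depths in the hundreds.
small_config <- function(seed = 11L, ...) {
  args <- list(n_residences = 3, occupants_per_residence = c(1, 2, 2),
               skin_sites = c("palm", "forearm", "forehead"),
               surface_sites = c("desk", "tv", "fridge"),
               air_sites = "bedroom_air", n_controls = 3,
               read_depth_range = c(400, 600),
               n_core_otus_per_individual = 10, n_shared_household_otus = 5,
               n_transient_otus_per_season = 6,
               n_identifying_otus_per_individual = 4,
               n_environment_otus = 40, n_contaminant_otus = 10,
               rng_seed = seed)
  args[names(list(...))] <- list(...)
  do.call(household_config, args)
}

# Turnover-heavy regime: weak permanent signal, strong seasonal turnover,
# surfaces forget faster than skin. Used for the delay-degradation and
# persistence-direction checks.
turnover_config <- function(seed = 1L, ...) {
  args <- list(n_residences = 4, occupants_per_residence = c(1, 1, 2, 2),
               skin_sites = c("palm", "forearm"),
               surface_sites = c("desk", "tv", "fridge"),
               air_sites = "bedroom_air", n_controls = 3,
               read_depth_range = c(300, 400),
               n_core_otus_per_individual = 3, n_shared_household_otus = 2,
               n_transient_otus_per_season = 12,
               n_identifying_otus_per_individual = 5,
               n_environment_otus = 40, n_contaminant_otus = 8,
               skin_retention_prob = 0.7, surface_retention_prob = 0.3,
               rng_seed = seed)
  args[names(list(...))] <- list(...)
  do.call(household_config, args)
}

# Minimal counts table + metadata built by hand. presence is a list:
# sample_id -> named count vector.
toy_table <- function(presence, taxonomy = NULL) {
  otus <- sort(unique(unlist(lapply(presence, names))))
  m <- matrix(0, length(presence), length(otus),
              dimnames = list(names(presence), otus))
  for (id in names(presence)) m[id, names(presence[[id]])] <- presence[[id]]
  otu_table(m, mode = "counts", taxonomy = taxonomy)
}

toy_meta <- function(sample_id, type, residence = NA, site = NA,
                     individual = NA, season = NA) {
  sample_metadata(data.frame(sample_id = sample_id, type = type,
                             residence = as.character(residence),
                             site = as.character(site),
                             individual = as.character(individual),
                             season = season, stringsAsFactors = FALSE))
}

# Random rooted tree with exponential branch lengths over given tip labels.
toy_tree <- function(tips, seed = NULL) {
  run <- function() {
    tr <- ape::rtree(length(tips), tip.label = sample(tips))
    tr$edge.length <- rexp(nrow(tr$edge))
    tr
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Star tree: every tip attached to the root with branch length len.
star_tree <- function(tips, len = 1) {
  n <- length(tips)
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 tip.label = tips,
                 edge.length = rep(len, n),
                 Nnode = 1L),
            class = "phylo")
}

# Empty annotation set: IndVal 0 and no hitting sets everywhere; lets the
# record builders run on minimal toy data.
null_annotations <- function() list(indval = list(), hitting_sets = list())

# Canonical single-context fixture: one individual, one skin site, one
# surface site, four seasons. OTU presence patterns chosen to pin down the
# interval/event construction rules.
canonical_study <- function() {
  skin_ids <- paste0("k", 1:4)
  surf_ids <- paste0("f", 1:4)
  # skin patterns
  skin <- list(
    k1 = c(allfour = 10, firsttwo = 10, interim = 10, lastonly = 0, single = 10,
           dep_delay = 10, dep_same = 10, never_dep = 10, pre_surface = 0),
    k2 = c(allfour = 10, firsttwo = 10, never_dep = 10),
    k3 = c(allfour = 10, interim = 10, never_dep = 10, pre_surface = 10),
    k4 = c(allfour = 10, lastonly = 10, never_dep = 10))
  # surface patterns: dep_delay arrives in spring, dep_same in winter,
  # pre_surface is on the surface before it is ever seen on skin
  surf <- list(
    f1 = c(dep_same = 5, pre_surface = 5, filler = 5),
    f2 = c(dep_delay = 5, filler = 5),
    f3 = c(filler = 5),
    f4 = c(filler = 5))
  tab <- toy_table(c(skin, surf))
  meta <- toy_meta(c(skin_ids, surf_ids),
                   type = rep(c("skin", "surface"), each = 4),
                   residence = "R1",
                   site = rep(c("palm", "desk"), each = 4),
                   individual = c(rep("a", 4), rep(NA, 4)),
                   season = c(1:4, 1:4))
  list(tab = tab, meta = meta)
}
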