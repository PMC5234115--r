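test_that("the default design reproduces the emulated study's sample counts", {
  cfg <- household_config(rng_seed = 3L)
  study <- generate_study(cfg)
  counts <- table(study$meta$type)
  expect_equal(unname(counts[["skin"]]), 19 * 5 * 4)   # 380
  expect_equal(unname(counts[["surface"]]), 9 * 8 * 4) # 288
  expect_equal(unname(counts[["air"]]), 9 * 4 * 4)     # 144
  expect_equal(unname(counts[["control"]]), 9)
  # combinatorics per stratum
  skin <- study$meta[study$meta$type == "skin", ]
  expect_equal(nrow(unique(skin[, c("individual", "site", "season")])), nrow(skin))
})

test_that("regeneration with the same seed is bit-identical", {
  a <- generate_study(small_config(seed = 7L))
  b <- generate_study(small_config(seed = 7L))
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$tree, b$tree)
  expect_identical(a$truth$otu_class, b$truth$otu_class)
  expect_identical(a$truth$mixing, b$truth$mixing)
  c <- generate_study(small_config(seed = 8L))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("table OTUs and tree leaves coincide exactly", {
  study <- generate_study(small_config())
  expect_setequal(colnames(study$table$values), study$tree$tip.label)
})

test_that("deterministic deposition limit makes surfaces the union of occupant skin", {
  cfg <- small_config(seed = 5L,
                      deposition_prob_base = 1, surface_retention_prob = 1,
                      skin_retention_prob = 1,
                      deposition_abundance_exponent = 0,
                      mix_weights = c(skin = 1, air = 0, residual = 0))
  study <- generate_study(cfg)
  meta <- study$meta
  truth <- study$truth
  surf <- meta[meta$type == "surface", ]
  for (k in seq_len(nrow(surf))) {
    r <- surf$residence[k]; s <- surf$season[k]; id <- surf$sample_id[k]
    occ <- unique(meta$individual[meta$type == "skin" & meta$residence == r])
    skin_union <- sort(unique(unlist(lapply(occ, function(i)
      truth$skin_present[[i]][[s]]))))
    expect_equal(sort(truth$surface_skin_support[[id]]), skin_union)
    realised <- colnames(study$table$values)[study$table$values[id, ] > 0]
    expect_true(all(realised %in% skin_union))
  }
})

test_that("surface read mass on skin-class OTUs converges to the skin mixing weight", {
  cfg <- small_config(seed = 9L, read_depth_range = c(100000L, 100000L),
                      deposition_prob_base = 1,
                      deposition_abundance_exponent = 0,
                      mix_weights = c(skin = 0.6, air = 0.2, residual = 0.2))
  study <- generate_study(cfg)
  skin_classes <- c("core", "shared", "transient", "identifying")
  skin_otus <- names(study$truth$otu_class)[study$truth$otu_class %in% skin_classes]
  surf_ids <- study$meta$sample_id[study$meta$type == "surface"]
  frac <- vapply(surf_ids, function(id) {
    v <- study$table$values[id, ]
    sum(v[skin_otus]) / sum(v)
  }, numeric(1))
  expect_true(all(abs(frac - 0.6) < 0.02))
})

test_that("generator rejects invalid configurations", {
  expect_error(small_config(read_depth_range = c(500, 400)), "min exceeds max")
  expect_error(small_config(mix_weights = c(skin = 0.5, air = 0.2, residual = 0.2)),
               "sum to 1")
  expect_error(small_config(n_seasons = 1), "at least 2")
  expect_error(small_config(skin_retention_prob = 1.2), "\\[0, 1\\]")
  expect_error(small_config(skin_sites = character(0)), "non-empty")
})

test_that("degrade_over_seasons at the retention extremes", {
  study <- generate_study(small_config(seed = 21L))
  # retention 1: identity on presence (and, as nothing changes, on counts)
  same <- degrade_over_seasons(study$truth, study$table, study$meta, 1, seed = 1)
  expect_identical(same$values, study$table$values)
  # retention 0: no non-permanent OTU present in two consecutive seasons
  gone <- degrade_over_seasons(study$truth, study$table, study$meta, 0, seed = 1)
  permanent <- names(study$truth$otu_class)[
    study$truth$otu_class %in% c("core", "shared")]
  meta <- study$meta[study$meta$type %in% c("skin", "surface"), ]
  key <- ifelse(meta$type == "skin",
                paste(meta$individual, meta$site),
                paste(meta$residence, meta$site))
  for (ctx in unique(key)) {
    rows <- meta[key == ctx, ]
    rows <- rows[order(rows$season), ]
    for (k in seq_len(nrow(rows) - 1)) {
      both <- gone$values[rows$sample_id[k], ] > 0 &
        gone$values[rows$sample_id[k + 1], ] > 0
      expect_true(all(names(which(both)) %in% permanent))
    }
  }
  # depths preserved
  expect_equal(rowSums(gone$values), rowSums(study$table$values))
})

test_that("degrade_over_seasons survival fraction matches the binomial expectation", {
  cfg <- household_config(
    n_residences = 1, occupants_per_residence = 1, n_seasons = 4,
    skin_sites = c("palm", "forearm"), surface_sites = "desk",
    air_sites = "bedroom_air", n_controls = 1,
    read_depth_range = c(50000L, 50000L),
    n_core_otus_per_individual = 5, n_shared_household_otus = 0,
    n_transient_otus_per_season = 1000,
    n_identifying_otus_per_individual = 0,
    n_environment_otus = 10, n_contaminant_otus = 5,
    skin_retention_prob = 1, surface_retention_prob = 1,
    rng_seed = 31L)
  study <- generate_study(cfg)
  deg <- degrade_over_seasons(study$truth, study$table, study$meta, 0.5, seed = 2)
  transient <- names(study$truth$otu_class)[study$truth$otu_class == "transient"]
  meta <- study$meta[study$meta$type == "skin", ]
  surv <- integer(0); at_risk <- integer(0)
  for (ctx in unique(paste(meta$individual, meta$site))) {
    rows <- meta[paste(meta$individual, meta$site) == ctx, ]
    rows <- rows[order(rows$season), ]
    for (k in seq_len(nrow(rows) - 1)) {
      cur <- rows$sample_id[k]; nxt <- rows$sample_id[k + 1]
      # condition on originally present at both seasons, so detection
      # dropout does not bias the survival estimate
      eligible <- transient[deg$values[cur, transient] > 0 &
                              study$table$values[nxt, transient] > 0]
      at_risk <- c(at_risk, length(eligible))
      surv <- c(surv, sum(deg$values[nxt, eligible] > 0))
    }
  }
  expect_gt(sum(at_risk), 2000)
  expect_lt(abs(sum(surv) / sum(at_risk) - 0.5), 0.05)
})

test_that("degrade_over_seasons validates retention", {
  study <- generate_study(small_config())
  expect_error(degrade_over_seasons(study$truth, study$table, study$meta, 1.5),
               "\\[0, 1\\]")
})
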