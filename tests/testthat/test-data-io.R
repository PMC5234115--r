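test_that("OTU table round-trips through TSV exactly", {
  tax <- c(A = "k__Bacteria;p__;c__;o__;f__Moraxellaceae;g__Acinetobacter",
           B = "k__Bacteria;p__;c__;o__;f__Staphylococcaceae;g__")
  tab <- otu_table(matrix(c(5, 0, 3, 2), 2, 2,
                          dimnames = list(c("s1", "s2"), c("A", "B"))),
                   taxonomy = tax)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_identical(back$values, tab$values)
  expect_identical(unname(back$taxonomy), unname(tax))
  fam <- otu_families(back)
  expect_equal(fam[["A"]], "Moraxellaceae")
})

test_that("malformed OTU tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "B\t-1\t0"), path)
  expect_error(read_otu_table(path), "negative.*B")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "B\t3"), path)
  expect_error(read_otu_table(path), "ragged.*B")
  writeLines(c("otu_id\ts1\ts2", "A\t1\t2", "A\t3\t4"), path)
  expect_error(read_otu_table(path), "duplicate")
  expect_error(otu_table(matrix(1.5, 1, 1, dimnames = list("s", "o"))),
               "integer")
})

test_that("metadata round-trips and is validated", {
  meta <- toy_meta(c("k1", "f1", "c1"), c("skin", "surface", "control"),
                   residence = c("R1", "R1", NA), site = c("palm", "desk", "kit"),
                   individual = c("R1_a", NA, NA), season = c(1, 2, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, path)
  expect_equal(read_sample_metadata(path), meta)
  expect_error(toy_meta("x", "skin", "R1", "palm", NA, 1), "individual")
  expect_error(toy_meta("x", "surface", "R1", "desk", NA, NA), "season")
})

test_that("contaminant rule is inclusive at the threshold boundary", {
  # a 100-read control with an OTU at exactly 5 reads must be flagged
  tab <- toy_table(list(ctrl = c(X = 5, Y = 95), s1 = c(X = 1, Y = 10, Z = 5)))
  expect_equal(flag_contaminants(tab, "ctrl"), c("X", "Y"))
  expect_true("X" %in% flag_contaminants(tab, "ctrl", threshold = 0.05))
  expect_false("X" %in% flag_contaminants(tab, "ctrl", threshold = 0.051))
  # all-zero controls flag nothing
  tab0 <- toy_table(list(ctrl = c(X = 0, Y = 0), s1 = c(X = 3, Y = 1)))
  expect_identical(flag_contaminants(tab0, "ctrl"), character(0))
  expect_error(flag_contaminants(tab, character(0)), "no control")
})

test_that("contaminant flags equal a brute-force per-control scan", {
  withr::with_seed(42, {
    m <- matrix(rpois(10 * 20, 3), 10, 20,
                dimnames = list(paste0("s", 1:10), paste0("o", 1:20)))
    tab <- otu_table(m)
    controls <- c("s1", "s4", "s7")
    got <- flag_contaminants(tab, controls, 0.08)
    manual <- character(0)
    for (o in colnames(m)) for (cc in controls) {
      if (sum(m[cc, ]) > 0 && m[cc, o] / sum(m[cc, ]) >= 0.08)
        manual <- union(manual, o)
    }
    expect_setequal(got, manual)
    # deterministic: the same table always yields the same flags
    expect_identical(flag_contaminants(tab, controls, 0.08), got)
  })
})

test_that("rarefaction hits the target depth exactly and respects support", {
  withr::with_seed(7, {
    m <- matrix(rpois(5 * 30, 20), 5, 30,
                dimnames = list(paste0("s", 1:5), paste0("o", 1:30)))
    tab <- otu_table(m)
    r <- rarefy(tab, depth = 100, seed = 1)
    expect_true(all(rowSums(r$values) == 100))
    expect_true(all(r$values <= m))               # subsample of the reads
    expect_identical(rarefy(tab, depth = 100, seed = 1)$values, r$values)
    # a sample already at depth is returned unchanged
    m2 <- m; m2[1, ] <- 0; m2[1, 1:4] <- 25
    r2 <- rarefy(otu_table(m2), depth = 100, seed = 1)
    expect_identical(r2$values[1, ], m2[1, ])
    # default depth is the most depauperate sample's total
    expect_equal(unique(rowSums(rarefy(tab, seed = 1)$values)),
                 min(rowSums(m)))
    # samples below an explicit depth are dropped with a warning
    expect_warning(r3 <- rarefy(tab, depth = max(rowSums(m)), seed = 1),
                   "dropping")
    expect_lt(nrow(r3$values), nrow(m))
  })
})

test_that("rarefied counts match the hypergeometric expectation", {
  total <- 1000; depth <- 200
  v <- c(o1 = 150, o2 = 850)
  tab <- toy_table(list(s = v))
  draws <- vapply(1:1000, function(k)
    rarefy(tab, depth = depth, seed = k)$values[1, "o1"], numeric(1))
  p <- v[["o1"]] / total
  expected <- depth * p
  hyper_var <- depth * p * (1 - p) * (total - depth) / (total - 1)
  se <- sqrt(hyper_var / 1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("prevalence filter keeps OTUs at exactly the cutoff", {
  m <- matrix(0, 10, 3, dimnames = list(paste0("s", 1:10), c("rare", "mid", "common")))
  m[1, "rare"] <- 1          # 1/10 samples: exactly 10%, kept
  m[1:3, "mid"] <- 1
  m[, "common"] <- 2
  tab <- otu_table(m)
  kept <- colnames(prevalence_filter(tab, 0.10)$values)
  expect_setequal(kept, c("rare", "mid", "common"))
  expect_setequal(colnames(prevalence_filter(tab, 0.2)$values), c("mid", "common"))
  expect_identical(prevalence_filter(tab, 0)$values, m)
  # idempotent
  f <- prevalence_filter(tab, 0.2)
  expect_identical(prevalence_filter(f, 0.2)$values, f$values)
})

test_that("prevalence filter equals a brute-force presence scan", {
  withr::with_seed(9, {
    m <- matrix(rbinom(12 * 25, 1, 0.25) * rpois(12 * 25, 4), 12, 25,
                dimnames = list(paste0("s", 1:12), paste0("o", 1:25)))
    tab <- otu_table(m)
    cut <- 0.25
    manual <- colnames(m)[vapply(colnames(m), function(o)
      mean(m[, o] > 0) >= cut, logical(1))]
    expect_setequal(colnames(prevalence_filter(tab, cut)$values), manual)
  })
})

test_that("relative abundances sum to one per non-empty sample", {
  study <- generate_study(small_config())
  rel <- relative_abundance(study$table)
  rs <- rowSums(rel$values)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("a generated study writes a complete on-disk bundle", {
  study <- generate_study(small_config(seed = 30L))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_setequal(list.files(dir),
                  c("otu_table.tsv", "metadata.tsv", "tree.nwk", "truth.json"))
  back <- read_otu_table(file.path(dir, "otu_table.tsv"))
  expect_identical(back$values, study$table$values)
  expect_equal(read_sample_metadata(file.path(dir, "metadata.tsv")), study$meta)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, study$tree$tip.label)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth$otu_class), names(study$truth$otu_class))
})

test_that("family source composition matches hand-computed sums", {
  tax <- c(A = "k__B;p__;c__;o__;f__Moraxellaceae;g__",
           B = "k__B;p__;c__;o__;f__Streptococcaceae;g__",
           C = "k__B;p__;c__;o__;f__Sphingomonadaceae;g__",
           D = "k__B;p__;c__;o__;f__;g__")
  tab <- toy_table(list(s1 = c(A = 6, B = 2, C = 2),
                        s2 = c(C = 10),
                        s3 = c(A = 1, D = 3)), taxonomy = tax)
  lists <- list(skin = c("Moraxellaceae", "Streptococcaceae"),
                leaf = "Sphingomonadaceae",
                soil = character(0))
  comp <- family_source_composition(tab, lists)
  expect_equal(comp["s1", "skin"], 0.8)
  expect_equal(comp["s1", "leaf"], 0.2)
  expect_equal(comp["s2", "skin"], 0)
  expect_equal(comp["s2", "leaf"], 1)       # all-leaf sample scores 1
  expect_equal(comp["s3", "skin"], 0.25)    # unannotated family never matches
  expect_true(all(comp[, "soil"] == 0))     # empty list scores 0
  expect_error(family_source_composition(toy_table(list(s = c(X = 1))), lists),
               "taxonomy")
})
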