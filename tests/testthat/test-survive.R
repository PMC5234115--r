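test_that("loss records reproduce the hand-enumerated canonical patterns", {
  toy <- canonical_study()
  rec <- build_loss_records(toy$tab, toy$meta, "skin", null_annotations())
  get <- function(o) rec[rec$otu == o, c("start", "stop", "event")]
  # present all four seasons: three intervals, censored
  r <- get("allfour")
  expect_equal(r$start, 1:3); expect_equal(r$stop, 2:4)
  expect_equal(r$event, c(0L, 0L, 0L))
  # winter and spring only: (1,2] none, (2,3] loss
  r <- get("firsttwo")
  expect_equal(r$start, 1:2); expect_equal(r$stop, 2:3)
  expect_equal(r$event, c(0L, 1L))
  # winter, absent spring, present summer: interim not a loss; loss after summer
  r <- get("interim")
  expect_equal(r$start, 1:3); expect_equal(r$stop, 2:4)
  expect_equal(r$event, c(0L, 0L, 1L))
  # interim season carries the lowest abundance bin
  rfull <- rec[rec$otu == "interim", ]
  expect_equal(as.character(rfull$abund_bin[rfull$start == 2]), "p0_69")
  # observed only in the final season: no transition, no record
  expect_equal(nrow(get("lastonly")), 0)
  # single-season subject: one at-risk interval ending in a loss
  r <- get("single")
  expect_equal(r$start, 1); expect_equal(r$stop, 2); expect_equal(r$event, 1L)
  # every event subject has exactly one event, on its last interval
  by_subj <- split(rec, rec$subject)
  for (s in by_subj) {
    expect_lte(sum(s$event), 1)
    if (sum(s$event) == 1) expect_equal(which(s$event == 1), nrow(s))
    expect_equal(nrow(s), max(s$stop) - min(s$start))
  }
})

test_that("the alternative loss placement ends records at the last observation", {
  toy <- canonical_study()
  rec <- build_loss_records(toy$tab, toy$meta, "skin", null_annotations(),
                            loss_at = "last_observed")
  r <- rec[rec$otu == "firsttwo", ]
  expect_equal(r$start, 1); expect_equal(r$stop, 2); expect_equal(r$event, 1L)
  expect_equal(nrow(rec[rec$otu == "single", ]), 0)
})

test_that("deposition records apply the same/later-season and exclusion rules", {
  toy <- canonical_study()
  rec <- build_deposition_records(toy$tab, toy$meta, null_annotations())
  get <- function(o) rec[rec$otu == o, c("start", "stop", "event")]
  # skin winter, surface spring: single interval (1,2] with the event
  r <- get("dep_delay")
  expect_equal(r$start, 1); expect_equal(r$stop, 2); expect_equal(r$event, 1L)
  # same-season deposition lands on the first interval
  r <- get("dep_same")
  expect_equal(r$start, 1); expect_equal(r$stop, 2); expect_equal(r$event, 1L)
  # on skin all seasons, never on a surface: censored through autumn
  r <- get("never_dep")
  expect_equal(r$start, 1:3); expect_equal(r$stop, 2:4)
  expect_equal(r$event, c(0L, 0L, 0L))
  # on the surface before first skin observation: excluded entirely
  expect_equal(nrow(get("pre_surface")), 0)
})

test_that("surface loss records honour the occupant-skin inclusion rule", {
  toy <- canonical_study()
  rec <- build_loss_records(toy$tab, toy$meta, "surface", null_annotations())
  # 'filler' is never on any occupant's skin: excluded from the surface model
  expect_equal(nrow(rec[rec$otu == "filler", ]), 0)
  # dep_same: on surface in winter only -> loss on (1,2]
  r <- rec[rec$otu == "dep_same", ]
  expect_equal(r$start, 1); expect_equal(r$event, 1L)
})

test_that("abundance percentile bins split at the stated boundaries", {
  relab <- setNames(seq(0.001, 0.1, length.out = 100), paste0("o", 1:100))
  bins <- microtrace:::abundance_bins(relab)
  expect_equal(sum(bins == "p99"), 2)      # ranks 99 and 100 of 100
  expect_equal(sum(bins == "p90_98"), 9)
  expect_equal(sum(bins == "p70_89"), 20)
  expect_equal(sum(bins == "p0_69"), 69)
  expect_equal(unname(microtrace:::indval_bin(c(0, 0.19, 0.2, 0.59, 0.6, 0.9, 1))),
               c("v0_02", "v0_02", "v02_06", "v02_06", "v06_09", "v09_1", "v09_1"))
})

test_that("cox_fit agrees with the established implementation on random data", {
  skip_if_not_installed("survival")
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- 50
      x <- rbinom(n, 1, 0.5)
      tm <- rexp(n, 0.4 * exp(0.8 * x))
      cens <- tm > stats::quantile(tm, 0.8)
      tm[cens] <- stats::quantile(tm, 0.8)
      rec <- data.frame(start = 0, stop = tm, event = as.integer(!cens), x = x)
      if (sum(rec$event) < 2 || length(unique(x[rec$event == 1])) < 2) next
      ours <- cox_fit(rec, covariates = "x")
      ref <- survival::coxph(survival::Surv(tm, !cens) ~ x, ties = "efron")
      expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(ours$se), sqrt(unname(diag(vcov(ref)))), tolerance = 1e-6)
    }
  })
})

test_that("cox_fit agrees with survival on counting-format ties", {
  skip_if_not_installed("survival")
  withr::with_seed(56, {
    n <- 120
    start <- sample(0:2, n, replace = TRUE)
    stop <- start + 1
    x <- rbinom(n, 1, 0.4)
    event <- rbinom(n, 1, plogis(-1 + 0.9 * x))
    rec <- data.frame(start = start, stop = stop, event = event, x = x)
    ours <- cox_fit(rec, covariates = "x")
    ref <- survival::coxph(survival::Surv(start, stop, event) ~ x, ties = "efron")
    expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-6)
  })
})

test_that("the Efron grid-search oracle confirms the 8-subject fit", {
  rec <- data.frame(start = rep(0, 8),
                    stop = c(1, 2, 3, 4, 5, 6, 7, 8),
                    event = c(1, 1, 0, 1, 1, 0, 1, 1),
                    x = c(1, 0, 1, 1, 0, 0, 1, 0))
  ours <- cox_fit(rec, covariates = "x", tol = 1e-10)
  grid_obj <- function(b) -oracle_efron_loglik(b, rec$start, rec$stop, rec$event, rec$x)
  oracle <- stats::optimize(grid_obj, c(-5, 5), tol = 1e-9)$minimum
  expect_equal(unname(coef(ours)), oracle, tolerance = 1e-4)
  # and the reported log partial likelihood matches the oracle's value
  expect_equal(ours$loglik,
               oracle_efron_loglik(coef(ours), rec$start, rec$stop, rec$event, rec$x),
               tolerance = 1e-8)
})

test_that("duplicating every record preserves coefficients and scales z by sqrt(2)", {
  withr::with_seed(57, {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n, 0.5 * exp(0.6 * x))
    rec <- data.frame(start = 0, stop = tm, event = 1L, x = x)
    # exact under Breslow tie handling (duplication creates tied pairs)
    f1 <- cox_fit(rec, covariates = "x", ties = "breslow")
    f2 <- cox_fit(rbind(rec, rec), covariates = "x", ties = "breslow")
    expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
    expect_equal(unname(f2$z / f1$z), sqrt(2), tolerance = 1e-6)
    # Efron's graded tie correction perturbs the duplicated fit only slightly
    e1 <- cox_fit(rec, covariates = "x")
    e2 <- cox_fit(rbind(rec, rec), covariates = "x")
    expect_equal(coef(e2), coef(e1), tolerance = 0.05)
    expect_equal(unname(e2$z / e1$z), sqrt(2), tolerance = 0.05)
  })
})

test_that("record order does not affect the fit", {
  withr::with_seed(58, {
    toy <- canonical_study()
    rec <- build_loss_records(toy$tab, toy$meta, "skin", null_annotations())
    rec$x <- rbinom(nrow(rec), 1, 0.5)
    if (length(unique(rec$x[rec$event == 1])) < 2) rec$x[rec$event == 1][1] <- 1 - rec$x[rec$event == 1][1]
    f1 <- cox_fit(rec, covariates = "x")
    f2 <- cox_fit(rec[sample(nrow(rec)), ], covariates = "x")
    expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  })
})

test_that("degenerate inputs are rejected or flagged", {
  rec <- data.frame(start = 0, stop = 1:4, event = 0L, x = c(0, 1, 0, 1))
  expect_error(cox_fit(rec, covariates = "x"), "no events")
  rec2 <- data.frame(start = c(0, 1), stop = c(1, 1), event = c(1L, 1L), x = c(0, 1))
  expect_error(cox_fit(rec2, covariates = "x"), "start < stop")
  # complete separation: events only in one covariate level
  withr::with_seed(59, {
    n <- 40
    x <- rep(c(0, 1), each = n / 2)
    tm <- runif(n, 1, 2)
    ev <- as.integer(x == 1)
    rec3 <- data.frame(start = 0, stop = tm, event = ev, x = x)
    expect_warning(f <- cox_fit(rec3, covariates = "x"), "separation")
    expect_true(any(f$unstable))
  })
})

test_that("hazard report shapes the three model families", {
  toy <- canonical_study()
  withr::with_seed(60, {
    mk <- function() {
      n <- 150
      x <- factor(sample(c("p0_69", "p99"), n, TRUE), levels = c("p0_69", "p99"))
      data.frame(start = 0, stop = runif(n, 0.5, 3),
                 event = rbinom(n, 1, 0.5), abund_bin = x)
    }
    fits <- lapply(1:3, function(i) cox_fit(mk(), covariates = "abund_bin"))
    rep <- hazard_report(fits[[1]], fits[[2]], fits[[3]])
    expect_setequal(unique(rep$model), c("skin_loss", "surface_loss", "deposition"))
    expect_true(all(rep$ci_lower <= rep$hazard_ratio & rep$hazard_ratio <= rep$ci_upper))
    expect_equal(rep$significant, rep$p < 0.05)
  })
})
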