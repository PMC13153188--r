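test_that("network activity score reproduces the worked z-sum example", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6))
  colnames(expr) <- paste0("s", 1:3)
  sc <- network_activity_score(expr, c("g1", "g2"))
  expect_equal(unname(sc), c(-1, 0, 1))
  expect_equal(names(sc), paste0("s", 1:3))
})

test_that("activity scores are standardized and equivariant to sample order", {
  co <- simulate_cohort(sim_config(seed = 21))
  sc <- network_activity_score(co$expr, co$signature)
  expect_lt(abs(mean(sc)), 1e-12)
  expect_lt(abs(sd(sc) - 1), 1e-12)

  perm <- sample(ncol(co$expr))
  sc_perm <- network_activity_score(co$expr[, perm], co$signature)
  expect_equal(unname(sc_perm), unname(sc[perm]))

  ## single signature gene reduces to that gene's z-scores
  one <- network_activity_score(co$expr, co$signature[1])
  z <- as.vector(scale(co$expr[co$signature[1], ]))
  expect_equal(unname(one), z)
})

test_that("missing and degenerate signature genes are handled explicitly", {
  expr <- rbind(g1 = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:4)
  expect_warning(sc <- network_activity_score(expr, c("g1", "nope")),
                 "absent")
  expect_equal(length(sc), 4)
  expect_warning(network_activity_score(expr, c("g1", "flat")),
                 "zero-variance")
  expect_error(suppressWarnings(network_activity_score(expr, "flat")),
               "zero variance")
  expect_error(suppressWarnings(network_activity_score(expr, "nope2")),
               "no signature gene")
})

test_that("weighted-mean pathway activity follows its linear contract", {
  set.seed(11)
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  z <- t(scale(t(expr)))
  unit <- pathway_activity_wmean(expr, paste0("g", 1:4))
  expect_equal(unname(unit), unname(colMeans(z)))

  single <- pathway_activity_wmean(expr, "g2", weights = 1)
  expect_equal(unname(single), unname(z["g2", ]))

  w <- c(2, -1, 0.5, 3)
  pos <- pathway_activity_wmean(expr, paste0("g", 1:4), weights = w)
  neg <- pathway_activity_wmean(expr, paste0("g", 1:4), weights = -w)
  expect_equal(neg, -pos)
  expect_error(pathway_activity_wmean(expr, paste0("g", 1:4),
                                      weights = rep(0, 4)), "zero")
})

test_that("log-rank test matches survdiff and degenerates correctly", {
  ## identical groups: O = E in every stratum
  time <- c(5, 8, 12, 5, 8, 12)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("a", "b"), each = 3)
  res <- logrank_test(time, event, grp)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  ## constructed 6-subject table against the textbook O/E/V sums
  time2 <- c(2, 4, 6, 1, 3, 5)
  event2 <- c(1, 1, 1, 1, 1, 0)
  grp2 <- rep(c("a", "b"), each = 3)
  res2 <- logrank_test(time2, event2, grp2)
  sd2 <- survival::survdiff(survival::Surv(time2, event2) ~ grp2)
  expect_equal(res2$statistic, sd2$chisq, tolerance = 1e-10)
  expect_equal(res2$observed, sd2$obs[1])
  expect_equal(res2$expected, sd2$exp[1], tolerance = 1e-10)

  expect_error(logrank_test(time, event, rep("a", 6)), "two")
  expect_error(logrank_test(c(-1, time[-1]), event, grp), "positive")
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(99)
  n <- 40
  time <- rexp(n, 0.01)
  event <- rbinom(n, 1, 0.8)
  ps <- replicate(500, {
    grp <- sample(rep(c("a", "b"), each = n / 2))
    logrank_test(time, event, grp)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("maxstat equals the brute-force maximum over admissible cutpoints", {
  skip_if_not_installed("survival")
  for (s in 1:5) {
    cfg <- sim_config(seed = 900 + s, cohort = list(n_samples = 40))
    co <- simulate_cohort(cfg)
    sc <- network_activity_score(co$expr, co$signature)
    cp <- maxstat_cutpoint(sc, co$survival)
    ## oracle: scan every admissible cutpoint through survdiff
    idx <- match(co$survival$sample, names(sc))
    s_ord <- sc[idx]
    cands <- sort(unique(s_ord))
    n <- length(s_ord)
    zs <- sapply(cands, function(ct) {
      nlow <- sum(s_ord <= ct)
      if (nlow / n < 0.1 || nlow / n > 0.9) return(NA_real_)
      survdiff_abs_z(co$survival$time, co$survival$event, s_ord <= ct)
    })
    expect_equal(cp$statistic, max(zs, na.rm = TRUE), tolerance = 1e-8)
  }
})

test_that("the maximized statistic dominates any fixed median split", {
  for (s in 1:5) {
    co <- simulate_cohort(sim_config(seed = 950 + s,
                                     cohort = list(n_samples = 60)))
    sc <- network_activity_score(co$expr, co$signature)
    cp <- maxstat_cutpoint(sc, co$survival)
    med <- stats::median(sc)
    idx <- match(co$survival$sample, names(sc))
    z_med <- abs(logrank_test(co$survival$time, co$survival$event,
                              factor(ifelse(sc[idx] <= med, "low", "high"),
                                     levels = c("low", "high")))$z)
    expect_gte(cp$statistic + 1e-12, z_med)
  }
})

test_that("maxstat respects minprop and recovers a planted separation", {
  co <- simulate_cohort(sim_config(seed = 33))
  sc <- network_activity_score(co$expr, co$signature)
  expect_error(maxstat_cutpoint(sc, co$survival, minprop = 0.6),
               "minprop")

  cp <- maxstat_cutpoint(sc, co$survival)
  expect_true(all(table(cp$groups) >= 0.1 * length(sc)))
  expect_lt(cp$logrank$p_value, 0.01)
  ## high-activity group should have worse survival (positive hazard effect)
  expect_gt(cor(sc, co$truth$activity[names(sc)]), 0.9)
})

test_that("the naive p at the maximized cutpoint is anticonservative under the null", {
  ## with no true effect, the maximum over candidate splits rejects far
  ## more often than a prespecified median split -- the reason selected
  ## cutpoints need model-based inference alongside
  n_sim <- 200
  max_hits <- 0
  med_hits <- 0
  for (s in seq_len(n_sim)) {
    cfg <- sim_config(seed = 5000 + s, cohort = list(
      effect_beta = 0, n_samples = 60, n_signature_genes = 5,
      n_background_genes = 5))
    co <- simulate_cohort(cfg)
    sc <- network_activity_score(co$expr, co$signature)
    cp <- maxstat_cutpoint(sc, co$survival)
    if (cp$logrank$p_value < 0.05) max_hits <- max_hits + 1
    idx <- match(co$survival$sample, names(sc))
    med_grp <- factor(ifelse(sc[idx] <= stats::median(sc), "low", "high"),
                      levels = c("low", "high"))
    if (logrank_test(co$survival$time, co$survival$event,
                     med_grp)$p_value < 0.05) {
      med_hits <- med_hits + 1
    }
  }
  expect_gt(max_hits, med_hits)
  expect_gt(max_hits / n_sim, 0.15)
})

test_that("Kaplan-Meier tables are valid product-limit estimates", {
  co <- simulate_cohort(sim_config(seed = 44, cohort = list(n_samples = 50)))
  grp <- co$truth$group[co$survival$sample]
  km <- km_table(co$survival$time, co$survival$event, grp)
  for (g in unique(km$group)) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_equal(sum(km$n_events), sum(co$survival$event))
})
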