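test_that("planted scar counts are recovered exactly and errors fire", {
  toy <- toy_genome()
  sim0 <- simulate_scar_profile(toy, 0, 0, 0, seed = 1)
  m <- merge_equal_segments(sim0$profile)
  expect_true(all(m$major_cn == 1 & m$minor_cn == 1))
  sc0 <- scar_scores(sim0$profile, toy)
  expect_equal(c(sc0$loh, sc0$tai, sc0$lst), c(0, 0, 0))

  sim <- simulate_scar_profile(toy, 3, 2, 4, seed = 7)
  sc <- scar_scores(sim$profile, toy)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(3, 2, 4))
  # cross-check with the independent brute-force counters
  expect_equal(oracle_loh(sim$profile, toy), 3)
  expect_equal(oracle_tai(sim$profile, toy), 2)
  expect_equal(oracle_lst(sim$profile, toy), 4)

  expect_error(simulate_scar_profile(toy, 100, 0, 0, seed = 1),
               "cannot place")
  # TAI events need one arm each: toy genome has 10 arms
  expect_error(simulate_scar_profile(toy, 0, 11, 0, seed = 1),
               "cannot place")
})

test_that("generator profiles recover planted counts on a large genome", {
  g <- hg19_like_genome()
  for (s in 1:5) {
    k <- withr::with_seed(500 + s, sample(10:25, 3, replace = TRUE))
    sim <- simulate_scar_profile(g, k[1], k[2], k[3], seed = 600 + s)
    sc <- scar_scores(sim$profile, g)
    expect_equal(c(sc$loh, sc$tai, sc$lst), k, info = s)
  }
})

test_that("catalog simulation is multinomial, seeded and validated", {
  dict <- synthetic_signature_dictionary()
  w <- c(Signature_1 = 0.5, Signature_3 = 0.5)
  c1 <- simulate_catalog(dict, w, 1234, seed = 9)
  c2 <- simulate_catalog(dict, w, 1234, seed = 9)
  expect_identical(unclass(c1), unclass(c2))    # determinism contract
  expect_equal(sum(c1), 1234)                   # total preserved
  expect_error(simulate_catalog(dict, w, 0, seed = 1), "at least 1")
  expect_error(simulate_catalog(dict, c(Signature_1 = 0.5), 10, seed = 1),
               "sum to 1")
  # one-hot Signature_3 at n = 10000: refit recovers the weight
  c3 <- simulate_catalog(dict, c(Signature_3 = 1), 10000, seed = 2)
  fit <- fit_exposures(c3, dict)
  expect_gte(fit$s3_proportion, 0.98)
})

test_that("expression generator plants abundances exactly at zero noise", {
  panels <- list(
    P1 = gene_set("P1", paste0("A", 1:10)),
    P2 = gene_set("P2", paste0("B", 1:10)))
  ab <- matrix(c(4, 0, 2, 3), nrow = 2,
               dimnames = list(c("S1", "S2"), c("P1", "P2")))
  m <- simulate_expression(panels, ab, noise_sd = 0,
                           n_background_genes = 5, seed = 1)
  lg <- log2_transform(m)
  expect_equal(unname(lg["A1", ]), c(4, 0))     # log2(x+1) = abundance
  expect_equal(unname(lg["B5", ]), c(2, 3))
  expect_equal(unname(m["A1", "S2"]), 0)        # zero abundance -> 0
  # overlapping panels are rejected (identifiability)
  bad <- list(P1 = gene_set("P1", c("G1", "G2")),
              P2 = gene_set("P2", c("G2", "G3")))
  expect_error(simulate_expression(bad, ab, seed = 1), "share genes")
})

test_that("planted abundances are recovered within the CLT bound", {
  noise_sd <- 0.5
  panels <- list(P1 = gene_set("P1", paste0("A", 1:10)))
  ab <- matrix(withr::with_seed(3, runif(100, 1, 6)), ncol = 1,
               dimnames = list(sprintf("S%03d", 1:100), "P1"))
  m <- simulate_expression(panels, ab, noise_sd = noise_sd,
                           n_background_genes = 10, seed = 4)
  sc <- score_table(m, panels)
  mae <- mean(abs(sc$P1 - ab[, 1]))
  expect_lt(mae, 3 * noise_sd / sqrt(10))
})

test_that("survival generator matches exponential closed forms", {
  # beta = 0, no censoring: KM median ~ ln 2 / rate
  x <- data.frame(z = rep(0, 2000))
  sv <- simulate_survival(x, beta = 0, baseline_rate = 0.1,
                          censor_rate = 0, seed = 5)
  km <- km_estimate(sv$time, sv$event)
  expect_true(km$median_reached)
  expect_lt(abs(km$median - log(2) / 0.1) / (log(2) / 0.1), 0.1)
  # same seed, same draws
  sv2 <- simulate_survival(x, beta = 0, baseline_rate = 0.1,
                           censor_rate = 0, seed = 5)
  expect_identical(sv, sv2)
  # binary covariate with beta = ln 2: Cox recovers it
  xb <- data.frame(z = rep(c(0, 1), each = 500))
  svb <- simulate_survival(xb, beta = log(2), baseline_rate = 0.05,
                           censor_rate = 0.01, seed = 6)
  fit <- cox_fit(svb$time, svb$event, xb)
  expect_gte(fit$beta, 0.55)
  expect_lte(fit$beta, 0.85)
})

test_that("cohort bundles are reproducible, validated, empty-safe", {
  cfg <- default_cohort_config(20)
  b1 <- simulate_cohort(cfg, seed = 11)
  b2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(b1$truth, b2$truth)
  expect_identical(unclass(b1$catalogs), unclass(b2$catalogs))
  expect_identical(unclass(b1$expression), unclass(b2$expression))
  expect_identical(b1$clinical, b2$clinical)

  bad <- cfg
  bad$proportions <- c(BRCA_MUT = 0.5, WT_HRD_HIGH = 0.5, WT_HRD_LOW = 0.5)
  expect_error(simulate_cohort(bad, seed = 1), "sum to 1")

  empty <- default_cohort_config(0)
  b0 <- simulate_cohort(empty, seed = 1)
  expect_length(b0$profiles, 0L)
  expect_null(b0$truth)
})

test_that("well-separated scar tiers give exact WT group recovery", {
  cfg <- default_cohort_config(40)
  cfg$scar_range_high <- c(20, 25)
  cfg$scar_range_low <- c(0, 1)
  b <- simulate_cohort(cfg, seed = 21)
  scars <- scar_scores(b$profiles, b$genome)
  groups <- classify_samples(b$clinical, scars)
  wt <- b$truth$intended_group != "BRCA_MUT"
  agree <- mean(as.character(groups$group[wt]) ==
                  b$truth$intended_group[wt])
  expect_gte(agree, 0.99)
})
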