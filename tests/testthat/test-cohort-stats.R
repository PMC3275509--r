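test_that("Kruskal-Wallis H matches the independent rank formula", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H,
               oracle_kw_h(list(c(1, 2, 3), c(4, 5, 6))))
  # identically patterned groups: no evidence of a difference
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_gt(kruskal_wallis(g)$p_value, 0.9)
  # all values equal
  eq <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(eq$H, 0)
  expect_equal(eq$p_value, 1)
  # property: random small samples, with and without ties
  set.seed(17)
  for (i in 1:25) {
    sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
    vals <- sample(1:6, sum(sizes), replace = TRUE)  # ties likely
    if (length(unique(vals)) == 1L) next
    groups <- split(vals, rep(seq_along(sizes), sizes))
    expect_equal(kruskal_wallis(groups)$H, oracle_kw_h(groups),
                 tolerance = 1e-12)
  }
})

test_that("the observed H sits where exact enumeration puts it", {
  # {1,2,3} vs {4,5,6}: the most extreme split; 2 of the 20 assignments
  # reach this H, so the exact permutation tail is 0.1
  g <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(oracle_kw_exact_p(g), 0.1)
  expect_equal(kruskal_wallis(g)$H, oracle_kw_h(g))
})

test_that("Mann-Whitney U and exact p match brute-force enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)
  # swapping the samples maps U to m*n - U with the same p
  mw2 <- mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw2$U, 9)
  expect_equal(mw2$p_value, mw$p_value)
  # identical samples: no evidence, U = n^2/2 with ties split evenly
  mw3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$U, 4.5)
  expect_gt(mw3$p_value, 0.99)
  # property: exact p agrees with enumeration for tie-free combined n <= 10
  set.seed(19)
  for (i in 1:20) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    vals <- sample(1:50, m + n)  # distinct -> tie-free
    x <- vals[1:m]; y <- vals[(m + 1):(m + n)]
    mw <- mann_whitney(x, y)
    expect_true(mw$exact)
    expect_equal(mw$U, oracle_mw_u(x, y))
    expect_equal(mw$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches hand computation and is affine-invariant", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)
  # tissue-level means: collagen vs RCP loss across the five tissues
  collagen <- c(25, 45, 49, 43, 44)
  rcp <- c(34, 16, 18, 27, 17)
  r_hand <- sum((collagen - mean(collagen)) * (rcp - mean(rcp))) /
    sqrt(sum((collagen - mean(collagen))^2) * sum((rcp - mean(rcp))^2))
  pc <- pearson_correlation(collagen, rcp)
  expect_equal(pc$r, r_hand)
  expect_lt(abs(pc$r - (-0.87)), 0.01)
  expect_equal(pc$n, 5)
  # invariance under positive-slope affine maps of either argument
  set.seed(23)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_correlation(2.5 * x + 7, y)$r,
               pearson_correlation(x, y)$r, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 0.3 * y - 2)$r,
               pearson_correlation(x, y)$r, tolerance = 1e-12)
  # zero variance is undefined, not zero
  expect_true(pearson_correlation(rep(1, 5), 1:5)$undefined)
})

test_that("collagen correlations are pooled, signed, and validate ids", {
  sen <- sens_noiseless(hz = 1)
  co <- simulate_cohort(6, "relative", sen, seed = 41)
  metrics <- analyze_traces(co$traces)
  cc <- collagen_correlations(metrics, co$collagen)
  expect_setequal(unique(cc$scope), c("pooled", "tissue_mean"))
  pooled <- cc[cc$scope == "pooled", ]
  expect_equal(pooled$n, c(30L, 30L))
  expect_lt(pooled$r[pooled$variable == "collagen_vs_rcp_loss_pct"], 0)
  expect_gt(pooled$r[pooled$variable == "collagen_vs_plateau_ratio_pct"], 0)

  bad <- co$collagen[-1, ]
  expect_error(collagen_correlations(metrics, bad), "unmatched")
  # constant collagen: undefined, flagged
  const <- co$collagen; const$collagen_ug_per_mg <- 40
  cc2 <- collagen_correlations(metrics, const)
  expect_true(all(cc2$undefined[cc2$scope == "pooled"]))
})

test_that("tissue summary reproduces a zero-SD cohort's inputs exactly", {
  zp <- lapply(builtin_profiles(), zero_sd_profile)
  co <- simulate_cohort(6, "absolute", sens_pure(hz = 1), seed = 1,
                        profiles = zp)
  metrics <- analyze_traces(co$traces)
  fits <- fit_traces(co$traces)
  s <- summarize_by_tissue(metrics, fits, co$collagen)
  ts <- s$tissue_summary
  getm <- function(metric, tissue)
    ts$mean[ts$metric == metric & ts$tissue == tissue]
  # identical rows per tissue -> SD 0 everywhere it is defined
  expect_true(all(ts$sd[!is.na(ts$sd)] < 1e-9))
  # liver plateau row reads back the printed 0.9 N
  expect_lt(abs(getm("pplat", "liver") - 0.9), 0.01 * 2.6)
  expect_lt(abs(getm("p0", "stomach") - 2.9), 1e-6)
  expect_lt(abs(getm("decline_pct_per_min", "muscle") - 15), 0.2)
  expect_lt(abs(getm("collagen_ug_per_mg", "skin") - 45), 1e-9)
  # no variation within or between identical draws -> omnibus may be absent;
  # the report renders the all-censored skin half-time as a lower bound
  tab <- format_summary_table(s)
  expect_true(any(grepl("> 60", tab[grep("half of the tension", tab)])))
})

test_that("single-suture tissues report missing (not zero) SDs", {
  sen <- sens_noiseless(hz = 1, duration_s = 120)
  co <- simulate_cohort(1, "relative", sen, seed = 5)
  metrics <- analyze_traces(co$traces, record_s = 120)
  s <- summarize_by_tissue(metrics)
  expect_true(all(is.na(s$tissue_summary$sd)))
  expect_false(any(s$tissue_summary$sd %in% 0))
})
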