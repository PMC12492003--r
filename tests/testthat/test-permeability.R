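test_that("spherical geometry follows the closed forms and scaling laws", {
  g <- sphereGeometry(0.12)
  expect_equal(g@vo, pi * 0.12^3 / 6, tolerance = 1e-12)   # ~9.048e-4 cm^3
  expect_equal(g@s, pi * 0.12^2, tolerance = 1e-12)        # ~4.524e-2 cm^2
  for (d in c(0.05, 0.1, 0.2))
    expect_equal(sphereGeometry(d)@vo / sphereGeometry(d)@s, d / 6)
  g2 <- sphereGeometry(0.24)
  expect_equal(g2@vo / g@vo, 8)
  expect_equal(g2@s / g@s, 4)
  expect_error(sphereGeometry(-1), "positive")
})

test_that("unit conversions are lossless and consistent", {
  expect_equal(mosmToMolPerCm3(200), 2e-4)
  expect_equal(mmToMolPerCm3(180), 1.8e-4)
  x <- c(0.3, 100, 207.5)
  expect_equal(mosmToMolPerCm3(x) * 1e6, x)
})

test_that("initial-slope fitting is exact OLS", {
  t <- seq(0, 120, by = 0.5)
  expect_equal(fitInitialSlope(t, rep(1, length(t)))$slope, 0)
  expect_equal(fitInitialSlope(t, 1 + 1e-3 * t)$slope, 1e-3, tolerance = 1e-12)

  set.seed(51)
  y <- 1 + 2e-4 * t + rnorm(length(t), 0, 0.01)
  f <- fitInitialSlope(t, y, window = 60)
  sel <- t <= 60
  expect_equal(f$slope, oracleOLSSlope(t[sel], y[sel]), tolerance = 1e-12)
  expect_equal(f$window, 60)
  expect_error(fitInitialSlope(c(0, 1), c(1, 1)), ">= 3 points")

  # default window: first 60 s or first 20% of the trace
  expect_equal(defaultFitWindow(seq(0, 120, 1)), 24)
  expect_equal(defaultFitWindow(seq(0, 600, 1)), 60)
})

test_that("permeability formulas match hand arithmetic and are linear", {
  g <- oocyteGeometry(9.0e-4, 4.5e-2)
  wd <- waterAssayDesign(200, 100)       # gradient 1e-4 mol/cm^3
  expect_equal(pWater(0, g, wd)$value, 0)
  expect_equal(pWater(1e-3, g, wd)$value,
               (9e-4 * 1e-3) / (4.5e-2 * 18 * 1e-4), tolerance = 1e-12)
  expect_equal(pWater(1e-3, g, wd)$value, 1.111111e-2, tolerance = 1e-6)

  sd <- soluteAssayDesign("urea", 200, 180, 0)
  expect_equal(pSolute(0, g, sd)$value, 0)
  expect_equal(pSolute(5e-4, g, sd)$value, 1.111111e-5, tolerance = 1e-6)
  expect_equal(pSolute(5e-4, g, sd)$kind, "P_urea")

  # linear in slope and in V0/S
  expect_equal(pWater(2e-3, g, wd)$value, 2 * pWater(1e-3, g, wd)$value)
  g2 <- oocyteGeometry(2 * 9.0e-4, 4.5e-2)
  expect_equal(pWater(1e-3, g2, wd)$value, 2 * pWater(1e-3, g, wd)$value)

  expect_error(pWater(1e-3, g, sd), "water-mode")
  expect_error(pSolute(1e-3, g, wd), "solute-mode")
  expect_error(waterAssayDesign(200, 200), "gradient")
})

test_that("estimator bias grows monotonically with the fit window", {
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()
  tr <- simulateSwelling(g, wd, truePWater = 2e-2, duration = 200, dt = 0.02)
  errs <- sapply(c(20, 60, 120), function(w) {
    f <- fitInitialSlope(tr$time_s, tr$rel_volume, window = w)
    abs(pWater(f$slope, g, wd)$value - 2e-2) / 2e-2
  })
  expect_true(all(diff(errs) > 0))
})

test_that("trace tables are processed per oocyte", {
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()
  tr1 <- simulateSwelling(g, wd, truePWater = 5e-3, oocyteId = "o1",
                          constructId = "aqp")
  tr2 <- simulateSwelling(g, wd, truePWater = 1e-3, oocyteId = "o2",
                          constructId = "ctrl")
  est <- estimateTracePermeabilities(rbind(tr1, tr2), wd, g)
  expect_equal(nrow(est), 2L)
  expect_equal(est$value[est$oocyte_id == "o1"], 5e-3, tolerance = 0.05)
  expect_equal(est$value[est$oocyte_id == "o2"], 1e-3, tolerance = 0.05)
  expect_error(estimateTracePermeabilities(tr1[, 1:3], wd, g), "columns")
})

test_that("group comparison flags constant data and ranks a clear effect", {
  const <- compareGroups(rep(1, 12), rep(c("a", "b", "c"), each = 4), "a")
  expect_true(const$constant_data)
  expect_gte(const$anova_p, 0.99)

  # three groups, n = 5, means 0/0/5, sd 1: the shifted group is extreme
  set.seed(61)
  vals <- c(rnorm(5, 0, 1), rnorm(5, 0, 1), rnorm(5, 5, 1))
  grp <- rep(c("control", "g1", "g2"), each = 5)
  for (meth in c("holm_sidak", "dunnett")) {
    r <- compareGroups(vals, grp, "control", method = meth)
    expect_lt(r$anova_p, 1e-4)
    p2 <- r$comparisons$p_adj[grepl("^g2", r$comparisons$comparison)]
    expect_lt(p2, 1e-4)
    expect_equal(r$comparisons$tier[grepl("^g2", r$comparisons$comparison)],
                 "****")
  }
  tk <- compareGroups(vals, grp, "control", method = "tukey")
  expect_lt(min(tk$comparisons$p_adj), 1e-4)
  expect_error(compareGroups(vals[1:10], grp[1:10], "missing"), "not present")
})

test_that("adjusted p-values never fall below the raw p-values", {
  set.seed(62)
  for (i in 1:10) {
    vals <- rnorm(20)
    grp <- rep(c("control", "a", "b", "c"), each = 5)
    r <- compareGroups(vals, grp, "control", method = "holm_sidak")
    fit <- summary(stats::aov(vals ~ factor(grp)))[[1]]
    mse <- fit[2, "Mean Sq"]; dfr <- fit[2, "Df"]
    raw <- sapply(c("a", "b", "c"), function(gl) {
      tt <- (mean(vals[grp == gl]) - mean(vals[grp == "control"])) /
        sqrt(mse * (2 / 5))
      2 * stats::pt(-abs(tt), dfr)
    })
    ord <- match(paste(c("a", "b", "c"), "vs control"),
                 r$comparisons$comparison)
    expect_true(all(r$comparisons$p_adj[ord] >= raw - 1e-12))
  }
})

test_that("a 5-sd effect at n = 10 is detected with power above 0.9", {
  set.seed(63)
  hits <- replicate(100, {
    vals <- c(rnorm(10, 0, 1), rnorm(10, 5, 1))
    grp <- rep(c("control", "aqp"), each = 10)
    r <- compareGroups(vals, grp, "control", method = "holm_sidak")
    r$comparisons$p_adj[1] < 0.05
  })
  expect_gt(mean(hits), 0.9)
})
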