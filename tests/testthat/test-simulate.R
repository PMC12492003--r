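test_that("swelling simulator respects conservation and equilibrium", {
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()

  # no water permeability: flat trace
  flat <- simulateSwelling(g, wd, truePWater = 0)
  expect_equal(flat$rel_volume, rep(1, nrow(flat)))

  # hypoosmotic bath: strictly increasing approach to osmotic equilibrium
  tr <- simulateSwelling(g, wd, truePWater = 5e-3)
  expect_true(all(diff(tr$rel_volume) > 0))
  # asymptote: internal osmolality approaches the bath, so V/V0 tends to
  # osm_in/osm_out = 2; the relaxation time constant grows to
  # (V/S)/(Pw*Vw*osm_out) ~ 1100 s as the cell swells, hence the long run
  long <- simulateSwelling(g, wd, truePWater = 2e-2, duration = 8000,
                           dt = 0.2)
  expect_equal(tail(long$rel_volume, 1), 2, tolerance = 0.01)

  # solute mode with zero gradients and P_water = 0 conserves volume
  sd0 <- soluteAssayDesign("urea", 200, 180, 0)
  noflux <- simulateSwelling(g, sd0, truePWater = 0, truePSolute = 0,
                             duration = 60, dt = 0.1)
  expect_equal(noflux$rel_volume, rep(1, nrow(noflux)), tolerance = 1e-12)
})

test_that("integration is converged at the default step size", {
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()
  a <- simulateSwelling(g, wd, truePWater = 2e-2, dt = 0.01)
  b <- simulateSwelling(g, wd, truePWater = 2e-2, dt = 0.005)
  expect_lt(abs(tail(a$rel_volume, 1) - tail(b$rel_volume, 1)), 1e-6)

  sdes <- soluteAssayDesign("urea")
  a2 <- simulateSwelling(g, sdes, truePSolute = 1e-5, dt = 0.1)
  b2 <- simulateSwelling(g, sdes, truePSolute = 1e-5, dt = 0.05)
  expect_lt(abs(tail(a2$rel_volume, 1) - tail(b2$rel_volume, 1)), 1e-6)
})

test_that("swelling noise is seeded and reproducible", {
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()
  a <- simulateSwelling(g, wd, truePWater = 5e-3, noiseSd = 0.005, seed = 9)
  b <- simulateSwelling(g, wd, truePWater = 5e-3, noiseSd = 0.005, seed = 9)
  c <- simulateSwelling(g, wd, truePWater = 5e-3, noiseSd = 0.005, seed = 10)
  expect_identical(a$rel_volume, b$rel_volume)
  expect_false(identical(a$rel_volume, c$rel_volume))
  expect_error(simulateSwelling(g, wd, noiseSd = 0.005), "seed")
  expect_error(simulateSwelling(g, wd, dt = -1), "dt")
})

test_that("codon simulator honours degenerate settings", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulateCodonAlignment(phy, 50L, omega = 1, seed = 12)
  seqs <- as.character(alignedSeqs(sim$alignment))
  expect_true(all(seqs == sim$rootSequence))

  # omega = 0: no nonsynonymous event is ever accepted
  phy2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
  sim0 <- simulateCodonAlignment(phy2, 300L, omega = 0, seed = 13)
  expect_equal(sum(sim0$events$nonsyn), 0L)
  r <- ng86Pair(as.character(alignedSeqs(sim0$alignment)[[1]]),
                as.character(alignedSeqs(sim0$alignment)[[2]]))
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  # determinism and absence of stop codons
  simA <- simulateCodonAlignment(phy2, 100L, omega = 0.5, seed = 14)
  simB <- simulateCodonAlignment(phy2, 100L, omega = 0.5, seed = 14)
  expect_identical(as.character(alignedSeqs(simA$alignment)),
                   as.character(alignedSeqs(simB$alignment)))
  codons <- unlist(lapply(simA$nodeSequences, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
  expect_error(simulateCodonAlignment(phy2, 100L, omega = 0.5), "seed")
})

test_that("estimated dN/dS is calibrated near one for neutral simulations", {
  phy <- ape::read.tree(text = "(a:0.1,b:0.1);")
  ratios <- sapply(1:50, function(i) {
    sim <- simulateCodonAlignment(phy, 300L, omega = 1, kappa = 1,
                                  seed = 7000 + i)
    s <- as.character(alignedSeqs(sim$alignment))
    r <- ng86Pair(s[[1]], s[[2]])
    r$dN / r$dS
  })
  mc <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 1.96 * mc + 0.02)
})

test_that("fixture bundles are deterministic and internally consistent", {
  d1 <- file.path(tempdir(), "fxt1"); d2 <- file.path(tempdir(), "fxt2")
  m1 <- makeFixtureSuite(d1, seed = 5L)
  m2 <- makeFixtureSuite(d2, seed = 5L)
  for (f in setdiff(names(m1$paths), "manifest")) {
    expect_identical(readLines(m1$paths[[f]]), readLines(m2$paths[[f]]),
                     info = f)
  }

  # manifest truth round-trips through the permeability estimator
  traces <- utils::read.csv(m1$paths$traces)
  g <- sphereGeometry(0.12)
  wd <- waterAssayDesign()
  water <- traces[traces$assay == "water", ]
  est <- estimateTracePermeabilities(water, wd, g)
  truth <- fixturePermeabilityTruth <- m1$permeability_truth
  for (cid in c("AanAqp10.2b1", "AanAqp10.2b2", "SkaAqp10.2b")) {
    got <- mean(est$value[est$construct_id == cid])
    want <- truth$P_water[truth$construct_id == cid]
    expect_equal(got, want, tolerance = 0.25)
  }
  ud <- soluteAssayDesign("urea")
  urea <- traces[traces$assay == "urea", ]
  estU <- estimateTracePermeabilities(urea, ud, g)
  for (cid in c("AanAqp10.2b2", "AanAqp10.2b3")) {
    got <- mean(estU$value[estU$construct_id == cid])
    want <- truth$P_urea[truth$construct_id == cid]
    expect_equal(got, want, tolerance = 0.4)
  }
  # broad paralogs outpace the narrow one for urea
  expect_gt(mean(estU$value[estU$construct_id == "AanAqp10.2b2"]),
            5 * mean(estU$value[estU$construct_id == "AanAqp10.2b1"]))
})
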