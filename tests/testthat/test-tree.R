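test_that("transition probability matrices are proper and JC-exact", {
  m <- substModel("JC69")
  for (t in c(0, 0.05, 0.3, 2)) {
    P <- probMatrix(m, t)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
    expect_equal(P["A", "A"], oracleJCProb("A", "A", t), tolerance = 1e-12)
    expect_equal(P["A", "C"], oracleJCProb("A", "C", t), tolerance = 1e-12)
  }
  # TN93 keeps its equilibrium distribution
  tn <- substModel("TN93", freqs = c(0.35, 0.15, 0.2, 0.3),
                   kappa1 = 4, kappa2 = 7)
  P <- probMatrix(tn, 0.4)
  expect_equal(as.numeric(tn@freqs %*% P), unname(tn@freqs),
               tolerance = 1e-12)
  expect_error(probMatrix(m, -0.1), ">= 0")
})

test_that("pruning log-likelihood matches closed forms and is root-invariant", {
  m <- substModel("JC69")
  aln <- c(a = "ACGTAC", b = "ACGTAA")

  # single leaf: sum of log base frequencies
  single <- list(edge = matrix(nrow = 0, ncol = 2), tip.label = "a",
                 Nnode = 0L)
  class(single) <- "phylo"
  expect_equal(treeLogLik(single, aln, m), 6 * log(0.25))

  # two leaves, total path 0.1: 5 constant sites + 1 difference
  phy <- ape::read.tree(text = "(a:0.05,b:0.05);")
  t <- 0.1
  closed <- 5 * log(0.25 * oracleJCProb("A", "A", t)) +
    log(0.25 * oracleJCProb("C", "A", t))
  expect_equal(treeLogLik(phy, aln, m), closed, tolerance = 1e-10)

  # pulley principle: only the path length matters under a reversible model
  phy2 <- ape::read.tree(text = "(a:0.02,b:0.08);")
  expect_equal(treeLogLik(phy2, aln, m), treeLogLik(phy, aln, m),
               tolerance = 1e-10)

  neg <- ape::read.tree(text = "(a:-0.01,b:0.08);")
  expect_error(treeLogLik(neg, aln, m), "negative branch length")
})

test_that("pruning equals exhaustive enumeration on 4-leaf 3-site toys", {
  m <- substModel("JC69")
  bl <- c(a = 0.1, b = 0.25, c = 0.07, d = 0.4, u = 0.15)
  phy <- ape::read.tree(text = sprintf("((a:%g,b:%g):%g,(c:%g,d:%g):0);",
                                       bl["a"], bl["b"], bl["u"],
                                       bl["c"], bl["d"]))
  aln <- c(a = "ACT", b = "AGT", c = "TGT", d = "ACA")
  want <- sum(sapply(1:3, function(s) {
    st <- vapply(aln, function(x) substr(x, s, s), character(1))
    log(oracleQuartetLik(st, bl))
  }))
  expect_equal(treeLogLik(phy, aln, m), want, tolerance = 1e-10)
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  phy <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.05);")
  set.seed(31)
  aln <- vapply(1:4, function(i) randomDNA(60, 300 + i), character(1))
  names(aln) <- c("a", "b", "c", "d")
  got <- treeLogLik(phy, aln, substModel("JC69"))
  pd <- phangorn::phyDat(t(sapply(aln, function(s) strsplit(s, "")[[1]])),
                         type = "DNA")
  want <- phangorn::pml(phy, pd, model = "JC")$logLik
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("marginal ancestral states behave at fixed and symmetric sites", {
  m <- substModel("JC69")
  phy <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  aln <- c(a = "AC", b = "AC", c = "AC", d = "AG")
  anc <- ancestralStates(phy, aln, m)
  expect_equal(unname(rowSums(anc$posterior)), rep(1, 2))
  # all leaves agree at site 1: that base dominates
  expect_equal(which.max(anc$posterior[1, ]), c(A = 1L))
  expect_gt(anc$posterior[1, "A"], 0.9)

  # two-leaf symmetric case: exact tie, broken toward A, flagged
  tie <- ancestralStates(ape::read.tree(text = "(a:0.1,b:0.1);"),
                         c(a = "A", b = "C"), m)
  expect_equal(tie$posterior[1, "A"], tie$posterior[1, "C"])
  expect_true(tie$ties[1])
  expect_equal(tie$sequence, "A")

  expect_error(
    ancestralStates(ape::read.tree(text = "(a:1,b:1,c:1);"), aln, m),
    "rooted")
})

test_that("reconstruction recovers a simulated root sequence", {
  phy <- ape::read.tree(text = paste0(
    "((a:0.02,b:0.02):0.02,(c:0.02,d:0.02):0.02,(e:0.02,f:0.02):0.02);"))
  phy <- ape::root(phy, outgroup = c("e", "f"), resolve.root = TRUE)
  sim <- simulateCodonAlignment(phy, 200L, omega = 0.5, kappa = 2, seed = 77)
  model <- fitTN93(phy, alignedSeqs(sim$alignment))
  anc <- ancestralStates(phy, alignedSeqs(sim$alignment), model)
  expect_gt(pairwiseIdentity(anc$sequence, sim$rootSequence), 98)
})

test_that("NJ recovers additive trees exactly and never leaves negatives", {
  # forced 2-taxon split
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- njTree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))

  # additive 4-taxon matrix: exact topology and branch lengths
  true <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.4):0.05);")
  est <- njTree(ape::cophenetic.phylo(true))
  expect_equal(ape::dist.topo(ape::unroot(true), est), 0, ignore_attr = TRUE)
  expect_equal(sort(est$edge.length),
               sort(c(0.1, 0.2, 0.3, 0.4, 0.1)), tolerance = 1e-10)

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # negative NJ branches are clamped with the deficit moved next door
  set.seed(41)
  for (i in 1:5) {
    base <- ape::cophenetic.phylo(ape::rtree(6))
    noise <- matrix(stats::runif(36, 0, 0.4), 6)
    d <- base + noise + t(noise); diag(d) <- 0
    est <- njTree(d)
    expect_true(all(est$edge.length >= 0))
  }
})

test_that("the eel-like paralog clade stays monophyletic in the NJ tree", {
  fx <- aqpflux:::fixtureDnDsTree()
  sim <- simulateCodonAlignment(fx, 200L, omega = 0.2, kappa = 2, seed = 55)
  est <- njTree(jcDistanceMatrix(sim$alignment))
  rooted <- rootOnOutgroup(est, "Cco_aqp10.2b")
  anguilla <- setdiff(fx$tip.label, "Cco_aqp10.2b")
  node <- ape::getMRCA(rooted, anguilla)
  clade <- ape::extract.clade(rooted, node)
  expect_setequal(clade$tip.label, anguilla)
})
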