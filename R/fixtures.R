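# Synthetic study bundle: every input the pipeline consumes, generated
# with known ground truth.  All sequences and traces are synthetic; ids
# follow the eel Aqp10 naming (Aan = European eel, Aja = Japanese eel,
# Aro = American eel, Amm = giant mottled eel, Ska = Kaup's arrowtooth
# eel, Cco = European conger, Mcy = Indo-Pacific tarpon, Agl = roundjaw
# bonefish) so fixture output reads like study output.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# the broad/narrow filter panel the fixture plants (and the truth table
# the classifier must reproduce)
fixtureFilterPanel <- function() {
  data.frame(
    seq_id = c("McyAqp10.1a", "AglAqp10.1a",
               "McyAqp10.2b", "AglAqp10.2b", "CcoAqp10.2b", "SkaAqp10.2b",
               "AanAqp10.2b1", "AjaAqp10.2b1",
               "AanAqp10.2b2", "AanAqp10.2b3"),
    p1 = c("F", "F", "F", "F", "F", "F", "F", "F", "F", "F"),
    p2 = c("S", "S", "G", "G", "G", "G", "G", "G", "G", "G"),
    p3 = c("A", "A", "Y", "Y", "Y", "Y", "Y", "Y", "G", "G"),
    p4 = rep("R", 10),
    call = c("broad", "broad", "narrow", "narrow", "narrow", "narrow",
             "narrow", "narrow", "broad", "broad"),
    stringsAsFactors = FALSE)
}

# synthetic protein alignment carrying the filter panel; the reference
# (AanAqp10.2b1) is ungapped except for a 5-column insertion private to
# the Aqp10.1a sequences, so column mapping across gaps is exercised.
buildFilterAlignment <- function(seed) {
  panel <- fixtureFilterPanel()
  refLen <- 230L
  insertAfter <- 100L                       # ungapped ref position
  filterPos <- c(63L, 201L, 205L, 211L)     # ungapped ref positions
  withLocalSeed(seed, {
    backbone <- sample(AA20, refLen, replace = TRUE)
    seqs <- character(nrow(panel))
    for (i in seq_len(nrow(panel))) {
      s <- backbone
      mut <- sample(setdiff(seq_len(refLen), filterPos),
                    size = round(0.08 * refLen))
      s[mut] <- sample(AA20, length(mut), replace = TRUE)
      s[filterPos] <- unlist(panel[i, c("p1", "p2", "p3", "p4")])
      insert <- if (grepl("10\\.1a$", panel$seq_id[i]))
        sample(AA20, 5, replace = TRUE) else rep("-", 5)
      seqs[i] <- paste(c(s[1:insertAfter], insert,
                         s[(insertAfter + 1L):refLen]), collapse = "")
    }
    names(seqs) <- panel$seq_id
    Biostrings::AAStringSet(seqs)
  })
}

# permeability ground truth per construct (cm/s); controls are
# water-injected oocytes with residual membrane permeability
fixturePermeabilityTruth <- function() {
  data.frame(
    construct_id = c("control", "AanAqp10.2b1", "AanAqp10.2b2",
                     "AanAqp10.2b3", "SkaAqp10.2b", "CcoAqp10.2b",
                     "McyAqp10.2b"),
    P_water   = c(1e-3, 1.5e-2, 1.4e-2, 1.3e-2, 1.2e-2, 1.1e-2, 1.0e-2),
    P_glycerol = c(2e-7, 1.0e-5, 9e-6, 8e-6, 8e-6, 7e-6, 7e-6),
    P_urea     = c(2e-7, 5e-7, 1.0e-5, 9e-6, 6e-7, 6e-7, 5e-7),
    P_boric_acid = c(2e-7, 5e-7, 8e-6, 7e-6, 6e-7, 5e-7, 5e-7),
    stringsAsFactors = FALSE)
}

# two-group (Gp1 = Y-at-position-3 paralogs, Gp2 = G-at-position-3
# paralogs) Anguilla tree with a conger outgroup, branch lengths in
# candidate mutations per nucleotide site
fixtureDnDsTree <- function() {
  nwk <- paste0(
    "(((Aan_aqp10.2b1:0.020,Aja_aqp10.2b1:0.020):0.005,",
    "(Aro_aqp10.2b1:0.018,Amm_aqp10.2b1:0.018):0.007):0.030,",
    "((Aan_aqp10.2b2:0.012,Aan_aqp10.2b3:0.012):0.013,",
    "(Aja_aqp10.2b2:0.015,Aro_aqp10.2b2:0.015):0.010):0.030,",
    "Cco_aqp10.2b:0.110);")
  ape::read.tree(text = nwk)
}

fixtureGroups <- function() {
  c(Aan_aqp10.2b1 = "Gp1", Aja_aqp10.2b1 = "Gp1",
    Aro_aqp10.2b1 = "Gp1", Amm_aqp10.2b1 = "Gp1",
    Aan_aqp10.2b2 = "Gp2", Aan_aqp10.2b3 = "Gp2",
    Aja_aqp10.2b2 = "Gp2", Aro_aqp10.2b2 = "Gp2",
    Cco_aqp10.2b = "other")
}

# strict-clock dated tree emulating the six-sequence clock analysis;
# ages in Mya, calibration: tarpon vs the rest at 175
fixtureClockAges <- function() {
  list(root = 175, ska_split = 120, cco_split = 100,
       b1_split = 16.2, b2b3_split = 3.2, rate = 1.5e-3)  # rate: subs/site/My
}

fixtureClockTree <- function() {
  a <- fixtureClockAges()
  r <- a$rate
  bl <- function(parentAge, childAge) (parentAge - childAge) * r
  nwk <- sprintf(
    paste0("(Mcy_aqp10.2b:%g,(Ska_aqp10.2b:%g,(Cco_aqp10.2b:%g,",
           "(Aan_aqp10.2b1:%g,(Aan_aqp10.2b2:%g,Aan_aqp10.2b3:%g):%g):%g",
           "):%g):%g);"),
    175 * r, 120 * r, 100 * r,
    a$b1_split * r, a$b2b3_split * r, a$b2b3_split * r,
    bl(a$b1_split, a$b2b3_split), bl(a$cco_split, a$b1_split),
    bl(a$ska_split, a$cco_split), bl(a$root, a$ska_split))
  ape::read.tree(text = nwk)
}

#' Generate the on-disk synthetic study bundle
#'
#' Writes every input the pipeline needs, with ground truth recorded in a
#' manifest: (i) a 10-sequence protein alignment carrying the broad/narrow
#' ar/R filter panel, (ii) noisy swelling traces for six Aqp10 constructs
#' plus water-injected controls under the hypoosmotic and 180 mM
#' glycerol/urea/boric-acid designs, (iii) a two-group codon alignment
#' with contrasting dN/dS plus its tree and group labels, and (iv) a
#' strict-clock codon alignment for calibration dating.  A ready-to-run
#' pipeline config is emitted alongside.  Byte-identical for a given seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving every stochastic component.
#' @param nOocytes oocytes per construct and assay (default 3).
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}); \code{$paths} lists all files.
#' @export
makeFixtureSuite <- function(dir, seed = 1L, nOocytes = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create '%s'", dir))
  paths <- list(
    filters = file.path(dir, "filters.fasta"),
    traces = file.path(dir, "traces.csv"),
    design = file.path(dir, "design.yaml"),
    codons = file.path(dir, "codons.fasta"),
    groups = file.path(dir, "groups.tsv"),
    tree = file.path(dir, "tree.nwk"),
    clockCodons = file.path(dir, "clock_codons.fasta"),
    clockTree = file.path(dir, "clock_tree_true.nwk"),
    config = file.path(dir, "pipeline_config.yaml"),
    manifest = file.path(dir, "manifest.json"))

  ## 1. ar/R filter alignment
  aln <- buildFilterAlignment(deriveSeed(seed, 1L))
  writeFasta(aln, paths$filters)

  ## 2. swelling traces + design
  geom <- sphereGeometry(0.12)
  truth <- fixturePermeabilityTruth()
  designs <- list(
    water = waterAssayDesign(200, 100),
    glycerol = soluteAssayDesign("glycerol"),
    urea = soluteAssayDesign("urea"),
    boric_acid = soluteAssayDesign("boric_acid"))
  rows <- list()
  stream <- 100L
  for (assay in names(designs)) {
    des <- designs[[assay]]
    for (ci in seq_len(nrow(truth))) {
      for (oo in seq_len(nOocytes)) {
        stream <- stream + 1L
        tr <- simulateSwelling(
          geom, des,
          truePWater = if (des@mode == "water") truth$P_water[ci] else Inf,
          truePSolute = if (des@mode == "water") 0
                        else truth[[paste0("P_", assay)]][ci],
          dt = if (des@mode == "water") 0.05 else 0.5,
          duration = if (des@mode == "water") 120 else 600,
          noiseSd = 0.005, seed = deriveSeed(seed, stream),
          oocyteId = sprintf("%s_%s_o%d", truth$construct_id[ci], assay, oo),
          constructId = truth$construct_id[ci])
        keep <- seq(1L, nrow(tr), by = if (des@mode == "water") 10L else 4L)
        tr <- tr[keep, ]
        tr$assay <- assay
        rows[[length(rows) + 1L]] <- tr
      }
    }
  }
  traces <- do.call(rbind, rows)
  utils::write.csv(traces, paths$traces, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    geometry = list(diameter_cm = 0.12),
    assays = list(
      water = list(mode = "water", osm_in_mosm = 200, osm_out_mosm = 100),
      glycerol = list(mode = "solute", solute = "glycerol",
                      osm_total_mosm = 200, sol_out_mm = 180, sol_in_mm = 0),
      urea = list(mode = "solute", solute = "urea",
                  osm_total_mosm = 200, sol_out_mm = 180, sol_in_mm = 0),
      boric_acid = list(mode = "solute", solute = "boric_acid",
                        osm_total_mosm = 200, sol_out_mm = 180,
                        sol_in_mm = 0))), paths$design)

  ## 3. two-group codon alignment (dN/dS contrast) + outgroup
  dtree <- fixtureDnDsTree()
  groups <- fixtureGroups()
  om <- edgeOmegaForClade(
    dtree, names(groups)[groups == "Gp2"], 0.51, 0.06)
  sim <- simulateCodonAlignment(dtree, nCodons = 174L, omega = om,
                                kappa = 2, seed = deriveSeed(seed, 2L))
  writeFasta(alignedSeqs(sim$alignment), paths$codons)
  utils::write.table(
    data.frame(seq_id = names(groups), group = unname(groups)),
    paths$groups, sep = "\t", row.names = FALSE, quote = FALSE)
  ape::write.tree(dtree, paths$tree)

  ## 4. strict-clock codon alignment
  ctree <- fixtureClockTree()
  csim <- simulateCodonAlignment(ctree, nCodons = 325L, omega = 0.25,
                                 kappa = 2, seed = deriveSeed(seed, 3L))
  writeFasta(alignedSeqs(csim$alignment), paths$clockCodons)
  ape::write.tree(ctree, paths$clockTree)

  ## 5. pipeline config
  cfg <- list(
    version = 1L,
    stages = c("permeability", "arr", "dnds", "clock"),
    # paths relative to the config file: the bundle is relocatable and
    # byte-identical for a given seed wherever it is written
    inputs = list(traces = basename(paths$traces),
                  design = basename(paths$design),
                  filters = basename(paths$filters),
                  codons = basename(paths$codons),
                  groups = basename(paths$groups),
                  clock_codons = basename(paths$clockCodons)),
    params = list(window = NULL, posthoc = "holm_sidak",
                  control = "control",
                  filter_reference = "AanAqp10.2b1",
                  filter_positions = c(63L, 201L, 205L, 211L),
                  outgroup = "Cco_aqp10.2b",
                  ancestor_label = "N20",
                  group_a = "Gp1", group_b = "Gp2",
                  n_boot = 500L,
                  calibration_tips = c("Mcy_aqp10.2b", "Aan_aqp10.2b1"),
                  calibration_age = 175),
    seeds = list(bootstrap = deriveSeed(seed, 4L)))
  yaml::write_yaml(cfg, paths$config)

  manifest <- list(
    seed = seed,
    filter_truth = fixtureFilterPanel(),
    filter_spec = list(reference = "AanAqp10.2b1",
                       positions = c(63L, 201L, 205L, 211L)),
    permeability_truth = truth,
    swelling = list(noise_sd = 0.005, n_oocytes = nOocytes,
                    diameter_cm = 0.12,
                    water = list(dt = 0.05, duration = 120, thin = 10),
                    solute = list(dt = 0.5, duration = 600, thin = 4)),
    dnds = list(n_codons = 174L, kappa = 2,
                omega_gp1 = 0.06, omega_gp2 = 0.51,
                groups = as.list(groups),
                root_sequence = sim$rootSequence),
    clock = c(fixtureClockAges(), list(n_codons = 325L, omega = 0.25)),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(paths = paths)))
}
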