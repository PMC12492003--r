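# Configuration-driven orchestration: permeability, filter annotation,
# dN/dS against a reconstructed ancestor, and clock dating, with a
# machine-readable run manifest.

pipelineStageNames <- c("permeability", "arr", "dnds", "clock")

validateRunConfig <- function(cfg) {
  for (field in c("stages", "inputs"))
    if (is.null(cfg[[field]]))
      stop(sprintf("config is missing required field '%s'", field))
  bad <- setdiff(cfg$stages, pipelineStageNames)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  need <- list(permeability = c("traces", "design"),
               arr = "filters",
               dnds = c("codons", "groups"),
               clock = "clock_codons")
  for (st in cfg$stages) {
    for (inp in need[[st]]) {
      p <- cfg$inputs[[inp]]
      if (is.null(p))
        stop(sprintf("config is missing input '%s' (needed by stage '%s')",
                     inp, st))
      if (!file.exists(p))
        stop(sprintf("input '%s' does not exist: %s", inp, p))
    }
  }
  if ("dnds" %in% cfg$stages) {
    nb <- cfg$params$n_boot
    if (!is.null(nb) && nb > 0 && is.null(cfg$seeds$bootstrap))
      stop("config is missing field 'seeds$bootstrap' (dnds bootstrap)")
  }
  invisible(cfg)
}

readDesignYaml <- function(path) {
  y <- yaml::read_yaml(path)
  designs <- lapply(y$assays, function(a) {
    if (a$mode == "water")
      waterAssayDesign(a$osm_in_mosm, a$osm_out_mosm)
    else
      soluteAssayDesign(a$solute, a$osm_total_mosm, a$sol_out_mm,
                        a$sol_in_mm %||% 0)
  })
  list(geometry = sphereGeometry(y$geometry$diameter_cm), designs = designs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stagePermeability <- function(cfg, outDir) {
  traces <- utils::read.csv(cfg$inputs$traces)
  dz <- readDesignYaml(cfg$inputs$design)
  byAssay <- if ("assay" %in% names(traces)) split(traces, traces$assay)
             else stats::setNames(list(traces), names(dz$designs)[1])
  perOocyte <- list(); stats <- list()
  for (assay in names(byAssay)) {
    des <- dz$designs[[assay]]
    if (is.null(des)) stop(sprintf("no design for assay '%s'", assay))
    est <- estimateTracePermeabilities(byAssay[[assay]], des, dz$geometry,
                                       window = cfg$params$window)
    est$assay <- assay
    perOocyte[[assay]] <- est
    cg <- compareGroups(est$value, est$construct_id,
                        controlId = cfg$params$control %||% "control",
                        method = cfg$params$posthoc %||% "holm_sidak")
    cmp <- cg$comparisons
    if (nrow(cmp)) cmp$assay <- assay
    stats[[assay]] <- list(anova_F = cg$anova_F, anova_p = cg$anova_p,
                           comparisons = cmp)
  }
  res <- do.call(rbind, perOocyte)
  rownames(res) <- NULL
  utils::write.table(res, file.path(outDir, "permeability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- do.call(rbind, lapply(split(res, list(res$assay, res$construct_id)),
    function(d) data.frame(assay = d$assay[1], construct_id = d$construct_id[1],
                           kind = d$kind[1], n = nrow(d),
                           mean = mean(d$value), sd = stats::sd(d$value))))
  rownames(summ) <- NULL
  utils::write.table(summ, file.path(outDir, "permeability_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(per_oocyte = res, summary = summ, stats = stats)
}

stageArr <- function(cfg, outDir) {
  aln <- parseFasta(cfg$inputs$filters, alphabet = "protein")
  spec <- filterSpec(cfg$params$filter_reference %||% "AanAqp10.2b1",
                     cfg$params$filter_positions %||% c(63L, 201L, 205L, 211L))
  filt <- extractFilters(aln, spec)
  utils::write.table(filt, file.path(outDir, "arr_filters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  filt
}

stageDnDs <- function(cfg, outDir) {
  seqs <- parseFasta(cfg$inputs$codons, alphabet = "nucleotide")
  groupsTab <- utils::read.table(cfg$inputs$groups, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  groups <- stats::setNames(groupsTab$group, groupsTab$seq_id)
  aln <- removeGapCodons(codonAlignment(seqs))
  # NJ on JC distances, rooted at the outgroup
  phy <- njTree(jcDistanceMatrix(aln))
  outgroup <- cfg$params$outgroup
  if (is.null(outgroup)) stop("config is missing field 'params$outgroup'")
  phy <- rootOnOutgroup(phy, outgroup)
  # marginal ML ancestor of the ingroup under fitted TN93
  model <- fitTN93(phy, alignedSeqs(aln))
  ingroup <- setdiff(phy$tip.label, outgroup)
  node <- ape::getMRCA(phy, ingroup)
  anc <- ancestralStates(phy, alignedSeqs(aln), model, node = node)
  ancLabel <- cfg$params$ancestor_label %||% "N20"
  seqsAll <- c(as.character(alignedSeqs(aln)),
               stats::setNames(anc$sequence, ancLabel))
  alnAll <- codonAlignment(seqsAll)
  groups[ancLabel] <- ancLabel
  nb <- cfg$params$n_boot %||% 500L
  res <- lapply(c(cfg$params$group_a %||% "Gp1", cfg$params$group_b %||% "Gp2"),
    function(gp) {
      r <- groupMeanDnDs(alnAll, groups, ancLabel, gp, nBoot = nb,
                         seed = cfg$seeds$bootstrap)
      data.frame(group_a = ancLabel, group_b = gp, dN = r$dN, dS = r$dS,
                 dN_se = r$dN_se, dS_se = r$dS_se, ratio = r$ratio,
                 n_boot = r$nBoot)
    })
  res <- do.call(rbind, res)
  utils::write.table(res, file.path(outDir, "dnds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeFasta(stats::setNames(anc$sequence, ancLabel),
             file.path(outDir, "ancestor.fasta"))
  list(table = res, ancestor = anc$sequence, model = model, tree = phy)
}

stageClock <- function(cfg, outDir) {
  seqs <- parseFasta(cfg$inputs$clock_codons, alphabet = "nucleotide")
  aln <- removeGapCodons(codonAlignment(seqs))
  phy <- njTree(jcDistanceMatrix(aln))
  calTips <- cfg$params$calibration_tips
  calAge <- cfg$params$calibration_age
  if (is.null(calTips) || is.null(calAge))
    stop("config is missing field 'params$calibration_tips'/'calibration_age'")
  # the calibration pair's split is taken as the root
  phy <- rootOnOutgroup(phy, calTips[1])
  tt <- dateTree(phy, calTips, calAge)
  writeTimeTree(tt, file.path(outDir, "timetree.nwk"))
  ntip <- ape::Ntip(tt@phy)
  ages <- data.frame(node = (ntip + 1L):(ntip + tt@phy$Nnode),
                     age_mya = tt@ages[(ntip + 1L):(ntip + tt@phy$Nnode)])
  utils::write.table(ages, file.path(outDir, "node_ages.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(timetree = tt, ages = ages)
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in dependency order and writes per-stage
#' outputs plus a run manifest (input checksums, seeds, parameters,
#' package version, output checksums) to the output directory.  Identical
#' config and inputs give identical outputs and manifests.
#'
#' @param config path to a YAML/JSON config file, or an equivalent named
#'   list.  Required fields: \code{stages} (subset of "permeability",
#'   "arr", "dnds", "clock"), \code{inputs} (paths keyed \code{traces},
#'   \code{design}, \code{filters}, \code{codons}, \code{groups},
#'   \code{clock_codons} as required by the stages), optional
#'   \code{params} and \code{seeds} (\code{seeds$bootstrap} is required
#'   when the dnds stage bootstraps).
#' @param outDir output directory (default: \code{config$out}, or
#'   \code{tempfile()}).
#' @return A run report: list with one element per executed stage plus
#'   \code{manifest}, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- if (is.character(config)) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                       simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  if (is.character(config)) {
    # input paths in a config file are relative to that file
    base <- dirname(normalizePath(config))
    cfg$inputs <- lapply(cfg$inputs, function(p) {
      if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p
      else file.path(base, p)
    })
  }
  validateRunConfig(cfg)
  outDir <- outDir %||% cfg$out %||% tempfile("aqpflux_run_")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  runners <- list(permeability = stagePermeability, arr = stageArr,
                  dnds = stageDnDs, clock = stageClock)
  for (st in intersect(pipelineStageNames, cfg$stages)) {
    message(sprintf("[aqpflux] stage %s ...", st))
    report[[st]] <- tryCatch(runners[[st]](cfg, outDir),
      error = function(e) stop(sprintf("stage '%s' failed: %s",
                                       st, conditionMessage(e)), call. = FALSE))
  }
  usedInputs <- unlist(cfg$inputs[!vapply(cfg$inputs, is.null, logical(1))])
  outFiles <- setdiff(list.files(outDir, full.names = TRUE),
                      file.path(outDir, "run_manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("aqpflux")),
    stages = cfg$stages,
    params = cfg$params,
    seeds = cfg$seeds,
    input_md5 = as.list(stats::setNames(tools::md5sum(usedInputs),
                                        basename(usedInputs))),
    output_md5 = as.list(stats::setNames(tools::md5sum(outFiles),
                                         basename(outFiles))))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest <- manifest
  report$out_dir <- outDir
  invisible(report)
}
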