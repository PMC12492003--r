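# Central S4 containers. Trees stay `ape::phylo` (the field's standard);
# sequence sets stay Biostrings XStringSet; these classes add the
# assay/analysis metadata the estimators need.

setOldClass("phylo")

#' CodonAlignment: a frame-aware, gap-aware nucleotide alignment
#'
#' Wraps a \code{Biostrings::DNAStringSet} whose members all have equal
#' width divisible by 3, with the reading frame anchored at column 1.
#'
#' @slot seqs A \code{DNAStringSet} of aligned coding sequences.
#' @export
setClass("CodonAlignment", representation(seqs = "ANY"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  if (!methods::is(s, "DNAStringSet"))
    return("'seqs' must be a DNAStringSet")
  if (length(s) < 1L) return("alignment needs at least one sequence")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L)
    return("all sequences must have identical aligned length")
  if (w[1] %% 3L != 0L)
    return(sprintf("aligned length (%d) is not a multiple of 3", w[1]))
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("sequences must carry unique names")
  bad <- grepl("[^ACGTN-]", toupper(as.character(s)))
  if (any(bad))
    return(sprintf("sequence '%s' contains characters outside {A,C,G,T,N,-}",
                   names(s)[which(bad)[1]]))
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param seqs A named \code{DNAStringSet}, named character vector, or list
#'   of equal-length aligned coding sequences (frame anchored at column 1).
#' @return A \code{\linkS4class{CodonAlignment}}.
#' @examples
#' codonAlignment(c(a = "ATGAAA", b = "ATGAAG"))
#' @export
codonAlignment <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  else
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  methods::new("CodonAlignment", seqs = seqs)
}

#' @describeIn codonAlignment Number of codon columns.
#' @param x A \code{CodonAlignment}.
#' @export
nCodons <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  Biostrings::width(x@seqs)[1] %/% 3L
}

#' @describeIn codonAlignment The underlying \code{DNAStringSet}.
#' @export
alignedSeqs <- function(x) {
  stopifnot(methods::is(x, "CodonAlignment"))
  x@seqs
}

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequences x %d codons (%d nt columns)\n",
              length(object@seqs), nCodons(object),
              Biostrings::width(object@seqs)[1]))
  ids <- names(object@seqs)
  cat("  ", paste(utils::head(ids, 6), collapse = ", "),
      if (length(ids) > 6) ", ..." else "", "\n", sep = "")
})

#' FilterSpec: where the ar/R selectivity filter sits in a reference
#'
#' Anchors the four aromatic/arginine constriction residues to 1-based
#' positions in the \emph{ungapped} reference sequence; alignment columns
#' are then derived with \code{\link{mapFilterColumns}}.
#'
#' @slot referenceId id of the reference sequence in the alignment.
#' @slot positions strictly increasing integer vector of length 4, 1-based
#'   residue indices in the ungapped reference.
#' @export
setClass("FilterSpec",
         representation(referenceId = "character", positions = "integer"))

setValidity("FilterSpec", function(object) {
  p <- object@positions
  if (length(object@referenceId) != 1L || !nzchar(object@referenceId))
    return("'referenceId' must be a single non-empty id")
  if (length(p) != 4L) return("'positions' must have length 4")
  if (any(p < 1L)) return("positions are 1-based and must be >= 1")
  if (any(diff(p) <= 0L)) return("positions must be strictly increasing")
  TRUE
})

#' Construct a FilterSpec
#'
#' @param referenceId id of the reference sequence.
#' @param positions four strictly increasing 1-based ungapped residue
#'   indices (filter positions 1--4).
#' @return A \code{\linkS4class{FilterSpec}}.
#' @export
filterSpec <- function(referenceId, positions) {
  methods::new("FilterSpec", referenceId = as.character(referenceId),
               positions = as.integer(positions))
}

#' Default ar/R filter anchor for Anguilla Aqp10.2b1
#'
#' Position 3 of the filter is residue 205 of AanAqp10.2b1 (the residue
#' replaced in the urea-permeable Y205G mutant).  Positions 1, 2 and 4 are
#' package defaults recorded here (and in fixture manifests) rather than
#' hard-coded in analysis functions; override them when annotating real
#' alignments against a structurally determined anchor.
#'
#' @param referenceId reference sequence id (default "AanAqp10.2b1").
#' @return A \code{\linkS4class{FilterSpec}}.
#' @export
filterSpecDefault <- function(referenceId = "AanAqp10.2b1") {
  filterSpec(referenceId, c(63L, 201L, 205L, 211L))
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec: reference '%s', ungapped positions %s\n",
              object@referenceId, paste(object@positions, collapse = ", ")))
})

#' Enzyme: a restriction endonuclease with an IUPAC recognition pattern
#'
#' @slot name enzyme name.
#' @slot recognition IUPAC nucleotide pattern on the top strand.
#' @slot cutOffset 0-based offset within the pattern after which the top
#'   strand is cut (0 .. nchar(recognition)).
#' @export
setClass("Enzyme",
         representation(name = "character", recognition = "character",
                        cutOffset = "integer"))

setValidity("Enzyme", function(object) {
  pat <- toupper(object@recognition)
  if (!nzchar(pat)) return("empty recognition pattern")
  if (grepl("[^ACGTRYSWKMBDHVN]", pat))
    return("recognition pattern must use IUPAC nucleotide codes")
  if (object@cutOffset < 0L || object@cutOffset > nchar(pat))
    return("cutOffset must lie within [0, pattern length]")
  TRUE
})

#' Construct an Enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition pattern, cut position optionally
#'   marked with "^" (overrides \code{cutOffset}).
#' @param cutOffset 0-based top-strand cut offset within the pattern.
#' @return An \code{\linkS4class{Enzyme}}.
#' @examples
#' enzyme("NcoI", "C^CATGG")
#' enzyme("BglI", "GCCNNNN^NGGC")
#' @export
enzyme <- function(name, recognition, cutOffset = NA_integer_) {
  recognition <- toupper(recognition)
  if (grepl("^", recognition, fixed = TRUE)) {
    cutOffset <- regexpr("^", recognition, fixed = TRUE)[1] - 1L
    recognition <- sub("^", "", recognition, fixed = TRUE)
  }
  if (is.na(cutOffset))
    stop("cut position must be given via '^' in the pattern or 'cutOffset'")
  methods::new("Enzyme", name = name, recognition = recognition,
               cutOffset = as.integer(cutOffset))
}

#' Enzymes used to discriminate eel aqp10.2b paralog amplicons
#'
#' NcoI (C^CATGG) cuts RT-PCR products derived from aqp10.2b1; BglI
#' (GCCNNNN^NGGC) cuts those derived from aqp10.2b2.
#'
#' @return Named list of \code{\linkS4class{Enzyme}} objects.
#' @export
knownEnzymes <- function() {
  list(NcoI = enzyme("NcoI", "C^CATGG"),
       BglI = enzyme("BglI", "GCCNNNN^NGGC"))
}

setMethod("show", "Enzyme", function(object) {
  pat <- object@recognition
  cat(sprintf("Enzyme %s: %s^%s\n", object@name,
              substr(pat, 1, object@cutOffset),
              substr(pat, object@cutOffset + 1L, nchar(pat))))
})

#' OocyteGeometry: initial volume and surface area of an oocyte
#'
#' @slot vo initial volume, cm^3.
#' @slot s initial surface area, cm^2.
#' @slot diameter source diameter, cm (NA when volume/area given directly).
#' @export
setClass("OocyteGeometry",
         representation(vo = "numeric", s = "numeric", diameter = "numeric"))

setValidity("OocyteGeometry", function(object) {
  if (object@vo <= 0 || object@s <= 0)
    return("volume and surface area must be positive")
  TRUE
})

#' Oocyte geometry from a sphere diameter
#'
#' Assumes spherical geometry: \eqn{V_o = \pi d^3/6}, \eqn{S = \pi d^2},
#' hence \eqn{V_o/S = d/6}.
#'
#' @param diameter oocyte diameter in cm (a stage V--VI Xenopus oocyte is
#'   about 0.12 cm).
#' @return An \code{\linkS4class{OocyteGeometry}}.
#' @examples
#' sphereGeometry(0.12)
#' @export
sphereGeometry <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("'diameter' must be a single positive number (cm)")
  methods::new("OocyteGeometry",
               vo = pi * diameter^3 / 6,
               s  = pi * diameter^2,
               diameter = diameter)
}

#' @describeIn sphereGeometry Geometry from explicit volume and area.
#' @param vo initial volume, cm^3.
#' @param s initial surface area, cm^2.
#' @export
oocyteGeometry <- function(vo, s) {
  methods::new("OocyteGeometry", vo = vo, s = s, diameter = NA_real_)
}

setMethod("show", "OocyteGeometry", function(object) {
  cat(sprintf("OocyteGeometry: V0 = %.4g cm^3, S = %.4g cm^2%s\n",
              object@vo, object@s,
              if (is.na(object@diameter)) ""
              else sprintf(" (d = %g cm)", object@diameter)))
})

#' AssayDesign: bath composition for a swelling assay
#'
#' Concentrations are stored in the canonical flux units mol/cm^3.
#' Constructors accept the bench units (mOsmol/kg and mM); for dilute
#' aqueous solutions 1 mOsmol/kg = 1 mM = 1e-6 mol/cm^3.
#'
#' @slot mode "water" (hypoosmotic shock) or "solute" (iso-osmotic bath with
#'   a permeant solute gradient).
#' @slot osmIn,osmOut internal/external osmolality, mol/cm^3.
#' @slot osmTotal total system osmolality (solute mode), mol/cm^3.
#' @slot solIn,solOut internal/external permeant solute, mol/cm^3.
#' @slot soluteName "glycerol", "urea" or "boric_acid" ("" in water mode).
#' @export
setClass("AssayDesign",
         representation(mode = "character", osmIn = "numeric",
                        osmOut = "numeric", osmTotal = "numeric",
                        solIn = "numeric", solOut = "numeric",
                        soluteName = "character"))

setValidity("AssayDesign", function(object) {
  if (!object@mode %in% c("water", "solute"))
    return("mode must be 'water' or 'solute'")
  if (object@mode == "water" && object@osmIn == object@osmOut)
    return("water mode requires an osmotic gradient (osmIn != osmOut)")
  if (object@mode == "solute") {
    if (object@solIn == object@solOut)
      return("solute mode requires a solute gradient (solIn != solOut)")
    if (object@osmTotal <= 0)
      return("solute mode requires osmTotal > 0")
  }
  TRUE
})

#' Water-transport assay design (hypoosmotic shock)
#'
#' Mirrors the standard oocyte protocol: incubation in full-strength ND96
#' (about 200 mOsmol/kg) then transfer to 2-fold diluted ND96 (about
#' 100 mOsmol/kg).
#'
#' @param osmInMosm internal (pre-shock) osmolality, mOsmol/kg.
#' @param osmOutMosm bath osmolality after transfer, mOsmol/kg.
#' @return An \code{\linkS4class{AssayDesign}}.
#' @export
waterAssayDesign <- function(osmInMosm = 200, osmOutMosm = 100) {
  methods::new("AssayDesign", mode = "water",
               osmIn = mosmToMolPerCm3(osmInMosm),
               osmOut = mosmToMolPerCm3(osmOutMosm),
               osmTotal = NA_real_, solIn = 0, solOut = 0,
               soluteName = "")
}

#' Solute-transport assay design (iso-osmotic solute bath)
#'
#' ND96 with NaCl partly replaced by 180 mM glycerol, urea or boric acid,
#' adjusted to the system osmolality (about 200 mOsmol/kg), so there is a
#' solute gradient but no initial osmotic gradient.
#'
#' @param solute "glycerol", "urea" or "boric_acid".
#' @param osmTotalMosm total system osmolality, mOsmol/kg.
#' @param solOutMm external permeant solute, mM.
#' @param solInMm internal permeant solute, mM.
#' @return An \code{\linkS4class{AssayDesign}}.
#' @export
soluteAssayDesign <- function(solute = c("glycerol", "urea", "boric_acid"),
                              osmTotalMosm = 200, solOutMm = 180,
                              solInMm = 0) {
  solute <- match.arg(solute)
  methods::new("AssayDesign", mode = "solute",
               osmIn = mosmToMolPerCm3(osmTotalMosm),
               osmOut = mosmToMolPerCm3(osmTotalMosm),
               osmTotal = mosmToMolPerCm3(osmTotalMosm),
               solIn = mmToMolPerCm3(solInMm),
               solOut = mmToMolPerCm3(solOutMm),
               soluteName = solute)
}

setMethod("show", "AssayDesign", function(object) {
  if (object@mode == "water")
    cat(sprintf("AssayDesign (water): osm_in %.0f -> osm_out %.0f mOsmol/kg\n",
                object@osmIn * 1e6, object@osmOut * 1e6))
  else
    cat(sprintf(
      "AssayDesign (solute, %s): %.0f mM gradient at %.0f mOsmol/kg\n",
      object@soluteName, (object@solOut - object@solIn) * 1e6,
      object@osmTotal * 1e6))
})

#' TimeTree: a rooted topology with node ages in Mya
#'
#' @slot phy rooted \code{ape::phylo} tree.
#' @slot ages numeric vector of ages (Mya) indexed by ape node number
#'   (1..Ntip are leaves with age 0; Ntip+1.. are internal nodes).
#' @slot calibrationNode ape node number of the calibrated node.
#' @slot calibrationAge calibration age, Mya.
#' @export
setClass("TimeTree",
         representation(phy = "phylo", ages = "numeric",
                        calibrationNode = "integer",
                        calibrationAge = "numeric"))

setValidity("TimeTree", function(object) {
  phy <- object@phy
  n <- ape::Ntip(phy) + phy$Nnode
  if (length(object@ages) != n)
    return("one age per node (tips + internal) required")
  if (any(object@ages < -1e-9)) return("node ages must be non-negative")
  parent <- object@phy$edge[, 1]; child <- object@phy$edge[, 2]
  if (any(object@ages[parent] < object@ages[child] - 1e-9))
    return("parent age must be >= child age on every edge")
  TRUE
})

#' Node ages of a TimeTree
#'
#' @param x A \code{\linkS4class{TimeTree}}.
#' @return Numeric vector of ages (Mya) indexed by ape node number.
#' @export
nodeAges <- function(x) {
  stopifnot(methods::is(x, "TimeTree"))
  x@ages
}

#' @describeIn nodeAges The underlying rooted \code{phylo}.
#' @export
timeTreePhylo <- function(x) {
  stopifnot(methods::is(x, "TimeTree"))
  x@phy
}

#' Age of the most recent common ancestor of a set of tips
#'
#' @param x A \code{\linkS4class{TimeTree}}.
#' @param tips character vector of tip labels (length >= 2).
#' @return Age in Mya of their MRCA.
#' @export
mrcaAge <- function(x, tips) {
  stopifnot(methods::is(x, "TimeTree"), length(tips) >= 2)
  node <- ape::getMRCA(x@phy, tips)
  x@ages[node]
}

setMethod("show", "TimeTree", function(object) {
  cat(sprintf(
    "TimeTree: %d tips, root age %.2f Mya (calibrated node at %.1f Mya)\n",
    ape::Ntip(object@phy), object@ages[ape::Ntip(object@phy) + 1L],
    object@calibrationAge))
})
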