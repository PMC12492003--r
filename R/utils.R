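# Unit conversions and small shared helpers.

# Molar volume of water, cm^3/mol (used by the osmotic flux formula).
V_W <- 18

#' Convert osmolality in mOsmol/kg to mol/cm^3
#'
#' Assumes a dilute aqueous solution (1 kg solvent ~ 1 L solution), the
#' approximation under which bench osmolalities (mOsmol/kg) and solute
#' concentrations (mM) can be mixed in one flux formula:
#' 1 mOsmol/kg = 1e-6 mol/cm^3.
#'
#' @param x osmolality in mOsmol/kg.
#' @return concentration in mol/cm^3.
#' @export
mosmToMolPerCm3 <- function(x) x * 1e-6

#' Convert millimolar concentration to mol/cm^3
#'
#' @param x concentration in mM.
#' @return concentration in mol/cm^3 (1 mM = 1e-6 mol/cm^3).
#' @export
mmToMolPerCm3 <- function(x) x * 1e-6

# IUPAC nucleotide code -> matching base set
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Does IUPAC pattern character `p` match concrete base `b`?
iupacMatches <- function(p, b) b %in% IUPAC_SETS[[p]]

# Derive a child RNG seed from a base seed and a stream index, keeping the
# result inside R's 32-bit integer range.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1103) %% 2147483647)
}

# Uppercase character sequence from an XString/XStringSet element or string.
asSeqChar <- function(x) toupper(as.character(x))

# Named, uppercased character vector from an XStringSet, list or named
# character vector (base as.character() would strip the names).
seqsAsChar <- function(aln) {
  nms <- names(aln)
  out <- toupper(vapply(seq_along(aln),
                        function(i) as.character(aln[[i]]), character(1)))
  names(out) <- nms
  out
}
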