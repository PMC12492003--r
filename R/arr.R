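# ar/R selectivity-filter extraction and broad/narrow classification.
#
# The aromatic/arginine (ar/R) constriction of an aquaporin pore is formed
# by four residues; bulky aromatics at filter positions 1 and 3 narrow the
# pore and restrict permeation to water and glycerol, while small residues
# at either position open it to urea and boric acid.

AROMATIC_SET <- c("F", "Y", "W")  # H excluded: never observed in Aqp10 filters

#' Map ungapped reference positions to alignment columns
#'
#' Column k of the result is the alignment column holding the reference
#' sequence's k-th specified ungapped residue.
#'
#' @param aln a named \code{AAStringSet} (or character vector) protein
#'   alignment.
#' @param spec a \code{\linkS4class{FilterSpec}}.
#' @return Integer vector of four 1-based alignment columns.
#' @export
mapFilterColumns <- function(aln, spec) {
  stopifnot(methods::is(spec, "FilterSpec"))
  seqs <- seqsAsChar(aln)
  if (!spec@referenceId %in% names(seqs))
    stop(sprintf("reference '%s' not found in alignment", spec@referenceId))
  ref <- strsplit(toupper(seqs[[spec@referenceId]]), "")[[1]]
  ungapped <- which(ref != "-")
  if (max(spec@positions) > length(ungapped))
    stop(sprintf(
      "filter position %d exceeds ungapped reference length (%d)",
      max(spec@positions), length(ungapped)))
  ungapped[spec@positions]
}

#' Extract the four ar/R filter residues for every sequence
#'
#' @param aln a named \code{AAStringSet} (or character vector) protein
#'   alignment.
#' @param spec a \code{\linkS4class{FilterSpec}} anchoring the filter in
#'   the reference; defaults to \code{\link{filterSpecDefault}()}.
#' @return Data frame with one row per sequence: \code{seq_id},
#'   \code{p1}..\code{p4} (residues; "-" where the sequence is gapped, with
#'   a warning), \code{col1}..\code{col4} (1-based alignment columns) and
#'   \code{call} ("broad", "narrow" or NA when unclassifiable).
#' @export
extractFilters <- function(aln, spec = filterSpecDefault()) {
  cols <- mapFilterColumns(aln, spec)
  seqs <- seqsAsChar(aln)
  ids <- names(seqs)
  res <- vapply(seqs, function(s) {
    strsplit(toupper(s), "")[[1]][cols]
  }, character(4))
  res <- t(res)
  gapped <- apply(res == "-", 1L, any)
  if (any(gapped))
    warning(sprintf("gap at a filter column in: %s",
                    paste(ids[gapped], collapse = ", ")))
  out <- data.frame(seq_id = ids,
                    p1 = res[, 1], p2 = res[, 2],
                    p3 = res[, 3], p4 = res[, 4],
                    col1 = cols[1], col2 = cols[2],
                    col3 = cols[3], col4 = cols[4],
                    row.names = NULL)
  out$call <- apply(res, 1L, function(r) {
    tryCatch(classifySelectivity(r), error = function(e) NA_character_)
  })
  out
}

#' Classify an ar/R filter as broad or narrow solute-selective
#'
#' "Narrow" (water + glycerol only) iff \emph{both} filter positions 1 and
#' 3 carry an aromatic residue (F, Y or W); any small residue at either
#' position gives "broad" (urea and boric acid also permeate).
#'
#' @param residues character vector of the four filter residues (positions
#'   1--4), or a one-row slice of \code{\link{extractFilters}} output.
#' @return "broad" or "narrow".
#' @examples
#' classifySelectivity(c("F", "G", "Y", "R"))  # narrow
#' classifySelectivity(c("F", "G", "G", "R"))  # broad
#' @export
classifySelectivity <- function(residues) {
  if (is.data.frame(residues))
    residues <- unlist(residues[1, c("p1", "p2", "p3", "p4")])
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 4L)
  if (residues[1] == "-" || residues[3] == "-")
    stop("gap at filter position 1 or 3: selectivity unclassifiable")
  if (residues[1] %in% AROMATIC_SET && residues[3] %in% AROMATIC_SET)
    "narrow" else "broad"
}
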