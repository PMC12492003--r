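# Codon-aware alignment processing and nucleotide distance matrices.

#' Remove gap-containing codon columns from a codon alignment
#'
#' A codon column-triplet is removed for \emph{all} sequences iff any
#' sequence has a gap in any of its three columns, so the reading frame is
#' never shifted.  The result is gap-free and its length is a multiple
#' of 3.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @return A gap-free \code{\linkS4class{CodonAlignment}} (possibly with
#'   fewer codons).
#' @export
removeGapCodons <- function(aln) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  seqs <- as.character(alignedSeqs(aln))
  mat <- do.call(rbind, strsplit(seqs, ""))
  nc <- ncol(mat) %/% 3L
  gapped <- vapply(seq_len(nc), function(k) {
    any(mat[, (3L * k - 2L):(3L * k)] == "-")
  }, logical(1))
  keepCols <- as.vector(vapply(which(!gapped),
                               function(k) (3L * k - 2L):(3L * k),
                               integer(3)))
  if (length(keepCols) == 0L) stop("all codons contain gaps")
  out <- apply(mat[, keepCols, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(seqs)
  codonAlignment(out)
}

#' Proportion of differing sites between aligned sequences
#'
#' Pairwise p-distance over columns where both sequences carry a concrete
#' base (gaps and Ns excluded pairwise).
#'
#' @param aln a named \code{DNAStringSet}/character vector of aligned
#'   sequences, or a \code{\linkS4class{CodonAlignment}}.
#' @return Symmetric matrix of p-distances.
#' @export
pDistanceMatrix <- function(aln) {
  if (methods::is(aln, "CodonAlignment")) aln <- alignedSeqs(aln)
  seqs <- seqsAsChar(aln)
  ids <- names(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- mat[i, ] %in% c("A", "C", "G", "T") &
            mat[j, ] %in% c("A", "C", "G", "T")
      if (!any(ok)) stop(sprintf("no comparable sites between '%s' and '%s'",
                                 ids[i], ids[j]))
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  d
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' Applies \code{\link{jcDistance}} to every pairwise p-distance.
#'
#' @inheritParams pDistanceMatrix
#' @return Symmetric matrix of JC69 distances (substitutions/site).
#' @export
jcDistanceMatrix <- function(aln) {
  p <- pDistanceMatrix(aln)
  d <- p
  d[] <- vapply(as.vector(p), jcDistance, numeric(1))
  d
}
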