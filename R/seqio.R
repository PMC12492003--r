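# FASTA IO and low-level sequence procedures: identity, dot plots,
# in-silico PCR and restriction digestion.

AA_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWYBZJUOX", "")[[1]], "-", "*")
NT_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Parse FASTA text into a Biostrings sequence set
#'
#' Headers are taken up to the first whitespace; wrapped sequence lines are
#' concatenated and uppercased.  Residues are validated against the
#' declared alphabet and format errors name the offending line.
#'
#' @param path path to a FASTA file, or a character vector of lines via
#'   \code{text=}.
#' @param text optional character scalar/vector holding FASTA text directly.
#' @param alphabet "auto" (default), "nucleotide" or "protein".
#' @return A named \code{DNAStringSet} (nucleotide) or \code{AAStringSet}
#'   (protein).  Gaps are preserved.
#' @examples
#' parseFasta(text = ">a\nAC\nGT")
#' @export
parseFasta <- function(path = NULL, text = NULL,
                       alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records found")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop(sprintf("FASTA record with empty id at line %d",
                 hdr[which(!nzchar(ids))[1]]))
  if (anyDuplicated(ids))
    stop(sprintf("duplicated FASTA id '%s'", ids[anyDuplicated(ids)]))
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- character(length(hdr))
  for (i in seq_along(hdr)) {
    body <- (hdr[i] + 1L):(bounds[i + 1L] - 1L)
    if (bounds[i + 1L] - 1L < hdr[i] + 1L) body <- integer(0)
    chunk <- toupper(gsub("\\s", "", lines[body]))
    ok <- if (alphabet == "nucleotide") !grepl("[^ACGTN-]", chunk)
          else if (alphabet == "protein")
            !grepl(sprintf("[^%s*-]", "ACDEFGHIKLMNPQRSTVWYBZJUOX"), chunk)
          else TRUE
    if (!all(ok))
      stop(sprintf("residue outside %s alphabet at line %d of FASTA input",
                   alphabet, body[which(!ok)[1]]))
    seqs[i] <- paste(chunk, collapse = "")
  }
  names(seqs) <- ids
  if (alphabet == "auto") {
    alphabet <- if (all(!grepl("[^ACGTN-]", seqs))) "nucleotide" else "protein"
  }
  if (alphabet == "nucleotide") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

#' Write a sequence set to FASTA
#'
#' Round-trips with \code{\link{parseFasta}}: ids and residues are
#' preserved exactly.
#'
#' @param seqs a named \code{XStringSet} or named character vector.
#' @param path output file path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Percent identity between two equal-length sequences
#'
#' Identity is matches / compared columns x 100.  With
#' \code{ignoreGapColumns} (default), columns where either sequence has a
#' gap are excluded from the comparison.  Full precision is returned; round
#' to the nearest integer for reporting.
#'
#' @param a,b sequences (character scalars or XString(Set) elements) of
#'   identical length.
#' @param ignoreGapColumns drop columns gapped in either sequence.
#' @return Percent identity in [0, 100]; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("ACGT", "ACGA")  # 75
#' @export
pairwiseIdentity <- function(a, b, ignoreGapColumns = TRUE) {
  av <- strsplit(asSeqChar(a), "")[[1]]
  bv <- strsplit(asSeqChar(b), "")[[1]]
  if (length(av) != length(bv))
    stop(sprintf("sequence lengths differ (%d vs %d); align first",
                 length(av), length(bv)))
  keep <- rep(TRUE, length(av))
  if (ignoreGapColumns) keep <- av != "-" & bv != "-"
  if (!any(keep)) stop("no comparable (ungapped) columns")
  100 * sum(av[keep] == bv[keep]) / sum(keep)
}

#' Windowed dot plot of two sequences
#'
#' Scores every ungapped window pair of length \code{window} with
#' \code{matchScore}/\code{mismatchScore} (EDNAFULL-diagonal defaults
#' +5/-4, the dotmatcher convention) and reports the anchors whose score
#' reaches \code{threshold}.  Coordinates are 0-based window starts.
#'
#' @param a,b sequences, each at least \code{window} long.
#' @param window window length (residues), default 20.
#' @param threshold minimum window score to report, default 70.
#' @param matchScore,mismatchScore per-column scores.
#' @return Data frame with columns \code{i}, \code{j} (0-based window
#'   starts in \code{a} and \code{b}) and \code{score}.
#' @export
dotPlot <- function(a, b, window = 20L, threshold = 70,
                    matchScore = 5, mismatchScore = -4) {
  av <- strsplit(asSeqChar(a), "")[[1]]
  bv <- strsplit(asSeqChar(b), "")[[1]]
  n <- length(av); m <- length(bv); w <- as.integer(window)
  if (w < 1L) stop("window must be >= 1")
  if (w > n || w > m)
    stop(sprintf("window (%d) exceeds a sequence length (%d, %d)", w, n, m))
  out_i <- integer(0); out_j <- integer(0); out_s <- numeric(0)
  # scan anti-diagonals: offset d = j - i
  for (d in (-(n - w)):(m - w)) {
    i0 <- max(0L, -d); j0 <- i0 + d          # 0-based starts
    len <- min(n - i0, m - j0)
    if (len < w) next
    eq <- av[(i0 + 1L):(i0 + len)] == bv[(j0 + 1L):(j0 + len)]
    cs <- cumsum(eq)
    matches <- cs[w:len] - c(0, cs)[seq_len(len - w + 1L)]
    score <- matches * matchScore + (w - matches) * mismatchScore
    hit <- which(score >= threshold)
    if (length(hit)) {
      out_i <- c(out_i, i0 + hit - 1L)
      out_j <- c(out_j, j0 + hit - 1L)
      out_s <- c(out_s, score[hit])
    }
  }
  res <- data.frame(i = out_i, j = out_j, score = out_s)
  res[order(res$i, res$j), , drop = FALSE]
}

#' In-silico PCR with exact primer matching
#'
#' The forward primer must match the template exactly; the reverse primer
#' binds where its reverse complement matches the template downstream.
#' Every forward/reverse site combination yielding a product is returned,
#' sorted by start.  The amplicon spans from the forward primer start to
#' the end of the reverse-primer binding site inclusive.
#'
#' @param template a nucleotide sequence (character or DNAString(Set)
#'   element); \code{templateId} names it in the output.
#' @param forward,reverse primer sequences, 5'->3', ACGT only.
#' @param templateId template identifier.
#' @return Data frame of amplicons: \code{template_id}, \code{start},
#'   \code{end} (0-based half-open), \code{length}, \code{sequence}.
#'   Empty when no product forms; a warning is raised for multiple products.
#' @export
inSilicoPCR <- function(template, forward, reverse, templateId = "template") {
  tpl <- asSeqChar(template)
  fwd <- asSeqChar(forward); rev <- asSeqChar(reverse)
  if (!nzchar(fwd) || !nzchar(rev)) stop("primers must be non-empty")
  if (grepl("[^ACGT]", fwd) || grepl("[^ACGT]", rev))
    stop("primers must contain only A, C, G, T")
  rcrev <- asSeqChar(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  fhits <- gregexpr(fwd, tpl, fixed = TRUE)[[1]]
  rhits <- gregexpr(rcrev, tpl, fixed = TRUE)[[1]]
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0))
  if (fhits[1] == -1L || rhits[1] == -1L) return(empty)
  prods <- empty
  for (f in as.integer(fhits)) {          # 1-based match starts
    for (r in as.integer(rhits)) {
      start0 <- f - 1L                    # 0-based amplicon start
      rcStart0 <- r - 1L
      end0 <- rcStart0 + nchar(rcrev)     # half-open amplicon end
      if (start0 + nchar(fwd) > rcStart0) next  # primer sites overlap/reversed
      prods <- rbind(prods, data.frame(
        template_id = templateId, start = start0, end = end0,
        length = end0 - start0,
        sequence = substr(tpl, start0 + 1L, end0)))
    }
  }
  prods <- prods[order(prods$start, prods$end), , drop = FALSE]
  rownames(prods) <- NULL
  if (nrow(prods) > 1L)
    warning(sprintf("in-silico PCR produced %d products on '%s'",
                    nrow(prods), templateId))
  prods
}

#' Restriction digestion of a linear sequence
#'
#' The enzyme's IUPAC recognition pattern is matched on the top strand at
#' every position (overlapping sites included); the top strand is cut after
#' \code{cutOffset} bases of each match.  Fragment lengths always sum to
#' the input length; a site-free sequence yields one fragment.
#'
#' @param seq nucleotide sequence (character or DNAString(Set) element).
#' @param enz an \code{\linkS4class{Enzyme}}.
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' digestSequence("AAAACCATGGAAAA", knownEnzymes()$NcoI)  # 5 9
#' @export
digestSequence <- function(seq, enz) {
  stopifnot(methods::is(enz, "Enzyme"))
  sv <- strsplit(asSeqChar(seq), "")[[1]]
  pat <- strsplit(toupper(enz@recognition), "")[[1]]
  n <- length(sv); k <- length(pat)
  if (n < k) return(n)
  cuts <- integer(0)
  for (s in 0:(n - k)) {                   # 0-based window start
    win <- sv[(s + 1L):(s + k)]
    if (all(mapply(iupacMatches, pat, win))) {
      cp <- s + enz@cutOffset
      if (cp > 0L && cp < n) cuts <- c(cuts, cp)
    }
  }
  cuts <- sort(unique(cuts))
  diff(c(0L, cuts, n))
}
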