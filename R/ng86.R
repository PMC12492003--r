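# Nei-Gojobori (1986) dN/dS: fractional synonymous site counting,
# pathway-averaged difference counting and Jukes-Cantor correction.
#
# Conventions (the NG86 ones): single-nucleotide changes to stop codons are
# excluded from potential-site denominators; mutational pathways passing
# through a stop codon are excluded from difference averaging; codons
# containing a stop (or an ambiguous base / gap) in either sequence are
# dropped from the comparison.

# cache for the precomputed codon tables
.ng86env <- new.env(parent = emptyenv())

ALL_CODONS <- as.vector(outer(
  outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
        function(a, b) paste0(a, b)),
  c("T", "C", "A", "G"), function(a, b) paste0(a, b)))

codonAA <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

senseCodons <- function() ALL_CODONS[codonAA(ALL_CODONS) != "*"]

# Per-codon synonymous site count: at each position, the fraction of
# non-stop single-nucleotide changes that are synonymous.  s + n = 3.
ng86CodonSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  cv <- strsplit(codon, "")[[1]]
  aa <- codonAA(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(bases, cv[pos])) {
      mut <- cv; mut[pos] <- b
      maa <- codonAA(paste(mut, collapse = ""))
      if (maa == "*") next
      valid <- valid + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons.  Pathways through stop codons are excluded; in the (never
# observed for the standard code) case that every pathway is blocked, all
# pathways are used with steps into stops counted as nonsynonymous.
ng86CodonDiffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  dpos <- which(v1 != v2)
  k <- length(dpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
                  "1" = list(dpos),
                  "2" = list(dpos, rev(dpos)),
                  "3" = {
                    p <- list()
                    for (x in dpos) for (y in setdiff(dpos, x))
                      p[[length(p) + 1L]] <- c(x, y, setdiff(dpos, c(x, y)))
                    p
                  })
  walk <- function(order, allowStops) {
    cur <- v1; sd <- 0L; nd <- 0L
    for (pos in order) {
      prevAA <- codonAA(paste(cur, collapse = ""))
      cur[pos] <- v2[pos]
      newAA <- codonAA(paste(cur, collapse = ""))
      if (newAA == "*" && !allowStops) return(NULL)
      if (newAA == prevAA) sd <- sd + 1L else nd <- nd + 1L
    }
    c(sd, nd)
  }
  counts <- Filter(Negate(is.null), lapply(perms, walk, allowStops = FALSE))
  if (length(counts) == 0L)
    counts <- lapply(perms, walk, allowStops = TRUE)
  m <- do.call(rbind, counts)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Lazily build and cache the sense-codon lookup tables: per-codon
# synonymous sites and 61x61 pathway-averaged Sd/Nd matrices.
ng86Tables <- function() {
  if (!is.null(.ng86env$tables)) return(.ng86env$tables)
  sense <- senseCodons()
  sites <- vapply(sense, ng86CodonSites, numeric(1))
  nsense <- length(sense)
  SD <- matrix(0, nsense, nsense, dimnames = list(sense, sense))
  ND <- SD
  for (i in seq_len(nsense)) {
    for (j in seq_len(nsense)) {
      if (i == j) next
      d <- ng86CodonDiffs(sense[i], sense[j])
      SD[i, j] <- d["sd"]; ND[i, j] <- d["nd"]
    }
  }
  .ng86env$tables <- list(sense = sense, sites = sites, SD = SD, ND = ND)
  .ng86env$tables
}

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}.
#'
#' @param p proportion of differing sites, in [0, 0.75).
#' @return Corrected distance in substitutions per site.
#' @examples
#' jcDistance(0.1)  # 0.10732...
#' @export
jcDistance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75))
    stop(sprintf("p = %.4g is at or beyond the Jukes-Cantor saturation bound (0.75)",
                 max(p)))
  -0.75 * log(1 - 4 * p / 3)
}

# Split an ungapped coding sequence into codons.
splitCodons <- function(x) {
  x <- asSeqChar(x)
  n <- nchar(x)
  if (n %% 3L != 0L)
    stop(sprintf("sequence length (%d) is not a multiple of 3", n))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Per-codon NG86 contributions for one sequence pair: usable codon mask,
# per-codon site counts (averaged between the sequences) and per-codon
# pathway-averaged differences.  The building block for ng86Pair and for
# fast codon bootstrapping.
ng86PairCodonwise <- function(a, b) {
  ca <- splitCodons(a); cb <- splitCodons(b)
  if (length(ca) != length(cb))
    stop("sequences have different codon counts")
  tb <- ng86Tables()
  ia <- match(ca, tb$sense); ib <- match(cb, tb$sense)
  usable <- !is.na(ia) & !is.na(ib)   # drops stop codons, gaps, ambiguity
  s <- ifelse(usable, (tb$sites[ia] + tb$sites[ib]) / 2, 0)
  nd <- sd <- numeric(length(ca))
  if (any(usable)) {
    idx <- cbind(ia[usable], ib[usable])
    sd[usable] <- tb$SD[idx]
    nd[usable] <- tb$ND[idx]
  }
  list(usable = usable, s = s, n = ifelse(usable, 3 - s, 0), sd = sd, nd = nd)
}

#' Nei-Gojobori pairwise dN/dS counts
#'
#' Computes potential synonymous/nonsynonymous sites (fractional counting,
#' averaged between the two sequences), pathway-averaged synonymous and
#' nonsynonymous differences, the proportions pS/pN and the Jukes-Cantor
#' corrected rates dS/dN.
#'
#' @param a,b ungapped, in-frame coding sequences of equal length
#'   (character or DNAString(Set) elements).  Codons containing a stop,
#'   gap or ambiguous base in either sequence are excluded.
#' @param correct apply the Jukes-Cantor correction (default).  When TRUE,
#'   pN or pS at or beyond the saturation bound (0.75) is an error; when
#'   FALSE, dS/dN are returned as NA and only the counts are reported
#'   (useful on very short sequences).
#' @return Named list: \code{S}, \code{N} (potential sites), \code{Sd},
#'   \code{Nd} (differences), \code{pS}, \code{pN}, \code{dS}, \code{dN},
#'   \code{nCodons} (codons compared).  Symmetric in its arguments;
#'   \code{S + N = 3 * nCodons}.
#' @examples
#' ng86Pair("TTTAAAGGGCCC", "TTCAAAGGGCCC")  # one synonymous difference
#' @export
ng86Pair <- function(a, b, correct = TRUE) {
  cw <- ng86PairCodonwise(a, b)
  if (!any(cw$usable)) stop("no comparable codons")
  S <- sum(cw$s); N <- sum(cw$n)
  Sd <- sum(cw$sd); Nd <- sum(cw$nd)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- dN <- NA_real_
  if (correct) {
    dS <- jcDistance(pS); dN <- jcDistance(pN)
  } else {
    if (pS < 0.75) dS <- jcDistance(pS)
    if (pN < 0.75) dN <- jcDistance(pN)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, nCodons = sum(cw$usable))
}

#' Mean between-group dN and dS with codon-bootstrap standard errors
#'
#' dN (and dS) is the arithmetic mean of the \code{\link{ng86Pair}} value
#' over all cross-group sequence pairs (MEGA's "mean distance between
#' groups"; within-group diversity is not netted off).  Standard errors are
#' the standard deviation of that statistic over codon-bootstrap
#' replicates: codon sites are resampled with replacement, using the same
#' sites for every sequence.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}} (gap-free; run
#'   \code{\link{removeGapCodons}} first if needed).
#' @param groups named character vector mapping sequence id to group label.
#' @param gA,gB the two group labels to compare.
#' @param nBoot bootstrap replicates (default 500; 0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap (required when nBoot > 0).
#' @return Named list: \code{dN}, \code{dS}, \code{dN_se}, \code{dS_se},
#'   \code{ratio} (dN/dS, NA when dS = 0), \code{nBoot}, \code{nPairs}.
#' @export
groupMeanDnDs <- function(aln, groups, gA, gB, nBoot = 500L, seed = NULL) {
  stopifnot(methods::is(aln, "CodonAlignment"))
  seqs <- as.character(alignedSeqs(aln))
  idsA <- names(groups)[groups == gA]
  idsB <- names(groups)[groups == gB]
  if (length(idsA) == 0L || length(idsB) == 0L)
    stop(sprintf("group '%s' or '%s' is empty", gA, gB))
  missing <- setdiff(c(idsA, idsB), names(seqs))
  if (length(missing))
    stop(sprintf("ids not in alignment: %s", paste(missing, collapse = ", ")))
  pairs <- expand.grid(a = idsA, b = idsB, stringsAsFactors = FALSE)
  nc <- nCodons(aln)
  # per-pair per-codon contribution matrices
  sM <- nM <- sdM <- ndM <- matrix(0, nrow(pairs), nc)
  for (k in seq_len(nrow(pairs))) {
    cw <- ng86PairCodonwise(seqs[[pairs$a[k]]], seqs[[pairs$b[k]]])
    sM[k, ] <- cw$s; nM[k, ] <- cw$n; sdM[k, ] <- cw$sd; ndM[k, ] <- cw$nd
  }
  pairDist <- function(idx) {
    S <- rowSums(sM[, idx, drop = FALSE]); N <- rowSums(nM[, idx, drop = FALSE])
    Sd <- rowSums(sdM[, idx, drop = FALSE]); Nd <- rowSums(ndM[, idx, drop = FALSE])
    pS <- ifelse(S > 0, Sd / S, 0); pN <- ifelse(N > 0, Nd / N, 0)
    if (any(pS >= 0.75) || any(pN >= 0.75)) {
      bad <- which(pS >= 0.75 | pN >= 0.75)[1]
      stop(sprintf("saturation (p >= 0.75) in pair %s vs %s",
                   pairs$a[bad], pairs$b[bad]))
    }
    c(dN = mean(jcDistance(pN)), dS = mean(jcDistance(pS)))
  }
  est <- pairDist(seq_len(nc))
  dN_se <- dS_se <- NA_real_
  nBoot <- as.integer(nBoot)
  if (nBoot > 0L) {
    if (is.null(seed)) stop("a seed is required for the codon bootstrap")
    reps <- withLocalSeed(seed, {
      vapply(seq_len(nBoot), function(i) {
        idx <- sample.int(nc, nc, replace = TRUE)
        tryCatch(pairDist(idx), error = function(e) c(dN = NA_real_, dS = NA_real_))
      }, c(dN = 0, dS = 0))
    })
    if (anyNA(reps))
      warning(sprintf("%d bootstrap replicates hit saturation and were dropped",
                      sum(is.na(reps[1, ]))))
    dN_se <- stats::sd(reps["dN", ], na.rm = TRUE)
    dS_se <- stats::sd(reps["dS", ], na.rm = TRUE)
  }
  list(dN = unname(est["dN"]), dS = unname(est["dS"]),
       dN_se = dN_se, dS_se = dS_se,
       ratio = if (est["dS"] > 0) unname(est["dN"] / est["dS"]) else NA_real_,
       nBoot = nBoot, nPairs = nrow(pairs))
}

# Run `expr` under a local RNG seed without disturbing the caller's stream.
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
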