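# Independent brute-force oracles used to check the package's
# implementations.  These deliberately share no code with the package
# internals beyond the standard genetic code table.

GC_TABLE <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")

oracleSenseCodons <- function() {
  all <- apply(expand.grid(ORACLE_BASES, ORACLE_BASES, ORACLE_BASES), 1L,
               paste, collapse = "")
  sort(all[GC_TABLE[all] != "*"])
}

# NG86 synonymous site count of one codon, written as a flat enumeration
# of all nine single-base mutants.
oracleNG86Sites <- function(codon) {
  aa <- GC_TABLE[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in ORACLE_BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GC_TABLE[[mut]] == "*") next
      valid <- valid + 1
      if (GC_TABLE[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# all orderings of a set, by recursive descent
oraclePermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oraclePermutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# pathway-averaged Sd/Nd between two sense codons, stop-free pathways
# only (all pathways, stop steps as nonsynonymous, if every one is
# blocked)
oracleNG86Diffs <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0L) return(c(0, 0))
  tally <- function(order, allowStop) {
    cur <- c1; syn <- 0; non <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (GC_TABLE[[nxt]] == "*" && !allowStop) return(NULL)
      if (GC_TABLE[[nxt]] == GC_TABLE[[cur]]) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  paths <- lapply(oraclePermutations(dpos), tally, allowStop = FALSE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0L)
    paths <- lapply(oraclePermutations(dpos), tally, allowStop = TRUE)
  colMeans(do.call(rbind, paths))
}

# naive O(n*m*w) dot-plot scorer
oracleDotplot <- function(a, b, w, thr, match = 5, mismatch = -4) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  hits <- NULL
  for (i in 0:(length(av) - w)) {
    for (j in 0:(length(bv) - w)) {
      eq <- sum(av[(i + 1):(i + w)] == bv[(j + 1):(j + w)])
      score <- eq * match + (w - eq) * mismatch
      if (score >= thr) hits <- rbind(hits, c(i, j, score))
    }
  }
  if (is.null(hits)) data.frame(i = integer(0), j = integer(0),
                                score = numeric(0))
  else data.frame(i = hits[, 1], j = hits[, 2], score = hits[, 3])
}

# OLS slope by explicit normal equations
oracleOLSSlope <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2]
}

# JC69 transition probability, closed form
oracleJCProb <- function(from, to, t) {
  if (from == to) 0.25 + 0.75 * exp(-4 * t / 3)
  else 0.25 - 0.25 * exp(-4 * t / 3)
}

# exhaustive likelihood of a 4-leaf tree ((a,b)u,(c,d)v) under JC69 by
# summing over both internal states at every site
oracleQuartetLik <- function(states, bl) {
  # states: named chars a,b,c,d (single site); bl: named branch lengths
  # a,b,c,d,u (internal edge u-v); root placed at u with prior 1/4
  tot <- 0
  for (u in ORACLE_BASES) {
    for (v in ORACLE_BASES) {
      tot <- tot + 0.25 *
        oracleJCProb(u, states[["a"]], bl[["a"]]) *
        oracleJCProb(u, states[["b"]], bl[["b"]]) *
        oracleJCProb(u, v, bl[["u"]]) *
        oracleJCProb(v, states[["c"]], bl[["c"]]) *
        oracleJCProb(v, states[["d"]], bl[["d"]])
    }
  }
  tot
}

randomCodingSeq <- function(nCodons, seed) {
  sense <- oracleSenseCodons()
  set.seed(seed)
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

randomDNA <- function(n, seed) {
  set.seed(seed)
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}
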