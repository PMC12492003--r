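# Substitution models (JC69 / K2P / TN93 with uniform rates), Felsenstein
# pruning, marginal ML ancestral states, and neighbor-joining trees.

BASES <- c("A", "C", "G", "T")

#' SubstModel: a reversible nucleotide substitution model
#'
#' Supports JC69, K2P and TN93 with uniform rates across sites.  The rate
#' matrix is normalized to one expected substitution per site per unit
#' branch length; its (symmetrizable) eigendecomposition is cached for
#' fast transition probabilities.
#'
#' @slot model "JC69", "K2P" or "TN93".
#' @slot freqs equilibrium base frequencies (A, C, G, T), summing to 1.
#' @slot rates named numeric: \code{a1} (A<->G transition), \code{a2}
#'   (C<->T transition), \code{b} (transversion) exchangeabilities.
#' @slot decomp cached eigendecomposition of the normalized rate matrix.
#' @export
setClass("SubstModel",
         representation(model = "character", freqs = "numeric",
                        rates = "numeric", decomp = "list"))

setValidity("SubstModel", function(object) {
  if (abs(sum(object@freqs) - 1) > 1e-8)
    return("base frequencies must sum to 1")
  if (any(object@freqs <= 0)) return("base frequencies must be positive")
  if (any(object@rates <= 0)) return("rates must be positive")
  TRUE
})

#' Construct a substitution model
#'
#' @param model "JC69", "K2P" or "TN93".
#' @param freqs base frequencies in A, C, G, T order (uniform for
#'   JC69/K2P; required meaningfully for TN93, e.g. empirical).
#' @param kappa transition/transversion rate ratio (K2P).
#' @param kappa1,kappa2 purine (A<->G) and pyrimidine (C<->T) transition /
#'   transversion rate ratios (TN93).
#' @return A \code{\linkS4class{SubstModel}}.
#' @examples
#' substModel("JC69")
#' substModel("TN93", freqs = c(0.3, 0.2, 0.2, 0.3), kappa1 = 4, kappa2 = 8)
#' @export
substModel <- function(model = c("JC69", "K2P", "TN93"), freqs = NULL,
                       kappa = 2, kappa1 = 2, kappa2 = 2) {
  model <- match.arg(model)
  if (model == "JC69") {
    freqs <- rep(0.25, 4); a1 <- a2 <- b <- 1
  } else if (model == "K2P") {
    freqs <- rep(0.25, 4); b <- 1; a1 <- a2 <- kappa
  } else {
    if (is.null(freqs)) stop("TN93 requires base frequencies")
    b <- 1; a1 <- kappa1; a2 <- kappa2
  }
  freqs <- freqs / sum(freqs)
  names(freqs) <- BASES
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    rate <- if ((BASES[i] == "A" && BASES[j] == "G") ||
                (BASES[i] == "G" && BASES[j] == "A")) a1
            else if ((BASES[i] == "C" && BASES[j] == "T") ||
                     (BASES[i] == "T" && BASES[j] == "C")) a2
            else b
    Q[i, j] <- rate * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # symmetrize: B = D^(1/2) Q D^(-1/2) has real eigensystem
  ds <- sqrt(freqs)
  B <- diag(ds) %*% Q %*% diag(1 / ds)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  decomp <- list(values = eig$values,
                 right = diag(1 / ds) %*% eig$vectors,
                 left = t(eig$vectors) %*% diag(ds))
  methods::new("SubstModel", model = model, freqs = freqs,
               rates = c(a1 = a1, a2 = a2, b = b), decomp = decomp)
}

setMethod("show", "SubstModel", function(object) {
  cat(sprintf("SubstModel %s: pi = (%s), rates a1=%.3g a2=%.3g b=%.3g\n",
              object@model,
              paste(sprintf("%.3f", object@freqs), collapse = ", "),
              object@rates["a1"], object@rates["a2"], object@rates["b"]))
})

#' Transition probability matrix P(t)
#'
#' @param model a \code{\linkS4class{SubstModel}}.
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 matrix, rows = ancestral base, cols = descendant base
#'   (A, C, G, T).
#' @export
probMatrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  d <- model@decomp
  P <- d$right %*% (exp(d$values * t) * d$left)
  P[P < 0] <- 0                         # clip tiny negative round-off
  dimnames(P) <- list(BASES, BASES)
  P
}

# tip partial-likelihood vector for one character
tipPartial <- function(ch) {
  v <- numeric(4); names(v) <- BASES
  set <- IUPAC_SETS[[ch]]
  if (is.null(set) || ch %in% c("-", "N")) set <- BASES
  v[set] <- 1
  v
}

# shared machinery: compressed site patterns + postorder partials.
# Returns partials (list node -> 4 x npat matrix), per-node cumulative log
# scalers (npat vectors), pattern weights, and the reordered tree.
pruningPartials <- function(phy, aln, model) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  seqs <- seqsAsChar(aln)
  tips <- phy$tip.label
  if (!all(tips %in% names(seqs)))
    stop(sprintf("alignment is missing tips: %s",
                 paste(setdiff(tips, names(seqs)), collapse = ", ")))
  mat <- do.call(rbind, strsplit(seqs[tips], ""))
  pat <- apply(mat, 2L, paste, collapse = "\r")
  upat <- unique(pat)
  w <- as.numeric(table(factor(pat, levels = upat)))
  cols <- match(upat, pat)
  npat <- length(upat)
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  partial <- vector("list", nnode)
  logsc <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    partial[[i]] <- vapply(mat[i, cols], tipPartial, numeric(4))
    logsc[[i]] <- numeric(npat)
  }
  phy2 <- ape::reorder.phylo(phy, "postorder")
  edgeP <- lapply(phy2$edge.length, function(t) probMatrix(model, t))
  for (k in seq_along(edgeP)) {
    p <- phy2$edge[k, 1]; ch <- phy2$edge[k, 2]
    contrib <- edgeP[[k]] %*% partial[[ch]]
    if (is.null(partial[[p]])) {
      partial[[p]] <- contrib
      logsc[[p]] <- logsc[[ch]]
    } else {
      partial[[p]] <- partial[[p]] * contrib
      logsc[[p]] <- logsc[[p]] + logsc[[ch]]
    }
    if (all(phy2$edge[, 1] != p | seq_along(edgeP) <= k)) {
      # node complete: rescale to guard against underflow
      mx <- apply(partial[[p]], 2L, max)
      mx[mx == 0] <- 1
      partial[[p]] <- sweep(partial[[p]], 2L, mx, "/")
      logsc[[p]] <- logsc[[p]] + log(mx)
    }
  }
  list(partial = partial, logsc = logsc, weights = w, patterns = cols,
       patternOf = match(pat, upat), phy = phy2, edgeP = edgeP, npat = npat)
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Sites are assumed independent with uniform rates; the likelihood is
#' additive in log over sites.  Works on rooted or unrooted (basal
#' multifurcation) trees; under a reversible model the value is invariant
#' to root placement.
#'
#' @param phy an \code{ape::phylo} tree with branch lengths in
#'   substitutions/site; tip labels must all appear in the alignment.
#' @param aln named \code{DNAStringSet}/character alignment (gaps and N
#'   treated as fully ambiguous).
#' @param model a \code{\linkS4class{SubstModel}}.
#' @return Total log-likelihood (numeric scalar).
#' @export
treeLogLik <- function(phy, aln, model) {
  if (ape::Ntip(phy) == 1L || is.null(phy$edge) || nrow(phy$edge) == 0L) {
    # single-leaf degenerate tree: sum of log base frequencies
    seqs <- seqsAsChar(aln)
    s <- strsplit(seqs[[phy$tip.label[1]]], "")[[1]]
    return(sum(log(model@freqs[s])))
  }
  pr <- pruningPartials(phy, aln, model)
  root <- ape::Ntip(pr$phy) + 1L
  site <- colSums(model@freqs * pr$partial[[root]])
  sum(pr$weights * (log(site) + pr$logsc[[root]]))
}

#' Marginal ML ancestral states at a node
#'
#' Computes, for every site, the marginal posterior distribution of the
#' ancestral base at \code{node} from the pruning partials (down pass)
#' combined with an up pass carrying the likelihood of the rest of the
#' tree, then reports the most probable base per site.  Ties are broken by
#' the fixed base order A < C < G < T and flagged.
#'
#' @param phy rooted \code{ape::phylo} tree with branch lengths.
#' @param aln named alignment (as in \code{\link{treeLogLik}}).
#' @param model a \code{\linkS4class{SubstModel}}.
#' @param node "root" (default) or an ape node number.
#' @return List: \code{posterior} (sites x 4 matrix of per-site posterior
#'   probabilities), \code{sequence} (most-probable sequence, character
#'   scalar), \code{ties} (logical per site), \code{node}.
#' @export
ancestralStates <- function(phy, aln, model, node = "root") {
  if (!ape::is.rooted(phy))
    stop("ancestral reconstruction needs a rooted tree")
  pr <- pruningPartials(phy, aln, model)
  phy2 <- pr$phy
  ntip <- ape::Ntip(phy2)
  root <- ntip + 1L
  nodeId <- if (identical(node, "root")) root else as.integer(node)
  if (nodeId > ntip + phy2$Nnode || nodeId < 1L)
    stop(sprintf("node %s not in tree", node))
  npat <- pr$npat
  # up pass: A[v] = per-pattern likelihood of data outside the clade of v,
  # as a function of the state at v (times the root prior).
  A <- vector("list", ntip + phy2$Nnode)
  A[[root]] <- matrix(model@freqs, 4, npat)
  preorder <- rev(seq_len(nrow(phy2$edge)))
  for (k in preorder) {
    p <- phy2$edge[k, 1]; v <- phy2$edge[k, 2]
    Fmat <- A[[p]]
    sibs <- which(phy2$edge[, 1] == p & phy2$edge[, 2] != v)
    for (sk in sibs)
      Fmat <- Fmat * (pr$edgeP[[sk]] %*% pr$partial[[phy2$edge[sk, 2]]])
    Av <- t(pr$edgeP[[k]]) %*% Fmat
    Av <- sweep(Av, 2L, colSums(Av), "/")      # normalize per pattern
    A[[v]] <- Av
  }
  post <- A[[nodeId]] * pr$partial[[nodeId]]
  post <- sweep(post, 2L, colSums(post), "/")
  postSites <- t(post[, pr$patternOf, drop = FALSE])
  colnames(postSites) <- BASES
  best <- apply(postSites, 1L, which.max)
  ties <- apply(postSites, 1L, function(x) sum(x >= max(x) - 1e-12) > 1L)
  list(posterior = postSites,
       sequence = paste(BASES[best], collapse = ""),
       ties = ties, node = nodeId)
}

#' Fit a TN93 model on a fixed topology
#'
#' Base frequencies are taken as the empirical frequencies of the
#' alignment; the two transition/transversion ratios are optimized by
#' maximum likelihood (relative tolerance 1e-8) with branch lengths held
#' fixed.
#'
#' @param phy tree with branch lengths.
#' @param aln named alignment.
#' @return A fitted \code{\linkS4class{SubstModel}} with attribute
#'   \code{logLik}.
#' @export
fitTN93 <- function(phy, aln) {
  seqs <- paste(seqsAsChar(aln), collapse = "")
  counts <- vapply(BASES, function(b) {
    lengths(regmatches(seqs, gregexpr(b, seqs, fixed = TRUE)))
  }, numeric(1))
  freqs <- counts / sum(counts)
  obj <- function(par) {
    m <- substModel("TN93", freqs = freqs,
                    kappa1 = exp(par[1]), kappa2 = exp(par[2]))
    -treeLogLik(phy, aln, m)
  }
  fit <- stats::optim(log(c(2, 2)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 500))
  m <- substModel("TN93", freqs = freqs,
                  kappa1 = exp(fit$par[1]), kappa2 = exp(fit$par[2]))
  attr(m, "logLik") <- -fit$value
  m
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard NJ agglomeration (via \code{ape::nj}); any negative branch
#' length is clamped to zero and the deficit moved to the adjacent sister
#' branch so path lengths through the pair are preserved.
#'
#' @param d symmetric, zero-diagonal distance matrix (or \code{dist}).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  if (n == 2L) {
    phy <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                edge.length = rep(d[1, 2] / 2, 2),
                tip.label = rownames(d), Nnode = 1L)
    class(phy) <- "phylo"
    attr(phy, "order") <- "cladewise"
    return(phy)
  }
  phy <- ape::nj(stats::as.dist(d))
  neg <- which(phy$edge.length < 0)
  for (k in neg) {
    deficit <- phy$edge.length[k]
    sib <- which(phy$edge[, 1] == phy$edge[k, 1] &
                 seq_len(nrow(phy$edge)) != k)
    if (length(sib)) phy$edge.length[sib[1]] <-
        phy$edge.length[sib[1]] + deficit
    phy$edge.length[k] <- 0
  }
  phy
}
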