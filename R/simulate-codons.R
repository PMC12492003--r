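# Gillespie-style codon evolution on a tree with per-branch dN/dS control.
#
# Candidate nucleotide mutations arrive along each branch as a Poisson
# process (branch length = expected candidate mutations per nucleotide
# site); transitions are kappa-fold more likely than each transversion.
# Candidates creating a stop codon are rejected; nonsynonymous candidates
# are accepted with probability omega; synonymous ones always.  True
# synonymous/nonsynonymous event counts are recorded per branch.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Per-edge omega vector with one value inside a clade
#'
#' Assigns \code{omegaClade} to every edge whose descendants all lie in
#' \code{tips} (the clade's stem edge included) and \code{omegaOther}
#' elsewhere.  Useful for two-group contrasts.
#'
#' @param phy an \code{ape::phylo} tree.
#' @param tips tip labels delimiting the clade.
#' @param omegaClade,omegaOther dN/dS values inside/outside the clade.
#' @return Numeric vector with one omega per row of \code{phy$edge}.
#' @export
edgeOmegaForClade <- function(phy, tips, omegaClade, omegaOther) {
  ntip <- ape::Ntip(phy)
  tipIds <- match(tips, phy$tip.label)
  if (anyNA(tipIds)) stop("unknown tip label")
  below <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    below[[po$edge[k, 1]]] <- c(below[[po$edge[k, 1]]],
                                below[[po$edge[k, 2]]])
  inClade <- vapply(seq_len(ntip + phy$Nnode),
                    function(v) all(below[[v]] %in% tipIds), logical(1))
  ifelse(inClade[phy$edge[, 2]], omegaClade, omegaOther)
}

#' Simulate a codon alignment on a tree
#'
#' @param phy an \code{ape::phylo} tree with branch lengths in expected
#'   candidate mutations per nucleotide site.
#' @param nCodons number of codons (>= 1).
#' @param omega dN/dS: a scalar, or one value per edge (see
#'   \code{\link{edgeOmegaForClade}}).
#' @param kappa transition/transversion rate ratio (default 2, a typical
#'   nuclear-gene value).
#' @param rootFreqs sense-codon frequencies at the root (default uniform
#'   over the 61 sense codons).
#' @param seed RNG seed (required; the simulation is deterministic given
#'   it).
#' @return List: \code{alignment} (a gap-free
#'   \code{\linkS4class{CodonAlignment}} of the tips),
#'   \code{rootSequence}, \code{nodeSequences} (all nodes, by ape node
#'   number), \code{events} (per-edge data frame with \code{syn},
#'   \code{nonsyn} accepted counts and \code{rejectedStop}),
#'   \code{omega} (per edge), \code{tree}.
#' @export
simulateCodonAlignment <- function(phy, nCodons, omega = 0.2, kappa = 2,
                                   rootFreqs = NULL, seed = NULL) {
  if (is.null(seed)) stop("a seed is required")
  stopifnot(nCodons >= 1L)
  nEdge <- nrow(phy$edge)
  if (length(omega) == 1L) omega <- rep(omega, nEdge)
  if (length(omega) != nEdge)
    stop("omega must be a scalar or one value per edge")
  if (any(omega < 0)) stop("omega must be >= 0")
  sense <- senseCodons()
  if (is.null(rootFreqs)) rootFreqs <- rep(1 / length(sense), length(sense))
  withLocalSeed(seed, {
    ntip <- ape::Ntip(phy)
    nnode <- ntip + phy$Nnode
    L <- 3L * nCodons
    seqs <- vector("list", nnode)
    rootCodons <- sample(sense, nCodons, replace = TRUE, prob = rootFreqs)
    root <- ntip + 1L
    seqs[[root]] <- unlist(strsplit(rootCodons, ""))
    ev <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                     length = phy$edge.length, omega = omega,
                     syn = 0L, nonsyn = 0L, rejectedStop = 0L)
    po <- ape::reorder.phylo(phy, "postorder")
    # evolve in preorder so a parent sequence exists before its children
    ord <- rev(seq_len(nEdge))
    edgeOrderMap <- match(paste(po$edge[, 1], po$edge[, 2]),
                          paste(phy$edge[, 1], phy$edge[, 2]))
    pTransition <- kappa / (kappa + 2)
    for (k in ord) {
      e <- edgeOrderMap[k]   # row in phy$edge / omega / ev
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      s <- seqs[[parent]]
      nEvents <- stats::rpois(1, phy$edge.length[e] * L)
      if (nEvents > 0) {
        pos <- sample.int(L, nEvents, replace = TRUE)
        u <- stats::runif(nEvents)
        for (i in seq_len(nEvents)) {
          p <- pos[i]
          base <- s[p]
          target <- if (u[i] < pTransition) TRANSITION_OF[[base]]
                    else {
                      tv <- setdiff(BASES, c(base, TRANSITION_OF[[base]]))
                      tv[1L + (u[i] > (1 + pTransition) / 2)]
                    }
          cStart <- p - (p - 1L) %% 3L
          codon <- s[cStart:(cStart + 2L)]
          newCodon <- codon; newCodon[(p - 1L) %% 3L + 1L] <- target
          oldAA <- codonAA(paste(codon, collapse = ""))
          newAA <- codonAA(paste(newCodon, collapse = ""))
          if (newAA == "*") { ev$rejectedStop[e] <- ev$rejectedStop[e] + 1L; next }
          if (newAA == oldAA) {
            s[p] <- target
            ev$syn[e] <- ev$syn[e] + 1L
          } else if (stats::runif(1) < omega[e]) {
            s[p] <- target
            ev$nonsyn[e] <- ev$nonsyn[e] + 1L
          }
        }
      }
      seqs[[child]] <- s
    }
    tipSeqs <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                      character(1))
    names(tipSeqs) <- phy$tip.label
    nodeSeqs <- vapply(seqs, paste, character(1), collapse = "")
    list(alignment = codonAlignment(tipSeqs),
         rootSequence = nodeSeqs[root],
         nodeSequences = nodeSeqs,
         events = ev, omega = omega, tree = phy)
  })
}
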