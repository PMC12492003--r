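# Single-calibration clock dating: mean-path ultrametricization of a
# phylogram plus linear scaling through one calibrated node.  This is a
# deliberately simple stand-in for relative-rate (RelTime-style) dating;
# see the methods vignette for the approximation involved.

#' Relative node depths by mean-path smoothing
#'
#' Assigns each internal node the mean, over the leaves below it, of the
#' path length from the node to the leaf, then reconciles depths so every
#' parent is at least as deep as its children.  Leaves sit at depth 0.
#' An already ultrametric tree is a fixed point.
#'
#' @param phy rooted \code{ape::phylo} tree with non-negative branch
#'   lengths.
#' @return Numeric vector of relative depths indexed by ape node number.
#' @export
ultrametricize <- function(phy) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  rootDist <- ape::node.depth.edgelength(phy)   # root -> node path length
  depth <- numeric(nnode)
  # leaves below each node, by postorder accumulation
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  for (v in (ntip + 1L):nnode)
    depth[v] <- mean(rootDist[below[[v]]] - rootDist[v])
  # reconcile: walking from the root down, a child never exceeds its parent
  pre <- rev(seq_len(nrow(po$edge)))
  for (k in pre) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (depth[ch] > depth[p]) depth[ch] <- depth[p]
  }
  depth
}

#' Root a phylogram on the outgroup edge at the balance point
#'
#' Roots the tree on the edge separating the outgroup from the ingroup,
#' placing the root where the mean root-to-leaf path length is equal on
#' the two sides (the natural choice when the basal split is the
#' calibration node of a clock analysis; rooting at either end node
#' instead would distort relative node depths).
#'
#' @param phy an (unrooted) \code{ape::phylo} tree with branch lengths.
#' @param outgroup tip label(s) of the outgroup.
#' @return A rooted \code{phylo} tree.
#' @export
rootOnOutgroup <- function(phy, outgroup) {
  phy2 <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  ntip <- ape::Ntip(phy2)
  rootNode <- ntip + 1L
  kids <- which(phy2$edge[, 1] == rootNode)
  if (length(kids) != 2L) return(phy2)   # already multifurcating; leave as is
  rootDist <- ape::node.depth.edgelength(phy2)
  below <- vector("list", ntip + phy2$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(phy2, "postorder")
  for (k in seq_len(nrow(po$edge)))
    below[[po$edge[k, 1]]] <- c(below[[po$edge[k, 1]]], below[[po$edge[k, 2]]])
  meanBelow <- function(v) mean(rootDist[below[[v]]] - rootDist[v])
  c1 <- phy2$edge[kids[1], 2]; c2 <- phy2$edge[kids[2], 2]
  outSide <- if (all(below[[c1]] %in% match(outgroup, phy2$tip.label)))
    c(kids[1], kids[2]) else c(kids[2], kids[1])
  total <- sum(phy2$edge.length[kids])
  mOut <- meanBelow(phy2$edge[outSide[1], 2])
  mIn <- meanBelow(phy2$edge[outSide[2], 2])
  yOut <- min(max((total + mIn - mOut) / 2, 0), total)
  phy2$edge.length[outSide[1]] <- yOut
  phy2$edge.length[outSide[2]] <- total - yOut
  phy2
}

#' Date a tree with a single calibration
#'
#' Converts relative depths from \code{\link{ultrametricize}} into
#' absolute ages (Mya) by scaling linearly so the most recent common
#' ancestor of \code{calTips} sits exactly at \code{calAge}.
#'
#' @param phy rooted \code{ape::phylo} tree with branch lengths
#'   (substitutions/site).
#' @param calTips character vector (>= 2) of tip labels whose MRCA is the
#'   calibrated node.
#' @param calAge calibration age in Mya (e.g. 175 for the
#'   Elopiformes/Anguilliformes split).
#' @return A \code{\linkS4class{TimeTree}}.
#' @export
dateTree <- function(phy, calTips, calAge) {
  if (calAge <= 0) stop("calibration age must be positive")
  depth <- ultrametricize(phy)
  node <- ape::getMRCA(phy, calTips)
  if (is.null(node)) stop("calibration node not resolvable from the tips given")
  if (node <= ape::Ntip(phy)) stop("calibration node is a leaf")
  if (depth[node] <= 0)
    stop("calibrated node has zero relative depth; cannot scale")
  ages <- depth * (calAge / depth[node])
  methods::new("TimeTree", phy = phy, ages = ages,
               calibrationNode = as.integer(node),
               calibrationAge = as.numeric(calAge))
}

#' Write a TimeTree to Newick with ages as internal node labels
#'
#' @param x a \code{\linkS4class{TimeTree}}.
#' @param path output file.
#' @param digits digits for the age labels.
#' @return \code{path}, invisibly.
#' @export
writeTimeTree <- function(x, path, digits = 2L) {
  phy <- x@phy
  ntip <- ape::Ntip(phy)
  phy$node.label <- formatC(x@ages[(ntip + 1L):(ntip + phy$Nnode)],
                            digits = digits, format = "f")
  ape::write.tree(phy, file = path)
  invisible(path)
}
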