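## p-distances, neighbor-joining reconstruction and column-resampling
## bootstrap support. Distances are uncorrected p-distances with
## pairwise deletion of gap/N sites; at the ~600 bp, low-divergence
## scale analysed here a substitution correction would be immaterial.

#' Pairwise p-distance matrix from an alignment
#'
#' \code{d = mismatches / comparable sites}, where a site is comparable
#' for a pair iff neither sequence has \code{-} or \code{N} there
#' (pairwise deletion).
#'
#' @param aln A \linkS4class{SequenceAlignment} with \code{n >= 3}.
#' @return List with \code{labels}, \code{d} (symmetric numeric matrix
#'   with zero diagonal) and \code{comparable} (matrix of per-pair
#'   comparable-site counts). A pair with zero comparable sites is an
#'   error naming the pair.
#' @export
pdistanceMatrix <- function(aln) {
  stopifnot(is(aln, "SequenceAlignment"))
  m <- alignmentMatrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  .pdistanceFromMatrix(m)
}

.pdistanceFromMatrix <- function(m) {
  n <- nrow(m)
  miss <- matrix(m %in% .MISSING_RESIDUES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- !miss[i, ] & !miss[j, ]
      nc <- sum(ok)
      if (nc == 0L)
        stop(sprintf("no comparable sites for pair (%s, %s)",
                     rownames(m)[i], rownames(m)[j]))
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  list(labels = rownames(m), d = d, comparable = comp)
}

#' Neighbor-joining tree reconstruction
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j}. Ties on Q are broken
#' deterministically by the lexicographically smallest pair of node
#' representatives (each node represented by its smallest descendant
#' leaf label). Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister edge. The returned tree is
#' unrooted (basal trifurcation).
#'
#' @param dm A symmetric distance matrix with labelled rows/columns, or
#'   the list returned by \code{\link{pdistanceMatrix}}.
#' @return An \code{ape} \code{phylo} object.
#' @export
neighborJoining <- function(dm) {
  D <- if (is.list(dm) && !is.null(dm$d)) dm$d else as.matrix(dm)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodeId <- seq_len(n)          # temp ids: leaves 1..n, internals > n
  repLabel <- labels            # smallest leaf label under each node
  nextId <- n
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  addEdge <- function(p, c, l) {
    parent <<- c(parent, p); child <<- c(child, c)
    elen <<- c(elen, l)
  }
  while (length(nodeId) > 3L) {
    r <- length(nodeId)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(repLabel[ij[1L]], repLabel[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    nextId <- nextId + 1L
    addEdge(nextId, nodeId[i], vi)
    addEdge(nextId, nodeId[j], vj)
    othr <- setdiff(seq_len(r), c(i, j))
    newD <- 0.5 * (D[i, othr] + D[j, othr] - D[i, j])
    newD <- pmax(newD, 0)
    D <- rbind(cbind(D[othr, othr, drop = FALSE], newD),
               c(newD, 0))
    nodeId <- c(nodeId[othr], nextId)
    repLabel <- c(repLabel[othr],
                  min(repLabel[c(i, j)]))
  }
  ## final three-point join (basal trifurcation)
  va <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  vb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  vc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  nextId <- nextId + 1L
  addEdge(nextId, nodeId[1L], max(va, 0))
  addEdge(nextId, nodeId[2L], max(vb, 0))
  addEdge(nextId, nodeId[3L], max(vc, 0))
  .makePhylo(parent, child, elen, nTips = n, root = nextId,
             tipLabels = labels)
}

## renumber temp node ids into ape's convention (tips 1..n, root n+1,
## internals preorder) and assemble a phylo object
.makePhylo <- function(parent, child, elen, nTips, root, tipLabels) {
  kids <- split(seq_along(parent), parent)
  newId <- integer(max(c(parent, child)))
  newId[seq_len(nTips)] <- seq_len(nTips)
  counter <- nTips
  edgeP <- integer(0); edgeC <- integer(0); edgeL <- numeric(0)
  visit <- function(node) {
    counter <<- counter + 1L
    newId[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      ch <- child[e]
      if (ch > nTips) visit(ch)
      edgeP <<- c(edgeP, newId[node])
      edgeC <<- c(edgeC, newId[ch])
      edgeL <<- c(edgeL, elen[e])
    }
  }
  visit(root)
  tr <- list(edge = cbind(edgeP, edgeC), edge.length = edgeL,
             tip.label = tipLabels, Nnode = counter - nTips)
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

## canonical non-trivial bipartition keys of an unrooted tree; the side
## not containing the overall smallest label represents each split
.treeSplits <- function(tr, allLabels = sort(tr$tip.label)) {
  n <- length(tr$tip.label)
  ref <- allLabels[1L]
  post <- ape::reorder.phylo(tr, "postorder")
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- n + 1L
  keys <- character(0)
  nodes <- integer(0)
  for (v in seq.int(n + 1L, n + tr$Nnode)) {
    if (v == root) next
    side <- sort(desc[[v]])
    if (ref %in% side) side <- sort(setdiff(allLabels, side))
    if (length(side) < 2L || length(side) > length(allLabels) - 2L)
      next
    keys <- c(keys, paste(side, collapse = "\r"))
    nodes <- c(nodes, v)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and annotates each internal edge of the full-data
#' tree with the fraction of replicates containing its bipartition.
#' Supports are stored in \code{node.label} (fractions in [0,1]; the
#' basal node is blank).
#'
#' @param aln A \linkS4class{SequenceAlignment} with \code{n >= 4}.
#' @param reps Number of bootstrap replicates (default 10000).
#' @param seed Optional integer seed.
#' @return The point-estimate \code{phylo} with bootstrap supports in
#'   \code{node.label}; the replicate count actually used is attached
#'   as attribute \code{"repsUsed"}.
#' @export
bootstrapSupport <- function(aln, reps = 10000, seed = NULL) {
  stopifnot(is(aln, "SequenceAlignment"))
  if (reps < 1) stop("reps must be >= 1")
  m <- alignmentMatrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 sequences")
  if (!is.null(seed)) set.seed(seed)
  point <- neighborJoining(.pdistanceFromMatrix(m))
  allLabels <- sort(point$tip.label)
  ps <- .treeSplits(point, allLabels)
  counts <- stats::setNames(numeric(length(ps$keys)), ps$keys)
  used <- 0L
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bt <- tryCatch(
      neighborJoining(.pdistanceFromMatrix(m[, cols, drop = FALSE])),
      error = function(e) NULL)
    if (is.null(bt)) next
    used <- used + 1L
    bk <- unique(.treeSplits(bt, allLabels)$keys)
    hit <- bk[bk %in% names(counts)]
    counts[hit] <- counts[hit] + 1
  }
  if (used == 0L) stop("all bootstrap replicates failed")
  support <- counts / used
  n <- length(point$tip.label)
  nodeLab <- rep("", point$Nnode)
  nodeLab[ps$nodes - n] <- format(round(support, 4), trim = TRUE)
  point$node.label <- nodeLab
  attr(point, "repsUsed") <- used
  point
}
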