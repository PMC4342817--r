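# Clade delineation: p-distances, neighbor joining, bootstrap support,
# label-purity clade extraction and Newick I/O (trees are ape "phylo"
# objects throughout).

#' Pairwise p-distance matrix from an alignment
#'
#' Entry (i, j) is the mismatch fraction over columns where both rows
#' carry a residue (pairwise deletion). A pair with no comparable column
#' is an error.
#'
#' @param msa An \linkS4class{Msa}, ideally already filtered of high-gap
#'   columns.
#' @return Symmetric numeric matrix with zero diagonal and row/column
#'   names taken from the alignment.
#' @export
pDistance <- function(msa) {
  stopifnot(methods::is(msa, "Msa"))
  m <- .msaMatrix(msa)
  n <- nrow(m)
  labels <- names(msaRows(msa))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both))
        stop("no comparable columns between '", labels[i], "' and '",
             labels[j], "'")
      d[i, j] <- d[j, i] <- mean(m[i, both] != m[j, both])
    }
  }
  d
}

.checkDistanceMatrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must carry labels")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix is asymmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal not 0")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with deterministic tie-breaking: among
#' pairs minimising the Q criterion, the lexicographically smallest
#' (cluster label, cluster label) pair is joined, where a cluster is
#' labelled by its alphabetically first leaf. Negative branch lengths
#' are clamped to zero with a warning.
#'
#' @param dm Symmetric labelled distance matrix (>= 3 labels).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(dm) {
  .checkDistanceMatrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 labels")
  labels <- rownames(dm)
  newick <- labels           # growing sub-newick per cluster
  minLab <- labels           # tie-break label per cluster
  d <- dm
  clamped <- FALSE
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # Deterministic tie-break: lexicographically smallest label pair.
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(minLab[ij[1]], minLab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- min(pick); j <- max(pick)
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0 || vj < 0) clamped <- TRUE
    vi <- max(vi, 0); vj <- max(vj, 0)
    newNewick <- paste0("(", newick[i], ":", fmt(vi), ",",
                        newick[j], ":", fmt(vj), ")")
    newMin <- min(minLab[i], minLab[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labs2 <- c(rownames(d)[keep], paste0("joined", m))
    dimnames(d2) <- list(labs2, labs2)
    d <- d2
    newick <- c(newick[keep], newNewick)
    minLab <- c(minLab[keep], newMin)
  }
  # Three-point termination.
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(v1, v2, v3) < 0)) clamped <- TRUE
  v <- pmax(c(v1, v2, v3), 0)
  if (clamped) warning("negative branch length(s) clamped to 0")
  txt <- paste0("(", newick[1], ":", fmt(v[1]), ",",
                newick[2], ":", fmt(v[2]), ",",
                newick[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}

# Canonical bipartition keys for every internal edge of an unrooted tree.
.bipartitionKeys <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    s <- tips[p]
    if (length(s) <= 1L || length(s) >= length(tips) - 1L) next
    if (ref %in% s) s <- setdiff(tips, s)
    keys <- c(keys, paste(sort(s), collapse = "\r"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement \code{nReps} times,
#' rebuilds the NJ tree for each replicate and reports, for every
#' internal edge of the full-data tree, the percentage of replicate
#' trees containing the same bipartition. Supports are attached as
#' internal node labels.
#'
#' @param msa An \linkS4class{Msa}.
#' @param nReps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return An \code{ape::phylo} tree with node labels giving percentage
#'   supports (root label empty).
#' @export
bootstrapSupport <- function(msa, nReps = 100L, seed = 1L) {
  stopifnot(methods::is(msa, "Msa"))
  if (!.isCount(nReps, 1L)) stop("nReps must be a positive integer")
  tree <- njTree(pDistance(msa))
  m <- .msaMatrix(msa)
  rowNames <- names(msaRows(msa))
  counts <- new.env(parent = emptyenv())
  withSeed(seed, {
    for (rep in seq_len(nReps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      res <- m[, cols, drop = FALSE]
      rows <- apply(res, 1, paste, collapse = "")
      names(rows) <- rowNames
      repTree <- njTree(pDistance(Msa(rows)))
      for (k in .bipartitionKeys(repTree)) {
        cur <- if (is.null(counts[[k]])) 0L else counts[[k]]
        assign(k, cur + 1L, envir = counts)
      }
    }
  })
  # Map each internal node of the reference tree to its bipartition key.
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)  # ordered by internal node numbering
  labs <- character(tree$Nnode)
  for (idx in seq_along(parts)) {
    s <- tips[parts[[idx]]]
    if (length(s) >= length(tips) - 1L || length(s) <= 1L ||
        length(s) == length(tips)) {
      labs[idx] <- ""
      next
    }
    if (ref %in% s) s <- setdiff(tips, s)
    k <- paste(sort(s), collapse = "\r")
    cnt <- if (is.null(counts[[k]])) 0L else counts[[k]]
    labs[idx] <- as.character(round(100 * cnt / nReps))
  }
  labs[1] <- ""  # root (trifurcation) has no separating edge
  tree$node.label <- labs
  tree
}

#' Extract label-pure clades from a tree
#'
#' An automated surrogate for identifying subfamily clusters by eye:
#' every bipartition side of the unrooted tree is a candidate clade; the
#' maximal non-overlapping candidates with at least \code{minSize}
#' leaves and label purity at least \code{minPurity} are returned
#' (preferring larger, then purer, candidates).
#'
#' @param tree An \code{ape::phylo} tree.
#' @param leafLabels Named character vector mapping every leaf to a
#'   candidate label.
#' @param minPurity Minimum fraction of the dominant label (default
#'   0.9).
#' @param minSize Minimum clade size (default 3).
#' @return List of entries with \code{tips}, \code{label} (dominant) and
#'   \code{purity}; non-overlapping.
#' @export
extractClades <- function(tree, leafLabels, minPurity = 0.9,
                          minSize = 3L) {
  tips <- tree$tip.label
  if (!all(tips %in% names(leafLabels)))
    stop("unlabeled leaf/leaves: ",
         paste(setdiff(tips, names(leafLabels)), collapse = ", "))
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    s <- tips[p]
    if (length(s) < length(tips)) {
      sides[[length(sides) + 1L]] <- s
      sides[[length(sides) + 1L]] <- setdiff(tips, s)
    }
  }
  sides <- unique(lapply(sides, sort))
  cand <- list()
  for (s in sides) {
    if (length(s) < minSize) next
    tab <- sort(table(leafLabels[s]), decreasing = TRUE)
    purity <- as.numeric(tab[1]) / length(s)
    if (purity < minPurity) next
    cand[[length(cand) + 1L]] <- list(tips = s, label = names(tab)[1],
                                      purity = purity)
  }
  if (!length(cand)) return(list())
  ord <- order(-vapply(cand, function(x) length(x$tips), numeric(1)),
               -vapply(cand, function(x) x$purity, numeric(1)),
               vapply(cand, function(x) x$label, character(1)),
               vapply(cand, function(x) paste(x$tips, collapse = ","),
                      character(1)))
  chosen <- list()
  used <- character(0)
  for (k in ord) {
    if (any(cand[[k]]$tips %in% used)) next
    chosen[[length(chosen) + 1L]] <- cand[[k]]
    used <- c(used, cand[[k]]$tips)
  }
  chosen
}

#' Read a Newick tree
#' @param x A file path, or a Newick string when \code{text = TRUE}.
#' @param text Interpret \code{x} as Newick text instead of a path.
#' @return An \code{ape::phylo} tree.
#' @export
readNewick <- function(x, text = FALSE) {
  tree <- tryCatch(
    if (text) ape::read.tree(text = x) else ape::read.tree(x),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick input")
  tree
}

#' Write a tree to Newick
#' @param tree An \code{ape::phylo} tree.
#' @param path Optional output path; when NULL the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Collapse weakly supported bipartitions (reporting option)
#'
#' Contracts internal edges whose bootstrap support is below
#' \code{minSupport} into polytomies. Intended for presentation only;
#' clade extraction operates on the uncollapsed tree.
#'
#' @param tree An \code{ape::phylo} with numeric node labels (supports).
#' @param minSupport Support percentage threshold (default 50).
#' @return The collapsed tree.
#' @export
collapseWeakNodes <- function(tree, minSupport = 50) {
  if (is.null(tree$node.label)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  low <- which(!is.na(sup) & sup < minSupport)
  if (!length(low)) return(tree)
  nodeIds <- low + length(tree$tip.label)
  drop <- tree$edge[, 2] %in% nodeIds
  tree$edge.length[drop] <- 0
  ape::di2multi(tree, tol = 1e-12)
}
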