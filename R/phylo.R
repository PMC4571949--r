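#' Read a protein alignment from FASTA
#'
#' @param path FASTA file with equal-length aligned sequences.
#' @return Character matrix, one row per taxon (rownames = names),
#'   uppercase residues with `-` for gaps.
#' @export
read_alignment <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                           set.attributes = FALSE, forceDNAtolower = FALSE)
  lens <- lengths(fa)
  if (length(unique(lens)) != 1)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  aln <- do.call(rbind, lapply(fa, toupper))
  rownames(aln) <- names(fa)
  validate_alignment(aln)
}

#' Write a protein alignment to FASTA
#'
#' @param aln character matrix as returned by [read_alignment()] or
#'   [simulate_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  validate_alignment(aln)
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path)
  invisible(path)
}

validate_alignment <- function(aln) {
  if (!is.matrix(aln) || !is.character(aln))
    stop("alignment must be a character matrix", call. = FALSE)
  if (nrow(aln) < 1 || ncol(aln) < 1)
    stop("alignment must have >= 1 row and column", call. = FALSE)
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("taxon names must be present and unique", call. = FALSE)
  aln
}

#' Pairwise p-distances of an alignment
#'
#' Proportion of differing sites over the columns where neither sequence
#' has a gap (`-`).
#'
#' @param aln character matrix alignment with >= 2 taxa.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames = taxon names.
#' @export
p_distance_matrix <- function(aln) {
  validate_alignment(aln)
  n <- nrow(aln)
  if (n < 2) stop("need >= 2 taxa", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- aln[i, ] != "-" & aln[j, ] != "-"
      if (!any(ok))
        stop(sprintf("no comparable columns between %s and %s",
                     rownames(aln)[i], rownames(aln)[j]), call. = FALSE)
      d[i, j] <- d[j, i] <- mean(aln[i, ok] != aln[j, ok])
    }
  }
  d
}

as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distances must be a square matrix or dist", call. = FALSE)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, ",
         "zero-diagonal", call. = FALSE)
  d
}

# choose, among index pairs (rows of `pairs`), the one whose sorted
# cluster-key pair is lexicographically smallest; keys are the smallest
# leaf label contained in each cluster
lexicographic_pick <- function(pairs, keys) {
  tags <- apply(pairs, 1, function(p) {
    k <- sort(c(keys[p[1]], keys[p[2]]))
    paste(k, collapse = "\r")
  })
  pairs[order(tags)[1], ]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou & Nei): repeated agglomeration of
#' the pair minimizing the Q criterion, with closed-form branch lengths.
#' Negative branch lengths are clamped to 0 with the deficit transferred
#' to the sibling branch so the joined pair's path length is preserved.
#' When two pairs tie on Q, the pair whose clusters contain the
#' lexicographically smallest leaf labels is joined, making the result
#' deterministic.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An unrooted `phylo` tree (package \pkg{ape}) with branch
#'   lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  nwk <- rownames(d)       # newick fragment per active cluster
  keys <- rownames(d)      # smallest leaf label per active cluster
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 & upper.tri(q), arr.ind = TRUE)
    ij <- lexicographic_pick(cand, keys)
    i <- ij[1]; j <- ij[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    u_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], li, nwk[j], lj)
    u_key <- min(keys[i], keys[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], u_nwk)
    keys <- c(keys[keep], u_key)
    n <- n - 1
  }
  # final three clusters join at a single internal node (three-point
  # formulas); negative lengths clamped at 0
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ord <- order(keys)
  lens <- pmax(c(l1, l2, l3), 0)[ord]
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[ord[1]], lens[1], nwk[ord[2]], lens[2],
                 nwk[ord[3]], lens[3])
  ape::read.tree(text = txt)
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group average-linkage agglomeration: each merge is the
#' pair of clusters with the smallest mean inter-cluster distance (mean
#' over all original cross pairs), the merged node sits at half that
#' distance, and the output is a rooted ultrametric tree.  Ties resolve
#' to the lexicographically smallest label pair.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 2 taxa.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("UPGMA needs >= 2 taxa", call. = FALSE)
  nwk <- rownames(d)
  keys <- rownames(d)
  size <- rep(1, n)
  height <- rep(0, n)
  while (n > 1) {
    dd <- d
    diag(dd) <- Inf
    dmin <- min(dd)
    cand <- which(dd <= dmin + 1e-12 & upper.tri(dd), arr.ind = TRUE)
    ij <- lexicographic_pick(cand, keys)
    i <- ij[1]; j <- ij[2]
    h <- d[i, j] / 2
    u_nwk <- sprintf("(%s:%.12g,%s:%.12g)",
                     nwk[i], h - height[i], nwk[j], h - height[j])
    newd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], u_nwk)
    keys <- c(keys[keep], min(keys[i], keys[j]))
    size <- c(size[keep], size[i] + size[j])
    height <- c(height[keep], h)
    n <- n - 1
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Canonical non-trivial splits of a tree, as the package compares them
# for bootstrap support.  rooted = TRUE treats each internal non-root
# node as a clade (rooted support, for UPGMA); rooted = FALSE
# canonicalizes each bipartition to the side not containing the
# alphabetically first taxon and drops trivial splits (unrooted support,
# for NJ).  Returns a character vector of comma-joined sorted leaf sets.
tree_splits <- function(tree, rooted = FALSE) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  clades <- ape::prop.part(tree)
  labs <- attr(clades, "labels")
  out <- character(0)
  for (cl in clades) {
    set <- sort(labs[cl])
    if (length(set) == n) next            # root: all taxa
    if (rooted) {
      if (length(set) < 2) next
      out <- c(out, paste(set, collapse = ","))
    } else {
      if (tips[1] %in% set) set <- setdiff(tips, set)
      if (length(set) < 2 || length(set) > n - 2) next
      out <- c(out, paste(sort(set), collapse = ","))
    }
  }
  unique(out)
}

build_tree <- function(d, method) {
  switch(method, nj = neighbor_joining(d), upgma = upgma(d))
}

#' Bootstrap supports for NJ / UPGMA trees
#'
#' Builds the full-data tree from gap-excluding p-distances, then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilds the tree each time, and scores each internal split of the
#' full-data tree by the percentage of replicate trees containing it.
#' For neighbor joining, splits are unrooted bipartitions; for UPGMA,
#' rooted clades (UPGMA places its own root, which outgroup rooting would
#' contradict, so the `outgroup` is validated but the UPGMA root is
#' kept).  For NJ the returned tree is rooted at the outgroup when one is
#' given.
#'
#' @param aln character matrix alignment.
#' @param method `"nj"` or `"upgma"`.
#' @param replicates number of bootstrap replicates, >= 1.
#' @param seed integer seed; identical seeds give identical supports.
#' @param outgroup tip label to root at (NJ), or `NULL`.
#' @return An object of class `bootstrap_result`: list with `tree` (a
#'   `phylo` whose internal node labels are integer supports in percent),
#'   `supports` (named vector keyed by comma-joined leaf sets), `method`,
#'   `replicates`.
#' @export
bootstrap_support <- function(aln, method = c("nj", "upgma"), replicates,
                              seed = NULL, outgroup = NULL) {
  method <- match.arg(method)
  validate_alignment(aln)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1)
    stop("replicates must be >= 1", call. = FALSE)
  if (!is.null(outgroup) && !outgroup %in% rownames(aln))
    stop("outgroup not found in alignment: ", outgroup, call. = FALSE)
  rooted <- method == "upgma"
  full <- build_tree(p_distance_matrix(aln), method)
  ref_splits <- tree_splits(full, rooted = rooted)
  counts <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      bt <- build_tree(p_distance_matrix(aln[, cols, drop = FALSE]), method)
      hits <- intersect(ref_splits, tree_splits(bt, rooted = rooted))
      counts[hits] <- counts[hits] + 1
    }
  })
  supports <- round(100 * counts / replicates)
  out_tree <- full
  if (method == "nj" && !is.null(outgroup))
    out_tree <- ape::root(full, outgroup = outgroup, resolve.root = TRUE)
  out_tree$node.label <- node_support_labels(out_tree, supports, rooted)
  structure(list(tree = out_tree, supports = supports, method = method,
                 replicates = replicates),
            class = "bootstrap_result")
}

# assign each internal node the support of the split its parent edge
# induces; unmatched (trivial or root) nodes get an empty label
node_support_labels <- function(tree, supports, rooted) {
  tips <- sort(tree$tip.label)
  clades <- ape::prop.part(tree)
  labs <- attr(clades, "labels")
  vapply(seq_along(clades), function(k) {
    set <- sort(labs[clades[[k]]])
    if (!rooted && tips[1] %in% set) set <- sort(setdiff(tips, set))
    key <- paste(set, collapse = ",")
    if (key %in% names(supports)) sprintf("%d", as.integer(supports[key]))
    else ""
  }, character(1))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<%s tree, %d bootstrap replicates, internal supports: %s>\n",
              toupper(x$method), x$replicates,
              paste(as.integer(x$supports), collapse = " ")))
  invisible(x)
}

#' Write a tree to Newick
#'
#' Branch lengths are written with 6 significant digits; bootstrap
#' supports, when present, appear as internal node labels.
#'
#' @param x a `phylo` or [bootstrap_support()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  tree <- if (inherits(x, "bootstrap_result")) x$tree else x
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
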