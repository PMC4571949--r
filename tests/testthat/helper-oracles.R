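# Independent oracles and fixture builders used across test files.

# Pearson correlation from the textbook sums, independent of stats::cor
pearson_manual <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# canonical unrooted splits of a phylo tree: each non-trivial bipartition
# represented by the side not containing the alphabetically first tip
unrooted_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    set <- sort(labs[cl])
    if (length(set) == n) next
    if (tips[1] %in% set) set <- sort(setdiff(tips, set))
    if (length(set) < 2 || length(set) > n - 2) next
    out <- c(out, paste(set, collapse = ","))
  }
  sort(unique(out))
}

# rooted clade sets of a phylo tree (internal, non-root nodes)
rooted_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(cl) paste(sort(labs[cl]), collapse = ","),
                character(1))
  sort(out[lengths(pp) < length(labs) & lengths(pp) >= 2])
}

# least-squares brute force over the three possible quartet topologies.
# For topology (p1 p2 | p3 p4) the five branch lengths map linearly onto
# the six pairwise distances; returns the winning split as a canonical
# string like "A,B".
quartet_ls_best <- function(d) {
  taxa <- rownames(d)
  stopifnot(length(taxa) == 4)
  pairs <- utils::combn(4, 2)
  dv <- apply(pairs, 2, function(p) d[p[1], p[2]])
  topos <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sse <- vapply(topos, function(tp) {
    # columns: terminal branches of tp[1..4], internal branch
    X <- matrix(0, 6, 5)
    for (k in 1:6) {
      a <- pairs[1, k]; b <- pairs[2, k]
      X[k, match(a, tp)] <- 1
      X[k, match(b, tp)] <- 1
      same_side <- (match(a, tp) <= 2) == (match(b, tp) <= 2)
      if (!same_side) X[k, 5] <- 1
    }
    co <- qr.solve(X, dv)
    sum((dv - X %*% co)^2)
  }, numeric(1))
  tp <- topos[[which.min(sse)]]
  side <- sort(taxa[tp[1:2]])
  if (sort(taxa)[1] %in% side) side <- sort(setdiff(taxa, side))
  paste(side, collapse = ",")
}

# naive O(n^3) UPGMA oracle: cluster distances recomputed each round as
# plain means over all original cross pairs; returns merge heights and
# the final partition history
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd / 2)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# random rigid motion (proper rotation + translation) of atom coordinates
rigid_transform <- function(atoms, seed) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  set.seed(seed)
  qrres <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrres)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, 0, 20)
  new <- xyz %*% R + matrix(shift, nrow(xyz), 3, byrow = TRUE)
  atoms$x <- new[, 1]; atoms$y <- new[, 2]; atoms$z <- new[, 3]
  atoms
}

# write a two-column spectrum text fixture and return its path
write_spectrum_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a clean 7-taxon tree with long internal branches: every clade should
# be recovered with full bootstrap support from a long alignment
clean_seven_taxon_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.1,B:0.1):0.3,(C:0.1,D:0.1):0.3):0.3,",
    "(E:0.1,(F:0.1,G:0.1):0.3):0.3);"))
}
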