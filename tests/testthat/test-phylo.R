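aln_from <- function(...) {
  seqs <- list(...)
  aln <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(aln) <- names(seqs)
  aln
}

test_that("p-distances count differing sites over gap-free columns", {
  aln <- aln_from(a = "ACGT", b = "ACGA", c = "CATG", d = "ACGT")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "d"], 0)
  expect_equal(d["a", "c"], 1)
  expect_true(isSymmetric(d))
  gappy <- aln_from(a = "AC-T", b = "A-GT")
  expect_equal(p_distance_matrix(gappy)["a", "b"], 0)  # only cols 1 and 4
  allgap <- aln_from(a = "A--", b = "-AA")
  expect_error(p_distance_matrix(allgap), "comparable")
  expect_error(p_distance_matrix(aln[1, , drop = FALSE]), ">= 2")
})

test_that("three-taxon NJ reproduces the three-point branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # la = (dab + dac - dbc)/2 etc.
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(la, (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-10)
})

test_that("NJ recovers the quartet chosen by least-squares brute force", {
  set.seed(17)
  for (i in 1:8) {
    # additive quartet with random branch lengths
    tr0 <- ape::read.tree(text = sprintf(
      "((A:%.3f,B:%.3f):%.3f,(C:%.3f,D:%.3f):0.001);",
      runif(1, 0.05, 0.4), runif(1, 0.05, 0.4), runif(1, 0.05, 0.3),
      runif(1, 0.05, 0.4), runif(1, 0.05, 0.4)))
    d <- ape::cophenetic.phylo(tr0)
    nj_split <- unrooted_splits(neighbor_joining(d))
    expect_equal(nj_split, quartet_ls_best(d))
  }
})

test_that("NJ inverts additive distances from random trees up to 8 leaves", {
  for (s in 1:6) {
    set.seed(100 + s)
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(d)
    expect_setequal(unrooted_splits(tr), unrooted_splits(tr0))
    cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(cd, d, tolerance = 1e-8)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ matches the ape implementation on random distance matrices", {
  for (s in 1:4) {
    set.seed(200 + s)
    n <- 7
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    mine <- neighbor_joining(d)
    reference <- ape::nj(as.dist(d))
    expect_setequal(unrooted_splits(mine), unrooted_splits(reference))
  }
})

test_that("UPGMA is ultrametric and matches a naive average-linkage oracle", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(two)
  expect_equal(max(ape::node.depth.edgelength(t2)), 0.2)  # root height d/2
  expect_error(upgma(two[1, 1, drop = FALSE]), ">= 2")

  for (s in 1:5) {
    set.seed(300 + s)
    n <- 6
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- upgma(d)
    # ultrametric: all root-to-leaf path lengths equal
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-10)
    # merge heights and merged leaf sets equal the O(n^3) oracle
    oracle <- naive_upgma(d)
    heights <- sort(ape::branching.times(tr))
    expect_equal(unname(sort(oracle$heights)), unname(heights),
                 tolerance = 1e-10)
    oracle_clades <- sort(vapply(oracle$merges, function(m)
      paste(sort(letters[m]), collapse = ","), character(1)))
    tree_clades <- sort(c(rooted_clades(tr),
                          paste(sort(letters[1:n]), collapse = ",")))
    expect_equal(oracle_clades, tree_clades)
  }
})

test_that("ultrametric input distances are reproduced exactly by UPGMA", {
  tr0 <- clean_seven_taxon_tree()
  d0 <- ape::cophenetic.phylo(tr0)
  # make the generating tree ultrametric by extending tips to equal depth
  um <- upgma(d0)
  d1 <- ape::cophenetic.phylo(upgma(ape::cophenetic.phylo(um)))
  expect_equal(d1[rownames(d0), colnames(d0)],
               ape::cophenetic.phylo(um)[rownames(d0), colnames(d0)],
               tolerance = 1e-10)
})

test_that("bootstrap supports are seed-pure, validated, and label-order invariant", {
  tr <- clean_seven_taxon_tree()
  aln <- simulate_alignment(tr, 500, seed = 3)
  expect_error(bootstrap_support(aln, "nj", 0, seed = 1), ">= 1")
  expect_error(bootstrap_support(aln, "nj", 10, seed = 1,
                                 outgroup = "ZZ"), "outgroup")
  b1 <- bootstrap_support(aln, "nj", 30, seed = 10, outgroup = "A")
  b2 <- bootstrap_support(aln, "nj", 30, seed = 10, outgroup = "A")
  expect_identical(b1$supports, b2$supports)
  # permuting the taxon rows leaves the split->support map unchanged
  perm <- aln[sample(nrow(aln)), , drop = FALSE]
  b3 <- bootstrap_support(perm, "nj", 30, seed = 10, outgroup = "A")
  expect_identical(b1$supports[sort(names(b1$supports))],
                   b3$supports[sort(names(b3$supports))])
})

test_that("clean alignments give full support and survive Newick export", {
  tr <- clean_seven_taxon_tree()
  aln <- simulate_alignment(tr, 1000, seed = 4)
  for (method in c("nj", "upgma")) {
    b <- bootstrap_support(aln, method, 50, seed = 11,
                           outgroup = if (method == "nj") "A" else NULL)
    expect_true(all(b$supports == 100))
    path <- tempfile(fileext = ".nwk")
    write_newick(b, path)
    back <- ape::read.tree(path)
    expect_setequal(back$tip.label, rownames(aln))
    expect_true(any(back$node.label == "100"))
  }
})

test_that("alignments round-trip through FASTA", {
  aln <- simulate_alignment(clean_seven_taxon_tree(), 60, seed = 12)
  path <- tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path)
  expect_identical(back[rownames(aln), ], aln)
})
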