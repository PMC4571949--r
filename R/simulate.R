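# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are pure functions of their
# arguments.  A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a fly R1-6 spectral-sensitivity spectrum
#'
#' Emulates the two-peaked structure of Drosophila R1-6 sensitivity: a
#' dominant UV peak contributed by the sensitizing pigment (modeled as a
#' Gaussian -- its true shape is not needed, only its presence, to
#' exercise the visible-window logic) plus the visible alpha band of the
#' rhodopsin itself.  Additive homoscedastic Gaussian noise; values are
#' clipped at 0 so the result is a valid sensitivity spectrum.
#'
#' @param lambda_max_R rhodopsin peak wavelength in nm.
#' @param uv_peak_center,uv_peak_width center (nm) and Gaussian sigma (nm)
#'   of the sensitizing-pigment band.
#' @param uv_to_visible_ratio height of the UV peak relative to the unit
#'   visible peak; the default 2 mimics the dominant UV peak of fly
#'   recordings.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed; identical seeds give identical spectra.
#' @param grid wavelengths in nm.
#' @param coefficients template shape coefficients.
#' @return A [spectrum()] of kind `"sensitivity"`.
#' @export
simulate_sensitivity <- function(lambda_max_R, uv_peak_center = 350,
                                 uv_peak_width = 25,
                                 uv_to_visible_ratio = 2,
                                 noise_sigma = 0, seed = NULL,
                                 grid = default_grid(),
                                 coefficients = template_coefficients()) {
  if (uv_peak_width <= 0) stop("uv_peak_width must be > 0", call. = FALSE)
  if (uv_to_visible_ratio < 0)
    stop("uv_to_visible_ratio must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  clean <- uv_to_visible_ratio *
    exp(-0.5 * ((grid - uv_peak_center) / uv_peak_width)^2) +
    alpha_band(grid, template_params(lambda_max_R, coefficients))
  v <- with_seed(seed, clean + stats::rnorm(length(grid), 0, noise_sigma))
  spectrum(grid, pmax(v, 0), kind = "sensitivity",
           label = sprintf("sim sensitivity R=%g", lambda_max_R))
}

#' Simulate a rhodopsin/metarhodopsin difference spectrum
#'
#' [build_difference()] plus additive Gaussian noise; seed-reproducible.
#'
#' @inheritParams build_difference
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return A [spectrum()] of kind `"difference"`.
#' @export
simulate_difference <- function(lambda_max_R, lambda_max_M,
                                amplitude_R = 1, amplitude_M = 1,
                                noise_sigma = 0, seed = NULL,
                                grid = default_grid(),
                                coefficients = template_coefficients()) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  ds <- build_difference(lambda_max_R, lambda_max_M, amplitude_R,
                         amplitude_M, grid, coefficients)
  v <- with_seed(seed, ds$value + stats::rnorm(length(grid), 0, noise_sigma))
  spectrum(grid, v, kind = "difference", label = ds$label)
}

# the 20 standard amino acids, one-letter codes
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# apply k successive equal-rates replacements (uniform over the other 19
# letters) to a single residue
mutate_residue <- function(res, k) {
  for (i in seq_len(k)) res <- sample(setdiff(AA_ALPHABET, res), 1)
  res
}

#' Evolve a protein alignment on a known tree
#'
#' Generates a gap-free amino-acid alignment under the simplest
#' equal-rates model: the root sequence is uniform over the 20 standard
#' residues, and along each branch every site receives a Poisson number
#' of replacement events (mean = branch length, in expected
#' substitutions/site), each replacing the residue with one of the other
#' 19 uniformly.  Under this model the expected p-distance between two
#' sequences at total path length d is `(19/20) * (1 - exp(-20 d / 19))`.
#'
#' @param tree a rooted `phylo` tree (package \pkg{ape}) with
#'   non-negative branch lengths in expected substitutions/site.
#' @param length number of alignment columns, >= 1.
#' @param seed integer seed.
#' @return A character matrix with one row per taxon (rownames = tip
#'   labels) and one column per site.
#' @export
simulate_alignment <- function(tree, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 1)
    stop("alignment length must be >= 1", call. = FALSE)
  with_seed(seed, {
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    ntip <- length(tr$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tr$Nnode)
    seqs[[root]] <- sample(AA_ALPHABET, length, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      s <- seqs[[parent]]
      nev <- stats::rpois(length, tr$edge.length[e])
      for (i in which(nev > 0)) s[i] <- mutate_residue(s[i], nev[i])
      seqs[[child]] <- s
    }
    aln <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(aln) <- tr$tip.label
    aln
  })
}

#' Generate a toy protein structure with a lysine-bound chromophore
#'
#' Emits a minimal set of ATOM/HETATM records: a chromophore residue
#' (default `LYR`, a lysine-bound retinal) whose atoms include a Schiff
#' base nitrogen `NZ` near the origin, surrounded by randomly placed
#' amino-acid residues, some of which carry side-chain oxygens.  Intended
#' for exercising the binding-pocket distance reports; the geometry is
#' random, not stereochemically sensible.
#'
#' @param n_residues number of non-chromophore residues.
#' @param seed integer seed.
#' @param chromophore residue name of the chromophore.
#' @param chain chain identifier.
#' @param box half-width (Angstrom) of the cube residues are placed in.
#' @return A [structure_atoms()] data frame.
#' @export
simulate_structure <- function(n_residues = 8, seed = NULL,
                               chromophore = "LYR", chain = "A",
                               box = 15) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  with_seed(seed, {
    resnames <- sample(c("ASP", "GLU", "SER", "TYR", "GLY", "ALA", "LEU"),
                       n_residues, replace = TRUE)
    rows <- list()
    add <- function(record, atom, resid, resno, x, y, z) {
      rows[[length(rows) + 1L]] <<- data.frame(
        record = record, atom = atom, resid = resid, chain = chain,
        resno = resno, x = x, y = y, z = z, stringsAsFactors = FALSE)
    }
    # chromophore: NZ at origin, a short polyene arm of carbons
    add("HETATM", "NZ", chromophore, 319L, 0, 0, 0)
    for (i in 1:4)
      add("HETATM", paste0("C", i), chromophore, 319L, 1.4 * i, 0.2 * i, 0)
    sidechain_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                        SER = "OG", TYR = "OH")
    for (r in seq_len(n_residues)) {
      center <- stats::runif(3, -box, box)
      add("ATOM", "CA", resnames[r], r, center[1], center[2], center[3])
      add("ATOM", "CB", resnames[r], r,
          center[1] + 1.5, center[2], center[3])
      for (o in sidechain_o[[resnames[r]]] %||% character(0)) {
        d <- stats::runif(3, -1.5, 1.5)
        add("ATOM", o, resnames[r], r,
            center[1] + d[1], center[2] + d[2], center[3] + d[3])
      }
    }
    structure_atoms(do.call(rbind, rows))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
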