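# chromophore NZ at origin plus residues placed at known distances
pocket_fixture <- function() {
  structure_atoms(data.frame(
    record = c("HETATM", "HETATM", "ATOM", "ATOM", "ATOM", "ATOM"),
    atom = c("NZ", "C1", "OD1", "CB", "OE1", "HA"),
    resid = c("LYR", "LYR", "ASP", "ASP", "GLU", "GLU"),
    chain = "A",
    resno = c(319, 319, 96, 96, 194, 194),
    x = c(0, 1.4, 0, 0, 0, 0),
    y = c(0, 0, 2.4, 3.5, -2.6, -0.5),
    z = 0, stringsAsFactors = FALSE))
}

test_that("the cutoff is a strict threshold on minimum heavy-atom distance", {
  at <- pocket_fixture()
  hit <- residues_within_cutoff(at, "LYR", cutoff = 2.5)
  expect_equal(hit$resno, 96L)
  expect_equal(hit$distance, 2.4)  # OD1 to NZ; the 2.6 A residue is out
  all_res <- residues_within_cutoff(at, "LYR", cutoff = 1e9)
  expect_setequal(all_res$resno, c(96, 194))
  expect_equal(all_res$distance, sort(all_res$distance))
  expect_error(residues_within_cutoff(at, "XYZ", 2.5), "matches no atoms")
  expect_error(residues_within_cutoff(at, "LYR", -1), "> 0")
})

test_that("hydrogens are excluded unless asked for", {
  at <- pocket_fixture()
  # GLU's HA sits 0.5 A from NZ but is a hydrogen
  d_heavy <- residues_within_cutoff(at, "LYR", 1e9)
  expect_equal(d_heavy$distance[d_heavy$resno == 194], 2.6)
  d_all <- residues_within_cutoff(at, "LYR", 1e9, include_hydrogens = TRUE)
  expect_equal(d_all$distance[d_all$resno == 194], 0.5)
})

test_that("minimum distances agree with exhaustive all-pairs computation", {
  at <- simulate_structure(n_residues = 10, seed = 21)
  got <- residues_within_cutoff(at, "LYR", cutoff = 1e9)
  chromo <- at[at$resid == "LYR" & at$element != "H", ]
  for (i in seq_len(nrow(got))) {
    ra <- at[at$resno == got$resno[i] & at$resid != "LYR" &
               at$element != "H", ]
    brute <- Inf
    for (p in seq_len(nrow(ra))) {
      for (q in seq_len(nrow(chromo))) {
        brute <- min(brute, sqrt(sum((
          c(ra$x[p], ra$y[p], ra$z[p]) -
            c(chromo$x[q], chromo$y[q], chromo$z[q]))^2)))
      }
    }
    expect_equal(got$distance[i], brute, tolerance = 1e-12)
  }
})

test_that("distance reports are invariant under rigid motions and monotone in cutoff", {
  at <- simulate_structure(n_residues = 8, seed = 22)
  moved <- structure_atoms(rigid_transform(as.data.frame(at), seed = 99))
  a <- residues_within_cutoff(at, "LYR", 1e9)
  b <- residues_within_cutoff(moved, "LYR", 1e9)
  expect_equal(b$distance[order(b$residue)], a$distance[order(a$residue)],
               tolerance = 1e-9)
  small <- residues_within_cutoff(at, "LYR", 8)
  big <- residues_within_cutoff(at, "LYR", 20)
  expect_true(all(small$residue %in% big$residue))
})

test_that("Schiff-base oxygen distances rank residues by construction", {
  at <- structure_atoms(data.frame(
    record = c("HETATM", "ATOM", "ATOM", "ATOM", "ATOM", "ATOM"),
    atom = c("NZ", "OE1", "OD1", "OD2", "OH", "CA"),
    resid = c("LYR", "GLU", "ASP", "ASP", "TYR", "GLY"),
    chain = "A",
    resno = c(319, 194, 96, 96, 203, 147),
    x = c(0, 3, 7.5, 7, 12, 2),
    y = 0, z = 0, stringsAsFactors = FALSE))
  rep_ <- schiff_base_distances(at, "LYR", "NZ",
                                residues = c(96, 147, 194, 203))
  expect_equal(rep_$resno, c(194, 96, 203, 147))
  expect_equal(rep_$distance, c(3, 7, 12, NA))  # min oxygen per residue
  expect_false(rep_$has_oxygen[rep_$resno == 147])  # glycine flagged
  expect_error(schiff_base_distances(at, "LYR", "NX", 96), "nitrogen")
  expect_error(schiff_base_distances(at, "LYR", "NZ", 999), "not found")
})

test_that("atom tables enforce uniqueness and finiteness", {
  df <- as.data.frame(pocket_fixture())
  dup <- rbind(df, df[1, ])
  expect_error(structure_atoms(dup), "duplicate")
  bad <- df; bad$x[1] <- NaN
  expect_error(structure_atoms(bad), "finite")
})
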