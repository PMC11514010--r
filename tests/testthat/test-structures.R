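test_that("XYZ files round-trip through write/read", {
  s <- toy_structure()
  p <- withr::local_tempfile(fileext = ".xyz")
  write_structure(s, p)
  s2 <- read_structure(p)
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-4)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-4)
  expect_equal(nrow(s2$atoms), 5L)
})

test_that("malformed XYZ records are rejected with a line number", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "bad", "Ag 0 0 0", "Ag 1 oops 0"), p)
  expect_error(read_structure(p), "line 4")
  writeLines(c("3", "short", "Ag 0 0 0"), p)
  expect_error(read_structure(p), "expected 3 atom")
})

test_that("PDB parsing keeps residue metadata and first altlocs", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AGLY A   1       1.450   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BGLY A   1       1.550   0.000   0.000  0.50  0.00           C",
    "HETATM    4 AG    AG A   2       3.000   1.000   0.000  1.00  0.00          AG",
    "END"
  ), p)
  expect_warning(s <- read_structure(p), "altloc")
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$element, c("N", "C", "Ag"))
  expect_equal(s$atoms$x[2], 1.45)      # altloc A kept
  expect_true(all(c("resid", "chain", "resno") %in% names(s$atoms)))
  s <- select_atoms(s, "silver", elements = "Ag")
  expect_equal(s$selections$silver, 3L)
})

test_that("unknown element symbols are rejected", {
  expect_error(
    structure3d(tibble::tibble(element = "Qq", x = 0, y = 0, z = 0)),
    "Qq"
  )
  expect_error(bond_table(toy_structure(), c("Ag", "Xx"), 3), "Xx")
})

test_that("self-superposition gives zero RMSD and the identity rotation", {
  s <- toy_structure()
  fit <- superpose(s, s, "core")
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3))
  expect_equal(fit$translation, c(0, 0, 0))
  expect_equal(glance(fit)$det_rotation, 1)
})

test_that("a known rigid transform is recovered by superposition", {
  set.seed(5)
  for (i in 1:10) {
    pair <- gen_toy_cluster(10, 15, seed = i)
    fit <- superpose(pair$mobile, pair$reference, "core")
    expect_lt(fit$rmsd, 1e-8)
    # the fit inverts the generating rotation
    expect_equal(fit$rotation %*% pair$rotation, diag(3), tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    # applying the transform superposes every atom, not just the core
    moved <- apply_superposition(fit, pair$mobile)
    expect_equal(moved$atoms$x, pair$reference$atoms$x, tolerance = 1e-6)
  }
})

test_that("superposition RMSD is invariant under a common rigid motion and optimal", {
  set.seed(9)
  for (i in 1:8) {
    pair <- gen_toy_cluster(8, 10, seed = 100 + i,
                            sigma_core = 0.3, sigma_ligand = 0.3)
    fit <- superpose(pair$mobile, pair$reference)
    # same motion applied to both structures
    rot_pair <- gen_toy_cluster(3, 0, seed = 999 + i)  # just for a rotation
    R <- rot_pair$rotation; tr <- rot_pair$translation
    spin <- function(s) {
      xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, tr, `+`)
      s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
      s
    }
    fit2 <- superpose(spin(pair$mobile), spin(pair$reference))
    expect_equal(fit2$rmsd, fit$rmsd, tolerance = 1e-8)
    # optimality: fitted RMSD <= raw RMSD without superposition
    raw <- sqrt(mean(rowSums((
      as.matrix(pair$mobile$atoms[c("x", "y", "z")]) -
        as.matrix(pair$reference$atoms[c("x", "y", "z")])
    )^2)))
    expect_lte(fit$rmsd, raw + 1e-12)
  }
})

test_that("reflected point sets still yield proper rotations", {
  set.seed(31)
  xyz <- matrix(rnorm(30), ncol = 3)
  ref <- structure3d(tibble::tibble(element = "C", x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3]))
  mirr <- structure3d(tibble::tibble(element = "C", x = -xyz[, 1],
                                     y = xyz[, 2], z = xyz[, 3]))
  fit <- superpose(mirr, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # near-collinear set is solved and flagged
  line <- tibble::tibble(element = "C", x = 1:4 + rnorm(4, sd = 1e-11),
                         y = rnorm(4, sd = 1e-11), z = rnorm(4, sd = 1e-11))
  lfit <- superpose(structure3d(line), structure3d(line))
  expect_true(lfit$degenerate)
  expect_equal(det(lfit$rotation), 1, tolerance = 1e-8)
})

test_that("superposition preconditions are enforced", {
  s <- toy_structure()
  expect_error(superpose(s, s, 1:2), "at least 3")
  s2 <- select_atoms(s, "four", indices = 1:4)
  s3 <- select_atoms(s, "four", indices = 1:3)
  expect_error(superpose(s2, s3, "four"), "differ")
  expect_error(superpose(s, s, "nope"), "unknown selection")
})

test_that("subset RMSDs are fitted independently in the report", {
  pair <- gen_toy_cluster(12, 24, seed = 4, sigma_core = 0.05,
                          sigma_ligand = 1.5)
  rep <- rmsd_report(pair$mobile, pair$reference, c("core", "ligand"))
  expect_equal(rep$label, c("core", "ligand"))
  expect_equal(rep$n_atoms, c(12L, 24L))
  expect_lt(rep$rmsd[1], rep$rmsd[2])
  expect_equal(nrow(rmsd_report(pair$mobile, pair$reference, character())), 0L)
  ident <- rmsd_report(pair$reference, pair$reference, c("core", "ligand"))
  expect_true(all(ident$rmsd < 1e-12))
})

test_that("agreement with an independent reference superposition fit", {
  pair <- gen_toy_cluster(10, 10, seed = 77, sigma_core = 0.2,
                          sigma_ligand = 0.2)
  fit <- superpose(pair$mobile, pair$reference)
  xyz_fixed <- matrix(t(as.matrix(pair$reference$atoms[c("x", "y", "z")])),
                      nrow = 1)
  xyz_mob <- matrix(t(as.matrix(pair$mobile$atoms[c("x", "y", "z")])),
                    nrow = 1)
  fitted <- bio3d::fit.xyz(xyz_fixed, xyz_mob,
                           fixed.inds = 1:60, mobile.inds = 1:60)
  dev <- matrix(fitted - xyz_fixed, ncol = 3, byrow = TRUE)
  expect_equal(fit$rmsd, sqrt(mean(rowSums(dev^2))), tolerance = 1e-6)
})

test_that("bond_table equals the all-pairs brute-force filter", {
  brute <- function(s, pair, cutoff) {
    at <- s$atoms
    hits <- list()
    for (i in seq_len(nrow(at) - 1)) {
      for (j in (i + 1):nrow(at)) {
        ok <- (at$element[i] == pair[1] && at$element[j] == pair[2]) ||
          (at$element[i] == pair[2] && at$element[j] == pair[1])
        if (!ok) next
        d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                    (at$z[i] - at$z[j])^2)
        if (d <= cutoff) hits[[length(hits) + 1]] <- c(i, j, d)
      }
    }
    if (!length(hits)) return(matrix(numeric(), ncol = 3))
    m <- do.call(rbind, hits)
    m[order(m[, 3]), , drop = FALSE]
  }
  set.seed(19)
  for (rep in 1:6) {
    at <- tibble::tibble(
      element = sample(c("Ag", "Cl", "C"), 20, replace = TRUE),
      x = runif(20, 0, 8), y = runif(20, 0, 8), z = runif(20, 0, 8)
    )
    s <- structure3d(at)
    for (pr in list(c("Ag", "Ag"), c("Ag", "Cl"))) {
      cutoff <- runif(1, 2, 6)
      got <- bond_table(s, pr, cutoff)
      want <- brute(s, pr, cutoff)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$i, as.integer(want[, 1]))
        expect_equal(got$j, as.integer(want[, 2]))
        expect_equal(got$distance, want[, 3])
      }
    }
  }
  # constructed two-silver case
  two <- structure3d(tibble::tibble(element = c("Ag", "Ag"),
                                    x = c(0, 2.9), y = 0, z = 0))
  tab <- bond_table(two, c("Ag", "Ag"), 3.2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$distance, 2.9)
  expect_equal(nrow(bond_table(two, c("Ag", "Ag"), 2.0)), 0L)
})

test_that("contact_report finds the carbonyl-amine motif with a closed boundary", {
  # O...N at exactly 2.72 Angstrom, with an N-H pointing back at the O
  s <- structure3d(tibble::tibble(
    element = c("O", "N", "H"),
    x = c(0, 2.72, 1.72),
    y = 0, z = 0
  ), selections = list(donor = c(2L, 3L), acceptor = 1L))
  hits <- contact_report(s, "donor", "acceptor", d_max = 3.5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distance, 2.72)
  expect_equal(nrow(contact_report(s, "donor", "acceptor", d_max = 2.0)), 0L)
  # boundary is closed: a pair at exactly d_max is included
  expect_equal(nrow(contact_report(s, "donor", "acceptor", d_max = 2.72)), 1L)
  # the linear N-H...O geometry passes an angle criterion
  ang <- contact_report(s, "donor", "acceptor", d_max = 3.5, angle_min = 150)
  expect_equal(nrow(ang), 1L)
  expect_equal(ang$angle, 180, tolerance = 1e-6)
  # angle requested without hydrogens in the donor selection
  s2 <- select_atoms(s, "donor", indices = 2L)
  expect_error(contact_report(s2, "donor", "acceptor", 3.5, angle_min = 150),
               "no hydrogens")
})
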