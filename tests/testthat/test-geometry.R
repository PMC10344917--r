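two_comp_model <- function(xyz_a, xyz_b, radius = 1.7) {
  structure_model(rep("C", nrow(xyz_a) + nrow(xyz_b)),
                  c(xyz_a[, 1], xyz_b[, 1]), c(xyz_a[, 2], xyz_b[, 2]),
                  c(xyz_a[, 3], xyz_b[, 3]),
                  rep(c("ligase", "target"), c(nrow(xyz_a), nrow(xyz_b))),
                  radius = radius)
}

test_that("clash counting applies a strict sub-cutoff distance criterion", {
  m <- two_comp_model(cbind(0, 0, 0), cbind(2.1, 0, 0))
  expect_equal(count_clashes(m, "ligase", "target"), 1L)
  m2 <- two_comp_model(cbind(0, 0, 0), cbind(2.3, 0, 0))
  expect_equal(count_clashes(m2, "ligase", "target"), 0L)
  expect_error(count_clashes(m, "ligase", "ligase"), "disjoint")
})

test_that("clash counts equal the all-pairs quadratic scan", {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0))  # 3x3 grid
  off <- g + matrix(rep(c(1.1, 0.4, 1.8), each = 9), ncol = 3)
  m <- two_comp_model(g, off)
  expect_equal(count_clashes(m, "ligase", "target"),
               oracle_clashes(g, off, 2.2))
  set.seed(71)
  for (i in 1:100) {
    a <- matrix(runif(3 * sample(2:8, 1), 0, 6), ncol = 3)
    b <- matrix(runif(3 * sample(2:8, 1), 0, 6), ncol = 3)
    cutoff <- runif(1, 1, 4)
    m <- two_comp_model(a, b)
    expect_equal(count_clashes(m, "ligase", "target", cutoff),
                 oracle_clashes(a, b, cutoff))
  }
})

test_that("assembly filter keeps models at or under the clash budgets", {
  expect_true(assembly_filter(5, 2)$keep)     # stated boundary
  expect_false(assembly_filter(6, 0)$keep)
  expect_false(assembly_filter(0, 3)$keep)
  v <- assembly_filter(c(0, 6, 0, 6), c(0, 0, 3, 3))
  expect_equal(v$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(v$reason[2], "protein-protein")
  expect_match(v$reason[3], "PROTAC")
})

test_that("Kabsch superposition nulls rigid transforms and is symmetric", {
  set.seed(72)
  a <- matrix(rnorm(30, sd = 5), ncol = 3)
  expect_equal(kabsch_rmsd(a, a), 0)
  for (s in 1:5) {
    b <- random_rigid(a, seed = 100 + s)
    expect_lt(kabsch_rmsd(a, b), 1e-9)
    expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-9)
  }
  expect_error(kabsch_rmsd(a, a[1:5, ]), "equal-size")
})

test_that("Kabsch RMSD matches a hand-computed displaced case", {
  # square in the xy plane vs the same square shifted +1 along z: optimal
  # alignment recentres, leaving zero residual => rmsd 0. Displacing only
  # two opposite corners by +1 z leaves, after centering (mean z 0.5) and
  # no rotation gain, per-atom residuals 0.5 => rmsd 0.5... computed from
  # the closed form below.
  sq <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1), 0)
  shifted <- sq; shifted[, 3] <- 1
  expect_lt(kabsch_rmsd(sq, shifted), 1e-12)
  two_up <- sq; two_up[c(1, 3), 3] <- 1
  # centred target zs (0.5,-0.5,0.5,-0.5); optimal rotation about the
  # (1,1,0)-type axis tilts the plane: residual from analytic minimisation
  r_num <- kabsch_rmsd(sq, two_up)
  # brute-force rotation search oracle over the known tilt axis
  ang <- seq(0, pi / 4, length.out = 2e4)
  ax <- c(1, -1, 0) / sqrt(2)
  rot_about <- function(u, th) {
    ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * outer(u, u)
  }
  cen <- function(m) sweep(m, 2, colMeans(m))
  best <- min(vapply(ang, function(th) {
    sqrt(mean(rowSums((cen(sq) - cen(two_up) %*% t(rot_about(ax, th)))^2)))
  }, numeric(1)))
  expect_equal(r_num, best, tolerance = 1e-4)
})

test_that("warhead similarity detects displacement and axis rotation", {
  # anisotropic warhead: distinct principal axes
  wh <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 0.3), c(0, 0, -0.3))
  mk <- function(xyz) structure_model(rep("C", nrow(xyz)), xyz[, 1], xyz[, 2],
                                      xyz[, 3], "protac",
                                      subcomponent = "target_warhead")
  a <- mk(wh)
  self <- warhead_similarity(a, a)
  expect_equal(self$cog_distance, 0)
  expect_equal(self$axis_angle_1, 0, tolerance = 1e-6)
  expect_true(self$similar)
  # rigid translation by 7 A
  b <- mk(sweep(wh, 2, c(7, 0, 0), `+`))
  tr <- warhead_similarity(a, b)
  expect_equal(tr$cog_distance, 7)
  expect_false(tr$similar)
  expect_equal(tr$axis_angle_1, 0, tolerance = 1e-6)
  # 25-degree rotation about the third principal axis turns axes 1 and 2
  th <- 25 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  c3 <- mk(wh %*% t(rz))
  rot <- warhead_similarity(a, c3)
  expect_equal(rot$axis_angle_1, 25, tolerance = 1e-6)
  expect_equal(rot$axis_angle_2, 25, tolerance = 1e-6)
  expect_false(rot$similar)
  expect_error(warhead_similarity(mk(wh[1:2, , drop = FALSE]), a), ">= 3")
})

test_that("model selection applies the two-stage strain/RMSD rule", {
  expect_true(model_selection(0.5, 2.0)$select_pass)
  v <- model_selection(c(0.7, 4.5, NA, 0.5), c(2, 1, 1, 3.5))
  expect_equal(v$prune_pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(v$select_pass, c(FALSE, FALSE, FALSE, FALSE))
  expect_match(v$reason[3], "no strain available")
  expect_match(v$reason[1], "thermal")
})

test_that("SASA matches sphere and spherical-cap closed forms", {
  one <- structure_model("C", 0, 0, 0, "protac", radius = 1.6)
  expect_equal(sasa(one)$total, 4 * pi * 3^2, tolerance = 1e-9)
  # two identical atoms far apart: exactly twice the single-atom area
  far <- structure_model(c("C", "C"), c(0, 50), c(0, 0), c(0, 0), "protac",
                         radius = 1.6)
  expect_equal(sasa(far)$total, 2 * 4 * pi * 3^2, tolerance = 1e-9)
  # overlapping pair at 2.0 A: cap formula, quadrature error < 0.5%
  near <- structure_model(c("C", "C"), c(0, 2), c(0, 0), c(0, 0), "protac",
                          radius = 1.6)
  expect_equal(sasa(near)$total, 2 * cap_exposed(3, 2), tolerance = 5e-3)
  # hydrogens are ignored; unknown elements are a named lookup error
  expect_error(structure_model("Xx", 0, 0, 0, "protac"), "Xx")
})

test_that("buried surface area follows the component decomposition", {
  toy <- generate_toy_complex()
  b <- buried_surface_area(toy$model)
  expect_equal(b$bsa_total, toy$truth$bsa_total, tolerance = 0.02)
  expect_equal(b$bsa_protein_protein, 0)
  expect_equal(b$bsa_protein_protac, b$bsa_total)
  # two-sphere burial reproduces the 75.4 A^2 cap value
  expect_equal(cap_buried_pair(3, 2), 75.398, tolerance = 1e-4)
  near <- structure_model(c("C", "C"), c(0, 2), c(0, 0), c(0, 0),
                          c("ligase", "target"), radius = 1.6)
  s_split <- 2 * 4 * pi * 9 - sasa(near)$total
  expect_equal(s_split, cap_buried_pair(3, 2), tolerance = 0.01 * 75.4)
  # refinement oracle: denser lattice agrees within 1%
  b_hi <- buried_surface_area(toy$model, n_points = 10000L)
  expect_equal(b$bsa_total, b_hi$bsa_total, tolerance = 0.01)
  # disjoint components bury nothing
  apart <- structure_model(rep("C", 3), c(0, 50, 100), c(0, 0, 0), c(0, 0, 0),
                           c("ligase", "protac", "target"), radius = 1.6)
  expect_equal(buried_surface_area(apart)$bsa_total, 0)
  expect_error(buried_surface_area(near), "missing component")
})

test_that("BSA is invariant to rigid motion and protein relabeling", {
  toy <- generate_toy_complex()
  b0 <- buried_surface_area(toy$model)
  m <- toy$model
  xyz <- random_rigid(as.matrix(m$atoms[, c("x", "y", "z")]), seed = 77)
  m$atoms[, c("x", "y", "z")] <- xyz
  b1 <- buried_surface_area(m)
  # the lattice is fixed in space, so reorientation shifts the quadrature
  # within its error bound (~1% on a buried-area difference at 960 points)
  expect_equal(b1$bsa_total, b0$bsa_total, tolerance = 0.02)
  # swap the two protein labels: decomposition is unchanged
  m2 <- toy$model
  m2$atoms$component <- c("target", "protac", "ligase")
  b2 <- buried_surface_area(m2)
  expect_equal(b2$bsa_total, b0$bsa_total, tolerance = 1e-12)
  expect_equal(b2$bsa_protein_protein, b0$bsa_protein_protein)
})
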