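test_that("charge assignment uses the carboxyl midpoint and skips apolar residues", {
  gly <- structure_model(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0))
  expect_equal(nrow(assign_charges(gly)), 0)

  asp <- structure_model(rbind(
    atom_row("A", 1, "ASP", "CA", "C", 0, 0, -2),
    atom_row("A", 1, "ASP", "OD1", "O", 0, 0, 0),
    atom_row("A", 1, "ASP", "OD2", "O", 2, 0, 0)))
  ch <- assign_charges(asp)
  expect_equal(nrow(ch), 1)
  expect_equal(c(ch$x, ch$y, ch$z), c(1, 0, 0))
  expect_equal(ch$q, -1)

  incomplete <- structure_model(rbind(
    atom_row("A", 1, "GLU", "CA", "C", 0, 0, 0),
    atom_row("A", 1, "GLU", "OE1", "O", 2, 0, 0)))
  expect_warning(ch2 <- assign_charges(incomplete), "skipped")
  expect_equal(nrow(ch2), 0)

  his <- structure_model(rbind(
    atom_row("A", 1, "HIS", "ND1", "N", 0, 0, 0),
    atom_row("A", 1, "HIS", "NE2", "N", 2, 0, 0)))
  expect_equal(nrow(assign_charges(his)), 0)
  expect_equal(assign_charges(his, his_charge = 0.5)$q, 0.5)
})

test_that("single-atom surface recovers the closed-form sphere area", {
  one <- structure_model(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0))
  pts <- sample_surface(one, probe = 1.4, dots_per_atom = 200)
  expect_equal(nrow(pts), 200)  # nothing occludes
  expect_equal(sum(pts$area), 4 * pi * (1.7 + 1.4)^2)
})

test_that("occlusion removes buried dots", {
  # two nearly coincident atoms: union area ~ one sphere
  two <- structure_model(rbind(
    atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
    atom_row("A", 2, "GLY", "CA", "C", 0.1, 0, 0)))
  pts <- sample_surface(two, dots_per_atom = 500)
  expect_equal(sum(pts$area), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.05)

  # caged atom: all dots occluded
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  cage <- rbind(
    atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
    do.call(rbind, lapply(seq_len(nrow(dirs)), function(i) {
      u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
      atom_row("A", 1 + i, "GLY", "CA", "C", 2 * u[1], 2 * u[2], 2 * u[3])
    })))
  pts2 <- sample_surface(structure_model(cage))
  expect_false(1 %in% pts2$atom)
})

test_that("screened potential matches the closed form to 1e-10 relative", {
  charges <- data.frame(chain = "A", resno = 1, ins = "", resid = "ASP",
                        x = 0, y = 0, z = 0, q = -1)
  r <- c(3, 5, 10, 20)
  pts <- data.frame(x = r, y = 0, z = 0)
  map <- screened_potential(charges, pts, ionic_strength = 0.15, eps = 78,
                            temperature = 298.15)
  # independent evaluation from physical constants
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23; na <- 6.02214076e23
  C <- e^2 * na / (4 * pi * eps0) * 1e10 / 1000
  lam <- 1e10 / sqrt(2 * na * e^2 * 0.15 * 1000 / (eps0 * 78 * kb * 298.15))
  expected <- C * (-1) * exp(-r / lam) / (78 * r)
  expect_equal(map$points$potential, expected, tolerance = 1e-10)
  # magnitude decays monotonically with distance
  expect_true(all(diff(abs(map$points$potential)) < 0))
})

test_that("potential is superposable, sign-symmetric, and Coulomb at zero salt", {
  pts <- data.frame(x = seq(2, 12, by = 2), y = 1, z = -1)
  q1 <- data.frame(chain = "A", resno = 1, ins = "", resid = "ASP",
                   x = 0, y = 0, z = 0, q = -1)
  q2 <- data.frame(chain = "A", resno = 2, ins = "", resid = "LYS",
                   x = 4, y = 2, z = 0, q = 1)
  both <- rbind(q1, q2)
  m1 <- screened_potential(q1, pts)$points$potential
  m2 <- screened_potential(q2, pts)$points$potential
  m12 <- screened_potential(both, pts)$points$potential
  expect_equal(m12, m1 + m2, tolerance = 1e-12)

  negated <- both; negated$q <- -negated$q
  expect_equal(screened_potential(negated, pts)$points$potential, -m12,
               tolerance = 1e-12)

  none <- q1[0, ]
  expect_equal(screened_potential(none, pts)$points$potential, rep(0, 6))

  # zero ionic strength: pure Coulomb (no decay factor)
  m0 <- screened_potential(q1, pts, ionic_strength = 0)$points$potential
  d <- sqrt((pts$x)^2 + (pts$y)^2 + (pts$z)^2)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; na <- 6.02214076e23
  C <- e^2 * na / (4 * pi * eps0) * 1e10 / 1000
  expect_equal(m0, -C / (78 * d), tolerance = 1e-12)

  coincident <- data.frame(x = 0, y = 0, z = 0)
  expect_warning(screened_potential(q1, coincident), "coincident")
})

test_that("patch detection recovers planted clusters exactly", {
  fix <- make_charge_fixture(list(
    list(center = c(0, 0, 0), n_charges = 3, sign = -1),
    list(center = c(40, 0, 0), n_charges = 3, sign = -1)))
  ch <- assign_charges(fix$model)
  map <- screened_potential(ch, sample_surface(fix$model))
  patches <- detect_patches(map)
  expect_length(patches, 2)
  got <- lapply(patches, function(p) sort(p$member_residues))
  expect_setequal(got, lapply(fix$expected, sort))
  # areas sorted descending, sum below the total surface
  areas <- vapply(patches, `[[`, 0, "area")
  expect_true(all(diff(areas) <= 0))
  expect_lt(sum(areas), sum(map$points$area))
  # membership partitions the super-threshold point set
  super <- which(map$points$potential <= -5)
  members <- sort(unlist(lapply(patches, `[[`, "member_points")))
  expect_equal(members, sort(super))
})

test_that("mixed-sign fixtures give one patch per sign selector", {
  fix <- make_charge_fixture(list(
    list(center = c(0, 0, 0), n_charges = 3, sign = -1),
    list(center = c(40, 0, 0), n_charges = 3, sign = +1)))
  ch <- assign_charges(fix$model)
  map <- screened_potential(ch, sample_surface(fix$model))
  expect_length(detect_patches(map, threshold = -5, sign = "neg"), 1)
  expect_length(detect_patches(map, threshold = 5, sign = "pos"), 1)
  expect_error(detect_patches(map, threshold = 5, sign = "neg"), "threshold")
})

test_that("a near-neutral map yields no patches", {
  pts <- data.frame(x = 1:10, y = 0, z = 0, area = 1, atom = 1,
                    chain = "A", resno = 1, resid = "GLY",
                    potential = rnorm(10, 0, 0.01))
  map <- structure(list(points = pts, ionic_strength = 0.15, eps = 78,
                        temperature = 298.15, debye_length = 7.8),
                   class = "SurfacePotentialMap")
  expect_length(detect_patches(map), 0)
})

test_that("carboxyl distances are Euclidean, symmetric and rigid-motion invariant", {
  m <- structure_model(rbind(
    atom_row("A", 1987, "ASP", "OD1", "O", -1, 0, 0),
    atom_row("A", 1987, "ASP", "OD2", "O", 1, 0, 0),
    atom_row("A", 2008, "GLU", "OE1", "O", 2, 4, 0),
    atom_row("A", 2008, "GLU", "OE2", "O", 4, 4, 0),
    atom_row("A", 2020, "LYS", "NZ", "N", 9, 9, 9)))
  d <- carboxyl_distance_matrix(m, c("D1987", "E2008"))
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d["D1987", "E2008"], 5)   # midpoints (0,0,0) and (3,4,0)
  expect_equal(d, t(d))
  expect_error(carboxyl_distance_matrix(m, c("D1987", "K2020")),
               "not aspartate/glutamate")

  # rotate + translate the model: distances unchanged
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot
  m2$atoms$x <- xyz[, 1] + 11; m2$atoms$y <- xyz[, 2] - 3
  m2$atoms$z <- xyz[, 3] + 5
  d2 <- carboxyl_distance_matrix(m2, c("D1987", "E2008"))
  expect_equal(d2, d, tolerance = 1e-12)
})

test_that("charge anisotropy measures the first moment about the site centroid", {
  sym <- data.frame(chain = "A", resno = 1:2, ins = "", resid = c("ASP", "LYS"),
                    x = c(-5, 5), y = 0, z = 0, q = c(-1, -1))
  expect_equal(charge_anisotropy(sym)$magnitude, 0)
  # one charged and one neutral reference site 20 A apart
  mix <- data.frame(chain = "A", resno = 1:2, ins = "", resid = c("GLY", "ASP"),
                    x = c(0, 20), y = 0, z = 0, q = c(0, -1))
  an <- charge_anisotropy(mix)
  expect_equal(an$magnitude, 10)
  expect_equal(abs(an$direction[1]), 1)
  expect_error(charge_anisotropy(sym[0, ]), "no charges")
})
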