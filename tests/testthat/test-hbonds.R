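planted_single <- function(distance = 2.9, angle = 160) {
  make_planted_complex(c("A", "B"), data.frame(
    donor_chain = "A", donor_resno = 10, acc_chain = "B", acc_resno = 100,
    distance = distance, angle = angle))
}

test_that("an apolar model yields no hydrogen bonds", {
  m <- structure_model(rbind(
    atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
    atom_row("A", 2, "GLY", "CA", "C", 30, 0, 0)))
  expect_equal(nrow(detect_hbonds(m)), 0)
})

test_that("planted geometry is detected at 2.9 A / 160 deg and rejected beyond cutoffs", {
  m <- planted_single()
  b <- detect_hbonds(m)
  expect_equal(nrow(b), 1)
  expect_equal(b$donor_atom, "N")
  expect_equal(b$acc_atom, "O")
  expect_equal(b$distance, 2.9, tolerance = 1e-9)
  expect_equal(b$angle, 160, tolerance = 1e-6)

  expect_equal(nrow(detect_hbonds(planted_single(distance = 4.2))), 0)
  expect_equal(nrow(detect_hbonds(planted_single(angle = 100))), 0)
  # the same 100-degree geometry passes once the angle criterion is relaxed
  expect_equal(nrow(detect_hbonds(planted_single(angle = 100),
                                  angle_min = 90)), 1)
})

test_that("explicit hydrogens take over the angle criterion when present", {
  # donor N with H pointing at the acceptor: ideal; H pointing away: rejected
  base <- rbind(
    atom_row("A", 1, "GLY", "N", "N", 0, 0, 0),
    atom_row("A", 1, "GLY", "CA", "C", -1.45, 0, 0),
    atom_row("B", 2, "GLY", "O", "O", 2.9, 0, 0),
    atom_row("B", 2, "GLY", "C", "C", 4.1, 0, 0))
  toward <- structure_model(rbind(base, atom_row("A", 1, "GLY", "H", "H", 1, 0, 0)))
  away <- structure_model(rbind(base, atom_row("A", 1, "GLY", "H", "H", -0.5, 0.85, 0)))
  expect_equal(nrow(detect_hbonds(toward)), 1)
  expect_equal(nrow(detect_hbonds(away)), 0)
})

test_that("planted inventories are recovered exactly with per-residue sub-counts", {
  bonds <- data.frame(
    donor_chain = c("A", "A", "A", "A", "A", "B", "B", "C"),
    donor_resno = c(10, 10, 11, 12, 13, 20, 21, 30),
    acc_chain = c("B", "B", "B", "B", "B", "A", "C", "A"),
    acc_resno = c(100, 101, 102, 103, 104, 50, 110, 60))
  m <- make_planted_complex(c("A", "B", "C"), bonds)
  inv <- interface_inventory(m, list(ANK = "A", MAML1 = "B", RBPJ = "C"))
  expect_equal(inv$counts[["ANK|MAML1"]], 6)
  expect_equal(inv$counts[["ANK|RBPJ"]], 1)
  expect_equal(inv$counts[["MAML1|RBPJ"]], 1)
  expect_equal(sum(inv$counts), 8)
  # the bifurcated donor contributes exactly its two planted bonds
  sub <- interface_bonds_involving(inv, c("ANK", "MAML1"), 10)
  expect_equal(nrow(sub), 2)
  expect_error(interface_inventory(m, list(ANK = "A", X = "Z")), "absent")
})

test_that("two bonds between one donor and one acceptor residue both count", {
  bonds <- data.frame(donor_chain = c("A", "A"), donor_resno = c(347, 347),
                      acc_chain = c("B", "B"), acc_resno = c(1994, 1994))
  m <- make_planted_complex(c("A", "B"), bonds)
  inv <- interface_inventory(m, list(RBPJ = "A", ANK = "B"))
  expect_equal(inv$counts[["ANK|RBPJ"]], 2)
  expect_equal(nrow(interface_bonds_involving(inv, c("ANK", "RBPJ"), 1994)), 2)
})

test_that("a single group produces an empty inventory", {
  m <- planted_single()
  inv <- interface_inventory(m, list(ALL = c("A", "B"))[1])
  expect_length(inv$counts, 0)
})

test_that("counts are invariant under relabeling and rigid motion", {
  bonds <- data.frame(donor_chain = c("A", "A"), donor_resno = c(1, 2),
                      acc_chain = c("B", "B"), acc_resno = c(10, 11))
  m <- make_planted_complex(c("A", "B"), bonds)
  inv <- interface_inventory(m, list(X = "A", Y = "B"))

  relabeled <- m
  relabeled$atoms$chain <- chartr("AB", "PQ", relabeled$atoms$chain)
  inv2 <- interface_inventory(relabeled, list(X = "P", Y = "Q"))
  expect_equal(unname(inv2$counts), unname(inv$counts))

  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot
  moved$atoms$x <- xyz[, 1] + 7; moved$atoms$y <- xyz[, 2] - 2
  moved$atoms$z <- xyz[, 3] + 1
  inv3 <- interface_inventory(moved, list(X = "A", Y = "B"))
  expect_equal(unname(inv3$counts), unname(inv$counts))
})

test_that("enlarging d_max never decreases a count", {
  bonds <- data.frame(donor_chain = "A", donor_resno = 1:3,
                      acc_chain = "B", acc_resno = 11:13,
                      distance = c(2.8, 3.2, 3.4), angle = 160)
  m <- make_planted_complex(c("A", "B"), bonds)
  counts <- vapply(c(3.0, 3.3, 3.5), function(dm) {
    inv <- interface_inventory(m, list(X = "A", Y = "B"), d_max = dm)
    if (length(inv$counts)) sum(inv$counts) else 0L
  }, integer(1))
  expect_equal(counts, c(1L, 2L, 3L))
})
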