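test_that("pair potential matches hand-counted pairing frequencies", {
  # "ADAD", window 1: three adjacent pairs, all A-D; marginals 0.5/0.5
  p <- estimate_pair_potential(residue_sequence("ADAD"), contact_window = 1)
  expect_equal(p$energies["A", "D"], -log(2))
  expect_equal(p$energies["D", "A"], -log(2))
  expect_true(is.na(p$energies["A", "A"]))  # never observed: flagged
  # homogeneous corpus: observed equals the marginal product
  p2 <- estimate_pair_potential(residue_sequence("AAAA"), contact_window = 1)
  expect_equal(p2$energies["A", "A"], 0)
  expect_error(estimate_pair_potential(residue_sequence("A"), 1),
               "at least 2")
})

test_that("estimated energies are symmetric and finite on observed cells", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    corpus <- lapply(1:3, function(i) {
      residue_sequence(paste(sample(aas, 40, TRUE), collapse = ""))
    })
    p <- estimate_pair_potential(corpus, contact_window = 2)
    expect_equal(p$energies, t(p$energies))
    expect_true(all(is.finite(p$energies[p$observed > 0])))
    expect_equal(sum(p$observed), 1)
  }
})

test_that("swapping observed and reference frequencies negates the energy", {
  p <- estimate_pair_potential(residue_sequence("ADKADDKA"), contact_window = 2)
  pos <- p$observed > 0 & p$reference > 0
  swapped <- -log(p$reference[pos] / p$observed[pos])
  expect_equal(unname(swapped), unname(-p$energies[pos]))
})

test_that("window energies match exhaustive enumeration on a toy alphabet", {
  pot <- toy_potential()
  e <- pot$energies
  seqs <- c("AADD", "ADADADAD", "DDAA", "AADDAA")
  for (s in seqs) {
    letters <- strsplit(s, "")[[1]]
    n <- length(letters)
    prof <- disorder_profile(residue_sequence(s), pot, window = 3,
                             midpoint = 0, slope = 1)
    # oracle: direct enumeration of each centred window
    expected <- vapply(seq_len(n), function(i) {
      nb <- setdiff(max(1, i - 1):min(n, i + 1), i)
      mean(vapply(nb, function(j) e[letters[i], letters[j]], 0))
    }, 0)
    expect_equal(prof$scores, plogis(expected), tolerance = 1e-12)
  }
})

test_that("self-attraction lowers and self-repulsion raises disorder", {
  pot <- toy_potential()
  lo <- disorder_profile(residue_sequence(strrep("A", 12)), pot, window = 5,
                         midpoint = 0, slope = 1)
  hi <- disorder_profile(residue_sequence(strrep("D", 12)), pot, window = 5,
                         midpoint = 0, slope = 1)
  expect_true(all(lo$scores < hi$scores))
  expect_true(all(lo$scores >= 0 & lo$scores <= 1))
  expect_true(all(hi$scores >= 0 & hi$scores <= 1))
})

test_that("scores stay in [0,1] and reverse with the sequence", {
  set.seed(9)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  corpus <- lapply(1:3, function(i) {
    residue_sequence(paste(sample(aas, 50, TRUE), collapse = ""))
  })
  pot <- estimate_pair_potential(corpus, 2)
  for (k in 1:5) {
    letters <- sample(aas, 15, TRUE)
    fwd <- disorder_profile(residue_sequence(paste(letters, collapse = "")),
                            pot, window = 5)
    rev_ <- disorder_profile(residue_sequence(paste(rev(letters), collapse = "")),
                             pot, window = 5)
    expect_true(all(fwd$scores >= 0 & fwd$scores <= 1))
    expect_equal(rev(fwd$scores), rev_$scores, tolerance = 1e-12)
  }
})

test_that("uniformly more favourable energies never raise a score", {
  pot <- toy_potential()
  shifted <- pair_potential(pot$energies - 0.7)
  s <- residue_sequence("ADDAADDA")
  base <- disorder_profile(s, pot, window = 5, midpoint = 0, slope = 1)
  down <- disorder_profile(s, shifted, window = 5, midpoint = 0, slope = 1)
  expect_true(all(down$scores <= base$scores))
})

test_that("disorder_profile validates inputs", {
  pot <- toy_potential()
  s <- residue_sequence("ADAD")
  expect_error(disorder_profile(s, pot, window = 4), "odd")
  expect_error(disorder_profile(residue_sequence("AKD"), pot, window = 3),
               "lacks letters: K")
})

test_that("domain means average the requested span", {
  prof <- structure(list(scores = c(0.2, 0.4, 0.6), numbering = 1:3,
                         window = 3, id = "t"), class = "DisorderProfile")
  expect_equal(domain_mean(prof), 0.4)
  expect_equal(domain_mean(prof, c(2, 3)), 0.5)
  const <- structure(list(scores = rep(0.4, 5), numbering = 1:5,
                          window = 3, id = "c"), class = "DisorderProfile")
  expect_equal(domain_mean(const), 0.4)
  expect_error(domain_mean(prof, c(10, 20)), "empty")
})

test_that("external score tables round-trip through the TSV reader", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# resno score", paste(1872:1876, c(0.3, 0.4, 0.5, 0.2, 0.1))),
             f)
  prof <- read_disorder_scores(f)
  expect_equal(domain_mean(prof), 0.3)
  expect_equal(prof$numbering[1], 1872)
  bad <- tempfile(fileext = ".tsv")
  writeLines("1 1.5", bad)
  expect_error(read_disorder_scores(bad), "\\[0, 1\\]")
})

test_that("charge-hydrophobicity plane places hand cases correctly", {
  expect_equal(charge_hydrophobicity(residue_sequence("GGGG"))$mean_net_charge, 0)
  expect_equal(charge_hydrophobicity(residue_sequence("DEKR"))$mean_net_charge, 0)
  pd <- charge_hydrophobicity(residue_sequence("DDDD"))
  expect_equal(pd$mean_net_charge, 1)
  # hand evaluation: H = (KD(D)+4.5)/9 = 1/9; boundary 2.785/9 - 1.151 < 1
  expect_equal(pd$mean_hydrophobicity, 1 / 9)
  expect_equal(pd$classification, "disordered-side")
  po <- charge_hydrophobicity(residue_sequence(strrep("I", 10)))
  expect_equal(po$classification, "ordered-side")
})
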