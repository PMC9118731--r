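test_that("segmentation handles empty and short sequences without repeats", {
  ann0 <- segment_repeats(residue_sequence(""))
  expect_length(ann0$repeats, 0)
  short <- residue_sequence("ACDEFGHIKL")
  ann1 <- segment_repeats(short)
  expect_length(ann1$repeats, 0)
  expect_equal(ann1$residual, 10)
  expect_error(segment_repeats(short, consensus = list()), "consensus")
})

test_that("tandem consensus copies segment at offsets 0, 33, 66", {
  unit <- "DGNTPLHLAARNGHLEVVKLLLEAGADVNAQDK"
  seq <- residue_sequence(strrep(unit, 3))
  ann <- segment_repeats(seq)
  expect_length(ann$repeats, 3)
  expect_equal(vapply(ann$repeats, function(r) r$offset, 0), c(1, 34, 67))
  expect_equal(ann$residual, 0)
  # brute force: each placed offset is the top-scoring among those
  # overlapping it
  pwm <- ank_consensus_pwm()
  letters <- strsplit(seq$letters, "")[[1]]
  scores <- vapply(seq_len(length(letters) - 32), function(s) {
    idx <- match(letters[s:(s + 32)], rownames(pwm))
    sum(pwm[cbind(idx, 1:33)])
  }, 0)
  for (r in ann$repeats) {
    window <- max(1, r$offset - 32):min(length(scores), r$offset + 32)
    expect_equal(r$offset, window[which.max(scores[window])])
  }
})

test_that("repeats are disjoint, ordered, and account for the domain", {
  unit <- "DGNTPLHLAARNGHLEVVKLLLEAGADVNAQDK"
  seq <- residue_sequence(paste0("GGGG", strrep(unit, 2), "PPP"))
  ann <- segment_repeats(seq)
  spans <- lapply(ann$repeats, `[[`, "span")
  if (length(spans) > 1) {
    for (i in seq_len(length(spans) - 1)) {
      expect_lt(spans[[i]][2], spans[[i + 1]][1])
    }
  }
  expect_equal(33 * length(ann$repeats) + ann$residual, nchar(seq$letters))
})

test_that("n_expected forces the best k non-overlapping placements", {
  unit <- "DGNTPLHLAARNGHLEVVKLLLEAGADVNAQDK"
  seq <- residue_sequence(strrep(unit, 4))
  ann <- segment_repeats(seq, n_expected = 2)
  expect_length(ann$repeats, 2)
})

test_that("template mode labels follow the positional template exactly", {
  seq <- residue_sequence(strrep("A", 33))
  ann <- segment_repeats(seq, n_expected = 1)
  ann <- assign_elements(ann)
  expect_equal(ann$repeats[[1]]$element_labels, ank_element_template())
  tpl <- ank_element_template()
  expect_equal(which(tpl == "a1"), 5:12)
  expect_equal(which(tpl == "a2"), 15:24)
  expect_equal(which(tpl == "bhp"), 25:31)
})

test_that("structure mode recovers the built helices and hairpin", {
  m <- make_repeat_structure(3, start_number = 1872)
  s <- extract_sequence(m, "A")
  ann <- assign_elements(segment_repeats(s), m, "A")
  for (rp in ann$repeats) {
    lab <- rp$element_labels
    expect_true(all(lab[5:12] == "a1"))       # built first helix
    expect_true(all(lab[16:23] == "a2"))      # built second helix (interior)
    expect_true(any(lab == "bhp"))
    expect_true(all(which(lab == "bhp") >= 25 & which(lab == "bhp") <= 31))
    runs <- rle(lab)
    expect_equal(sum(runs$values == "a1"), 1)
    expect_equal(sum(runs$values == "a2"), 1)
    expect_equal(sum(runs$values == "bhp"), 1)
  }
  bad <- segment_repeats(extract_sequence(m, "A"))
  bad$repeats[[1]]$span <- bad$repeats[[1]]$span + 5000
  expect_error(assign_elements(bad, m, "A"), "lacks residues")
})

test_that("composition profiles count the selected class and sum to one", {
  s <- residue_sequence("AAAA")
  p <- composition_profile(s, rep("a1", 4), "helix")
  expect_equal(unname(p$frequencies["A"]), 1)
  expect_equal(p$n, 4)
  expect_equal(sum(p$frequencies), 1)

  s2 <- residue_sequence("ADAD")
  p2 <- composition_profile(s2, c("a1", "bhp", "a1", "bhp"), "helix")
  expect_equal(unname(p2$frequencies["A"]), 1)
  expect_equal(p2$n, 2)
  p3 <- composition_profile(s2, c("a1", "bhp", "a1", "bhp"), "hairpin")
  expect_equal(unname(p3$frequencies["D"]), 1)

  empty <- composition_profile(s2, rep("a1", 4), "loop")
  expect_equal(empty$n, 0)
  expect_error(composition_profile(s2, c("a1", "a1"), "all"), "parallel")
})

test_that("composition frequencies sum to one across random cases", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    letters <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                            replace = TRUE), collapse = "")
    labels <- sample(c("a1", "a2", "bhp", "loop"), n, replace = TRUE)
    p <- composition_profile(residue_sequence(letters), labels, "all")
    expect_equal(sum(p$frequencies), 1)
  }
})

test_that("enrichment is zero against itself and matches hand arithmetic", {
  s <- residue_sequence("ADKE")
  p <- composition_profile(s, rep("a1", 4), "helix")
  e <- enrichment(p, p)
  expect_true(all(e$table$log2_ratio == 0))

  ft <- setNames(numeric(20), sort(c("A","C","D","E","F","G","H","I","K","L",
                                     "M","N","P","Q","R","S","T","V","W","Y")))
  fr <- ft
  ft["A"] <- 0.5; fr["A"] <- 0.25
  tp <- structure(list(element_class = "helix", frequencies = ft, n = 4),
                  class = "CompositionProfile")
  rp <- structure(list(element_class = "helix", frequencies = fr, n = 4),
                  class = "CompositionProfile")
  e2 <- enrichment(tp, rp, pseudocount = 0)
  expect_equal(e2$table$log2_ratio[e2$table$aa == "A"], 1)
  mismatched <- structure(list(element_class = "loop", frequencies = fr, n = 4),
                          class = "CompositionProfile")
  expect_error(enrichment(tp, mismatched), "classes differ")
})

test_that("percent similarity matches hand-scored columns", {
  expect_equal(percent_similarity(residue_sequence("ACDE"),
                                  residue_sequence("ACDE")), 100)
  # E vs G scores negative under BLOSUM62: 3 of 4 columns positive
  expect_equal(percent_similarity(residue_sequence("ACDE"),
                                  residue_sequence("ACDG")), 75)
  expect_error(percent_similarity(residue_sequence(""),
                                  residue_sequence("ACD")), "non-empty")
})

test_that("percent similarity is symmetric and 100 only for identity", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    a <- residue_sequence(paste(sample(aas, 12, TRUE), collapse = ""))
    b <- residue_sequence(paste(sample(aas, 12, TRUE), collapse = ""))
    expect_equal(percent_similarity(a, b), percent_similarity(b, a))
  }
  a <- residue_sequence("WWWWWW")
  b <- residue_sequence("WWWWWA")  # W-A is negative under BLOSUM62
  expect_lt(percent_similarity(a, b), 100)
})

test_that("alignment score agrees with exhaustive enumeration on tiny inputs", {
  cases <- list(c("ACD", "AD"), c("WLK", "WK"), c("AAG", "AG"),
                c("MKV", "MKV"), c("ACDEF", "ACEF"), c("KRDE", "KDE"))
  for (cs in cases) {
    oracle <- brute_force_align_score(cs[1], cs[2], blosum62,
                                      gap_open = 10, gap_extend = 1)
    aln <- Biostrings::pairwiseAlignment(
      cs[1], cs[2], type = "global", substitutionMatrix = blosum62,
      gapOpening = 10, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle)
  }
})
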