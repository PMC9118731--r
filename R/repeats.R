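# Ankyrin repeat segmentation and composition analysis
#
# The ankyrin (ANK) repeat is a 33-residue module: two antiparallel
# alpha-helices (a1, a2) followed by a beta-hairpin (bhp), with short
# connecting loops. Tandem copies stack into the ankyrin domain, whose long
# axis is roughly perpendicular to the helices. Segmentation scans a
# sequence with a position-weight matrix (PWM) built from a packaged set of
# consensus-derived 33-residue repeats and selects the maximal-scoring
# non-overlapping placement by dynamic programming.

# Consensus-derived 33-residue ankyrin repeats (curated around the classic
# TPLH...GADVNA signature; not extracts of any particular protein).
ANK_REPEAT_SET <- c(
  "DGNTPLHLAARNGHLEVVKLLLEAGADVNAQDK",
  "SGHTPLHLAAQEGHLEIVEVLLKAGADVNAKDM",
  "DGRTPLHIAAREGHLEVVKLLLDNGADVNARDK",
  "NGQTALHLAAKNGHLEIVKLLLQHGADVNAQDK",
  "DGNTPLHLAARSGNLEVVRLLLEAGADVNSKDS",
  "TGKTPLHVAAENGHLEVVRYLLEAGANVNAQTK",
  "DGFTPLHLAAHEGHLEIVEVLLKNGADVNAKDN",
  "SGRTPLHLASRNGHLPVVELLLSHGADVNAQDK"
)

ANK_REPEAT_LENGTH <- 33L

#' Position-weight matrix for the ankyrin repeat
#'
#' Log-odds matrix (natural log, uniform background) over a 33-column
#' alignment of consensus-derived ankyrin repeats.
#'
#' @param sequences character vector of aligned repeat sequences, all the
#'   same length.
#' @param pseudocount added per amino acid per column before normalising.
#' @return 20 x L numeric matrix (rows named by amino acid) with attribute
#'   `width`.
#' @export
ank_consensus_pwm <- function(sequences = ANK_REPEAT_SET, pseudocount = 0.5) {
  if (length(sequences) == 0) stop("empty consensus set")
  w <- unique(nchar(sequences))
  if (length(w) != 1) stop("consensus sequences have unequal lengths")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  mat <- matrix(pseudocount, nrow = 20, ncol = w,
                dimnames = list(AA_ALPHABET, NULL))
  for (s in sequences) {
    letters <- strsplit(toupper(s), "")[[1]]
    for (j in seq_len(w)) {
      if (letters[j] %in% AA_ALPHABET) {
        mat[letters[j], j] <- mat[letters[j], j] + 1
      }
    }
  }
  freq <- sweep(mat, 2, colSums(mat), "/")
  pwm <- log(freq / (1 / 20))
  attr(pwm, "width") <- w
  pwm
}

score_offsets <- function(letters, pwm) {
  w <- attr(pwm, "width")
  n <- length(letters)
  if (n < w) return(numeric(0))
  idx <- match(letters, rownames(pwm))  # NA for X: scored as background (0)
  vapply(seq_len(n - w + 1L), function(s) {
    cols <- seq_len(w)
    rows <- idx[s + cols - 1L]
    sum(pwm[cbind(rows[!is.na(rows)], cols[!is.na(rows)])])
  }, numeric(1))
}

# Weighted interval scheduling over candidate starts (all widths = w).
# Maximises total score over non-overlapping placements; ties resolved in
# favour of the leftmost placement set.
select_placements <- function(scores, w, threshold, n_expected = NULL) {
  n <- length(scores)
  if (n == 0) return(integer(0))
  if (is.null(n_expected)) {
    keep <- which(scores > threshold)
    if (length(keep) == 0) return(integer(0))
    best <- numeric(n + 1)   # best[i+1]: best total using starts <= i
    take <- logical(n)
    for (i in seq_len(n)) {
      skip <- best[i]
      if (i %in% keep) {
        prev <- if (i - w >= 1) best[i - w + 1] else 0
        with_i <- prev + scores[i]
        if (with_i >= skip - 1e-12) {  # prefer taking (leftmost) on ties
          best[i + 1] <- with_i
          take[i] <- TRUE
        } else best[i + 1] <- skip
      } else best[i + 1] <- skip
    }
    starts <- integer(0)
    i <- n
    while (i >= 1) {
      if (take[i] && abs(best[i + 1] - ((if (i - w >= 1) best[i - w + 1] else 0) +
                                          scores[i])) < 1e-9) {
        starts <- c(i, starts)
        i <- i - w
      } else i <- i - 1
    }
    starts
  } else {
    k_max <- min(n_expected, n %/% 1)
    # DP with cardinality: best[k, i] over starts <= i using exactly k
    best <- matrix(-Inf, nrow = k_max + 1, ncol = n + 1)
    best[1, ] <- 0
    for (k in seq_len(k_max)) {
      for (i in seq_len(n)) {
        skip <- best[k + 1, i]
        prev <- if (i - w >= 1) best[k, i - w + 1] else if (k == 1) 0 else -Inf
        best[k + 1, i + 1] <- max(skip, prev + scores[i])
      }
    }
    k <- max(which(is.finite(best[, n + 1]))) - 1
    if (k == 0) return(integer(0))
    starts <- integer(0)
    i <- n
    while (k > 0 && i >= 1) {
      prev <- if (i - w >= 1) best[k, i - w + 1] else if (k == 1) 0 else -Inf
      if (is.finite(prev) && abs(best[k + 1, i + 1] - (prev + scores[i])) < 1e-9) {
        starts <- c(i, starts)
        i <- i - w
        k <- k - 1
      } else i <- i - 1
    }
    starts
  }
}

#' Segment a sequence into 33-residue ankyrin repeats
#'
#' @param seq a [residue_sequence()].
#' @param consensus PWM from [ank_consensus_pwm()].
#' @param n_expected optionally force the number of repeats (the best
#'   `n_expected` non-overlapping placements regardless of threshold).
#' @param threshold minimum PWM log-odds score for a placement (default 0:
#'   better than uniform background).
#' @return object of class `RepeatAnnotation`: `repeats` (list with `index`,
#'   `span` in author numbers, `offset` 1-based sequence position,
#'   `element_labels`), `domain_span`, `residual` (unassigned residue count)
#'   and the segmented sequence.
#' @export
segment_repeats <- function(seq, consensus = ank_consensus_pwm(),
                            n_expected = NULL, threshold = 0) {
  if (!inherits(seq, "ResidueSequence")) stop("seq must be a ResidueSequence")
  if (is.null(attr(consensus, "width")) || !is.matrix(consensus)) {
    stop("malformed consensus profile (expected PWM with width attribute)")
  }
  w <- attr(consensus, "width")
  letters <- seq_letters(seq)
  n <- length(letters)
  scores <- score_offsets(letters, consensus)
  starts <- select_placements(scores, w, threshold, n_expected)
  repeats <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    list(index = k,
         span = c(seq$numbering[s], seq$numbering[s + w - 1L]),
         offset = s,
         score = scores[s],
         element_labels = NULL)
  })
  assigned <- sum(lengths(lapply(starts, function(s) seq(s, s + w - 1L))))
  structure(
    list(seq = seq,
         domain_span = if (n > 0) c(seq$numbering[1], seq$numbering[n])
                       else c(NA_integer_, NA_integer_),
         repeats = repeats,
         residual = n - assigned),
    class = "RepeatAnnotation"
  )
}

#' @export
print.RepeatAnnotation <- function(x, ...) {
  cat("RepeatAnnotation:", length(x$repeats), "repeat(s), residual",
      x$residual, "residue(s)\n")
  for (r in x$repeats) {
    cat(sprintf("  ANK%d  %d-%d  score %.1f\n", r$index, r$span[1],
                r$span[2], r$score))
  }
  invisible(x)
}

#' Positional element template for a 33-residue repeat
#'
#' Positions 5-12 are the first helix (a1), 15-24 the second (a2), 25-31 the
#' beta-hairpin (bhp); everything else is loop.
#' @return character vector of length 33 with values `a1`, `a2`, `bhp`, `loop`.
#' @export
ank_element_template <- function() {
  tpl <- rep("loop", ANK_REPEAT_LENGTH)
  tpl[5:12] <- "a1"
  tpl[15:24] <- "a2"
  tpl[25:31] <- "bhp"
  tpl
}

# CA-geometry helix detection: residue windows with ideal alpha i,i+3 and
# i,i+4 CA distances mark i..i+4 as helical.
helical_mask <- function(ca) {
  n <- nrow(ca)
  helical <- logical(n)
  if (n < 5) return(helical)
  for (i in seq_len(n - 4)) {
    d13 <- sqrt(sum((ca[i, ] - ca[i + 3, ])^2))
    d14 <- sqrt(sum((ca[i, ] - ca[i + 4, ])^2))
    if (d13 > 4.2 && d13 < 5.9 && d14 > 4.9 && d14 < 7.0) {
      helical[i:(i + 4)] <- TRUE
    }
  }
  helical
}

runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Label repeat positions with secondary-structure elements
#'
#' With no structure, the fixed positional template applies. With a model,
#' helices are detected from CA geometry (two helical runs per repeat become
#' a1 and a2) and the segment following a2, trimmed of the final two
#' positions, becomes the beta-hairpin.
#'
#' @param annotation a `RepeatAnnotation`.
#' @param model optional `StructureModel` whose `chain_id` chain carries the
#'   annotated residues (matched by author number).
#' @param chain_id chain to use when `model` is given.
#' @param template positional template for sequence-only mode.
#' @return the annotation with `element_labels` filled per repeat.
#' @export
assign_elements <- function(annotation, model = NULL, chain_id = NULL,
                            template = ank_element_template()) {
  if (length(annotation$repeats) == 0) stop("annotation has no repeats")
  w <- ANK_REPEAT_LENGTH
  if (is.null(model)) {
    for (k in seq_along(annotation$repeats)) {
      annotation$repeats[[k]]$element_labels <- template
    }
    return(annotation)
  }
  if (is.null(chain_id)) chain_id <- model_chains(model)[1]
  ca <- model$atoms[model$atoms$chain == chain_id &
                      model$atoms$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno, ca$ins), , drop = FALSE]
  for (k in seq_along(annotation$repeats)) {
    rp <- annotation$repeats[[k]]
    pos <- match(seq(rp$span[1], rp$span[2]), ca$resno)
    if (anyNA(pos)) {
      stop("model chain ", chain_id, " lacks residues ", rp$span[1], "-",
           rp$span[2], " of repeat ", rp$index)
    }
    coords <- as.matrix(ca[pos, c("x", "y", "z")])
    helical <- helical_mask(coords)
    labels <- rep("loop", w)
    runs <- runs_of(helical)
    runs <- runs[runs$end - runs$start + 1 >= 4, , drop = FALSE]
    if (nrow(runs) >= 1) labels[runs$start[1]:runs$end[1]] <- "a1"
    if (nrow(runs) >= 2) {
      labels[runs$start[2]:runs$end[2]] <- "a2"
      hp_start <- runs$end[2] + 1
      hp_end <- w - 2
      if (hp_start <= hp_end) labels[hp_start:hp_end] <- "bhp"
    }
    annotation$repeats[[k]]$element_labels <- labels
  }
  annotation
}

#' Per-residue element labels across an annotated sequence
#'
#' @param annotation a `RepeatAnnotation` with elements assigned.
#' @return character vector parallel to the annotation's sequence; residues
#'   outside any repeat are labelled `residual`.
#' @export
annotation_labels <- function(annotation) {
  n <- nchar(annotation$seq$letters)
  labels <- rep("residual", n)
  for (rp in annotation$repeats) {
    if (is.null(rp$element_labels)) {
      stop("element labels not assigned; run assign_elements() first")
    }
    labels[rp$offset:(rp$offset + ANK_REPEAT_LENGTH - 1L)] <- rp$element_labels
  }
  labels
}

ELEMENT_CLASSES <- list(
  "helix"   = c("a1", "a2"),
  "hairpin" = "bhp",
  "loop"    = "loop",
  "all"     = c("a1", "a2", "bhp", "loop", "residual")
)

#' Amino-acid composition of an element class
#'
#' @param seq a [residue_sequence()].
#' @param labels per-residue element labels parallel to `seq` (values `a1`,
#'   `a2`, `bhp`, `loop`, `residual`).
#' @param element_class one of `"helix"` (a1 + a2), `"hairpin"`, `"loop"`,
#'   `"all"`.
#' @return object of class `CompositionProfile`: `frequencies` (named over
#'   the 20 amino acids, summing to 1 when `n > 0`), `n`, `element_class`.
#'   `X` residues are excluded from the count.
#' @export
composition_profile <- function(seq, labels, element_class = "all") {
  letters <- seq_letters(seq)
  if (length(labels) != length(letters)) {
    stop("labels not parallel to sequence (", length(labels), " vs ",
         length(letters), ")")
  }
  cls <- match.arg(element_class, names(ELEMENT_CLASSES))
  sel <- letters[labels %in% ELEMENT_CLASSES[[cls]] & letters %in% AA_ALPHABET]
  freq <- setNames(numeric(20), AA_ALPHABET)
  if (length(sel) > 0) {
    tab <- table(factor(sel, levels = AA_ALPHABET))
    freq[] <- as.numeric(tab) / length(sel)
  }
  structure(list(element_class = cls, frequencies = freq, n = length(sel)),
            class = "CompositionProfile")
}

#' Log2 composition enrichment of a target profile over a reference
#'
#' @param target,reference `CompositionProfile`s of the same element class.
#' @param pseudocount added to both frequencies (keeps absent residues
#'   finite).
#' @return object of class `EnrichmentTable`: data.frame with `aa` and
#'   `log2_ratio = log2((f_t + p)/(f_r + p))`.
#' @export
enrichment <- function(target, reference, pseudocount = 0.01) {
  if (!identical(target$element_class, reference$element_class)) {
    stop("element classes differ: ", target$element_class, " vs ",
         reference$element_class)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  ratio <- log2((target$frequencies + pseudocount) /
                  (reference$frequencies + pseudocount))
  structure(
    list(element_class = target$element_class,
         table = data.frame(aa = AA_ALPHABET, log2_ratio = unname(ratio))),
    class = "EnrichmentTable"
  )
}

#' Percent similarity under global alignment
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties; similarity
#' is the fraction of alignment columns, excluding terminal gaps, whose pair
#' of residues has a positive substitution score.
#'
#' @param a,b [residue_sequence()]s (non-empty).
#' @param matrix substitution matrix name available in Biostrings (default
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend positive gap penalties.
#' @return percentage in `[0, 100]`.
#' @export
percent_similarity <- function(a, b, matrix = "BLOSUM62",
                               gap_open = 10, gap_extend = 1) {
  if (nchar(a$letters) == 0 || nchar(b$letters) == 0) {
    stop("percent_similarity requires non-empty sequences")
  }
  submat <- if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else matrix
  aln <- Biostrings::pairwiseAlignment(
    a$letters, b$letters, type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(p)
  gap <- p == "-" | s == "-"
  lead <- 0
  while (lead < ncol_aln && gap[lead + 1]) lead <- lead + 1
  trail <- 0
  while (trail < ncol_aln - lead && gap[ncol_aln - trail]) trail <- trail + 1
  cols <- seq.int(lead + 1, ncol_aln - trail)
  if (length(cols) == 0) return(0)
  pos <- vapply(cols, function(j) {
    if (gap[j]) return(FALSE)
    pj <- p[j]; sj <- s[j]
    pj %in% rownames(submat) && sj %in% colnames(submat) &&
      submat[pj, sj] > 0
  }, logical(1))
  100 * sum(pos) / length(cols)
}
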