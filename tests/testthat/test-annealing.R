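test_that("template extension is U->T conversion plus an A-run", {
  t1 <- extend_template(rnas[["miR-222-21 nt"]], tail_length = 4)
  expect_identical(t1$sequence, "AGCTACATCTGGCTACTGGGTAAAA")
  t2 <- extend_template(rnas[["miR-222-21 nt"]], tail_length = 0)
  expect_identical(t2$sequence, t2$core)
  t3 <- extend_template(rnas[["RNA#1"]], tail_length = 10)
  expect_identical(t3$sequence,
                   paste0("GAAGGAGGGTGACCTGATAAACCAA", strrep("A", 10)))
})

test_that("annealing profiles report terminal and window mismatches", {
  t21 <- extend_template(rnas[["miR-222-21 nt"]], name = "21nt")
  t25 <- extend_template(rnas[["miR-222-25 nt"]], name = "25nt")
  t221_23 <- extend_template(rnas[["miR-221-23 nt"]], name = "221-23")

  # a 24 nt primer on the 21 nt template: positions 22-24 (C,T,C) face the
  # poly(A) tail
  pr <- anneal_profile(forward_primer("F222-24", primers[["F222-24"]]), t21)
  expect_equal(pr$terminal_mismatch_run, 3L)
  expect_equal(pr$window_mismatches, 3L)
  expect_equal(pr$internal_mismatches, 0L)

  # prefix primer on a longer isoform: perfect match
  pr2 <- anneal_profile(forward_primer("F222-21", primers[["F222-21"]]), t25)
  expect_true(all(pr2$match_vector))
  expect_equal(pr2$terminal_mismatch_run, 0L)

  # 4A tail over T,T,C then the template tail A
  pr3 <- anneal_profile(forward_primer("F221-20-4A",
                                       primers[["F221-20-4A"]]), t221_23)
  expect_equal(pr3$window_mismatches, 3L)
  expect_equal(pr3$terminal_mismatch_run, 0L)

  # primer longer than the extended template is a coverage error
  expect_error(anneal_profile(forward_primer("p", strrep("A", 30)),
                              extend_template("AGCUACAUCUGGCUACUGGGU",
                                              tail_length = 2)),
               "extends past")
})

test_that("the classification cascade reproduces the selectivity rules", {
  f222 <- fams[["miR-222"]]
  t21 <- extend_template(rnas[["miR-222-21 nt"]], name = "21nt")
  t23 <- extend_template(rnas[["miR-222-23 nt"]], name = "23nt")
  t24 <- extend_template(rnas[["miR-222-24 nt"]], name = "24nt")
  cls <- function(p, t) predict_amplification(p, t)$class

  # unmodified primer two bases past the template 3' end: blocked
  expect_identical(cls(design_forward_primer(f222, 23, 0), t21), "blocked")
  # tailed short primer against +3 nt isoform: blocked (3 window mismatches)
  expect_identical(cls(design_forward_primer(f222, 21, 4), t24), "blocked")
  # +2 nt isoform: reduced (2 window mismatches)
  expect_identical(cls(design_forward_primer(f222, 21, 4), t23), "reduced")
  # A-rich 3' context weakens blocking to reduced
  expect_identical(cls(design_forward_primer(fams[["RNA#1"]], 21, 4),
                       extend_template(rnas[["RNA#1"]], name = "RNA#1")),
                   "reduced")
  # a tailed long primer on a short isoform: the A-run pairs with poly(A),
  # restoring enough terminal stability -> reduced, not blocked
  p24_4a <- design_forward_primer(f222, 24, 4)
  pr <- anneal_profile(p24_4a, t21)
  expect_equal(pr$internal_mismatches, 3L)
  expect_equal(pr$window_mismatches, 0L)
  expect_identical(cls(p24_4a, t21), "reduced")
  # single terminal mismatch is only reduced
  expect_identical(cls(design_forward_primer(f222, 22, 0), t21), "reduced")
})

test_that("central mismatches discriminate with short but not long primers", {
  t7 <- extend_template(rnas[["RNA#7"]], name = "RNA#7")
  t7m <- extend_template(rnas[["RNA#7-MIS"]], name = "RNA#7-MIS")
  cls <- function(nm, t)
    predict_amplification(forward_primer(nm, primers[[nm]]), t)$class
  # two central mismatches over 22 nt cross the internal-fraction threshold
  expect_identical(cls("F7MIS-22", t7), "reduced")
  expect_identical(cls("F7-22", t7m), "reduced")
  # the same two mismatches over 27 nt do not
  expect_identical(cls("F7MIS-27", t7), "amplified")
  expect_identical(cls("F7-27", t7m), "amplified")
  # on-target pairs amplify
  expect_identical(cls("F7-22", t7), "amplified")
  expect_identical(cls("F7MIS-22", t7m), "amplified")
  # the 4A tail potentiates the discrimination (reduced -> blocked)
  expect_identical(cls("F7MIS-22-4A", t7), "blocked")
  expect_identical(cls("F7-22-4A", t7m), "blocked")
})

test_that("classes agree with an independent rule oracle on all fixture pairs", {
  templates <- lapply(names(rnas), function(n)
    extend_template(rnas[[n]], tail_length = 10, name = n))
  pnames <- regenerable_primer_names()
  n_pairs <- 0L
  for (pn in pnames) {
    p <- forward_primer(pn, primers[[pn]])
    for (tmpl in templates) {
      got <- predict_amplification(p, tmpl)$class
      want <- oracle_class(p$sequence, tmpl$sequence)
      expect_identical(got, want,
                       label = sprintf("%s vs %s", pn, tmpl$name))
      n_pairs <- n_pairs + 1L
    }
  }
  expect_gte(n_pairs, 200L)
})

test_that("efficiency is monotone in window and terminal mismatches", {
  rules <- efficiency_rules()
  set.seed(42)
  # random match vectors up to 28 positions; flipping any matched position
  # in the 3' window to a mismatch must never increase efficiency
  for (rep in 1:200) {
    n <- sample(18:28, 1)
    mv <- stats::runif(n) > 0.25
    base <- paste(ifelse(mv, "A", "C"), collapse = "")
    tmpl <- extend_template(dna_to_rna(strrep("A", n)), tail_length = 0)
    prof <- anneal_profile(forward_primer("p", base), tmpl)
    eff0 <- classify_annealing(prof, rules)$efficiency
    flip <- which(mv)
    if (!length(flip)) next
    i <- sample(flip, 1)
    mv2 <- mv; mv2[i] <- FALSE
    prof2 <- anneal_profile(
      forward_primer("p", paste(ifelse(mv2, "A", "C"), collapse = "")), tmpl)
    expect_lte(classify_annealing(prof2, rules)$efficiency, eff0)
  }
})

test_that("prefix and deficit properties hold across whole families", {
  # an unmodified primer targeting length L amplifies every templated
  # isoform of length >= L and is blocked on isoforms of length <= L - 2
  for (fn in c("miR-221", "miR-222", "RNA#7")) {
    fam <- fams[[fn]]
    ref_len <- nchar(fam$reference_sequence)
    for (L in 18:ref_len) {
      p <- design_forward_primer(fam, L, 0)
      for (tl in 18:ref_len) {
        tmpl <- extend_template(substr(fam$reference_sequence, 1, tl),
                                name = sprintf("%s-%d", fn, tl))
        cls <- predict_amplification(p, tmpl)$class
        if (tl >= L) expect_identical(cls, "amplified",
                                      label = sprintf("%s L=%d tl=%d", fn, L, tl))
        if (tl <= L - 2L) expect_identical(cls, "blocked",
                                           label = sprintf("%s L=%d tl=%d", fn, L, tl))
      }
    }
  }
})

test_that("adding a 4A tail never lowers efficiency on shorter templates", {
  rules <- efficiency_rules()
  for (fn in names(fams)) {
    fam <- fams[[fn]]
    ref_len <- nchar(fam$reference_sequence)
    for (L in 18:ref_len) {
      p0 <- design_forward_primer(fam, L, 0)
      p4 <- design_forward_primer(fam, L, 4)
      for (tl in 18:L) {
        tmpl <- extend_template(substr(fam$reference_sequence, 1, tl),
                                name = "t", tail_length = 15)
        e0 <- predict_amplification(p0, tmpl, rules)$efficiency
        e4 <- predict_amplification(p4, tmpl, rules)$efficiency
        expect_gte(e4, e0)
      }
    }
  }
})

test_that("4A short primers beat unmodified short primers on long RNAs", {
  rules <- efficiency_rules()
  stems <- c("RNA#1" = 21L, "RNA#2" = 22L, "RNA#3" = 22L, "RNA#4" = 22L,
             "RNA#5" = 22L, "RNA#6" = 21L, "RNA#7" = 22L)
  for (fn in names(stems)) {
    fam <- fams[[fn]]
    L <- stems[[fn]]
    tmpl <- extend_template(fam$reference_sequence, name = fn)
    e_short_4a <- predict_amplification(
      design_forward_primer(fam, L, 4), tmpl, rules)$efficiency
    e_short <- predict_amplification(
      design_forward_primer(fam, L, 0), tmpl, rules)$efficiency
    e_long <- predict_amplification(
      design_forward_primer(fam, nchar(fam$reference_sequence), 0),
      tmpl, rules)$efficiency
    expect_lt(e_short_4a, e_short)
    expect_lte(e_short, e_long)
  }
})

test_that("classification is invariant to the modelled tail length", {
  f222 <- fams[["miR-222"]]
  for (tl in c(8, 10, 15, 30)) {
    tmpl <- extend_template(rnas[["miR-222-21 nt"]], tail_length = tl)
    expect_identical(
      predict_amplification(design_forward_primer(f222, 21, 4), tmpl)$class,
      "amplified")
    expect_identical(
      predict_amplification(design_forward_primer(f222, 24, 4), tmpl)$class,
      "reduced")
  }
})

test_that("cross-amplification matrix reconstructs the unmodified panel", {
  f222 <- fams[["miR-222"]]
  panel <- lapply(21:25, function(L) design_forward_primer(f222, L, 0))
  templates <- lapply(21:25, function(L)
    extend_template(rnas[[sprintf("miR-222-%d nt", L)]],
                    name = sprintf("miR-222-%d nt", L)))
  m <- cross_amplification_matrix(panel, templates)
  # row-normalized diagonal is 100%
  expect_equal(unname(diag(m$percent)), rep(100, 5))
  # every pair with a >= 2 nt primer overhang is annotated '#'
  for (i in 1:5) for (j in 1:5) {
    deficit <- (20 + j) - (20 + i)  # primer target - template length
    if (deficit >= 2) {
      expect_identical(m$class[i, j], "blocked")
      expect_identical(m$flag[i, j], "#")
    }
    if (deficit <= 0) expect_identical(m$class[i, j], "amplified")
  }
})

test_that("cross-amplification matrix reconstructs the 4A panel", {
  f222 <- fams[["miR-222"]]
  panel <- lapply(21:25, function(L) design_forward_primer(f222, L, 4))
  templates <- lapply(21:25, function(L)
    extend_template(rnas[[sprintf("miR-222-%d nt", L)]],
                    name = sprintf("miR-222-%d nt", L)))
  m <- cross_amplification_matrix(panel, templates)
  # the short-target tailed primer: amplified up to +1 nt, reduced at
  # +2 nt, blocked beyond
  expect_identical(unname(m$class[, "F222-21-4A"]),
                   c("amplified", "amplified", "reduced", "blocked",
                     "blocked"))
  expect_equal(unname(diag(m$percent)), rep(100, 5))
})

test_that("degenerate and failing matrix cases are handled", {
  f222 <- fams[["miR-222"]]
  p <- design_forward_primer(f222, 21, 0)
  t21 <- extend_template(rnas[["miR-222-21 nt"]], name = "miR-222-21 nt")
  m <- cross_amplification_matrix(list(p), list(t21))
  expect_equal(unname(m$percent[1, 1]), 100)
  # no on-target primer for a row
  t24 <- extend_template(rnas[["miR-222-24 nt"]], name = "miR-222-24 nt")
  expect_error(cross_amplification_matrix(list(p), list(t24)),
               "no on-target")
  # but an explicit reference rescues it
  m2 <- cross_amplification_matrix(list(p), list(t24),
                                   reference_primers = "F222-21")
  expect_equal(unname(m2$percent[1, 1]), 100)
})
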