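# Topography metric hierarchy.

seg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

test_that("match_segments pairs helices one-to-one by overlap", {
  m <- match_segments(seg(5, 25), seg(7, 23), min_overlap = 3)
  expect_identical(nrow(m$pairs), 1L)
  expect_identical(m$pairs$overlap, 17L)

  # the larger-overlap predicted helix wins; the other stays unmatched
  m2 <- match_segments(seg(5, 25), seg(1, 6, 20, 30), min_overlap = 3)
  expect_identical(nrow(m2$pairs), 1L)
  expect_identical(m2$pairs$pred_idx, 2L)
  expect_identical(m2$pairs$overlap, 6L)
  expect_identical(m2$unmatched_predicted, 1L)

  m3 <- match_segments(seg(5, 25, 40, 60), seg(numeric(0)), min_overlap = 3)
  expect_identical(nrow(m3$pairs), 0L)
  expect_identical(m3$unmatched_observed, c(1L, 2L))
})

test_that("matcher attains the exhaustive-enumeration maximum pair count", {
  set.seed(57)
  for (rep in 1:200) {
    L <- sample(40:120, 1)
    obs <- random_segments(L, max_segs = 4L)
    pred <- random_segments(L, max_segs = 4L)
    t <- sample(1:5, 1)
    m <- match_segments(obs, pred, min_overlap = t)
    expect_identical(nrow(m$pairs), max_pairs_oracle(obs, pred, t))
    # contract: every pair respects the threshold, partition holds
    expect_true(all(m$pairs$overlap >= t))
    expect_identical(sort(c(m$pairs$obs_idx, m$unmatched_observed)),
                     seq_len(nrow(obs)))
    expect_identical(sort(c(m$pairs$pred_idx, m$unmatched_predicted)),
                     seq_len(nrow(pred)))
  }
})

test_that("per-protein correctness requires all and only all helices", {
  perfect <- match_segments(seg(3, 10, 20, 30, 40, 50),
                            seg(3, 10, 20, 30, 40, 50))
  expect_true(per_protein_correct(perfect))
  spurious <- match_segments(seg(3, 10, 20, 30, 40, 50),
                             seg(3, 10, 20, 30, 40, 50, 60, 70))
  expect_false(per_protein_correct(spurious))
  vacuous <- match_segments(seg(numeric(0)), seg(numeric(0)))
  expect_true(per_protein_correct(vacuous))
})

test_that("pooled segment scores divide pairs by observed and predicted", {
  # 10 observed, 8 predicted, 7 matched across two proteins
  m1 <- match_segments(seg(1, 10, 21, 30, 41, 50, 61, 70, 81, 90, 101, 110),
                       seg(1, 10, 21, 30, 41, 50, 61, 70, 81, 90))
  m2 <- match_segments(seg(1, 10, 21, 30, 41, 50, 61, 70),
                       seg(1, 10, 21, 30, 121, 130))
  sc <- dataset_segment_scores(list(m1, m2))
  expect_identical(sc$n_observed, 10L)
  expect_identical(sc$n_predicted, 8L)
  expect_identical(sc$n_pairs, 7L)
  expect_equal(sc$sens, 70)
  expect_equal(sc$spec, 87.5)

  none <- dataset_segment_scores(match_segments(seg(1, 10), seg(numeric(0))))
  expect_equal(none$sens, 0)
  expect_true(is.na(none$spec))
})

test_that("swap symmetry: sens(obs,pred) equals spec(pred,obs)", {
  set.seed(91)
  for (rep in 1:50) {
    L <- sample(40:120, 1)
    a <- random_segments(L)
    b <- random_segments(L)
    s1 <- dataset_segment_scores(match_segments(a, b))
    s2 <- dataset_segment_scores(match_segments(b, a))
    expect_equal(s1$sens, s2$spec)
    expect_equal(s1$spec, s2$sens)
  }
})

test_that("boundary accuracy pools end deviations over matched pairs", {
  b1 <- boundary_accuracy(match_segments(seg(5, 25), seg(7, 23)))
  expect_equal(b1$boundary_exact, 0)
  expect_equal(b1$boundary_within2, 100)
  expect_equal(b1$boundary_mad, 2)

  b2 <- boundary_accuracy(match_segments(seg(5, 25), seg(5, 25)))
  expect_equal(b2$boundary_exact, 100)
  expect_equal(b2$boundary_mad, 0)

  # pairs (5,25)v(5,28) and (40,50)v(38,50): deviations 0,3,2,0
  b3 <- boundary_accuracy(match_segments(seg(5, 25, 40, 50),
                                         seg(5, 28, 38, 50)))
  expect_equal(b3$boundary_exact, 50)
  expect_equal(b3$boundary_within2, 75)
  expect_equal(b3$boundary_mad, 1.25)

  b4 <- boundary_accuracy(match_segments(seg(5, 25), seg(numeric(0))))
  expect_true(is.na(b4$boundary_exact))
  expect_true(is.na(b4$boundary_mad))
})

test_that("residue confusion counts position by position, M positive", {
  cc <- residue_confusion("iiMMMoo", "iiMMMoo")
  expect_identical(cc, list(tp = 3L, fp = 0L, tn = 4L, fn = 0L))
  cc2 <- residue_confusion("iiMMMoo", "iMMMMoo")
  expect_identical(cc2, list(tp = 3L, fp = 1L, tn = 3L, fn = 0L))
  cc3 <- residue_confusion("iiooUii", "UUUUUUU")
  expect_identical(cc3$tn, 7L)
  expect_identical(cc3$tp, 0L)
})

test_that("MCC follows the formula with the zero-factor convention", {
  expect_equal(mcc(list(tp = 8, tn = 10, fp = 2, fn = 0)),
               80 / sqrt(10 * 8 * 12 * 10))
  expect_equal(mcc(list(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  # all-M prediction on mixed truth: a zero column
  cc <- residue_confusion("iiMMMoo", "MMMMMMM")
  expect_equal(mcc(cc), 0)
})

test_that("MCC is invariant under simultaneous class swap", {
  set.seed(17)
  for (rep in 1:30) {
    L <- sample(30:100, 1)
    a <- random_states(L)
    b <- random_states(L)
    cc <- residue_confusion(a, b)
    swapped <- list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
    expect_equal(mcc(cc), mcc(swapped))
  }
})

test_that("Sov matches hand-checkable extremes", {
  s <- "UUMMMMMMUU"
  expect_equal(sov(s, s), 100)
  expect_equal(sov("UUUUMMMMMMMMMMMMMMMMUUUU", "UUUUUUUUUUUUUUUUUUUUUUUU"), 0)
  expect_true(is.na(sov("UUUU", "UUMM")))
  expect_equal(sov("UUMMMMMMUU", "UUUMMMMMMU"),
               sov_oracle("UUMMMMMMUU", "UUUMMMMMMU"))
})

test_that("Sov agrees with the literal-formula oracle on random pairs", {
  set.seed(23)
  for (rep in 1:200) {
    L <- sample(30:120, 1)
    a <- random_states(L)
    if (!nrow(segments_from_states(a))) next
    b <- random_states(L)
    expect_equal(sov(a, b), sov_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("aggregation pools and averages at the documented granularity", {
  r1 <- score_protein("iiMMMMMoo", "iiMMMMMoo")   # perfect
  r2 <- score_protein("iiMMMMMoo", "iiiiiiioo")   # missed helix
  agg <- aggregate_topography(list(r1, r2))
  expect_equal(agg$q_ok, 50)
  expect_equal(agg$q2, mean(c(100, 100 * 4 / 9)))
  expect_equal(agg$sens, 50)
  # single protein: aggregate equals its own scores
  solo <- aggregate_topography(list(r1))
  expect_equal(solo$q_ok, 100)
  expect_equal(solo$q2, r1$q2)
  expect_equal(solo$sov, r1$sov)
  expect_error(aggregate_topography(list()), "empty")
})

test_that("perfect and empty predictions hit the score extremes", {
  set.seed(31)
  spec <- generator_spec(n_proteins = 5, class_mix = c(helical_membrane = 1),
                         seed = 5)
  refs <- generate_dataset(spec)$references
  res_perfect <- lapply(refs, function(r) score_protein(r$states, r$states))
  agg <- aggregate_topography(res_perfect)
  expect_equal(agg$q_ok, 100)
  expect_equal(agg$sens, 100)
  expect_equal(agg$spec, 100)
  expect_equal(agg$mcc, 1)
  expect_equal(agg$sov, 100)
  expect_equal(agg$boundary_mad, 0)

  res_empty <- lapply(refs, function(r) {
    empty <- gsub("M", "U", r$states)
    score_protein(r$states, empty)
  })
  agg0 <- aggregate_topography(res_empty)
  expect_equal(agg0$q_ok, 0)
  expect_equal(agg0$sens, 0)
})
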