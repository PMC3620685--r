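# Synthetic fixture generator and the logged perturbation model.

test_that("generated datasets are deterministic and splittable", {
  spec <- generator_spec(n_proteins = 8, seed = 99)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$records, d2$records)
  expect_identical(lapply(d1$references, `[[`, "states"),
                   lapply(d2$references, `[[`, "states"))
  # growing the dataset leaves earlier proteins untouched
  d3 <- generate_dataset(generator_spec(n_proteins = 12, seed = 99))
  expect_identical(d3$references[["SYN0005"]]$states,
                   d1$references[["SYN0005"]]$states)
  # empty dataset
  d0 <- generate_dataset(generator_spec(n_proteins = 0, seed = 99))
  expect_identical(nrow(d0$records), 0L)
})

test_that("generated annotations satisfy the reference invariants", {
  spec <- generator_spec(n_proteins = 30, p_half_membrane = 0.3, seed = 3)
  d <- generate_dataset(spec)
  for (k in seq_len(nrow(d$records))) {
    ref <- d$references[[d$records$id[k]]]
    expect_identical(ref$helices[, c("start", "end")],
                     segments_from_states(ref$states))
    expect_identical(nchar(ref$states), nchar(d$records$sequence[k]))
    if (d$records$chain_class[k] != "helical_membrane") {
      expect_identical(nrow(ref$helices), 0L)
      expect_identical(d$records$helix_profile[k], "none")
    } else {
      expect_gt(nrow(ref$helices), 0L)
      has_half <- any(ref$helices$kind == "half_membrane")
      expect_identical(d$records$helix_profile[k],
                       if (has_half) "has_half_membrane" else "tm_only")
      # loops alternate across full-TM helices, repeat around half-membrane
      expect_identical(flag_half_membrane(ref)$helices$kind,
                       ref$helices$kind)
    }
  }
})

test_that("p_half_membrane = 0 yields no re-entrant helices", {
  spec <- generator_spec(n_proteins = 15, p_half_membrane = 0,
                         class_mix = c(helical_membrane = 1), seed = 21)
  d <- generate_dataset(spec)
  kinds <- unlist(lapply(d$references, function(r)
    flag_half_membrane(r)$helices$kind))
  expect_true(all(kinds == "full_tm"))
})

test_that("zero perturbation reproduces the reference exactly", {
  spec <- generator_spec(n_proteins = 5, class_mix = c(helical_membrane = 1),
                         seed = 8)
  refs <- generate_dataset(spec)$references
  ps <- perturbation_spec(seed = 1)
  for (ref in refs) {
    out <- perturb(ref, ps)
    expect_identical(out$prediction$states, ref$states)
    expect_identical(nrow(out$log), 0L)
    sc <- score_protein(ref$states, out$prediction$states)
    expect_true(sc$topo_ok)
    expect_equal(sc$sov, 100)
    expect_equal(sc$mcc, 1)
  }
})

test_that("dropping every helix forces zero sensitivity", {
  spec <- generator_spec(n_proteins = 1, helix_count_range = c(3, 3),
                         class_mix = c(helical_membrane = 1), seed = 14)
  ref <- generate_dataset(spec)$references[[1]]
  out <- perturb(ref, perturbation_spec(p_drop_helix = 1, seed = 2))
  expect_identical(nrow(segments_from_states(out$prediction$states)), 0L)
  expect_identical(sum(out$log$op == "drop"), 3L)
  sc <- dataset_segment_scores(match_segments(
    segments_from_states(ref$states),
    segments_from_states(out$prediction$states)))
  expect_equal(sc$sens, 0)
  expect_true(is.na(sc$spec))
})

test_that("replaying the log reproduces the perturbed prediction exactly", {
  set.seed(55)
  for (rep in 1:40) {
    spec <- generator_spec(n_proteins = 1, p_half_membrane = 0.2,
                           class_mix = c(helical_membrane = 0.9,
                                         soluble = 0.1),
                           seed = rep)
    ref <- generate_dataset(spec)$references[[1]]
    ps <- perturbation_spec(boundary_jitter_max = sample(0:3, 1),
                            p_drop_helix = runif(1, 0, 0.6),
                            p_insert_helix = runif(1),
                            p_flip_orientation = runif(1, 0, 0.5),
                            p_merge_adjacent = runif(1, 0, 0.5),
                            seed = 1000 + rep)
    out <- perturb(ref, ps)
    expect_identical(replay_log(ref, out$log), out$prediction$states)
  }
})

test_that("a uniform +2 boundary shift gives the forced boundary scores", {
  # constructed log: every helix end shifted by exactly +2
  ref <- reference_annotation(
    "P", "iiiiiMMMMMMMMMMooooooooMMMMMMMMMMiiiiiii")
  h <- ref$helices
  log <- data.frame(op = "jitter", h = seq_len(nrow(h)),
                    a = h$start, b = h$end,
                    c = h$start + 2L, d = h$end + 2L)
  pred <- replay_log(ref, log)
  b <- boundary_accuracy(match_segments(segments_from_states(ref$states),
                                        segments_from_states(pred)))
  expect_equal(b$boundary_exact, 0)
  expect_equal(b$boundary_within2, 100)
  expect_equal(b$boundary_mad, 2)
  # and the oracle sees the same thing
  e <- expected_scores_from_log(ref, log)
  expect_identical(as.numeric(e$boundary_devs), rep(2, 4))
})

test_that("expected_scores_from_log matches direct edit arithmetic", {
  ref <- reference_annotation(
    "P", paste0("iii", "MMMMMMMMMM", "ooo", "MMMMMMMMMM", "iii",
                "MMMMMMMMMM", "ooo", "MMMMMMMMMM", "iii"))
  # drop 1 of 4 helices
  e1 <- expected_scores_from_log(ref, data.frame(op = "drop", h = 2L,
                                                 a = NA, b = NA,
                                                 c = NA, d = NA))
  expect_identical(e1$n_pairs, 3L)
  expect_identical(e1$n_observed, 4L)
  expect_false(e1$topo_ok)
  # insert 1 spurious helix beside 4 correct ones: spec 4/5
  pred5 <- paste0("iii", "MMMMMMMMMM", "ooo", "MMMMMMMMMM", "iii",
                  "MMMMMMMMMM", "ooo", "MMMMMMMMMM", "iMM")
  m <- match_segments(segments_from_states(ref$states),
                      segments_from_states(pred5), min_overlap = 2)
  sc <- dataset_segment_scores(m)
  expect_equal(sc$sens, 100)
  expect_equal(sc$spec, 80)
  # flip orientation only: topography untouched, orientation wrong
  e3 <- expected_scores_from_log(ref, data.frame(op = "flip", h = NA,
                                                 a = NA, b = NA,
                                                 c = NA, d = NA))
  expect_true(e3$topo_ok)
  expect_false(e3$orientation)
  expect_equal(e3$q2, 100)
})
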