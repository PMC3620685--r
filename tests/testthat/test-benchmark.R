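# Benchmark orchestration: score tables, subset summaries, rendering.

make_bench_fixture <- function(seed = 5, n = 12) {
  spec <- generator_spec(n_proteins = n, class_mix = c(helical_membrane = 1),
                         seed = seed)
  d <- generate_dataset(spec)
  d
}

test_that("a perfect method scores 100 everywhere", {
  d <- make_bench_fixture()
  preds <- lapply(d$references, `[[`, "states")
  cfg <- subset_config(similarity_threshold = NA, max_resolution = NA,
                       methods = c("xray", "nmr", "other"))
  tab <- run_benchmark(cfg, d$records, d$references,
                       list(perfect = preds))$table
  expect_equal(tab$q_ok, 100)
  expect_equal(tab$sens, 100)
  expect_equal(tab$spec, 100)
  expect_equal(tab$boundary_exact, 100)
  expect_equal(tab$boundary_mad, 0)
  expect_equal(tab$mcc, 1)
  expect_equal(tab$sov, 100)
  expect_equal(tab$localisation, 100)
  expect_equal(tab$orientation, 100)
  expect_equal(tab$res_topology, 100)
  expect_identical(tab$n_proteins, nrow(d$records))
})

test_that("methods missing predictions are scored on the intersection", {
  d <- make_bench_fixture()
  preds <- lapply(d$references, `[[`, "states")
  half <- preds[seq_len(length(preds) %/% 2)]
  cfg <- subset_config(similarity_threshold = NA, max_resolution = NA,
                       methods = c("xray", "nmr", "other"))
  tab <- run_benchmark(cfg, d$records, d$references,
                       list(full = preds, partial = half))$table
  expect_identical(tab$n_proteins[tab$method == "full"], length(preds))
  expect_identical(tab$n_proteins[tab$method == "partial"], length(half))
  # intersection scoring never degrades the scores themselves
  expect_equal(tab$q_ok, c(100, 100))
})

test_that("decoy chains with false-positive helices depress specificity", {
  spec <- generator_spec(n_proteins = 24,
                         class_mix = c(helical_membrane = 0.5,
                                       beta_barrel = 0.2, soluble = 0.3),
                         seed = 77)
  d <- generate_dataset(spec)
  # method that always predicts one helix, even on decoys
  fp <- perturb_dataset(d$references,
                        perturbation_spec(p_insert_helix = 1, seed = 31),
                        method = "overcaller")
  preds <- lapply(fp$predictions, `[[`, "states")
  cfg_hel <- subset_config(similarity_threshold = NA, max_resolution = NA,
                           methods = c("xray", "nmr", "other"))
  cfg_all <- subset_config(similarity_threshold = NA, max_resolution = NA,
                           classes = c("helical_membrane", "beta_barrel",
                                       "soluble"),
                           methods = c("xray", "nmr", "other"))
  t_hel <- run_benchmark(cfg_hel, d$records, d$references,
                         list(overcaller = preds))$table
  t_all <- run_benchmark(cfg_all, d$records, d$references,
                         list(overcaller = preds))$table
  # adding decoys adds predicted helices with nothing to match
  expect_lt(t_all$spec, t_hel$spec)
  expect_equal(t_all$sens, t_hel$sens)  # observed helices unchanged
})

test_that("subset summary counts helices by kind and always adds up", {
  d <- make_bench_fixture(seed = 42, n = 15)
  s <- summarize_subset(d$records, d$references)
  expect_identical(s$n_mh, s$n_tmh + s$n_half)
  expect_identical(s$n_seqs, 15L)
  expect_identical(unname(s$per_class["helical_membrane"]), 15L)
  # empty subset
  empty <- summarize_subset(d$records[0, ], d$references)
  expect_identical(empty$n_seqs, 0L)
  expect_identical(empty$n_mh, 0L)
})

test_that("removing a protein leaves other per-protein scores unchanged", {
  d <- make_bench_fixture(seed = 9, n = 6)
  pert <- perturb_dataset(d$references,
                          perturbation_spec(boundary_jitter_max = 2,
                                            p_drop_helix = 0.3, seed = 4))
  preds <- lapply(pert$predictions, `[[`, "states")
  per_protein <- function(ids) {
    lapply(ids, function(id)
      score_protein(d$references[[id]]$states, preds[[id]]))
  }
  all_ids <- names(preds)
  drop_one <- setdiff(all_ids, all_ids[3])
  a <- per_protein(drop_one)
  b <- per_protein(all_ids)[match(drop_one, all_ids)]
  expect_equal(a, b)
})

test_that("benchmark runs are deterministic end to end", {
  d <- make_bench_fixture(seed = 11, n = 8)
  pert <- perturb_dataset(d$references,
                          perturbation_spec(boundary_jitter_max = 2,
                                            p_drop_helix = 0.2,
                                            p_flip_orientation = 0.2,
                                            seed = 6))
  preds <- lapply(pert$predictions, `[[`, "states")
  cfg <- subset_config(similarity_threshold = NA, max_resolution = NA,
                       methods = c("xray", "nmr", "other"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(run_benchmark(cfg, d$records, d$references,
                                  list(m = preds)), f1)
  write_score_table(run_benchmark(cfg, d$records, d$references,
                                  list(m = preds)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("run_benchmark applies the similarity threshold via hobohm2", {
  d <- make_bench_fixture(seed = 13, n = 4)
  ids <- d$records$id
  m <- matrix(10, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 80  # ids 1 and 2 redundant
  diag(m) <- 100
  sim <- structure(list(ids = ids, values = m, alignment_kind = "global"),
                   class = "tm_simmatrix")
  preds <- lapply(d$references, `[[`, "states")
  cfg <- subset_config(similarity_threshold = 30, max_resolution = NA,
                       methods = c("xray", "nmr", "other"))
  out <- run_benchmark(cfg, d$records, d$references, list(m = preds),
                       similarity = sim)
  expect_identical(length(out$subset_ids), 3L)
  expect_false(ids[2] %in% out$subset_ids)  # lexicographically greatest of the pair
})

test_that("visual comparison wraps and marks symmetric differences", {
  seqv <- paste(rep("A", 130), collapse = "")
  obs <- states_from_segments(data.frame(start = 20, end = 40), 130,
                              side_fill = paste(rep("i", 130), collapse = ""))
  pred <- states_from_segments(data.frame(start = 25, end = 45), 130,
                               side_fill = paste(rep("i", 130), collapse = ""))
  block <- render_comparison(seqv, obs, pred, id = "P1")
  lines <- strsplit(block, "\n")[[1]]
  expect_identical(sum(startsWith(lines, "SEQ")), 3L)  # 60 + 60 + 10
  dif <- paste(substring(lines[startsWith(lines, "DIF")], 12), collapse = "")
  starred <- which(strsplit(dif, "")[[1]] == "*")
  expect_identical(starred, c(20:24, 41:45))  # symmetric difference

  same <- render_comparison(seqv, obs, obs)
  difs <- substring(grep("^DIF", strsplit(same, "\n")[[1]], value = TRUE), 12)
  expect_true(all(grepl("^ *$", difs)))
  expect_error(render_comparison("AA", "iii", "iii"), "length")
})
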