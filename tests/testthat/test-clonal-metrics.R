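test_that("annotation validation enforces the generation graph", {
  expect_s3_class(toy_annotation(), "generation_annotation")
  expect_error(toy_annotation(generations = c(2L, 3L, 4L)), "generation 1")
  expect_error(toy_annotation(generations = c(1L, 3L, 3L)), "generation - 1")
})

test_that("IS counts are distinct per scope", {
  ann <- toy_annotation()
  shared <- toy_matrix(matrix(c(10, 10, 10), nrow = 1,
                              dimnames = list(NULL, c("T1", "T2", "T3"))))
  cnt <- is_counts(shared, ann)
  expect_identical(cnt$total, 1L)
  expect_equal(unname(cnt$per_tumor), c(1, 1, 1))
  # set-algebra oracle on a synthetic experiment
  rec <- default_record()
  cm <- record_matrix(rec)
  cnt2 <- is_counts(cm, generation_annotation(rec$design))
  brute <- length(unique(cm$is_ids[rowSums(cm$detected) > 0]))
  expect_identical(cnt2$total, brute)
})

test_that("generation exclusivity covers the boundary cases and the printed arithmetic", {
  ann <- toy_annotation()
  disjoint <- toy_matrix(cbind(T1 = c(5, 0, 0), T2 = c(0, 5, 0),
                               T3 = c(0, 0, 5)))
  expect_equal(generation_exclusive_fraction(disjoint, ann), 1)
  identical_sets <- toy_matrix(cbind(T1 = c(5, 5), T2 = c(5, 5),
                                     T3 = c(5, 5)))
  expect_equal(generation_exclusive_fraction(identical_sets, ann), 0)
  # 183 of 236 IS in a single generation gives the published 78%
  expect_equal(round(183 / 236, 2), 0.78)
  n_multi <- 236 - 183
  reads <- cbind(T1 = c(rep(1, 100), rep(1, n_multi), rep(0, 83)),
                 T2 = c(rep(0, 100), rep(1, n_multi), rep(1, 43), rep(0, 40)),
                 T3 = c(rep(0, 100), rep(0, n_multi), rep(0, 43), rep(1, 40)))
  cm236 <- toy_matrix(reads)
  expect_equal(round(generation_exclusive_fraction(cm236, ann), 2), 0.78)
})

test_that("detected-once fractions count single-tumor IS with per-generation denominators", {
  ann <- toy_annotation()
  once_all <- toy_matrix(cbind(T1 = c(1, 0, 0), T2 = c(0, 1, 0),
                               T3 = c(0, 0, 1)))
  expect_equal(detected_once_fraction(once_all, ann)$overall, 1)
  twice <- toy_matrix(cbind(T1 = 1, T2 = 1, T3 = 0))
  expect_equal(detected_once_fraction(twice, ann)$overall, 0)
  # brute-force multiplicity oracle on synthetic data
  rec <- default_record()
  cm <- record_matrix(rec)
  res <- detected_once_fraction(cm, generation_annotation(rec$design))
  mult <- rowSums(cm$detected)
  expect_equal(res$overall, mean(mult[mult > 0] == 1))
  # detected-once IS are always generation-exclusive
  ann2 <- generation_annotation(rec$design)
  gen_of <- ann2$generation[match(cm$tumor_ids, ann2$tumor_id)]
  n_gens <- apply(cm$detected, 1, function(d) length(unique(gen_of[d])))
  expect_true(all(n_gens[mult == 1] == 1))
})

test_that("dominant-clone persistence fraction matches an exhaustive scan", {
  ann <- toy_annotation()
  everywhere <- toy_matrix(cbind(T1 = c(9, 1), T2 = c(9, 1), T3 = c(9, 1)))
  expect_equal(dominant_nonpersistent_fraction(everywhere, ann), 0)
  confined <- toy_matrix(cbind(T1 = c(9, 1, 0), T2 = c(0, 0, 1),
                               T3 = c(0, 0, 0)))
  expect_equal(dominant_nonpersistent_fraction(confined, ann), 1)
  rec <- default_record()
  cm <- record_matrix(rec)
  ann2 <- generation_annotation(rec$design)
  got <- dominant_nonpersistent_fraction(cm, ann2, 0.5)
  gen_of <- ann2$generation[match(cm$tumor_ids, ann2$tumor_id)]
  dom <- which(apply(cm$contribution, 1, max) >= 0.5)
  brute <- mean(vapply(dom, function(i)
    length(unique(gen_of[cm$detected[i, ]])) == 1L, logical(1)))
  expect_equal(got, brute)
})

test_that("prior-generation fraction contrasts succession against hierarchy", {
  ann <- toy_annotation()
  reuse <- toy_matrix(cbind(T1 = c(1, 1), T2 = c(1, 1), T3 = c(1, 1)))
  expect_equal(unname(prior_generation_fraction(reuse, ann)), 1)
  allnew <- toy_matrix(cbind(T1 = c(1, 0, 0), T2 = c(0, 1, 0),
                             T3 = c(0, 0, 1)))
  expect_equal(unname(prior_generation_fraction(allnew, ann)), 0)
  pg <- function(scenario, seeds, ...) {
    vapply(seeds, function(s) {
      rec <- simulate_serial_experiment(
        simulation_config(seed = s, scenario = scenario, ...))
      unname(prior_generation_fraction(record_matrix(rec),
                                       generation_annotation(rec$design)))
    }, numeric(1))
  }
  succ <- pg("succession", 601:615)
  hier <- pg("hierarchy", 701:715, p_inactivate = 0)
  expect_gt(median(hier), median(succ))
})

test_that("pairwise overlap is the sibling Jaccard index", {
  ann <- generation_annotation(data.frame(
    tumor_id = c("T1", "A", "B"), patient = "P1", experiment = "E1",
    generation = c(1L, 2L, 2L), parent_tumor = c(NA, "T1", "T1"),
    stringsAsFactors = FALSE))
  same <- toy_matrix(cbind(T1 = c(1, 1), A = c(1, 1), B = c(1, 1)))
  expect_equal(pairwise_overlap(same, ann)$overlap, 1)
  disjoint <- toy_matrix(cbind(T1 = c(1, 1), A = c(1, 0), B = c(0, 1)))
  expect_equal(pairwise_overlap(disjoint, ann)$overlap, 0)
  half <- toy_matrix(cbind(T1 = c(1, 1, 1), A = c(1, 1, 0), B = c(1, 0, 1)))
  expect_equal(pairwise_overlap(half, ann)$overlap, 1 / 3)
  expect_equal(pairwise_overlap(half, ann, denominator = "smaller")$overlap,
               1 / 2)
})

test_that("metrics are invariant to row and column permutations", {
  rec <- default_record()
  cm <- record_matrix(rec)
  ann <- generation_annotation(rec$design)
  set.seed(31)
  pi_r <- sample(length(cm$is_ids)); pi_c <- sample(length(cm$tumor_ids))
  cmp <- cm
  cmp$contribution <- cm$contribution[pi_r, pi_c]
  cmp$detected <- cm$detected[pi_r, pi_c]
  cmp$is_ids <- cm$is_ids[pi_r]; cmp$tumor_ids <- cm$tumor_ids[pi_c]
  expect_equal(generation_exclusive_fraction(cmp, ann),
               generation_exclusive_fraction(cm, ann))
  expect_equal(detected_once_fraction(cmp, ann)$overall,
               detected_once_fraction(cm, ann)$overall)
  expect_equal(dominant_nonpersistent_fraction(cmp, ann),
               dominant_nonpersistent_fraction(cm, ann))
  expect_equal(sort(pairwise_overlap(cmp, ann)$overlap),
               sort(pairwise_overlap(cm, ann)$overlap))
})

test_that("summary aggregates all metrics consistently", {
  rec <- default_record()
  cm <- record_matrix(rec)
  ann <- generation_annotation(rec$design)
  s <- succession_summary(cm, ann)
  expect_identical(s$counts$total, is_counts(cm, ann)$total)
  expect_true(all(unlist(s[c("generation_exclusive_fraction")]) >= 0))
  expect_output(print(s), "Distinct IS")
})
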