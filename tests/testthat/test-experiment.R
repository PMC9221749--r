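# Cross-validation plan, CI aggregation, experiment runner plumbing.

check_plan_invariants <- function(ids, plan) {
  n <- length(ids)
  expect_length(plan$entries, plan$repetitions * plan$folds)
  # the groups' test ids partition all ids into ~n/groups chunks
  test_sets <- list()
  for (r in seq_len(plan$repetitions)) {
    tests <- unique(lapply(plan$entries[vapply(plan$entries, `[[`, 1,
                                               "repetition") == r],
                           `[[`, "test_ids"))
    expect_length(tests, 1)
    test_sets[[r]] <- tests[[1]]
    expect_length(setdiff(tests[[1]], ids), 0)
    expect_true(length(tests[[1]]) %in%
                  c(floor(n / plan$groups), ceiling(n / plan$groups)))
  }
  if (plan$repetitions == plan$groups)
    expect_setequal(unlist(test_sets), ids)
  for (e in plan$entries) {
    # disjoint and covering per entry
    expect_length(intersect(e$test_ids, e$val_ids), 0)
    expect_length(intersect(e$test_ids, e$train_ids), 0)
    expect_length(intersect(e$val_ids, e$train_ids), 0)
    expect_setequal(c(e$test_ids, e$val_ids, e$train_ids), ids)
  }
  # within a repetition the folds' val ids partition the non-test ids
  for (r in seq_len(plan$repetitions)) {
    es <- plan$entries[vapply(plan$entries, `[[`, 1, "repetition") == r]
    vals <- unlist(lapply(es, `[[`, "val_ids"))
    expect_equal(anyDuplicated(vals), 0)
    expect_setequal(vals, setdiff(ids, test_sets[[r]]))
  }
}

test_that("cv plan invariants hold for n in {15, 100, 1781}", {
  for (n in c(15, 100, 1781)) {
    ids <- sprintf("img_%04d", seq_len(n))
    plan <- make_cv_plan(ids, seed = 42)
    check_plan_invariants(ids, plan)
  }
  # frozen arithmetic at the reference dataset size
  plan <- make_cv_plan(sprintf("i%04d", 1:1781), seed = 1)
  sizes <- sort(vapply(plan$entries[c(1, 4, 7, 10, 13)],
                       function(e) length(e$test_ids), numeric(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(357, 356, 356, 356, 356))
  # and at n = 15: |test| = 3, |val| = 4, |train| = 8
  p15 <- make_cv_plan(sprintf("i%02d", 1:15), seed = 1)
  e <- p15$entries[[1]]
  expect_equal(c(length(e$test_ids), length(e$val_ids),
                 length(e$train_ids)), c(3, 4, 8))
})

test_that("cv plan is deterministic and validates input", {
  ids <- sprintf("a%03d", 1:40)
  expect_identical(make_cv_plan(ids, seed = 5), make_cv_plan(ids, seed = 5))
  expect_false(identical(make_cv_plan(ids, seed = 5),
                         make_cv_plan(ids, seed = 6)))
  expect_error(make_cv_plan(sprintf("a%d", 1:14)), "at least")
  expect_error(make_cv_plan(rep("a", 20)), "unique")
  expect_error(make_cv_plan(ids, repetitions = 6), "exceed")
})

test_that("aggregate_ci matches Student-t arithmetic", {
  # zero variance: degenerate interval
  s <- aggregate_ci(rep(0.8, 15))
  expect_equal(s$ci_low, 0.8)
  expect_equal(s$ci_high, 0.8)
  # {0, 1}: half-width = t(.975, 1) * sd / sqrt(2) = 12.7062 * 0.5 = 6.3531
  s <- aggregate_ci(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci_high - s$mean, qt(0.975, 1) * sd(c(0, 1)) / sqrt(2))
  expect_equal(s$ci_high - s$mean, 6.3531, tolerance = 1e-4)
  # CI always contains the mean
  set.seed(50)
  for (i in 1:200) {
    x <- rnorm(sample(2:20, 1))
    s <- aggregate_ci(x)
    expect_lte(s$ci_low, s$mean)
    expect_gte(s$ci_high, s$mean)
  }
  expect_error(aggregate_ci(0.5), "at least 2")
})

test_that("oracle-driven experiment reports all-perfect summaries", {
  cfg <- tiny_gen_config()
  ds <- generate_dataset(cfg, 16, seed = 3)
  res <- run_experiment(ds, tile_counts = 1, oracle = oracle_model(),
                        seed = 2)
  expect_true(all(res$summary$mean == 1))
  expect_true(all(res$summary$ci_low <= res$summary$mean))
  expect_equal(nrow(res$results), 15 * 5)  # 15 entries x 5 channel rows
  # every image is tested exactly 3 times per tile setting
  counted <- table(unlist(lapply(res$plan$entries, `[[`, "test_ids")))
  expect_true(all(counted == 3))
})

test_that("oracle metrics are independent of tile count end to end", {
  cfg <- tiny_gen_config()
  ds <- generate_dataset(cfg, 16, seed = 4)
  om <- oracle_model(corrupt_period = 6)
  res <- run_experiment(ds, tile_counts = c(1, 6), oracle = om, seed = 2)
  s1 <- res$summary[res$summary$tile_count == 1,
                    c("channel", "metric", "mean")]
  s6 <- res$summary[res$summary$tile_count == 6,
                    c("channel", "metric", "mean")]
  rownames(s1) <- rownames(s6) <- NULL
  expect_equal(s1, s6)
})

test_that("experiment CSV output is byte-stable across runs", {
  cfg <- tiny_gen_config()
  ds <- generate_dataset(cfg, 16, seed = 9)
  om <- oracle_model(corrupt_period = 9)
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  unlink(c(d1, d2), recursive = TRUE)
  run_experiment(ds, tile_counts = c(1, 2), oracle = om, seed = 5,
                 out_dir = d1)
  run_experiment(ds, tile_counts = c(1, 2), oracle = om, seed = 5,
                 out_dir = d2)
  for (f in c("results.csv", "summary.csv", "convergence.csv")) {
    b1 <- readBin(file.path(d1, f), "raw", file.info(file.path(d1, f))$size)
    b2 <- readBin(file.path(d2, f), "raw", file.info(file.path(d2, f))$size)
    expect_identical(b1, b2, info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
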