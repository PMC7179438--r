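test_that("generators are deterministic under a fixed seed", {
  a <- simulate_compound_table(n_compounds = 15, seed = 42)
  b <- simulate_compound_table(n_compounds = 15, seed = 42)
  expect_identical(a, b)
  expect_identical(simulate_ranked_screen(seed = 5),
                   simulate_ranked_screen(seed = 5))
  ph <- a2a_pharmacophore()
  expect_identical(simulate_feature_cloud(ph, seed = 5, n_decoys = 4),
                   simulate_feature_cloud(ph, seed = 5, n_decoys = 4))
  # and they do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_compound_table(n_compounds = 5, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("zero-noise tables are exactly linear in the descriptors", {
  sim <- simulate_compound_table(n_compounds = 40, noise_sd = 0, seed = 3)
  fit <- fit_qsar(sim$table, names(sim$truth$betas))
  expect_lt(max(abs(fit$coefficients - sim$truth$betas)), 1e-8)
  expect_lt(abs(fit$intercept - sim$truth$intercept), 1e-8)
  # integer descriptors really are integers
  for (col in c("NA", "PF", "HG", "AR")) {
    expect_equal(sim$table[[col]], round(sim$table[[col]]))
  }
})

test_that("fitted coefficients cover the truth across replicates", {
  hits <- vapply(1:200, function(i) {
    sim <- simulate_compound_table(n_compounds = 200, noise_sd = 0.3, seed = i)
    fit <- fit_qsar(sim$table, names(sim$truth$betas))
    se <- summary(fit$lm)$coefficients[-1, "Std. Error"]
    all(abs(fit$coefficients - sim$truth$betas) <= 3 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("recovery error grows with the noise level", {
  err_at <- function(noise) {
    mean(vapply(1:40, function(i) {
      sim <- simulate_compound_table(n_compounds = 60, noise_sd = noise,
                                     seed = 1000 + i)
      fit <- fit_qsar(sim$table, names(sim$truth$betas))
      sqrt(mean((fit$coefficients - sim$truth$betas)^2))
    }, numeric(1)))
  }
  errs <- vapply(c(0.05, 0.3, 1.0), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("outlier injection shifts the labelled rows", {
  sim <- simulate_compound_table(n_compounds = 50, noise_sd = 0,
                                 outlier_fraction = 0.1, outlier_shift = 4,
                                 seed = 8)
  expect_length(sim$truth$outlier_ids, 5)
  clean <- simulate_compound_table(n_compounds = 50, noise_sd = 0, seed = 8)
  moved <- sim$table$pec50 - clean$table$pec50
  expect_setequal(sim$table$compound_id[abs(moved) > 1e-12],
                  sim$truth$outlier_ids)
  expect_true(all(abs(moved[abs(moved) > 1e-12] - 4) < 1e-12))
  expect_error(simulate_compound_table(betas = c(MV = 1),
                                       descriptor_ranges = list(MV = c(2, 1))),
               "low must be < high")
})

test_that("copula correlation induces correlated descriptors", {
  sim <- simulate_compound_table(n_compounds = 400, correlation = 0.9, seed = 2)
  cors <- cor(as.matrix(sim$table[c("MV", "MP")]))[1, 2]
  expect_gt(cors, 0.7)
  flat <- simulate_compound_table(n_compounds = 400, seed = 2)
  expect_lt(abs(cor(as.matrix(flat$table[c("MV", "MP")]))[1, 2]), 0.2)
})

test_that("ranked-screen pins place exact label counts in prefixes", {
  s <- simulate_ranked_screen(seed = 11)
  expect_equal(sum(s$label[1:13] == "agonist"), 12)
  expect_equal(sum(s$label[1:19] == "antagonist"), 4)
  expect_equal(as.vector(table(factor(s$label,
                                      c("agonist", "antagonist", "decoy")))),
               c(15, 15, 500))

  all_decoy <- simulate_ranked_screen(n_decoys = 30, n_agonists = 0,
                                      n_antagonists = 0, pins = NULL, seed = 1)
  curve <- recovery_curve(all_decoy)
  expect_true(all(curve$percent_agonists_recovered == 0))

  expect_error(simulate_ranked_screen(
    pins = list(agonist = c(k = 5, count = 12)), seed = 1), "infeasible")
  expect_error(simulate_ranked_screen(
    n_agonists = 3, pins = list(agonist = c(k = 13, count = 12)), seed = 1),
    "infeasible")
})

test_that("feature clouds honour jitter, decoys and rigid transforms", {
  ph <- a2a_pharmacophore()
  clean <- simulate_feature_cloud(ph, jitter_sd = 0, seed = 21)
  res <- match_pharmacophore(ph, clean)
  expect_true(res$matched)
  expect_lt(res$rmsd, 1e-6)

  with_decoys <- simulate_feature_cloud(ph, jitter_sd = 0, n_decoys = 10,
                                        seed = 22)
  expect_true(match_pharmacophore(ph, with_decoys)$matched)

  # jitter far beyond the tolerance radii destroys the match
  wrecked <- vapply(1:25, function(i) {
    cloud <- simulate_feature_cloud(ph, jitter_sd = 5 * max(ph$radius),
                                    seed = 100 + i)
    match_pharmacophore(ph, cloud)$matched
  }, logical(1))
  expect_true(all(!wrecked))
})
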