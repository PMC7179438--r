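test_that("subset enumeration matches the combinatorial design", {
  specs <- enumerate_models(c("MV", "MP", "NA", "PF", "HG", "AR"), sizes = 4:6)
  expect_equal(nrow(specs), 22)
  expect_equal(as.vector(table(specs$p)), c(15, 6, 1))
  expect_equal(nrow(enumerate_models(letters[1:6], sizes = 6)), 1)

  # brute-force nested-loop oracle for C(5, 2)
  vars <- letters[1:5]
  oracle <- list()
  for (i in 1:4) for (j in (i + 1):5) oracle <- c(oracle, list(c(vars[i], vars[j])))
  got <- enumerate_models(vars, sizes = 2)
  expect_equal(nrow(got), 10)
  expect_equal(got$descriptors, oracle)

  expect_error(enumerate_models(letters[1:3], sizes = 4), "sizes must lie")
  expect_error(enumerate_models(c("a", "a"), 1), "unique")
})

test_that("model statistics follow the n - p - 1 convention", {
  s <- model_stats(rss = 1 - 0.8944, tss = 1, n = 16, p = 4)
  expect_equal(round(s$r2_adj, 4), 0.8560)
  expect_equal(s$f, 23.2970, tolerance = 0.05 / 23)
  s5 <- model_stats(rss = 1 - 0.9281, tss = 1, n = 16, p = 5)
  expect_equal(round(s5$r2_adj, 4), 0.8922)
  null <- model_stats(rss = 5, tss = 5, n = 16, p = 4)
  expect_equal(null$f, 0)
  expect_equal(null$r, 0)
  expect_error(model_stats(1, 0, 16, 4), "tss")
  expect_error(model_stats(1, 2, 5, 4), "degrees of freedom")
})

test_that("OLS refit on the curated training set reproduces the reference model", {
  fit <- fit_qsar(training_table(), c("MV", "MP", "NA", "HG"),
                  exclude = study_outliers)
  expect_equal(fit$n_train, 16)
  expect_equal(fit$stats$r, 0.9457, tolerance = 5e-4 / 0.9457)
  expect_equal(fit$stats$see, 0.3228, tolerance = 5e-4)
  expect_equal(fit$stats$f, 23.2970, tolerance = 5e-3)
  ref <- a2a_models()$tetra
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-3)
})

test_that("an exactly linear activity is fitted perfectly", {
  sim <- simulate_compound_table(n_compounds = 25, noise_sd = 0, seed = 5)
  fit <- fit_qsar(sim$table, names(sim$truth$betas))
  expect_equal(fit$stats$r, 1, tolerance = 1e-10)
  expect_lt(fit$stats$see, 1e-8)
  expect_lt(max(abs(resid(fit$lm))), 1e-8)
  expect_equal(unname(fit$coefficients), unname(sim$truth$betas),
               tolerance = 1e-8)
})

test_that("fitted coefficients equal the normal-equations oracle", {
  set.seed(9)
  tbl <- tibble::tibble(compound_id = as.character(1:8),
                        d1 = rnorm(8), d2 = rnorm(8), pec50 = rnorm(8))
  attr(tbl, "descriptor_names") <- c("d1", "d2")
  fit <- fit_qsar(tbl, c("d1", "d2"))
  oracle <- normal_equations(tbl[c("d1", "d2")], tbl$pec50)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(oracle),
               tolerance = 1e-10)
})

test_that("OLS equals the oracle across 100 random well-conditioned tables", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    p <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    tbl <- tibble::as_tibble(as.data.frame(x))
    names(tbl) <- paste0("d", seq_len(p))
    tbl$compound_id <- as.character(seq_len(n))
    tbl$pec50 <- y
    attr(tbl, "descriptor_names") <- paste0("d", seq_len(p))
    fit <- fit_qsar(tbl, paste0("d", seq_len(p)))
    oracle <- normal_equations(x, y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("fit invariants hold: residual mean, r identity, row order", {
  tr <- training_table()
  fit <- fit_qsar(tr, c("MV", "MP", "NA", "PF", "HG"), exclude = study_outliers)
  expect_lt(abs(mean(resid(fit$lm))), 1e-10)
  expect_equal(fit$stats$r, sqrt(fit$stats$r2), tolerance = 1e-12)
  expect_equal(fit$stats$r, cor(fit$fitted, fit$observed), tolerance = 1e-12)
  expect_equal(fit$stats$r2_adj,
               1 - (1 - fit$stats$r2) * (fit$n_train - 1) / (fit$n_train - 5 - 1),
               tolerance = 1e-12)

  shuffled <- dplyr::slice(tr, sample(dplyr::n()))
  fit2 <- fit_qsar(shuffled, c("MV", "MP", "NA", "PF", "HG"),
                   exclude = study_outliers)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(fit2$stats, fit$stats, tolerance = 1e-12)
})

test_that("adding a descriptor never decreases r2", {
  tr <- training_table()
  subsets <- list(c("MV"), c("MV", "MP"), c("MV", "MP", "NA"),
                  c("MV", "MP", "NA", "PF"), c("MV", "MP", "NA", "PF", "HG"),
                  c("MV", "MP", "NA", "PF", "HG", "AR"))
  r2 <- vapply(subsets, function(s) {
    fit_qsar(tr, s, exclude = study_outliers)$stats$r2
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("degenerate designs raise informative errors", {
  tr <- training_table()
  dup <- dplyr::mutate(tr, MV2 = MV * 2)
  attr(dup, "descriptor_names") <- c(descriptor_names(tr), "MV2")
  expect_error(fit_qsar(dup, c("MV", "MV2")), "rank-deficient")
  expect_error(fit_qsar(tr[1:4, ], c("MV", "MP", "NA")), "at least p \\+ 2")
  expect_error(fit_qsar(tr, c("MV", "nope")), "missing descriptor.*nope")
})

test_that("model ranking follows r, then F, then SEE, then subset label", {
  fake <- tibble::tibble(
    subset = c("A", "B", "C", "D", "E"),
    r = c(0.96, 0.94, 0.96, 0.96, 0.96),
    f = c(20, 30, 25, 20, 20),
    see = c(0.30, 0.10, 0.20, 0.20, 0.30)
  )
  ranked <- rank_models(fake)
  expect_equal(ranked$subset, c("C", "D", "A", "E", "B"))

  # exhaustive pairwise-comparison sort oracle on random stat tables
  set.seed(31)
  for (i in 1:5) {
    m <- tibble::tibble(subset = sample(LETTERS[1:8]),
                        r = round(runif(8, 0.5, 1), 2),
                        f = round(runif(8, 5, 30), 1),
                        see = round(runif(8, 0.1, 0.5), 2))
    better <- function(a, b) {
      if (m$r[a] != m$r[b]) return(m$r[a] > m$r[b])
      if (m$f[a] != m$f[b]) return(m$f[a] > m$f[b])
      if (m$see[a] != m$see[b]) return(m$see[a] < m$see[b])
      m$subset[a] < m$subset[b]
    }
    idx <- seq_len(nrow(m))
    for (a in idx) for (b in idx) if (a != b && better(a, b) && better(b, a)) {
      fail("oracle comparison is not antisymmetric")
    }
    # selection sort with the oracle comparator
    order_oracle <- integer(0)
    left <- idx
    while (length(left)) {
      best <- left[1]
      for (cand in left[-1]) if (better(cand, best)) best <- cand
      order_oracle <- c(order_oracle, best)
      left <- setdiff(left, best)
    }
    expect_equal(rank_models(m)$subset, m$subset[order_oracle])
  }
})

test_that("best-subset search over the training fixture is reproducible", {
  models <- rank_models(fit_all_models(training_table(), sizes = 4,
                                       exclude = study_outliers))
  expect_equal(nrow(models), 15)
  # the volume/polarizability/atom-count/pharmacophore subset leads by raw r,
  # with the published hydrophobic-group variant immediately behind it
  expect_equal(models$subset[1], "MV+MP+NA+PF")
  expect_equal(models$subset[2], "MV+MP+NA+HG")
  expect_equal(models$r[2], 0.9457, tolerance = 5e-4)
  expect_true(all(diff(models$r) <= 1e-12))
})

test_that("pinned outlier mode reproduces the curated training split", {
  tr <- training_table()
  out <- detect_outliers(tr, c("MV", "MP", "NA", "HG"), ids = c(2:5, 8))
  expect_equal(out, as.character(c(2:5, 8)))
  kept <- dplyr::filter(tr, !compound_id %in% out)
  expect_equal(kept$compound_id, as.character(c(1, 6, 7, 9:21)))
  expect_error(detect_outliers(tr, "MV", ids = "99"), "not in table.*99")
})

test_that("iterative outlier rule flags contaminated rows and only those", {
  clean <- simulate_compound_table(n_compounds = 30, noise_sd = 0, seed = 13)
  expect_length(detect_outliers(clean$table, names(clean$truth$betas)), 0)

  noisy <- simulate_compound_table(n_compounds = 30, noise_sd = 0.1, seed = 17)
  tbl <- noisy$table
  tbl$pec50[tbl$compound_id == "12"] <- tbl$pec50[tbl$compound_id == "12"] + 5 * 0.1
  flagged <- detect_outliers(tbl, names(noisy$truth$betas), threshold = 2)
  expect_true("12" %in% flagged)

  # removal stops before the design becomes unfittable
  tiny <- simulate_compound_table(n_compounds = 7, noise_sd = 3, seed = 23)
  expect_error(
    detect_outliers(tiny$table, names(tiny$truth$betas), threshold = 0.1),
    "fewer than p \\+ 2"
  )
})

test_that("tidy and glance expose the model in broom style", {
  fit <- fit_qsar(training_table(), c("MV", "MP", "NA", "HG"),
                  exclude = study_outliers)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "MV", "MP", "NA", "HG"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 16)
  expect_equal(gl$p, 4)
  ref <- glance(a2a_models()$tetra)
  expect_equal(ref$r, 0.9457)
})
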