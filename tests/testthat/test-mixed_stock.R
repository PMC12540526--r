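test_that("immature filter applies the mean - 2 SD adult size rule", {
  ref <- c(105, 110, 115)  # mean 110, sd 5
  f <- filter_immature(c(99, 101, 100), ref)
  expect_equal(f$threshold, 100)
  expect_identical(f$kept, 1L)
  expect_identical(f$excluded, c(2L, 3L))  # threshold itself is adult-sized
  all_small <- filter_immature(c(50, 60, 70), ref)
  expect_identical(all_small$kept, 1:3)
  expect_warning(fm <- filter_immature(c(99, NA), ref), "missing CCL")
  expect_identical(fm$kept, 1:2)
  expect_error(filter_immature(c(90), c(110)), ">= 2")
})

test_that("Gelman-Rubin shrink factor matches hand-computed values", {
  n <- 50
  x <- rnorm(n)
  expect_equal(gelman_rubin(list(x, x)), sqrt((n - 1) / n))
  # W = 1, B = 13.5, n = 3 -> sqrt((2/3 + 4.5) / 1)
  expect_equal(gelman_rubin(list(1:3, 4:6)), sqrt(2 / 3 + 4.5))
  expect_identical(gelman_rubin(list(rep(1, 10), rep(2, 10))), Inf)
  expect_equal(gelman_rubin(list(rep(1, 10), rep(1, 10))), 1)
  expect_error(gelman_rubin(list(1:3)), "two chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal")
})

test_that("model building pools rookeries by MSA group and reports orphans", {
  rk <- frequency_table(matrix(c(5L, 5L, 0L, 8L, 2L, 0L, 0L, 0L, 10L),
                               3, 3, byrow = TRUE,
                               dimnames = list(c("FL1", "FL2", "ASC"),
                                               c("h1", "h2", "h3"))),
                        marker = "extended")
  mx <- frequency_table(matrix(c(4L, 1L, 3L, 2L), 1, 4,
                               dimnames = list("M1",
                                               c("h1", "h2", "h3", "h4"))),
                        marker = "extended")
  meta <- data.frame(abbrev = c("FL1", "FL2", "ASC"),
                     full_name = c("a", "b", "c"),
                     role = "rookery",
                     msa_group = c("USA", "USA", "ASC"),
                     nester_abundance = c(100, 200, 5000),
                     region = "")
  expect_message(model <- build_msa_inputs(rk, mx, meta), "orphan.*h4")
  expect_identical(nrow(model$baselines), 2L)
  expect_identical(unname(model$baselines["USA", "h1"]), 13L)
  expect_equal(unname(model$sizes["USA"]), 300)
  expect_identical(model$orphans, "h4")
  # harmonization conserves totals
  expect_identical(sum(model$baselines), sum(rk$counts))
  expect_identical(sum(model$mixtures), sum(mx$counts))
  bad_mix <- frequency_table(matrix(0L, 1, 1, dimnames = list("M1", "h1")),
                             marker = "extended", drop_empty = FALSE)
  expect_error(build_msa_inputs(rk, bad_mix, meta), "zero individuals")
  meta$nester_abundance[3] <- NA
  expect_error(build_msa_inputs(rk, mx, meta), "abundance")
})

test_that("degenerate single-rookery models give certain contributions", {
  X <- matrix(c(5L, 5L), 1, 2, dimnames = list("R1", c("h1", "h2")))
  Y <- matrix(c(3L, 2L), 1, 2, dimnames = list("M1", c("h1", "h2")))
  m <- msa_model(X, Y, prior_mode = "uniform")
  r <- run_msa(m, msa_config(n_iterations = 200, n_chains = 2, seed = 3))
  expect_true(all(r$draws == 1))
  s <- summarize_msa(r, "R1")
  expect_equal(s$mean, 1)
  expect_equal(s$q2.5, 1)
  expect_error(summarize_msa(r, "R9"), "unknown rookery")
})

test_that("a haplotype private to one baseline forces its assignment", {
  X <- matrix(c(40L, 0L, 0L, 40L), 2, 2, byrow = TRUE,
              dimnames = list(c("R1", "R2"), c("h1", "h2")))
  Y <- matrix(c(30L, 0L), 1, 2, dimnames = list("M1", c("h1", "h2")))
  m <- msa_model(X, Y, prior_mode = "uniform")
  r <- run_msa(m, msa_config(n_iterations = 5000, n_chains = 2, seed = 5),
               baseline_prior_mass = 1e-8)
  mean_r1 <- r$summary$mean[r$summary$rookery == "R1"]
  expect_gt(mean_r1, 0.93)
})

test_that("every posterior draw lies on the simplex", {
  set.seed(21)
  X <- matrix(rpois(12, 8) + 1L, 3, 4,
              dimnames = list(paste0("R", 1:3), paste0("h", 1:4)))
  Y <- matrix(rpois(8, 6) + 1L, 2, 4,
              dimnames = list(paste0("M", 1:2), paste0("h", 1:4)))
  m <- msa_model(X, Y, sizes = setNames(c(10, 20, 30), rownames(X)))
  r <- run_msa(m, msa_config(n_iterations = 1000, n_chains = 2, seed = 9))
  sums <- apply(r$draws, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(r$draws >= 0 & r$draws <= 1))
  # mixture-wise posterior means are themselves on the simplex
  by_mix <- tapply(r$summary$mean, r$summary$mixture, sum)
  expect_equal(as.numeric(by_mix), rep(1, 2), tolerance = 1e-9)
})

test_that("with uninformative data the posterior returns the prior", {
  # identical baselines make the likelihood flat in the contributions
  X <- matrix(rep(c(30L, 30L, 30L), each = 3), 3, 3,
              dimnames = list(paste0("R", 1:3), paste0("h", 1:3)))
  Y <- matrix(c(10L, 10L, 10L), 1, 3,
              dimnames = list("M1", colnames(X)))
  sizes <- setNames(c(5000, 2000, 1000), rownames(X))
  for (mode in c("size_weighted", "uniform")) {
    m <- msa_model(X, Y, sizes = sizes, prior_mode = mode)
    r <- run_msa(m, msa_config(n_iterations = 20000, n_chains = 4,
                               seed = 31))
    prior_mean <- if (mode == "size_weighted") sizes / sum(sizes)
                  else rep(1 / 3, 3)
    for (k in 1:3) {
      draws <- r$draws[, 1, k]
      se <- mcse_batch(draws)
      expect_lt(abs(mean(draws) - prior_mean[k]), 3 * se + 0.01)
    }
  }
})

test_that("permuting rookery order permutes the results", {
  set.seed(41)
  X <- matrix(c(40L, 5L, 0L, 2L, 35L, 5L, 0L, 5L, 45L), 3, 3, byrow = TRUE,
              dimnames = list(paste0("R", 1:3), paste0("h", 1:3)))
  Y <- matrix(c(20L, 10L, 5L), 1, 3, dimnames = list("M1", colnames(X)))
  perm <- c(3, 1, 2)
  m1 <- msa_model(X, Y, prior_mode = "uniform")
  m2 <- msa_model(X[perm, ], Y, prior_mode = "uniform")
  cfg <- msa_config(n_iterations = 20000, n_chains = 2, seed = 8)
  r1 <- run_msa(m1, cfg)
  r2 <- run_msa(m2, cfg)
  mean1 <- setNames(r1$summary$mean, r1$summary$rookery)
  mean2 <- setNames(r2$summary$mean, r2$summary$rookery)
  expect_equal(mean2[names(mean1)], mean1, tolerance = 0.02)
})
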