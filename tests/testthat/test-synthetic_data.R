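test_that("generators are fully deterministic under a fixed seed", {
  l1 <- make_library(4, 4, seed = 5)
  l2 <- make_library(4, 4, seed = 5)
  expect_identical(l1, l2)
  b1 <- simulate_baselines(3, 6, seed = 5)
  b2 <- simulate_baselines(3, 6, seed = 5)
  expect_identical(b1, b2)
  m1 <- simulate_mixture(b1$pi, c(0.5, 0.3, 0.2), 50, seed = 5)
  expect_identical(m1, simulate_mixture(b1$pi, c(0.5, 0.3, 0.2), 50,
                                        seed = 5))
  h1 <- simulate_heteroplasmy(matrix(4L, 10, 4), 0.3, seed = 5)
  expect_identical(h1, simulate_heteroplasmy(matrix(4L, 10, 4), 0.3,
                                             seed = 5))
  expect_identical(simulate_ccl(5, 5, seed = 5), simulate_ccl(5, 5, seed = 5))
})

test_that("the synthetic library mirrors real haplotype structure", {
  lib <- make_library(n_dloop = 4, n_mtstr = 3, seed = 2)
  seqs <- lib$dloop_seqs
  expect_length(seqs, 4)
  expect_true(all(nchar(seqs) == 738))
  # the two SY-A1 variants share the short window, differ beyond it
  expect_identical(substr(seqs[["SY-A1.1"]], 1, 486),
                   substr(seqs[["SY-A1.3"]], 1, 486))
  expect_false(identical(seqs[["SY-A1.1"]], seqs[["SY-A1.3"]]))
  # other families differ inside the short window
  expect_false(identical(substr(seqs[["SY-A1.1"]], 1, 486),
                         substr(seqs[["SY-A2.1"]], 1, 486)))
  # mtSTR loci 3-4 fixed at 4 repeats; 7-12-4-4 is the first haplotype
  expect_true(all(lib$mtstr$r3 == 4) && all(lib$mtstr$r4 == 4))
  expect_identical(lib$mtstr$name[1], "7-12-4-4")
  # construction arithmetic of the repeat region
  anchors <- default_mtstr_anchors()
  s <- build_mtstr_sequence(c(7, 12, 4, 4))
  expect_identical(nchar(s),
                   sum(nchar(anchors)) + 2L * (7L + 12L + 4L + 4L) +
                     nchar("CGGCTTCG"))
  expect_error(make_library(600, 2), "mutation sites")
  expect_error(make_library(4, 100), "combinations")
})

test_that("baseline frequencies converge to their generating vectors", {
  b <- simulate_baselines(2, 6, sample_sizes = 1e5, seed = 13,
                          dominant_mass = 0.75)
  phat <- b$table$counts / rowSums(b$table$counts)
  expect_lt(max(abs(phat - b$pi)), 0.01)
  expect_equal(mean(b$pi[, 1]), 0.75, tolerance = 0.15)
  expect_error(simulate_baselines(2, 1), "H")
  expect_error(simulate_baselines(2, 4, dominant_mass = 1.2),
               "dominant_mass")
})

test_that("mixtures follow the finite-mixture identity with exact labels", {
  b <- simulate_baselines(3, 6, seed = 17)
  m <- simulate_mixture(b$pi, c(1, 0, 0), 40, seed = 17)
  expect_true(all(m$sources == 1))
  theta <- c(0.5, 0.3, 0.2)
  m2 <- simulate_mixture(b$pi, theta, 20000, seed = 18)
  expect_identical(sum(m2$counts), 20000L)
  expect_length(m2$sources, 20000)
  expected <- colSums(theta * b$pi)
  expect_lt(max(abs(m2$counts / 20000 - expected)), 0.015)
  expect_error(simulate_mixture(b$pi, c(0.5, 0.5), 10), "per rookery")
  expect_error(simulate_mixture(b$pi, c(0.9, 0.2, 0.1), 10), "simplex")
  expect_error(simulate_mixture(b$pi, theta, 0), "n must be")
})

test_that("injected unclear heteroplasmy is exactly what the resolver excludes", {
  reps <- cbind(sample(6:8, 200, TRUE), sample(10:17, 200, TRUE), 4L, 4L)
  het <- simulate_heteroplasmy(reps, fraction_unclear = 0.3, seed = 23)
  resolved <- vapply(het$locus_variants, function(lv)
    resolve_heteroplasmy(lv)$status, character(1))
  expect_identical(resolved == "unclear", het$unclear)
  expect_identical(sum(het$unclear), 60L)
  # clear profiles resolve to the true repeats
  clear_idx <- which(!het$unclear)
  for (i in clear_idx[1:20]) {
    expect_identical(resolve_heteroplasmy(het$locus_variants[[i]])$repeats,
                     as.integer(reps[i, ]))
  }
  none <- simulate_heteroplasmy(reps, fraction_unclear = 0, seed = 23)
  expect_false(any(none$unclear))
})

test_that("CCL simulation supports the size-filter error analysis", {
  # juveniles far below the adult range are always kept; any crossing of
  # the mean - 2 SD threshold can only come from the adult lower tail
  d <- simulate_ccl(100, 100, adult_mean = 112, adult_sd = 2,
                    juvenile_mean = 52, juvenile_sd = 2, seed = 7)
  ref <- simulate_ccl(200, 0, adult_mean = 112, adult_sd = 2, seed = 8)$ccl
  f <- filter_immature(d$ccl, ref)
  expect_true(all(which(d$stage == "juvenile") %in% f$kept))
  expect_true(all(d$stage[f$excluded] == "adult"))
  # adults below the threshold occur at the ~2.3% normal tail rate
  expect_lt(sum(d$stage[f$kept] == "adult") / 100,
            pnorm(f$threshold, 112, 2) + 3 * sqrt(0.023 * 0.977 / 100) + 0.01)
  # overlapping classes: misclassification matches the normal tail
  n <- 4000
  d2 <- simulate_ccl(0, n, juvenile_mean = 95, juvenile_sd = 10, seed = 9)
  f2 <- filter_immature(d2$ccl, ref)
  p_tail <- 1 - pnorm(f2$threshold, 95, 10)
  obs <- length(f2$excluded) / n
  mc_se <- sqrt(p_tail * (1 - p_tail) / n)
  expect_lt(abs(obs - p_tail), 3 * mc_se + 0.005)
  # no adults at all: everything is kept
  d3 <- simulate_ccl(0, 50, seed = 10)
  expect_length(filter_immature(d3$ccl, ref)$excluded, 0)
  expect_error(simulate_ccl(5, 5, adult_sd = 0), "positive")
})
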