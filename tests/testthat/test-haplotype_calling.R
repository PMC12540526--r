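test_that("short haplotype names derive by stripping the variant suffix", {
  expect_identical(derive_short_name("CM-A8.3"), "CM-A8")
  expect_identical(derive_short_name("CM-A8"), "CM-A8")
  expect_identical(derive_short_name("CM-A45.1"), "CM-A45")
  expect_error(derive_short_name(""), "empty")
})

test_that("mtSTR repeat counting inverts the sequence builder", {
  p <- call_mtstr(build_mtstr_sequence(c(7, 12, 4, 4)))
  expect_identical(p$repeats, c(7L, 12L, 4L, 4L))
  expect_identical(p$haplotype, "7-12-4-4")
  expect_identical(p$status, "clear")
  # property: inverse over random repeat vectors in [1, 30]^4
  set.seed(42)
  for (i in 1:40) {
    r <- sample(1:30, 4, replace = TRUE)
    expect_identical(call_mtstr(build_mtstr_sequence(r))$repeats,
                     as.integer(r))
  }
})

test_that("mtSTR calling flags missing anchors and validates fixed loci", {
  s <- build_mtstr_sequence(c(7, 12, 4, 4))
  broken <- sub(default_mtstr_anchors()[3], "GGGGGGGG", s, fixed = TRUE)
  p <- call_mtstr(broken)
  expect_identical(p$status, "unidentified")
  expect_identical(p$flags, "mtstr_unidentified")
  expect_warning(validate_mtstr(call_mtstr(build_mtstr_sequence(c(7, 12, 5, 4)))),
                 "locus 3")
  expect_silent(validate_mtstr(call_mtstr(s)))
})

test_that("heteroplasmy resolves by dominant peak with a >= threshold rule", {
  lv <- list(data.frame(repeat_count = 7, fraction = 1),
             data.frame(repeat_count = c(12, 13), fraction = c(0.8, 0.2)),
             data.frame(repeat_count = 4, fraction = 1),
             data.frame(repeat_count = 4, fraction = 1))
  p <- resolve_heteroplasmy(lv)
  expect_identical(p$haplotype, "7-12-4-4")
  lv[[2]]$fraction <- c(0.55, 0.45)
  p2 <- resolve_heteroplasmy(lv, dominance_threshold = 0.6)
  expect_identical(p2$status, "unclear")
  expect_identical(p2$flags, "heteroplasmy_unclear")
  # boundary: dominance exactly at the threshold counts as clear
  lv[[2]]$fraction <- c(0.6, 0.4)
  expect_identical(resolve_heteroplasmy(lv, 0.6)$status, "clear")
  lv[[2]] <- lv[[2]][0, ]
  expect_error(resolve_heteroplasmy(lv), "empty candidate list at locus 2")
})

test_that("combined haplotypes require both components", {
  expect_identical(combine_haplotypes("CM-A8.1", "7-12-4-4"),
                   "CM-A8.1/7-12-4-4")
  expect_identical(combine_haplotypes(NA, "7-12-4-4"), NA_character_)
  p <- call_mtstr(build_mtstr_sequence(c(7, 12, 4, 4)))
  expect_identical(combine_haplotypes("CM-A8.1", p), "CM-A8.1/7-12-4-4")
  expect_error(combine_haplotypes("CM-A8.1", "7-12-4"), "pattern")
})

test_that("D-loop truncation and matching recovers library haplotypes exactly", {
  lib <- make_library(n_dloop = 5, n_mtstr = 3, seed = 11)
  cons <- dloop_consensus(lib$library)
  set.seed(1)
  for (nm in names(lib$dloop_seqs)) {
    read <- paste0(paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                         collapse = ""),
                   lib$dloop_seqs[[nm]],
                   paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                         collapse = ""))
    res <- truncate_and_match_dloop(read, lib$library, consensus = cons)
    expect_identical(res$extended_hap, nm)
    expect_identical(res$short_hap, derive_short_name(nm))
    expect_length(res$flags, 0)
  }
})

test_that("a single substitution inside the window yields a novel candidate", {
  lib <- make_library(n_dloop = 3, n_mtstr = 3, seed = 12)
  s <- lib$dloop_seqs[["SY-A1.1"]]
  pos <- 600L
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  res <- truncate_and_match_dloop(s, lib$library)
  expect_identical(res$flags, "novel_candidate")
  expect_identical(res$closest, "SY-A1.1")
  expect_identical(res$mismatches, 1L)
  # the substitution is beyond the short window, so the short call survives
  expect_identical(res$short_hap, "SY-A1")
  # too-short queries fail cleanly
  short <- truncate_and_match_dloop(substr(s, 1, 100), lib$library)
  expect_identical(short$flags, "dloop_failed")
  expect_true(is.na(short$extended_hap))
})

test_that("tabulation bookkeeping partitions the cohort exactly", {
  calls <- read_call_counts(table2_path())
  tab_ext <- tabulate_calls(calls, marker = "extended")
  expect_identical(tab_ext$n_assigned, 267L)
  expect_identical(tab_ext$n_total, 289L)
  expect_identical(tab_ext$n_assigned + sum(tab_ext$excluded$n), 289L)
  # collapsing the extended table by parent name reproduces the short table
  tab_short <- tabulate_calls(calls, marker = "short")
  collapsed <- collapse_haplotypes(tab_ext$table)
  expect_identical(collapsed$counts[, colnames(tab_short$table$counts)],
                   tab_short$table$counts[1, ])
  expect_error(tabulate_calls(calls, group_by = "beach"), "unknown group")
  empty <- tabulate_calls(calls[0, ], marker = "short")
  expect_identical(empty$n_assigned, 0L)
  expect_identical(ncol(empty$table$counts), 0L)
})
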