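#' Validate and complete a run configuration
#'
#' Reads a YAML configuration (or takes a list), rejects unknown keys, and
#' fills defaults: 50,000 MCMC iterations, 4 chains, alpha 0.05, shrink
#' threshold 1.2, 10,000 permutations. The completed configuration is
#' echoed into the run manifest by [run_pipeline()].
#'
#' @param config path to a YAML file, or a (possibly nested) list.
#' @return list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) ts_stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    seed = 1L,
    output_dir = "turtlestock_run",
    marker = "combined",
    n_permutations = 10000L,
    alpha = 0.05,
    msa = list(n_iterations = 50000L, n_chains = 4L, burn_in = 0.5,
               thinning = 1L, convergence_threshold = 1.2,
               prior_mode = "size_weighted", prior_strength = 1),
    simulate = list(R = 3L, M = 2L, n_dloop = 4L, n_mtstr = 4L,
                    n_base = 200L, n_mix = 200L, fraction_unclear = 0.1,
                    dominant_mass = 0.75, concentration = 0.5,
                    abundances = c(5000, 2000, 1000),
                    adult_fraction = 0.05, n_ccl_reference = 100L,
                    theta = NULL))
  merge_known <- function(def, got, path) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown))
      ts_stop("unknown config key(s): ",
              paste0(path, unknown, collapse = ", "))
    for (k in names(got)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge_known(def[[k]], as.list(got[[k]]),
                                paste0(path, k, "."))
      } else {
        def[[k]] <- got[[k]]
      }
    }
    def
  }
  cfg <- merge_known(defaults, as.list(config), "")
  if (!cfg$marker %in% c("short", "extended", "combined"))
    ts_stop("marker must be one of short, extended, combined")
  if (cfg$n_permutations < 0) ts_stop("n_permutations must be nonnegative")
  check_prob(cfg$alpha, "alpha", open = TRUE)
  # msa_config() applies the detailed MCMC checks
  cfg$msa_config <- msa_config(
    n_iterations = cfg$msa$n_iterations, n_chains = cfg$msa$n_chains,
    burn_in = cfg$msa$burn_in, thinning = cfg$msa$thinning,
    seed = derive_seed(cfg$seed, 100L),
    convergence_threshold = cfg$msa$convergence_threshold,
    prior_strength = cfg$msa$prior_strength)
  structure(cfg, class = "run_config")
}

# internal: deterministic CSV writer used by the pipeline
write_result_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
}

#' Run the full synthetic-data pipeline end to end
#'
#' Generates a haplotype library and seeded synthetic cohorts (rookery
#' baselines, finite-mixture foraging samples with known contribution
#' vectors, heteroplasmic mtSTR profiles, CCL distributions), writes the
#' generated inputs, then exercises every analysis stage on them: haplotype
#' calling, immature filtering, tabulation, haplotype diversity, pairwise
#' F_ST with permutation tests and the Narum FDR threshold, PCoA, AMOVA on
#' the PCoA-derived grouping, and the Bayesian mixed stock analysis. All
#' randomness derives from the single configured seed, so two runs with the
#' same configuration are byte-identical.
#'
#' @param config a `run_config` (see [validate_config()]), or anything
#'   accepted by it.
#' @return (invisibly) a list with the truth records, per-sample calls,
#'   frequency tables, statistics and the `msa_result`; all artifacts are
#'   written under `config$output_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  sim <- config$simulate
  out <- config$output_dir
  dir.create(file.path(out, "inputs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "results"), recursive = TRUE,
             showWarnings = FALSE)

  ## --- generation -------------------------------------------------------
  lib <- make_library(sim$n_dloop, sim$n_mtstr, seed = config$seed)
  dloop_names <- names(lib$dloop_seqs)
  mt <- lib$mtstr
  combined_names <- as.vector(outer(dloop_names, mt$name, paste, sep = "/"))
  H <- length(combined_names)
  R <- sim$R
  M <- sim$M
  base <- simulate_baselines(R, H, concentration = sim$concentration,
                             dominant_mass = sim$dominant_mass,
                             sample_sizes = sim$n_base, seed = config$seed,
                             hap_names = combined_names)
  theta <- sim$theta
  if (is.null(theta)) {
    if (R == 3 && M == 2) {
      theta <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.3, 0.5))
    } else {
      set.seed(derive_seed(config$seed, 6L))
      g <- matrix(stats::rgamma(M * R, shape = 5), M, R)
      theta <- g / rowSums(g)
    }
  }
  theta <- matrix(unlist(theta), nrow = M,
                  dimnames = list(paste0("M", seq_len(M)),
                                  rownames(base$pi)))
  mixtures <- lapply(seq_len(M), function(m)
    simulate_mixture(base$pi, theta[m, ], sim$n_mix,
                     seed = derive_seed(config$seed, 10L + m)))

  # per-individual truth across all cohorts
  pops <- c(rep(rownames(base$pi), times = rowSums(base$table$counts)),
            rep(rownames(theta), each = sim$n_mix))
  true_combined <- c(
    unlist(lapply(seq_len(R), function(r)
      rep(combined_names, times = base$table$counts[r, ]))),
    unlist(lapply(mixtures, `[[`, "haplotypes")))
  n_all <- length(true_combined)
  comp <- split_combined(true_combined)
  true_repeats <- do.call(rbind, lapply(comp$mtstr, function(s)
    as.integer(strsplit(s, "-")[[1]])))

  het <- simulate_heteroplasmy(true_repeats,
                               fraction_unclear = sim$fraction_unclear,
                               seed = config$seed)
  # CCL only matters for foraging mixtures; rookery samples are nesters
  is_mix <- grepl("^M", pops)
  set.seed(derive_seed(config$seed, 7L))
  ccl <- rep(NA_real_, n_all)
  n_mix_all <- sum(is_mix)
  adult <- is_mix & stats::runif(n_all) < sim$adult_fraction
  ccl[is_mix & !adult] <- stats::rnorm(sum(is_mix & !adult), 65, 10)
  ccl[adult] <- stats::rnorm(sum(adult), 112, 5)
  reference_ccl <- simulate_ccl(sim$n_ccl_reference, 0,
                                seed = derive_seed(config$seed, 8L))$ccl

  # reads: library sequence of the true haplotype with random flanks
  set.seed(derive_seed(config$seed, 9L))
  bases <- c("A", "C", "G", "T")
  flank <- function(k) paste0(sample(bases, k, replace = TRUE),
                              collapse = "")
  reads <- vapply(seq_len(n_all), function(i)
    paste0(flank(30), lib$dloop_seqs[[comp$extended[i]]], flank(30)),
    character(1))
  names(reads) <- sprintf("S%05d", seq_len(n_all))
  write_fasta(reads, file.path(out, "inputs", "dloop_reads.fasta"))
  write_frequency_table(base$table,
                        file.path(out, "inputs", "baseline_counts.csv"))
  meta <- data.frame(abbrev = c(rownames(base$pi), rownames(theta)),
                     full_name = c(paste("Rookery", seq_len(R)),
                                   paste("Mixture", seq_len(M))),
                     role = rep(c("rookery", "foraging"), c(R, M)),
                     msa_group = c(rownames(base$pi), rep("", M)),
                     nester_abundance = c(rep_len(sim$abundances, R),
                                          rep(NA, M)),
                     region = "synthetic", stringsAsFactors = FALSE)
  write_result_csv(meta, file.path(out, "inputs"), "population_meta.csv")

  ## --- haplotype calling ------------------------------------------------
  spec <- window_spec()
  calls <- data.frame(sample_id = names(reads), population = pops,
                      year = NA_integer_, short_hap = NA_character_,
                      extended_hap = NA_character_,
                      mtstr_hap = NA_character_,
                      combined_hap = NA_character_, flags = "",
                      stringsAsFactors = FALSE)
  cons <- dloop_consensus(lib$library, spec$extended_length)
  for (i in seq_len(n_all)) {
    dl <- truncate_and_match_dloop(reads[[i]], lib$library, spec, cons)
    calls$extended_hap[i] <- dl$extended_hap
    calls$short_hap[i] <- dl$short_hap
    pr <- resolve_heteroplasmy(het$locus_variants[[i]])
    calls$mtstr_hap[i] <- pr$haplotype
    calls$combined_hap[i] <- combine_haplotypes(dl$extended_hap, pr)
    calls$flags[i] <- paste(c(dl$flags, pr$flags), collapse = ";")
  }
  # immature filter applies to foraging mixtures only
  imm <- filter_immature(ccl[is_mix], reference_ccl)
  keep <- rep(TRUE, n_all)
  keep[which(is_mix)[imm$excluded]] <- FALSE
  write_result_csv(cbind(calls, ccl = round(ccl, 2), kept = keep),
                   file.path(out, "results"), "calls.csv")

  kept_calls <- calls[keep, , drop = FALSE]
  tab_rook <- tabulate_calls(kept_calls[!is_mix[keep], ],
                             marker = config$marker)
  tab_mix <- tabulate_calls(kept_calls[is_mix[keep], ],
                            marker = config$marker)
  write_frequency_table(tab_rook$table,
                        file.path(out, "results", "rookery_freq.csv"))
  write_frequency_table(tab_mix$table,
                        file.path(out, "results", "mixture_freq.csv"))

  ## --- population statistics -------------------------------------------
  div <- diversity_table(tab_rook$table)
  write_result_csv(div, file.path(out, "results"), "diversity.csv")
  fst <- pairwise_fst(tab_rook$table,
                      n_permutations = config$n_permutations,
                      seed = derive_seed(config$seed, 20L),
                      alpha = config$alpha)
  write_result_csv(as.data.frame(fst$values),
                   file.path(out, "results"), "fst_values.csv")
  write_result_csv(as.data.frame(fst$p_values),
                   file.path(out, "results"), "fst_pvalues.csv")
  pc <- pcoa_genetic(fst$values)
  write_result_csv(as.data.frame(pc$coordinates),
                   file.path(out, "results"), "pcoa_coordinates.csv")
  grouping <- if (length(unique(sign(pc$coordinates[, 1]))) > 1) {
    ifelse(pc$coordinates[, 1] >= 0, "G1", "G2")
  } else {
    c("G1", rep("G2", R - 1))
  }
  names(grouping) <- rownames(tab_rook$table$counts)
  am <- suppressWarnings(
    amova(tab_rook$table, grouping,
          n_permutations = min(config$n_permutations, 1000L),
          seed = derive_seed(config$seed, 21L)))
  write_result_csv(
    data.frame(component = names(am$variance_components),
               sigma2 = am$variance_components,
               stringsAsFactors = FALSE),
    file.path(out, "results"), "amova_components.csv")

  ## --- mixed stock analysis --------------------------------------------
  model <- build_msa_inputs(tab_rook$table, tab_mix$table,
                            read_population_meta(
                              file.path(out, "inputs",
                                        "population_meta.csv")),
                            prior_mode = config$msa$prior_mode)
  msa <- run_msa(model, config$msa_config)
  write_result_csv(msa$summary, file.path(out, "results"),
                   "msa_summary.csv")
  write_result_csv(as.data.frame(msa$rhat), file.path(out, "results"),
                   "msa_rhat.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("turtlestock")),
    seed = config$seed,
    marker = config$marker,
    n_permutations = config$n_permutations,
    alpha = config$alpha,
    msa = config$msa,
    simulate = lapply(sim, function(x) if (is.null(x)) "default" else x),
    fdr_threshold = fst$fdr_threshold,
    msa_converged = msa$converged,
    immature_threshold_cm = imm$threshold)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(
    truth = list(library = lib, pi = base$pi, theta = theta,
                 combined = true_combined, unclear = het$unclear,
                 populations = pops, ccl = ccl, is_mixture = is_mix),
    calls = calls, kept = keep, immature = imm,
    rookery_tab = tab_rook, mixture_tab = tab_mix,
    diversity = div, fst = fst, pcoa = pc, amova = am, msa = msa,
    config = config))
}
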