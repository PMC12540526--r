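#' Filter foraging samples to immature individuals by carapace length
#'
#' Mixed stock analysis of juvenile foraging aggregations must exclude
#' adults, which may forage closer to their natal rookery. The adult size
#' threshold is the average minimum adult size: the mean curved carapace
#' length (CCL) of a reference set of nesting females minus two standard
#' deviations (sample SD, n-1). Individuals with CCL below the threshold
#' are kept; missing CCL values are kept with a warning.
#'
#' @param ccl_values numeric CCL measurements (cm) of foraging individuals.
#' @param reference_nesting_ccl numeric CCL of nesting females (>= 2 values).
#' @return list with `kept` (indices kept), `excluded` (indices removed),
#'   `threshold` (cm).
#' @export
filter_immature <- function(ccl_values, reference_nesting_ccl) {
  ref <- reference_nesting_ccl[!is.na(reference_nesting_ccl)]
  if (length(ref) < 2) ts_stop("reference nesting CCL set must have >= 2 values")
  threshold <- mean(ref) - 2 * stats::sd(ref)
  missing <- is.na(ccl_values)
  if (any(missing))
    ts_warn(sum(missing), " sample(s) with missing CCL kept by default")
  keep <- missing | ccl_values < threshold
  list(kept = which(keep), excluded = which(!keep), threshold = threshold)
}

#' Mixed stock analysis run configuration
#'
#' @param n_iterations Gibbs iterations per chain (default 50000).
#' @param n_chains number of chains (default 4; >= 2 needed for the
#'   Gelman-Rubin diagnostic).
#' @param burn_in fraction of each chain discarded (default 0.5).
#' @param thinning keep every `thinning`-th post-burn-in draw (default 1).
#' @param seed master RNG seed; each chain derives its own seed from it.
#' @param convergence_threshold shrink-factor limit below which the run is
#'   declared converged (default 1.2).
#' @param prior_strength total Dirichlet mass c on each mixture's
#'   contribution vector (default 1, weakly informative).
#' @return list of class `msa_config`.
#' @export
msa_config <- function(n_iterations = 50000L, n_chains = 4L, burn_in = 0.5,
                       thinning = 1L, seed = 1L,
                       convergence_threshold = 1.2, prior_strength = 1) {
  n_iterations <- as.integer(n_iterations)
  n_chains <- as.integer(n_chains)
  thinning <- as.integer(thinning)
  if (n_iterations < 2L) ts_stop("n_iterations must be >= 2")
  if (n_chains < 1L) ts_stop("n_chains must be >= 1")
  check_prob(burn_in, "burn_in")
  if (burn_in >= 1) ts_stop("burn_in fraction must be < 1")
  if (thinning < 1L) ts_stop("thinning must be >= 1")
  if (convergence_threshold <= 1) ts_stop("convergence_threshold must be > 1")
  if (prior_strength <= 0) ts_stop("prior_strength must be positive")
  structure(list(n_iterations = n_iterations, n_chains = n_chains,
                 burn_in = burn_in, thinning = thinning, seed = seed,
                 convergence_threshold = convergence_threshold,
                 prior_strength = prior_strength),
            class = "msa_config")
}

#' Construct a mixed stock model directly from matrices
#'
#' @param baselines R x H integer matrix of rookery haplotype counts, with
#'   rookery rownames and haplotype colnames.
#' @param mixtures M x H integer matrix of mixture haplotype counts on the
#'   same haplotype columns, with mixture rownames.
#' @param sizes named nonnegative numeric vector of rookery abundances
#'   (required for size-weighted priors).
#' @param prior_mode `"size_weighted"` or `"uniform"`.
#' @param mixture_weights optional named weights S_m used to derive
#'   rookery-centric quantities; defaults to the mixture sample sizes.
#' @return list of class `msa_model`.
#' @export
msa_model <- function(baselines, mixtures, sizes = NULL,
                      prior_mode = c("size_weighted", "uniform"),
                      mixture_weights = NULL) {
  prior_mode <- match.arg(prior_mode)
  baselines <- as.matrix(baselines)
  mixtures <- as.matrix(mixtures)
  if (!identical(colnames(baselines), colnames(mixtures)))
    ts_stop("baselines and mixtures must share identical haplotype columns")
  if (nrow(baselines) < 1L || nrow(mixtures) < 1L)
    ts_stop("need at least one rookery and one mixture")
  if (any(baselines < 0) || any(mixtures < 0))
    ts_stop("counts must be nonnegative")
  if (any(colSums(baselines) + colSums(mixtures) == 0))
    ts_stop("haplotype column(s) absent from every baseline and mixture")
  if (prior_mode == "size_weighted") {
    if (is.null(sizes) || any(is.na(sizes[rownames(baselines)])) ||
        any(sizes[rownames(baselines)] <= 0))
      ts_stop("size-weighted priors require a positive abundance for every rookery")
    sizes <- sizes[rownames(baselines)]
  }
  S <- if (is.null(mixture_weights)) rowSums(mixtures)
       else mixture_weights[rownames(mixtures)]
  orphans <- colnames(mixtures)[colSums(baselines) == 0 &
                                colSums(mixtures) > 0]
  structure(list(baselines = baselines, mixtures = mixtures,
                 sizes = sizes, prior_mode = prior_mode,
                 mixture_weights = S, orphans = orphans),
            class = "msa_model")
}

#' Build mixed stock model inputs from frequency tables and metadata
#'
#' Pools rookery populations by their MSA group (counts and abundances
#' summed), harmonizes the haplotype lists of baselines and mixtures by
#' union, and retains haplotypes observed only in mixtures ("orphans") with
#' zero baseline counts, reporting them.
#'
#' @param rookery_table a `frequency_table` whose rows are rookery
#'   populations.
#' @param mixture_table a `frequency_table` whose rows are foraging
#'   aggregations (mixtures).
#' @param meta a `population_meta` data frame covering the rookery rows
#'   (abbrev, msa_group, nester_abundance).
#' @param prior_mode `"size_weighted"` or `"uniform"`.
#' @return an `msa_model`.
#' @export
build_msa_inputs <- function(rookery_table, mixture_table, meta,
                             prior_mode = c("size_weighted", "uniform")) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(rookery_table, "frequency_table"),
            inherits(mixture_table, "frequency_table"))
  rc <- rookery_table$counts
  mc <- mixture_table$counts
  if (any(rowSums(mc) == 0))
    ts_stop("mixture(s) with zero individuals: ",
            paste(rownames(mc)[rowSums(mc) == 0], collapse = ", "))
  idx <- match(rownames(rc), meta$abbrev)
  if (any(is.na(idx)))
    ts_stop("rookery population(s) missing from metadata: ",
            paste(rownames(rc)[is.na(idx)], collapse = ", "))
  grp <- meta$msa_group[idx]
  pooled <- rowsum(rc, grp)
  sizes <- tapply(meta$nester_abundance[idx], grp, sum)
  haps <- union(colnames(pooled), colnames(mc))
  X <- matrix(0L, nrow(pooled), length(haps),
              dimnames = list(rownames(pooled), haps))
  X[, colnames(pooled)] <- pooled
  Y <- matrix(0L, nrow(mc), length(haps),
              dimnames = list(rownames(mc), haps))
  Y[, colnames(mc)] <- mc
  model <- msa_model(X, Y, sizes = stats::setNames(as.numeric(sizes),
                                                   names(sizes)),
                     prior_mode = prior_mode)
  if (length(model$orphans))
    message("orphan haplotype(s) absent from every baseline: ",
            paste(model$orphans, collapse = ", "))
  model
}

#' Gelman-Rubin shrink factor per parameter
#'
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \cdot W + B/n}{W}}}
#' with `W` the mean within-chain variance and `B = n Var(chain means)`.
#' Chains with zero within-chain variance give R-hat 1 when their means
#' agree and +Inf when they differ.
#'
#' @param chains list (length >= 2) of equal-length numeric vectors, or of
#'   equal-dimension draw matrices (iterations x parameters).
#' @return numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    ts_stop("need at least two chains")
  mats <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch)
  })
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    ts_stop("chains must have equal lengths and parameter counts")
  n <- dims[1, 1]
  if (n < 2L) ts_stop("chains must contain at least 2 draws")
  P <- dims[2, 1]
  rhat <- numeric(P)
  for (p in seq_len(P)) {
    draws <- vapply(mats, function(m) m[, p], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B <- n * stats::var(colMeans(draws))
    rhat[p] <- if (W == 0) {
      if (B == 0) 1 else Inf
    } else {
      sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  if (!is.null(colnames(mats[[1]]))) names(rhat) <- colnames(mats[[1]])
  rhat
}

#' Run the many-to-many Bayesian mixed stock analysis
#'
#' Gibbs sampler over the Dirichlet-multinomial mixture model with latent
#' source assignment: each mixture m has a contribution vector
#' \eqn{\theta_m} over rookeries with Dirichlet prior \eqn{\alpha_{m,r} =
#' c N_r / \sum N} (size-weighted) or \eqn{c/R} (uniform); each rookery's
#' haplotype frequencies \eqn{\pi_r} have a Dirichlet(\eqn{\beta}) prior
#' (\eqn{\beta = 1/H} by default) updated by the baseline counts. Chains
#' start from overdispersed draws (\eqn{\theta_m} from its prior) under
#' distinct derived seeds; post-burn-in draws are pooled after a
#' Gelman-Rubin check. Rookery-centric shares \eqn{\phi_{r,m} =
#' \theta_{m,r} S_m / \sum_{m'} \theta_{m',r} S_{m'}} are derived per draw
#' with mixture weights S (sample sizes by default). A non-converged run is
#' returned with `converged = FALSE`, not discarded.
#'
#' @param model an `msa_model`.
#' @param config an `msa_config`.
#' @param baseline_prior_mass Dirichlet mass beta per haplotype for the
#'   rookery frequency priors; default `1/H`.
#' @return list of class `msa_result`: `draws` (kept draws x M x R array of
#'   theta), `summary` (per mixture x rookery mean/median/2.5%/97.5%),
#'   `phi_summary` (rookery-centric), `rhat` (M x R), `converged`,
#'   `config`, `model`.
#' @export
run_msa <- function(model, config = msa_config(),
                    baseline_prior_mass = NULL) {
  stopifnot(inherits(model, "msa_model"), inherits(config, "msa_config"))
  X <- model$baselines
  Y <- model$mixtures
  R <- nrow(X)
  H <- ncol(X)
  M <- nrow(Y)
  beta <- if (is.null(baseline_prior_mass)) 1 / H else baseline_prior_mass
  w <- if (model$prior_mode == "size_weighted") {
    model$sizes / sum(model$sizes)
  } else {
    rep(1 / R, R)
  }
  alpha <- matrix(rep(config$prior_strength * w, each = M), M, R)
  storage.mode(X) <- "integer"
  storage.mode(Y) <- "integer"
  n_iter <- config$n_iterations
  keep_from <- floor(config$burn_in * n_iter) + 1L
  keep <- seq(keep_from, n_iter, by = config$thinning)
  chain_draws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, ch))
    d <- msa_gibbs_chain(X, Y, alpha, beta, n_iter)
    dim(d) <- c(n_iter, M, R)
    chain_draws[[ch]] <- d[keep, , , drop = FALSE]
  }
  nk <- length(keep)
  param_names <- as.vector(outer(rownames(Y), rownames(X), paste,
                                 sep = ":"))
  if (config$n_chains >= 2L) {
    flat <- lapply(chain_draws, function(d) {
      m <- matrix(d, nrow = nk, ncol = M * R)
      colnames(m) <- param_names
      m
    })
    rhat_vec <- gelman_rubin(flat)
  } else {
    rhat_vec <- stats::setNames(rep(NA_real_, M * R), param_names)
  }
  rhat <- matrix(rhat_vec, M, R, dimnames = list(rownames(Y), rownames(X)))
  converged <- if (all(is.na(rhat_vec))) NA
               else all(rhat_vec < config$convergence_threshold)
  if (isFALSE(converged))
    ts_warn("Gelman-Rubin shrink factor >= ", config$convergence_threshold,
            " for some parameter(s): treat estimates with caution")
  draws <- array(NA_real_, c(nk * config$n_chains, M, R),
                 dimnames = list(NULL, rownames(Y), rownames(X)))
  for (ch in seq_len(config$n_chains))
    draws[(ch - 1L) * nk + seq_len(nk), , ] <- chain_draws[[ch]]
  qs <- function(v) c(mean = mean(v), median = stats::median(v),
                      q2.5 = unname(stats::quantile(v, 0.025)),
                      q97.5 = unname(stats::quantile(v, 0.975)))
  summary_df <- do.call(rbind, lapply(seq_len(M), function(m) {
    do.call(rbind, lapply(seq_len(R), function(r) {
      s <- qs(draws[, m, r])
      data.frame(mixture = rownames(Y)[m], rookery = rownames(X)[r],
                 mean = s["mean"], median = s["median"], q2.5 = s["q2.5"],
                 q97.5 = s["q97.5"], rhat = rhat[m, r],
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }))
  # rookery-centric phi derived per draw
  S <- model$mixture_weights
  phi_summary <- do.call(rbind, lapply(seq_len(R), function(r) {
    th <- draws[, , r]
    if (M == 1L) th <- matrix(th, ncol = 1L)
    num <- sweep(th, 2, S, "*")
    denom <- rowSums(num)
    phi <- num / ifelse(denom == 0, 1, denom)
    do.call(rbind, lapply(seq_len(M), function(m) {
      s <- qs(phi[, m])
      data.frame(rookery = rownames(X)[r], mixture = rownames(Y)[m],
                 mean = s["mean"], median = s["median"], q2.5 = s["q2.5"],
                 q97.5 = s["q97.5"], row.names = NULL,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(draws = draws, summary = summary_df,
                 phi_summary = phi_summary, rhat = rhat,
                 converged = converged, config = config, model = model),
            class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("msa_result: %d draws, %d mixtures x %d rookeries, converged: %s\n",
              dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3],
              format(x$converged)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize posterior contributions of one rookery to each mixture
#'
#' @param result an `msa_result`.
#' @param focus_rookery rookery name; `NULL` returns the full summary.
#' @return data frame with per-mixture posterior mean, median and 95%
#'   credible interval of the focus rookery's contribution.
#' @export
summarize_msa <- function(result, focus_rookery = NULL) {
  stopifnot(inherits(result, "msa_result"))
  if (is.null(focus_rookery)) return(result$summary)
  if (!focus_rookery %in% result$summary$rookery)
    ts_stop("unknown rookery: ", focus_rookery)
  result$summary[result$summary$rookery == focus_rookery, , drop = FALSE]
}
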