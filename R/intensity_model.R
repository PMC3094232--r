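# split-half potential-scale-reduction diagnostic on a list of chains
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq_len(n2) + n2])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  m <- vapply(halves, mean, 0)
  v <- vapply(halves, stats::var, 0)
  w <- mean(v)
  b <- n * stats::var(m)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the Bayesian sharing-intensity model
#'
#' Estimates, for every region pair (i, j) of two homologous arms
#' (inversions plus the aggregate outside region on each side), the
#' multiplicative intensity `gamma_{i,j}` at which the pair shares
#' homologous markers relative to the uniform-placement expectation.
#'
#' The likelihood is `O_{i,j} ~ Binomial(N, pi_{i,j})` with
#' `pi_{i,j} = f_i f_j gamma_{i,j}` and
#' `gamma_{i,j} = lambda_i^(1) lambda_j^(2) + mu_{i,j}`: a product of
#' per-region marginal intensities plus a random effect. The random effect
#' has a three-component mixture prior — a point mass at zero (weight
#' `p0`), a positive-truncated normal around a hot mean `mu_H > 0` (weight
#' `pH`), and a negative-truncated normal around a cold mean `mu_C < 0`
#' (weight `pC`) — so only large deviations from the neutral model are
#' declared hot or cold. The hot/cold means carry flat priors (bounded for
#' propriety); each cell carries a Jeffreys `Beta(1/2, 1/2)`-type reference
#' term on `pi_{i,j}`; marginal intensities are anchored by fixing species
#' 1's first region to 1 and are interpreted only through ratios.
#' Sampling is Metropolis-within-Gibbs with a Metropolized
#' mixture-allocation move (proposals drawn from the prior) and adaptive
#' random-walk scales frozen after burn-in; multiple chains start from
#' dispersed marginal intensities and split-chain R-hat is reported per
#' pair.
#'
#' @param counts A `shared_counts` table from [count_shared()] including
#'   the outside region on both arms.
#' @param burnin Burn-in iterations per chain.
#' @param samples Retained samples per chain.
#' @param chains Number of chains (dispersed starts).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed (fixed seed + chain count gives bit-identical
#'   results).
#' @param sigma Spread of the hot/cold random-effect components (fixed).
#' @param p0,pH,pC Mixture weights (must sum to 1). `pH = pC = 0` reduces
#'   the model to the pure product-intensity form.
#' @param mu_bound Support bound making the flat hot/cold-mean priors
#'   proper.
#' @param rhat_threshold Convergence flag threshold on split-chain R-hat.
#' @return An `intensity_fit` object; see [tidy.intensity_fit()],
#'   [hot_probability()] and [connectivity_ratio()].
#' @export
fit_intensity_model <- function(counts, burnin = 20000, samples = 20000,
                                chains = 4, thin = 1, seed = NULL,
                                sigma = 1, p0 = 0.99, pH = 0.005,
                                pC = 0.005, mu_bound = 50,
                                rhat_threshold = 1.1) {
  stopifnot(inherits(counts, "shared_counts"))
  if (abs(p0 + pH + pC - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (burnin <= 0 || samples <= 0) stop("burnin and samples must be > 0")
  n <- attr(counts, "n_homologs")
  if (is.null(n) || n <= 0) stop("counts must carry a positive homolog total")
  if (!any(counts$kind1 == "outside") || !any(counts$kind2 == "outside")) {
    stop("counts must include the outside region on both arms")
  }
  zero <- counts$f1 == 0 | counts$f2 == 0
  if (any(zero)) {
    warning(sum(zero), " region pair(s) with zero fractional length excluded")
    drop1 <- unique(counts$region1[counts$f1 == 0])
    drop2 <- unique(counts$region2[counts$f2 == 0])
    counts <- counts[!counts$region1 %in% drop1 &
                       !counts$region2 %in% drop2, ]
  }
  r1 <- dplyr::distinct(tibble::as_tibble(counts)[c("region1", "kind1", "f1")])
  r2 <- dplyr::distinct(tibble::as_tibble(counts)[c("region2", "kind2", "f2")])
  r1 <- dplyr::arrange(r1, .data$kind1 != "inversion")  # outside last
  r2 <- dplyr::arrange(r2, .data$kind2 != "inversion")
  nr1 <- nrow(r1); nr2 <- nrow(r2)
  o_mat <- matrix(NA_real_, nr1, nr2)
  i1 <- match(counts$region1, r1$region1)
  i2 <- match(counts$region2, r2$region2)
  o_mat[cbind(i1, i2)] <- counts$O
  if (anyNA(o_mat)) stop("counts must cover the full region-pair grid")
  ff <- outer(r1$f1, r2$f2)
  if (any(ff >= 1)) {
    stop("a region pair has f1*f2 >= 1; the binomial mean cannot stay below 1")
  }
  if (!is.null(seed)) set.seed(seed)
  keep <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init1 <- rnorm(nr1, 0, 0.5)
    init2 <- rnorm(nr2, 0, 0.5)
    init1[1] <- 0
    # shrink dispersed starts until admissible (pi < 1, gamma fine at mu=0)
    repeat {
      pi0 <- ff * outer(exp(init1), exp(init2))
      if (all(pi0 < 1)) break
      init1 <- init1 * 0.8; init2 <- init2 * 0.8
    }
    keep[[ch]] <- intensity_mcmc_cpp(
      o_mat, n, r1$f1, r2$f2, anchor = 0L,
      p0 = p0, pH = pH, pC = pC, sigma = sigma, mu_bound = mu_bound,
      burnin = as.integer(burnin), n_keep = as.integer(samples),
      thin = as.integer(thin),
      init_loglam1 = init1, init_loglam2 = init2,
      init_muH = 1 + runif(1), init_muC = -1 - runif(1))
  }
  gamma <- do.call(rbind, lapply(keep, `[[`, "gamma"))
  lam1 <- do.call(rbind, lapply(keep, `[[`, "lam1"))
  lam2 <- do.call(rbind, lapply(keep, `[[`, "lam2"))
  chain_id <- rep(seq_len(chains), each = samples)
  cells <- tidyr::expand_grid(j = seq_len(nr2), i = seq_len(nr1))
  cells <- dplyr::arrange(cells, .data$j, .data$i)  # column-major cell order
  pairs <- tibble::tibble(
    region1 = r1$region1[cells$i], kind1 = r1$kind1[cells$i],
    f1 = r1$f1[cells$i],
    region2 = r2$region2[cells$j], kind2 = r2$kind2[cells$j],
    f2 = r2$f2[cells$j],
    O = o_mat[cbind(cells$i, cells$j)])
  rhat <- vapply(seq_len(ncol(gamma)), function(c) {
    split_rhat(split(gamma[, c], chain_id))
  }, 0)
  converged <- all(is.na(rhat) | rhat < rhat_threshold)
  if (!converged) {
    warning("split-chain R-hat exceeds ", rhat_threshold,
            " for some region pairs; inspect diagnostics")
  }
  structure(list(
    pairs = pairs, gamma = gamma, lam1 = lam1, lam2 = lam2,
    muH = unlist(lapply(keep, `[[`, "muH")),
    muC = unlist(lapply(keep, `[[`, "muC")),
    hot_frac = colMeans(do.call(rbind, lapply(keep, `[[`, "hot_frac"))),
    cold_frac = colMeans(do.call(rbind, lapply(keep, `[[`, "cold_frac"))),
    chain_id = chain_id, rhat = rhat, converged = converged,
    regions1 = r1, regions2 = r2,
    settings = list(burnin = burnin, samples = samples, chains = chains,
                    thin = thin, seed = seed, sigma = sigma,
                    p0 = p0, pH = pH, pC = pC, mu_bound = mu_bound),
    species = c(attr(counts, "species1"), attr(counts, "species2")),
    arms = c(attr(counts, "arm1"), attr(counts, "arm2")),
    n_homologs = n
  ), class = "intensity_fit")
}

cell_index <- function(fit, region1, region2) {
  hit <- which(fit$pairs$region1 == region1 & fit$pairs$region2 == region2)
  if (length(hit) != 1) {
    stop("unknown region pair (", region1, ", ", region2, ")")
  }
  hit
}

#' Posterior hotspot probability of a region pair
#'
#' Fraction of retained posterior samples in which the sharing intensity
#' `gamma_{i,j}` exceeds 1.
#'
#' @param fit An `intensity_fit`.
#' @param region1,region2 Region ids on species 1 and 2 (`"outside"`
#'   allowed).
#' @return A probability.
#' @export
hot_probability <- function(fit, region1, region2) {
  stopifnot(inherits(fit, "intensity_fit"))
  mean(fit$gamma[, cell_index(fit, region1, region2)] > 1)
}

#' Outside/inside connectivity ratio
#'
#' Posterior summary of the ratio of the average sharing intensity of
#' region pairs involving the outside regions to the average over
#' inversion-by-inversion pairs. Per retained sample, the outside average
#' is `(sum_i gamma_{i,out} + sum_j gamma_{out,j} + gamma_{out,out}) /
#' (N1 + N2 + 1)` with `N1`, `N2` the numbers of inverted regions on the
#' two arms, and the inside average is the unweighted mean over inversion
#' pairs. Ratios below 1 indicate that regions outside inversions are
#' under-connected relative to the inversions.
#'
#' @param fit An `intensity_fit`.
#' @return A one-row tibble with `estimate` (posterior expectation),
#'   `conf.low`, `conf.high` (central 95% credible interval); the ratio
#'   samples are attached as attribute `"samples"`.
#' @export
connectivity_ratio <- function(fit) {
  stopifnot(inherits(fit, "intensity_fit"))
  p <- fit$pairs
  inside <- p$kind1 == "inversion" & p$kind2 == "inversion"
  outside <- p$kind1 == "outside" | p$kind2 == "outside"
  if (!any(inside)) stop("no inversion regions on either arm")
  r_out <- rowMeans(fit$gamma[, outside, drop = FALSE])
  r_in <- rowMeans(fit$gamma[, inside, drop = FALSE])
  ratio <- r_out / r_in
  out <- tibble::tibble(estimate = mean(ratio),
                        conf.low = unname(quantile(ratio, 0.025)),
                        conf.high = unname(quantile(ratio, 0.975)))
  attr(out, "samples") <- ratio
  out
}

#' @describeIn fit_intensity_model Per region-pair posterior summaries:
#'   posterior mean intensity, central 95% credible interval, hotspot
#'   probability `Pr(gamma > 1)`, hot/cold component occupancy and R-hat.
#' @param x An `intensity_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.intensity_fit <- function(x, ...) {
  g <- x$gamma
  tibble::tibble(
    region1 = x$pairs$region1, region2 = x$pairs$region2,
    kind1 = x$pairs$kind1, kind2 = x$pairs$kind2,
    O = x$pairs$O, E = x$n_homologs * x$pairs$f1 * x$pairs$f2,
    estimate = colMeans(g),
    conf.low = apply(g, 2, quantile, 0.025),
    conf.high = apply(g, 2, quantile, 0.975),
    pr_hot = colMeans(g > 1),
    p_hot_component = x$hot_frac,
    p_cold_component = x$cold_frac,
    rhat = x$rhat)
}

#' @describeIn fit_intensity_model One-row fit summary.
#' @exportS3Method generics::glance
glance.intensity_fit <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), n_homologs = x$n_homologs,
                 chains = x$settings$chains,
                 samples = x$settings$samples,
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' @export
print.intensity_fit <- function(x, ...) {
  cat("Sharing-intensity model:", x$species[1], x$arms[1], "vs",
      x$species[2], x$arms[2], "\n")
  cat(sprintf("  %d region pairs, N = %d homologs, %d chains x %d samples\n",
              nrow(x$pairs), x$n_homologs, x$settings$chains,
              x$settings$samples))
  cat(sprintf("  max split R-hat = %.3f (%s)\n",
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  top <- dplyr::arrange(tidy(x), dplyr::desc(.data$pr_hot))
  print(utils::head(top, 5))
  invisible(x)
}
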