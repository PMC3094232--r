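#' Expected shared-marker counts under pure chance
#'
#' Under the null that homologous markers fall uniformly and independently
#' on the two arms, the expected number of the `N` shared homologs
#' co-located in region pair (i, j) is `E = N * f_i * f_j`, where `f` is
#' the fractional region length. Pairs with a zero fraction are excluded
#' (they would later divide by `E = 0`) with a warning.
#'
#' @param counts A `shared_counts` table from [count_shared()].
#' @return The table with an `E` column appended; attributes preserved.
#' @export
expected_counts <- function(counts) {
  n <- attr(counts, "n_homologs")
  if (is.null(n) || n <= 0) stop("counts must carry a positive homolog total")
  at <- attributes(counts)
  zero <- counts$f1 == 0 | counts$f2 == 0
  if (any(zero)) {
    warning(sum(zero), " region pair(s) with zero fractional length excluded")
    counts <- counts[!zero, ]
  }
  counts$E <- n * counts$f1 * counts$f2
  for (a in c("species1", "arm1", "species2", "arm2", "n_homologs",
              "arm_length1", "arm_length2")) {
    attr(counts, a) <- at[[a]]
  }
  class(counts) <- unique(c("shared_counts", class(counts)))
  counts
}

#' Discrepancy matrix and sharing statistic
#'
#' Computes the per-pair discrepancy `D = (O - E)^2 / E` between observed
#' and expected shared-marker counts, together with the sign of `O - E`
#' (for hot/cold rendering) and the summed statistic `T = sum(D)`.
#'
#' @param counts A `shared_counts` table carrying `O` and `E` columns
#'   (see [expected_counts()]), already restricted to the statistic's
#'   scope.
#' @return A list with `tab` (the table with `D` and `sign` columns) and
#'   `statistic` (`T`).
#' @export
sharing_statistic <- function(counts) {
  if (!all(c("O", "E") %in% names(counts))) {
    stop("counts must carry O and E columns")
  }
  if (any(counts$E <= 0)) stop("E must be positive on included pairs")
  counts$D <- (counts$O - counts$E)^2 / counts$E
  counts$sign <- sign(counts$O - counts$E)
  list(tab = counts, statistic = sum(counts$D))
}

#' Asymptotic p-value of the sharing statistic
#'
#' The summed discrepancy is asymptotically chi-squared when the homolog
#' total `N` is large; this returns the upper-tail probability.
#'
#' @param statistic Observed statistic `T` (>= 0).
#' @param df Degrees of freedom (>= 1); conventionally the number of region
#'   pairs included in the statistic.
#' @return The upper-tail p-value.
#' @export
asymptotic_pvalue <- function(statistic, df) {
  if (statistic < 0) stop("statistic must be >= 0")
  if (df < 1) stop("df must be >= 1")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

scope_pairs <- function(counts) {
  counts[counts$kind1 == "inversion" & counts$kind2 == "inversion", ]
}

# membership matrix of a position matrix in each inversion of a region set
inv_membership <- function(pos, inv) {
  purrr::map(seq_len(nrow(inv)), function(k) {
    pos >= inv$start_mb[k] & pos < inv$end_mb[k]
  })
}

#' Monte-Carlo p-value for the sharing statistic
#'
#' Simulates the null distribution of the sharing statistic by
#' repositioning every homolog pair uniformly and independently on its two
#' arms, recounting the shared-marker table, and recomputing the statistic
#' against the *original* expected counts. The p-value is the plain
#' proportion of draws whose statistic is at least the observed one (ties
#' count as exceedances); a reported 0 should be read as "less than
#' 1/n_draws".
#'
#' @inheritParams count_shared
#' @param n_draws Number of null draws (>= 1).
#' @param seed Optional integer seed.
#' @param chunk Draws simulated per block (memory/time trade-off).
#' @return A list with `p`, `null_sample` (the simulated statistics),
#'   `statistic` (observed `T`) and `n_draws`.
#' @export
monte_carlo_pvalue <- function(markers1, markers2, regions1, regions2,
                               homologs = NULL, n_draws = 10000,
                               seed = NULL, chunk = 2000L) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- count_shared(markers1, markers2, regions1, regions2, homologs)
  n <- attr(counts, "n_homologs")
  l1 <- attr(counts, "arm_length1")
  l2 <- attr(counts, "arm_length2")
  scoped <- sharing_statistic(scope_pairs(expected_counts(counts)))
  tab <- scoped$tab
  t_obs <- scoped$statistic
  k1 <- single_arm(markers1, "markers1")
  k2 <- single_arm(markers2, "markers2")
  inv1 <- regions1[regions1$species == k1$species &
                     regions1$arm == k1$arm & regions1$kind == "inversion", ]
  inv2 <- regions2[regions2$species == k2$species &
                     regions2$arm == k2$arm & regions2$kind == "inversion", ]
  i1 <- match(tab$region1, inv1$region_id)
  i2 <- match(tab$region2, inv2$region_id)
  null_sample <- numeric(0)
  remaining <- n_draws
  while (remaining > 0) {
    m <- min(chunk, remaining)
    pos1 <- matrix(runif(n * m, 0, l1), nrow = n)
    pos2 <- matrix(runif(n * m, 0, l2), nrow = n)
    b1 <- inv_membership(pos1, inv1)
    b2 <- inv_membership(pos2, inv2)
    t_chunk <- numeric(m)
    for (r in seq_len(nrow(tab))) {
      o_sim <- .colSums(b1[[i1[r]]] & b2[[i2[r]]], n, m)
      t_chunk <- t_chunk + (o_sim - tab$E[r])^2 / tab$E[r]
    }
    null_sample <- c(null_sample, t_chunk)
    remaining <- remaining - m
  }
  list(p = mean(null_sample >= t_obs), null_sample = null_sample,
       statistic = t_obs, n_draws = n_draws)
}

#' Test for nonrandom sharing of homologs between inversions
#'
#' Full frequentist test of whether homologous markers co-locate within
#' polymorphic inversion pairs of two species more often than uniform
#' placement predicts. The statistic sums the discrepancy
#' `(O - E)^2 / E` over inversion-by-inversion region pairs; an asymptotic
#' chi-squared p-value and a Monte-Carlo p-value (uniform repositioning of
#' every homolog pair) are both reported.
#'
#' @inheritParams monte_carlo_pvalue
#' @param df Degrees of freedom for the asymptotic p-value; defaults to
#'   the number of inversion pairs included in the statistic.
#' @return A `sharing_test` object; see [tidy.sharing_test()] and
#'   [glance.sharing_test()].
#' @examples
#' sc <- sharing_scenario(60, 50,
#'   data.frame(region_id = "a", start_mb = 10, end_mb = 25),
#'   data.frame(region_id = "b", start_mb = 5, end_mb = 20),
#'   n_homologs = 100, seed = 42)
#' d <- gen_shared_markers(sc)
#' fit <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
#'                     n_draws = 200, seed = 1)
#' glance(fit)
#' @export
sharing_test <- function(markers1, markers2, regions1, regions2,
                         homologs = NULL, n_draws = 10000, seed = NULL,
                         df = NULL, chunk = 2000L) {
  counts <- count_shared(markers1, markers2, regions1, regions2, homologs)
  scoped <- sharing_statistic(scope_pairs(expected_counts(counts)))
  if (is.null(df)) df <- nrow(scoped$tab)
  mc <- monte_carlo_pvalue(markers1, markers2, regions1, regions2,
                           homologs = homologs, n_draws = n_draws,
                           seed = seed, chunk = chunk)
  structure(list(
    pairs = scoped$tab,
    counts = counts,
    statistic = scoped$statistic,
    df = df,
    p_asymptotic = asymptotic_pvalue(scoped$statistic, df),
    p_simulated = mc$p,
    null_sample = mc$null_sample,
    n_draws = n_draws,
    seed = seed,
    species = c(attr(counts, "species1"), attr(counts, "species2")),
    arms = c(attr(counts, "arm1"), attr(counts, "arm2")),
    n_homologs = attr(counts, "n_homologs")
  ), class = "sharing_test")
}

#' @describeIn sharing_test Per region-pair discrepancies.
#' @param x A `sharing_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sharing_test <- function(x, ...) {
  tibble::as_tibble(x$pairs[c("region1", "region2", "f1", "f2",
                              "O", "E", "D", "sign")])
}

#' @describeIn sharing_test One-row test summary.
#' @exportS3Method generics::glance
glance.sharing_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p_asymptotic = x$p_asymptotic,
                 p_simulated = x$p_simulated,
                 n_draws = x$n_draws, n_homologs = x$n_homologs)
}

#' @export
print.sharing_test <- function(x, ...) {
  cat("Sharing test:", x$species[1], x$arms[1], "vs",
      x$species[2], x$arms[2], "\n")
  cat(sprintf("  N = %d shared homologs over %d inversion pairs\n",
              x$n_homologs, nrow(x$pairs)))
  cat(sprintf("  T = %.3f (df = %d)\n", x$statistic, x$df))
  cat(sprintf("  asymptotic p = %.4g\n", x$p_asymptotic))
  p_lab <- if (x$p_simulated == 0) {
    sprintf("< %.2g", 1 / x$n_draws)
  } else {
    sprintf("%.4g", x$p_simulated)
  }
  cat(sprintf("  simulated  p = %s (%d draws)\n", p_lab, x$n_draws))
  invisible(x)
}
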