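fit_fixture <- function(n = 300, gamma = NULL, seed = 5, fit_seed = 17, ...) {
  sc <- sharing_scenario(
    60, 60,
    tibble::tibble(region_id = c("p", "q", "r"),
                   start_mb = c(5, 22, 40), end_mb = c(18, 34, 52)),
    tibble::tibble(region_id = c("x", "y", "z"),
                   start_mb = c(3, 25, 44), end_mb = c(16, 38, 55)),
    n_homologs = n, gamma = gamma, seed = seed)
  d <- gen_shared_markers(sc)
  cnt <- count_shared(d$markers1, d$markers2, d$regions1, d$regions2)
  suppressWarnings(fit_intensity_model(cnt, burnin = 2500, samples = 2500,
                                       chains = 2, seed = fit_seed, ...))
}

test_that("without hot/cold components the model is a pure product", {
  fit <- fit_fixture(pH = 0, pC = 0, p0 = 1)
  nr1 <- nrow(fit$regions1)
  for (c in seq_len(ncol(fit$gamma))) {
    i <- (c - 1) %% nr1 + 1
    j <- (c - 1) %/% nr1 + 1
    expect_equal(fit$gamma[, c], fit$lam1[, i] * fit$lam2[, j])
  }
  # anchored marginal is exactly 1 in every sample
  expect_true(all(fit$lam1[, 1] == 1))
})

test_that("fits are bit-reproducible from the seed", {
  f1 <- fit_fixture(fit_seed = 23)
  f2 <- fit_fixture(fit_seed = 23)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(connectivity_ratio(f1)$estimate,
                   connectivity_ratio(f2)$estimate)
})

test_that("hot probability equals a direct sample recount", {
  fit <- fit_fixture()
  td <- tidy(fit)
  for (k in c(1, 5, nrow(td))) {
    expect_equal(hot_probability(fit, td$region1[k], td$region2[k]),
                 mean(fit$gamma[, k] > 1))
  }
  expect_error(hot_probability(fit, "nope", "x"), "unknown region pair")
})

test_that("connectivity ratio is 1 for a homogeneous posterior", {
  pairs <- tidyr::expand_grid(region1 = c("a", "outside"),
                              region2 = c("b", "outside"))
  pairs$kind1 <- ifelse(pairs$region1 == "outside", "outside", "inversion")
  pairs$kind2 <- ifelse(pairs$region2 == "outside", "outside", "inversion")
  fake <- structure(list(pairs = pairs,
                         gamma = matrix(2, nrow = 50, ncol = 4)),
                    class = "intensity_fit")
  cr <- connectivity_ratio(fake)
  expect_equal(cr$estimate, 1)
  expect_equal(cr$conf.low, 1)

  fake$pairs$kind1 <- "outside"
  fake$pairs$kind2 <- "outside"
  expect_error(connectivity_ratio(fake), "no inversion regions")
})

test_that("null data give calibrated intensities", {
  est <- c(); prh <- c()
  for (s in 1:8) {
    fit <- fit_fixture(n = 500, seed = s, fit_seed = 400 + s)
    td <- tidy(fit)
    est <- c(est, td$estimate)
    prh <- c(prh, td$pr_hot)
  }
  expect_true(all(est > 0.55 & est < 1.6))
  expect_lt(abs(mean(est) - 1), 0.1)
  expect_gt(mean(prh), 0.3)
  expect_lt(mean(prh), 0.7)
  expect_lte(mean(prh > 0.99), 0.05)  # no decisive hotspot calls under null
})

test_that("planted intensities are recovered in rank order", {
  # one dataset per planted value on the same region pair: the recovered
  # posterior means must reproduce the planted ordering
  planted <- c(0.2, 1, 3, 6)
  est <- vapply(seq_along(planted), function(k) {
    gam <- tibble::tibble(region1 = "p", region2 = "x",
                          gamma = planted[k])
    fit <- fit_fixture(n = 400, gamma = gam, seed = 40 + k,
                       fit_seed = 60 + k)
    tidy(fit)$estimate[fit$pairs$region1 == "p" & fit$pairs$region2 == "x"]
  }, 0)
  expect_true(all(diff(est) > 0))
  expect_lt(est[1], 0.7)
  gam6 <- tibble::tibble(region1 = "p", region2 = "x", gamma = 6)
  fit6 <- fit_fixture(n = 400, gamma = gam6, seed = 44, fit_seed = 64)
  expect_gt(hot_probability(fit6, "p", "x"), 0.95)
})

test_that("invalid model specifications are rejected", {
  d <- gen_shared_markers(sharing_scenario(
    60, 60,
    tibble::tibble(region_id = "a", start_mb = 5, end_mb = 15),
    tibble::tibble(region_id = "b", start_mb = 5, end_mb = 15),
    n_homologs = 30, seed = 1))
  cnt <- count_shared(d$markers1, d$markers2, d$regions1, d$regions2)
  expect_error(fit_intensity_model(cnt, p0 = 0.9, pH = 0.2, pC = 0.2),
               "sum to 1")
  inv_only <- cnt[cnt$kind1 == "inversion" & cnt$kind2 == "inversion", ]
  attr(inv_only, "n_homologs") <- attr(cnt, "n_homologs")
  class(inv_only) <- class(cnt)
  expect_error(fit_intensity_model(inv_only), "outside region")
})
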