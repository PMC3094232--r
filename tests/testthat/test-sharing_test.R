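fixture_pair <- function(n = 150, seed = 5, gamma = NULL) {
  sc <- sharing_scenario(
    61.5, 55,
    tibble::tibble(region_id = c("a1", "a2", "a3"),
                   start_mb = c(2, 20, 28), end_mb = c(14, 27, 34)),
    tibble::tibble(region_id = c("b1", "b2"),
                   start_mb = c(5, 30), end_mb = c(16, 40)),
    n_homologs = n, gamma = gamma, seed = seed)
  gen_shared_markers(sc)
}

test_that("expected counts are N * f_i * f_j", {
  # N = 100 homologs, f1 = 0.2, f2 = 0.5 -> E = 10
  al <- arm_lengths(c("s1", "s2"), "2R", c(50, 20))
  r1 <- as_region_set(tibble::tibble(species = "s1", arm = "2R",
                                     region_id = "A", start_mb = 0,
                                     end_mb = 10), al)
  r2 <- as_region_set(tibble::tibble(species = "s2", arm = "2R",
                                     region_id = "B", start_mb = 0,
                                     end_mb = 10), al)
  set.seed(1)
  ids <- sprintf("h%03d", 1:100)
  m1 <- toy_map("s1", ids, sort(runif(100, 0, 50)), 50)
  m2 <- toy_map("s2", ids, sort(runif(100, 0, 20)), 20)
  ec <- expected_counts(count_shared(m1, m2, r1, r2))
  expect_equal(ec$E[ec$region1 == "A" & ec$region2 == "B"], 10)
  # full matrix equals the elementwise oracle
  expect_equal(ec$E, 100 * ec$f1 * ec$f2)
})

test_that("zero-fraction pairs are excluded with a warning", {
  al <- arm_lengths(c("s1", "s2"), "2R", c(50, 50))
  # inversion covering the whole arm leaves a zero-length outside region
  r1 <- as_region_set(tibble::tibble(species = "s1", arm = "2R",
                                     region_id = "A", start_mb = 0,
                                     end_mb = 50), al)
  r2 <- as_region_set(tibble::tibble(species = "s2", arm = "2R",
                                     region_id = "B", start_mb = 10,
                                     end_mb = 30), al)
  m1 <- toy_map("s1", c("h1", "h2"), c(5, 25), 50)
  m2 <- toy_map("s2", c("h1", "h2"), c(15, 45), 50)
  expect_warning(ec <- expected_counts(count_shared(m1, m2, r1, r2)),
                 "zero fractional length")
  expect_false(any(ec$f1 == 0 | ec$f2 == 0))
})

test_that("the discrepancy statistic follows its definition", {
  tab <- tibble::tibble(region1 = "A", kind1 = "inversion", f1 = 0.5,
                        region2 = "B", kind2 = "inversion", f2 = 0.5,
                        O = 10, E = 2.5)
  st <- sharing_statistic(tab)
  expect_equal(st$tab$D, 22.5)  # (10 - 2.5)^2 / 2.5
  expect_equal(st$statistic, 22.5)
  tab$O <- tab$E
  expect_equal(sharing_statistic(tab)$statistic, 0)

  d <- fixture_pair()
  st <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                     n_draws = 50, seed = 1)
  expect_equal(st$statistic,
               oracle_statistic(d$markers1, d$markers2,
                                d$regions1, d$regions2))
})

test_that("asymptotic p-values follow the chi-squared tail", {
  expect_equal(asymptotic_pvalue(0, 4), 1)
  expect_equal(asymptotic_pvalue(3.841, 1), 0.05, tolerance = 1e-3)
  ps <- vapply(c(1, 5, 10, 20), asymptotic_pvalue, 0, df = 3)
  expect_true(all(diff(ps) < 0))
  expect_error(asymptotic_pvalue(-1, 1), ">= 0")
})

test_that("Monte-Carlo p-values are reproducible and tie-inclusive", {
  d <- fixture_pair(n = 80, seed = 2)
  mc1 <- monte_carlo_pvalue(d$markers1, d$markers2, d$regions1, d$regions2,
                            n_draws = 500, seed = 77)
  mc2 <- monte_carlo_pvalue(d$markers1, d$markers2, d$regions1, d$regions2,
                            n_draws = 500, seed = 77)
  expect_identical(mc1$null_sample, mc2$null_sample)
  expect_identical(mc1$p, mc2$p)
  # plain proportion with ties counted as exceedances
  expect_equal(mc1$p, mean(mc1$null_sample >= mc1$statistic))
})

test_that("simulated and asymptotic p-values agree on large-N null data", {
  d <- fixture_pair(n = 2000, seed = 9)
  st <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                     n_draws = 2000, seed = 4)
  expect_lt(abs(st$p_simulated - st$p_asymptotic), 0.1)
})

test_that("the statistic is invariant to region relabeling", {
  d <- fixture_pair(n = 100, seed = 6)
  r1b <- d$regions1
  r1b$region_id[r1b$kind == "inversion"] <-
    rev(r1b$region_id[r1b$kind == "inversion"])
  st1 <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                      n_draws = 50, seed = 1)
  st2 <- sharing_test(d$markers1, d$markers2, r1b, d$regions2,
                      n_draws = 50, seed = 1)
  expect_equal(st1$statistic, st2$statistic)
})

test_that("df defaults to the number of inversion pairs and is overridable", {
  d <- fixture_pair(n = 60, seed = 8)
  st <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                     n_draws = 20, seed = 1)
  expect_equal(st$df, 6)  # 3 x 2 inversion pairs
  st5 <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                      n_draws = 20, seed = 1, df = 5)
  expect_equal(st5$p_asymptotic, asymptotic_pvalue(st5$statistic, 5))
  expect_output(print(st), "simulated")
})
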