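null_scenario <- function(n, seed) {
  sharing_scenario(
    60, 50,
    tibble::tibble(region_id = c("a1", "a2"), start_mb = c(5, 30),
                   end_mb = c(15, 45)),
    tibble::tibble(region_id = c("b1", "b2"), start_mb = c(0, 25),
                   end_mb = c(10, 40)),
    n_homologs = n, seed = seed)
}

test_that("generators are reproducible from the seed", {
  d1 <- gen_shared_markers(null_scenario(50, 3))
  d2 <- gen_shared_markers(null_scenario(50, 3))
  expect_equal(d1$markers1, d2$markers1)
  expect_equal(d1$markers2, d2$markers2)
  d3 <- gen_shared_markers(null_scenario(50, 4))
  expect_false(identical(d1$markers1$position_mb, d3$markers1$position_mb))

  t1 <- gen_rearranged_orders(30, c(3, 4, 5), seed = 9)
  t2 <- gen_rearranged_orders(30, c(3, 4, 5), seed = 9)
  expect_equal(t1, t2)
})

test_that("uniform intensities give uniform marginal placement", {
  sc <- null_scenario(10000, 11)
  d <- gen_shared_markers(sc)
  # empirical fraction in each region within 3 binomial standard errors
  for (side in 1:2) {
    reg <- d[[paste0("regions", side)]]
    pos <- d[[paste0("markers", side)]]$position_mb
    inv <- reg[reg$kind == "inversion", ]
    for (k in seq_len(nrow(reg))) {
      inside <- if (reg$kind[k] == "inversion") {
        mean(pos >= reg$start_mb[k] & pos < reg$end_mb[k])
      } else {
        mean(!purrr::reduce(purrr::map(seq_len(nrow(inv)), function(q) {
          pos >= inv$start_mb[q] & pos < inv$end_mb[q]
        }), `|`))
      }
      se <- sqrt(reg$f[k] * (1 - reg$f[k]) / 10000)
      expect_lt(abs(inside - reg$f[k]), 3 * se + 1e-9)
    }
  }
})

test_that("a planted hotspot inflates the pair count as expected", {
  # small-f regions so the categorical normaliser stays near 1
  sc0 <- sharing_scenario(
    60, 60,
    tibble::tibble(region_id = "A", start_mb = 10, end_mb = 12),
    tibble::tibble(region_id = "B", start_mb = 40, end_mb = 42),
    n_homologs = 200,
    gamma = tibble::tibble(region1 = "A", region2 = "B", gamma = 6),
    seed = 1)
  f_a <- 2 / 60; f_b <- 2 / 60
  o_ab <- vapply(1:200, function(s) {
    sc0$seed <- s
    d <- gen_shared_markers(sc0)
    cnt <- count_shared(d$markers1, d$markers2, d$regions1, d$regions2)
    cnt$O[cnt$region1 == "A" & cnt$region2 == "B"]
  }, 0)
  expected <- 6 * 200 * f_a * f_b
  se <- sd(o_ab) / sqrt(200)
  expect_lt(abs(mean(o_ab) - expected), 3 * se + 0.05 * expected)
})

test_that("degenerate scenarios behave", {
  d <- gen_shared_markers(null_scenario(0, 1))
  expect_equal(nrow(d$markers1), 0)
  expect_equal(nrow(d$homologs), 0)
  expect_equal(nrow(d$regions1), 3)  # regions still valid

  bad <- null_scenario(10, 1)
  bad$gamma <- tibble::tibble(region1 = c("a1", "a2", "outside"),
                              region2 = "x", gamma = 0)
  expect_error(sharing_scenario(60, 50, bad$inversions1, bad$inversions2,
                                10, gamma = tibble::tibble(
                                  region1 = "a1", region2 = "b1",
                                  gamma = -1)),
               "gamma must be >= 0")
})

test_that("rearranged orders obey reversal mechanics", {
  t0 <- gen_rearranged_orders(12, c(0, 0, 0), seed = 5)
  expect_equal(t0[[1]]$homolog_group, t0[[2]]$homolog_group)
  expect_equal(t0[[1]]$homolog_group, t0[[3]]$homolog_group)
  expect_equal(t0[[1]]$homolog_group, sprintf("G%04d", 1:12))

  # a single reversal of positions 2..4 on a 6-gene arm
  expect_equal(armdyn:::apply_reversal(1:6, 2, 4), c(1, 4, 3, 2, 5, 6))

  # one sampled reversal leaves exactly one contiguous reversed segment
  t1 <- gen_rearranged_orders(20, c(1, 0, 0), seed = 8)
  ord <- match(t1[[1]]$homolog_group, sprintf("G%04d", 1:20))
  diffidx <- which(ord != 1:20)
  expect_true(length(diffidx) >= 2)
  s <- min(diffidx); e <- max(diffidx)
  # the whole segment [s..e] is reversed (its midpoint stays put when the
  # segment length is odd, so compare the full span, not diffidx itself)
  expect_equal(ord[s:e], e:s)

  expect_error(gen_rearranged_orders(10, c(-1, 0, 0)), "non-negative")
})

test_that("breakpoint counts grow with the number of reversals", {
  counts <- c(1, 3, 6, 12)
  mean_bp <- vapply(seq_along(counts), function(k) {
    mean(vapply(1:200, function(r) {
      tr <- gen_rearranged_orders(40, c(counts[k], 0, 0),
                                  seed = 1000 * k + r)
      ordA <- match(tr[[1]]$homolog_group, sprintf("G%04d", 1:40))
      oracle_breakpoints(ordA, 1:40)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_bp) > 0))
})

test_that("block-length draws match their closed-form moments", {
  set.seed(31)
  counts <- vapply(1:1000, function(i)
    gen_block_lengths(0.25, 90, 60)$count, 0)
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 1000))

  set.seed(32)
  lens <- unlist(lapply(1:400, function(i)
    gen_block_lengths(0.25, 100, 60)$lengths_mb))
  expect_lt(abs(mean(lens) - 0.6), 3 * 0.6 / sqrt(length(lens)))

  # scaled lengths are L-free: mean b/L = 1/gamma for any L
  for (L in c(30, 120)) {
    set.seed(33)
    sl <- unlist(lapply(1:300, function(i)
      gen_block_lengths(0.3, 50, L)$lengths_mb)) / L
    expect_lt(abs(mean(sl) - 1 / 50), 4 * (1 / 50) / sqrt(length(sl)))
  }
  expect_error(gen_block_lengths(0, 1, 1), "positive")
})
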