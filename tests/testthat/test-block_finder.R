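test_that("identical maps form a single forward block", {
  A <- toy_map("A", paste0("m", 1:5), 1:5, 10)
  b <- find_pairwise_blocks(A, A)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_markers, 5)
  expect_equal(b$orientation, "forward")
})

test_that("a reversed tail splits into forward and reversed blocks", {
  A <- toy_map("A", paste0("m", 1:5), 1:5, 10)
  B <- toy_map("B", paste0("m", c(1, 2, 3, 5, 4)), 1:5, 10)
  b <- find_pairwise_blocks(A, B)
  expect_equal(nrow(b), 2)
  expect_equal(b$members[[1]], c("m1", "m2", "m3"))
  expect_equal(b$orientation[1], "forward")
  expect_equal(sort(b$members[[2]]), c("m4", "m5"))
  expect_equal(b$orientation[2], "reversed")
})

test_that("distance conservation breaks adjacency beyond the tolerance", {
  # gaps 1.0 vs 2.5 Mb: |1 - 2.5| = 1.5 > 0.5 * 2.5
  A <- toy_map("A", c("m1", "m2"), c(0, 1), 5)
  B <- toy_map("B", c("m1", "m2"), c(0, 2.5), 5)
  expect_equal(nrow(find_pairwise_blocks(A, B, rel_tol = 0.5)), 0)
  expect_equal(nrow(find_pairwise_blocks(A, B, rel_tol = Inf)), 1)
  expect_equal(nrow(find_pairwise_blocks(A, toy_map("B", "m1", 1, 5))), 0)
})

test_that("block finding is symmetric in marker membership", {
  for (s in 1:30) {
    inst <- random_block_instance(s)
    ab <- find_pairwise_blocks(inst$A, inst$B, inst$rel_tol)
    ba <- find_pairwise_blocks(inst$B, inst$A, inst$rel_tol)
    expect_equal(
      sort(vapply(ab$members, function(m) paste(sort(m), collapse = "+"),
                  "")),
      sort(vapply(ba$members, function(m) paste(sort(m), collapse = "+"),
                  "")),
      info = paste("seed", s))
  }
})

test_that("the scan matches brute-force maximal-run enumeration", {
  for (s in 1:150) {
    inst <- random_block_instance(s)
    got <- find_pairwise_blocks(inst$A, inst$B, inst$rel_tol)
    want <- oracle_blocks(inst$A, inst$B, inst$rel_tol)
    expect_equal(nrow(got), length(want), info = paste("seed", s))
    if (nrow(got) > 0) {
      expect_equal(got$members, lapply(want, `[[`, "members"),
                   info = paste("seed", s))
      expect_equal(got$orientation,
                   vapply(want, `[[`, "", "orientation"),
                   info = paste("seed", s))
    }
    # blocks never overlap in marker membership
    all_members <- unlist(got$members)
    expect_equal(anyDuplicated(all_members), 0)
  }
})

test_that("three identical maps give one fully conserved block", {
  A <- toy_map("A", paste0("m", 1:6), 1:6, 10)
  B <- toy_map("B", paste0("m", 1:6), 1:6, 10)
  C <- toy_map("C", paste0("m", 1:6), 1:6, 10)
  cl <- classify_blocks(find_pairwise_blocks(A, B),
                        find_pairwise_blocks(A, C),
                        find_pairwise_blocks(B, C))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$class, "fully_conserved")
  expect_equal(cl$n_markers, 6)
})

test_that("a disruption in the third species leaves a partial remainder", {
  A <- toy_map("A", paste0("m", 1:6), 1:6, 50)
  B <- toy_map("B", paste0("m", 1:6), 1:6, 50)
  # C keeps m1..m3 conserved; m4..m6 keep order but distances explode
  C <- toy_map("C", paste0("m", 1:6), c(1, 2, 3, 10, 20, 40), 50)
  cl <- classify_blocks(find_pairwise_blocks(A, B),
                        find_pairwise_blocks(A, C),
                        find_pairwise_blocks(B, C))
  expect_equal(sort(cl$class), c("fully_conserved", "partial"))
  full <- cl[cl$class == "fully_conserved", ]
  expect_equal(full$members[[1]], c("m1", "m2", "m3"))
  part <- cl[cl$class == "partial", ]
  expect_equal(part$members[[1]], c("m4", "m5", "m6"))
  expect_equal(part$pair, "A-B")

  st <- block_stats(cl, 50)
  expect_equal(st$n_blocks[st$set == "c"], 1)
  expect_equal(st$n_blocks[st$set == "c+d"], 2)
  expect_equal(st$total_length_mb[st$set == "c+d"], 2 + 2)
  expect_equal(st$mean_length_mb[st$set == "c+d"], 2)
})

test_that("classification rejects inconsistent universes and empty inputs", {
  A <- toy_map("A", paste0("m", 1:4), 1:4, 10)
  B <- toy_map("B", paste0("m", 1:4), 1:4, 10)
  C <- toy_map("C", paste0("m", 2:5), 2:5, 10)
  expect_error(classify_blocks(find_pairwise_blocks(A, B),
                               find_pairwise_blocks(A, C),
                               find_pairwise_blocks(B, C)),
               "inconsistent homolog universes")

  # maps sharing markers but with no conserved adjacency: empty classification
  A2 <- toy_map("A", paste0("m", 1:4), c(1, 2, 4, 8), 20)
  B2 <- toy_map("B", paste0("m", c(3, 1, 4, 2)), c(1, 3, 7, 15), 20)
  C2 <- toy_map("C", paste0("m", c(2, 4, 1, 3)), c(1, 4, 9, 16), 20)
  cl <- classify_blocks(find_pairwise_blocks(A2, B2, 0.1),
                        find_pairwise_blocks(A2, C2, 0.1),
                        find_pairwise_blocks(B2, C2, 0.1))
  expect_equal(nrow(cl), 0)
})
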