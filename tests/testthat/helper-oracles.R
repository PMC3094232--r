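# small map constructors -----------------------------------------------------

toy_arm_lengths <- function(species, L) {
  arm_lengths(species, rep("2R", length(species)), L)
}

toy_map <- function(species, ids, pos, L = max(pos) + 1) {
  as_marker_map(
    tibble::tibble(species = species, arm = "2R", marker = ids,
                   homolog_group = ids, position_mb = pos,
                   source = "physical"),
    toy_arm_lengths(species, L))
}

# brute-force membership oracle for count_shared -----------------------------
# loops every homolog x region pair and applies the half-open convention
# directly; the outside region is "in no inversion"
oracle_count <- function(markers1, markers2, regions1, regions2) {
  shared <- intersect(markers1$homolog_group, markers2$homolog_group)
  in_region <- function(p, reg, inv) {
    if (reg$kind == "inversion") {
      p >= reg$start_mb && p < reg$end_mb
    } else {
      ok <- TRUE
      for (k in seq_len(nrow(inv))) {
        if (p >= inv$start_mb[k] && p < inv$end_mb[k]) ok <- FALSE
      }
      ok
    }
  }
  inv1 <- regions1[regions1$kind == "inversion", ]
  inv2 <- regions2[regions2$kind == "inversion", ]
  out <- expand.grid(i = seq_len(nrow(regions1)), j = seq_len(nrow(regions2)))
  out$O <- 0
  for (h in shared) {
    p1 <- markers1$position_mb[markers1$homolog_group == h]
    p2 <- markers2$position_mb[markers2$homolog_group == h]
    for (r in seq_len(nrow(out))) {
      if (in_region(p1, regions1[out$i[r], ], inv1) &&
          in_region(p2, regions2[out$j[r], ], inv2)) {
        out$O[r] <- out$O[r] + 1
      }
    }
  }
  out$region1 <- regions1$region_id[out$i]
  out$region2 <- regions2$region_id[out$j]
  out
}

# flat-loop recomputation of the sharing statistic ---------------------------
oracle_statistic <- function(markers1, markers2, regions1, regions2) {
  shared <- intersect(markers1$homolog_group, markers2$homolog_group)
  n <- length(shared)
  inv1 <- regions1[regions1$kind == "inversion", ]
  inv2 <- regions2[regions2$kind == "inversion", ]
  t_stat <- 0
  for (i in seq_len(nrow(inv1))) {
    for (j in seq_len(nrow(inv2))) {
      o <- 0
      for (h in shared) {
        p1 <- markers1$position_mb[markers1$homolog_group == h]
        p2 <- markers2$position_mb[markers2$homolog_group == h]
        if (p1 >= inv1$start_mb[i] && p1 < inv1$end_mb[i] &&
            p2 >= inv2$start_mb[j] && p2 < inv2$end_mb[j]) o <- o + 1
      }
      e <- n * inv1$f[i] * inv2$f[j]
      t_stat <- t_stat + (o - e)^2 / e
    }
  }
  t_stat
}

# brute-force maximal-colinear-run enumeration -------------------------------
# independent route: enumerate every interval of the shared A-order, test
# colinearity + distance conservation directly, keep the maximal ones, then
# apply the documented left-to-right tie-break
oracle_blocks <- function(map_a, map_b, rel_tol = 0.5) {
  shared <- intersect(map_a$homolog_group, map_b$homolog_group)
  pos_a <- map_a$position_mb[match(shared, map_a$homolog_group)]
  pos_b <- map_b$position_mb[match(shared, map_b$homolog_group)]
  o <- order(pos_a)
  shared <- shared[o]; pos_a <- pos_a[o]; pos_b <- pos_b[o]
  rb <- rank(pos_b)
  n <- length(shared)
  valid <- function(s, e) {
    d <- diff(rb[s:e])
    if (!(all(d == 1) || all(d == -1))) return(FALSE)
    if (is.finite(rel_tol)) {
      for (k in s:(e - 1)) {
        ga <- pos_a[k + 1] - pos_a[k]
        gb <- abs(pos_b[k + 1] - pos_b[k])
        if (abs(ga - gb) > rel_tol * max(ga, gb)) return(FALSE)
      }
    }
    TRUE
  }
  maximal <- list()
  if (n >= 2) {
    for (s in 1:(n - 1)) {
      for (e in (s + 1):n) {
        if (!valid(s, e)) next
        ext_l <- s > 1 && valid(s - 1, e)
        ext_r <- e < n && valid(s, e + 1)
        if (!ext_l && !ext_r) maximal[[length(maximal) + 1]] <- c(s, e)
      }
    }
  }
  if (length(maximal) == 0) return(list())
  maximal <- maximal[order(vapply(maximal, `[`, 0, 1))]
  res <- list()
  next_free <- 1
  for (iv in maximal) {
    s <- max(iv[1], next_free)
    if (iv[2] - s + 1 >= 2) {
      res[[length(res) + 1]] <- list(
        members = shared[s:iv[2]],
        orientation = if (rb[s + 1] - rb[s] > 0) "forward" else "reversed")
      next_free <- iv[2] + 1
    }
  }
  res
}

# unsigned breakpoint count between two gene orders --------------------------
oracle_breakpoints <- function(ord1, ord2) {
  pos2 <- match(ord1, ord2)
  sum(abs(diff(pos2)) != 1)
}

# random small instance for block-finder equivalence -------------------------
random_block_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:10, 1)
  ids <- sprintf("m%02d", seq_len(n))
  pos_a <- sort(runif(n, 0, 20))
  # B order: random permutation, positions random or mimicking A's gaps
  perm <- sample(n)
  pos_b <- sort(runif(n, 0, 20))
  L <- 25
  list(
    A = toy_map("A", ids, pos_a, L),
    B = toy_map("B", ids[perm], pos_b, L),
    rel_tol = sample(c(0.3, 0.5, 1, Inf), 1))
}
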