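#' Define a marker-sharing scenario
#'
#' Bundles the study conditions under which synthetic two-species marker
#' maps are generated: arm lengths, inversion layouts, the number of
#' homologous markers, and (optionally) planted sharing intensities for
#' chosen region pairs. With no planted intensities the generator emits the
#' null model in which homologs are placed uniformly and independently on
#' the two arms.
#'
#' @param arm_length1,arm_length2 Arm lengths in megabases.
#' @param inversions1,inversions2 Data frames with columns `region_id`,
#'   `start_mb`, `end_mb` (may overlap; may have zero rows).
#' @param n_homologs Number of homologous marker pairs to place.
#' @param gamma Optional data frame with columns `region1`, `region2`,
#'   `gamma` planting the sharing intensity of specific region pairs
#'   (`"outside"` is a valid region id); pairs not listed default to 1.
#' @param species Length-2 character vector of species names.
#' @param arms Length-2 character vector of arm names.
#' @param seed Integer seed recorded in the scenario.
#' @return A `sharing_scenario` list.
#' @export
sharing_scenario <- function(arm_length1, arm_length2,
                             inversions1, inversions2,
                             n_homologs,
                             gamma = NULL,
                             species = c("sp1", "sp2"),
                             arms = c("2R", "2R"),
                             seed = 1L) {
  if (n_homologs < 0) stop("n_homologs must be >= 0")
  if (!is.null(gamma)) {
    gamma <- tibble::as_tibble(gamma)
    if (any(gamma$gamma < 0)) stop("planted gamma must be >= 0")
  }
  structure(list(arm_length1 = arm_length1, arm_length2 = arm_length2,
                 inversions1 = tibble::as_tibble(inversions1),
                 inversions2 = tibble::as_tibble(inversions2),
                 n_homologs = as.integer(n_homologs), gamma = gamma,
                 species = species, arms = arms, seed = as.integer(seed)),
            class = "sharing_scenario")
}

# split [0, L) into atoms at inversion breakpoints; each atom knows which
# regions cover it (the aggregate outside region when no inversion does)
atomize_arm <- function(inversions, L) {
  cuts <- sort(unique(c(0, inversions$start_mb, inversions$end_mb, L)))
  cuts <- cuts[cuts >= 0 & cuts <= L]
  atoms <- tibble::tibble(start = head(cuts, -1), end = tail(cuts, -1))
  atoms <- atoms[atoms$end > atoms$start, ]
  atoms$regions <- purrr::map2(atoms$start, atoms$end, function(s, e) {
    cov <- inversions$region_id[inversions$start_mb <= s &
                                  inversions$end_mb >= e]
    if (length(cov) == 0) "outside" else cov
  })
  atoms$len <- atoms$end - atoms$start
  atoms
}

planted_gamma <- function(gamma_tbl, regions1, regions2) {
  if (is.null(gamma_tbl) || nrow(gamma_tbl) == 0) return(1)
  hit <- gamma_tbl[gamma_tbl$region1 %in% regions1 &
                     gamma_tbl$region2 %in% regions2, ]
  if (nrow(hit) == 0) 1 else max(hit$gamma)
}

#' Generate synthetic shared marker maps
#'
#' Places `n_homologs` homologous marker pairs on the two arms of a
#' [sharing_scenario()]. Each arm is atomised into disjoint sub-intervals
#' at inversion breakpoints; a homolog's (region-pair) location is drawn
#' from a categorical with weight proportional to
#' `len_a * len_b * gamma*(a, b)`, where a planted intensity on an
#' inversion applies to all its atoms and conflicts on shared atoms take
#' the maximum planted value. Positions are then uniform within the chosen
#' atoms, so with all intensities equal to 1 the marginal position law is
#' uniform on each arm.
#'
#' @param scenario A [sharing_scenario()].
#' @param seed Integer seed; defaults to the scenario's seed.
#' @return A list with elements `markers1`, `markers2` (marker maps),
#'   `regions1`, `regions2` (region sets), `homologs` (correspondence
#'   table) and `arm_len` (arm-length table).
#' @export
gen_shared_markers <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sharing_scenario"))
  set.seed(seed)
  sp <- scenario$species
  arms <- scenario$arms
  al <- arm_lengths(sp, arms, c(scenario$arm_length1, scenario$arm_length2))
  inv1 <- scenario$inversions1
  inv2 <- scenario$inversions2
  reg1 <- as_region_set(
    if (nrow(inv1)) dplyr::mutate(inv1, species = sp[1], arm = arms[1]) else inv1[0, ],
    al[1, ])
  reg2 <- as_region_set(
    if (nrow(inv2)) dplyr::mutate(inv2, species = sp[2], arm = arms[2]) else inv2[0, ],
    al[2, ])
  a1 <- atomize_arm(inv1, scenario$arm_length1)
  a2 <- atomize_arm(inv2, scenario$arm_length2)
  grid <- tidyr::expand_grid(i = seq_len(nrow(a1)), j = seq_len(nrow(a2)))
  grid$gamma <- purrr::map2_dbl(grid$i, grid$j, function(i, j) {
    planted_gamma(scenario$gamma, a1$regions[[i]], a2$regions[[j]])
  })
  grid$w <- a1$len[grid$i] * a2$len[grid$j] * grid$gamma
  if (sum(grid$w) <= 0) stop("all placement weights are zero")
  n <- scenario$n_homologs
  if (n > 0) {
    pick <- sample.int(nrow(grid), n, replace = TRUE, prob = grid$w)
    i <- grid$i[pick]; j <- grid$j[pick]
    pos1 <- runif(n, a1$start[i], a1$end[i])
    pos2 <- runif(n, a2$start[j], a2$end[j])
    hid <- sprintf("H%04d", seq_len(n))
    m1 <- tibble::tibble(species = sp[1], arm = arms[1],
                         marker = sprintf("S1M%04d", seq_len(n)),
                         homolog_group = hid, position_mb = pos1,
                         source = sample(c("physical", "in-silico"), n,
                                         replace = TRUE))
    m2 <- tibble::tibble(species = sp[2], arm = arms[2],
                         marker = sprintf("S2M%04d", seq_len(n)),
                         homolog_group = hid, position_mb = pos2,
                         source = sample(c("physical", "in-silico"), n,
                                         replace = TRUE))
  } else {
    m1 <- tibble::tibble(species = character(), arm = character(),
                         marker = character(), homolog_group = character(),
                         position_mb = numeric(), source = character())
    m2 <- m1
  }
  markers1 <- if (n > 0) as_marker_map(m1, al) else
    dplyr::mutate(m1, arm_length_mb = numeric())
  markers2 <- if (n > 0) as_marker_map(m2, al) else
    dplyr::mutate(m2, arm_length_mb = numeric())
  homologs <- if (n > 0) homolog_table(markers1, markers2) else
    tibble::tibble(homolog_group = character())
  list(markers1 = markers1, markers2 = markers2,
       regions1 = reg1, regions2 = reg2,
       homologs = homologs, arm_len = al)
}

# reverse the order of genes in positions i..j of an order vector
apply_reversal <- function(ord, i, j) {
  ord[i:j] <- ord[j:i]
  ord
}

sample_segment <- function(n, length_dist, geom_p) {
  if (length_dist == "uniform") {
    ij <- sort(sample.int(n, 2))
  } else {
    len <- 2 + stats::rgeom(1, geom_p)
    len <- min(len, n)
    start <- sample.int(n - len + 1, 1)
    ij <- c(start, start + len - 1)
  }
  ij
}

#' Generate three rearranged gene orders from a common ancestor
#'
#' Starts from an ancestral arm carrying `n_genes` genes in identity order
#' with equal unit spacing, and lets each of three lineages independently
#' accumulate a given number of segment reversals. Reversal segments are
#' drawn uniformly over all contiguous segments of length at least 2 (a
#' length-1 unsigned reversal is a no-op) or with truncated-geometric
#' lengths. Positions are re-assigned as permuted index times the unit
#' spacing, so gene content is conserved and only order changes.
#'
#' @param n_genes Number of genes on the ancestral arm.
#' @param reversals Integer vector (length 3) of per-lineage reversal
#'   counts.
#' @param length_dist `"uniform"` or `"geometric"` segment-length law.
#' @param geom_p Success probability of the truncated-geometric law.
#' @param spacing_mb Inter-gene spacing in megabases.
#' @param species Length-3 character vector of lineage names.
#' @param arm Arm label shared by the three maps.
#' @param seed Integer seed.
#' @return A named list of three ordered marker maps (tibbles in
#'   marker-map layout).
#' @export
gen_rearranged_orders <- function(n_genes, reversals,
                                  length_dist = c("uniform", "geometric"),
                                  geom_p = 0.3, spacing_mb = 1,
                                  species = c("spA", "spB", "spC"),
                                  arm = "2R", seed = 1L) {
  length_dist <- match.arg(length_dist)
  if (length(reversals) != 3 || any(reversals < 0)) {
    stop("reversals must be three non-negative counts")
  }
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  al <- arm_lengths(species, rep(arm, 3), rep(n_genes * spacing_mb, 3))
  maps <- purrr::map(seq_len(3), function(k) {
    ord <- seq_len(n_genes)
    if (n_genes >= 2) {
      for (r in seq_len(reversals[k])) {
        ij <- sample_segment(n_genes, length_dist, geom_p)
        ord <- apply_reversal(ord, ij[1], ij[2])
      }
    }
    tb <- tibble::tibble(
      species = species[k], arm = arm,
      marker = sprintf("G%04d", ord),
      homolog_group = sprintf("G%04d", ord),
      position_mb = (seq_len(n_genes) - 1) * spacing_mb,
      source = "in-silico")
    as_marker_map(tb, al)
  })
  setNames(maps, species)
}

#' Draw synthetic conserved-block counts and lengths
#'
#' Samples from the compound Poisson process used for disruption-rate
#' inference: the block count is `Poisson(lambda * L)` and each block's
#' arm-scaled length `b / L` is `Exponential(rate = gamma)`, so the mean
#' block length is `L / gamma`.
#'
#' @param lambda Block count rate per megabase (> 0).
#' @param gamma Per-unit-length rate of the block-length process (> 0).
#' @param L Arm length in megabases (> 0).
#' @param seed Optional integer seed.
#' @return A list with `count` and `lengths_mb`.
#' @export
gen_block_lengths <- function(lambda, gamma, L, seed = NULL) {
  if (lambda <= 0 || gamma <= 0 || L <= 0) {
    stop("lambda, gamma and L must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  count <- rpois(1, lambda * L)
  lengths <- L * rexp(count, rate = gamma)
  list(count = count, lengths_mb = lengths)
}

#' Study-condition sharing scenario
#'
#' A ready-made [sharing_scenario()] emulating the comparative-mapping
#' study conditions: a ~61.5-Mb arm carrying five polymorphic inversions
#' (sizes 4-12.5 Mb, two of them overlapping, mirroring the nested 2R
#' inversion systems) against a ~55-Mb arm with four inversions, and a
#' homolog count in the 87-230 range typical of physically plus in-silico
#' mapped markers shared by a species pair.
#'
#' @param n_homologs Homologous marker pairs (default 230).
#' @param gamma Optional planted intensities (see [sharing_scenario()]).
#' @param seed Integer seed.
#' @return A `sharing_scenario`.
#' @export
study_sharing_scenario <- function(n_homologs = 230, gamma = NULL,
                                   seed = 1L) {
  inv1 <- tibble::tibble(
    region_id = c("j", "b", "d", "c", "u"),
    start_mb = c(2.0, 18.0, 24.0, 26.8, 31.8),
    end_mb = c(14.5, 26.2, 30.0, 31.5, 35.8))
  inv2 <- tibble::tibble(
    region_id = c("e", "f", "g", "h"),
    start_mb = c(4.0, 14.0, 25.0, 38.0),
    end_mb = c(10.0, 20.0, 32.0, 42.3))
  sharing_scenario(61.5, 55.0, inv1, inv2, n_homologs = n_homologs,
                   gamma = gamma,
                   species = c("gambiae_like", "stephensi_like"),
                   seed = seed)
}

#' Materialise the standard synthetic fixture set
#'
#' Writes the small synthetic dataset used by the test suite and the
#' worked examples: marker and inversion tables for a two-species sharing
#' comparison (from [study_sharing_scenario()]), three-lineage rearranged
#' gene orders for the block analyses, an arm-length table, and a pipeline
#' configuration referencing them. All outputs are plain TSV/YAML.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_homologs Homolog count for the sharing pair.
#' @param n_genes Gene count for the three-lineage rearrangement trio.
#' @param reversals Per-lineage reversal counts for the trio.
#' @return The directory path, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L, n_homologs = 230,
                           n_genes = 87, reversals = c(12, 12, 12)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- study_sharing_scenario(n_homologs = n_homologs, seed = seed)
  d <- gen_shared_markers(sc)
  trio <- gen_rearranged_orders(n_genes, reversals, spacing_mb = 0.7,
                                seed = seed + 1L)
  al <- dplyr::bind_rows(
    d$arm_len,
    arm_lengths(names(trio), "2R", rep(n_genes * 0.7, 3)))
  markers <- dplyr::bind_rows(c(list(d$markers1, d$markers2), unname(trio)))
  readr::write_tsv(al, file.path(dir, "synthetic_arm_lengths.tsv"))
  write_marker_table(markers, file.path(dir, "synthetic_markers.tsv"))
  write_region_table(dplyr::bind_rows(d$regions1, d$regions2),
                     file.path(dir, "synthetic_inversions.tsv"))
  config <- list(
    seed = as.integer(seed),
    arm_lengths = "synthetic_arm_lengths.tsv",
    markers = "synthetic_markers.tsv",
    regions = "synthetic_inversions.tsv",
    sharing_pairs = list(list(species1 = "gambiae_like", arm1 = "2R",
                              species2 = "stephensi_like", arm2 = "2R")),
    block_triples = list(list(label = "2R", ref = "spA",
                              others = list("spB", "spC"),
                              arms = list(spA = "2R", spB = "2R",
                                          spC = "2R"))))
  yaml::write_yaml(config, file.path(dir, "synthetic_config.yaml"))
  invisible(dir)
}
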