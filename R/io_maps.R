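#' Arm length lookup table
#'
#' Helper for building the arm-length table consumed by the readers. Physical
#' maps give marker positions in megabases along a chromosome arm; the total
#' arm length bounds positions and defines the fractional lengths of
#' inversion regions.
#'
#' @param species Character vector of species identifiers.
#' @param arm Character vector of arm identifiers (recycled against
#'   `species`), e.g. `"2R"`, `"2L"`, `"3R"`, `"3L"`, `"X"`.
#' @param length_mb Numeric vector of arm lengths in megabases.
#' @return A tibble with columns `species`, `arm`, `length_mb`.
#' @examples
#' arm_lengths("An_gambiae", c("2R", "2L"), c(61.5, 49.4))
#' @export
arm_lengths <- function(species, arm, length_mb) {
  out <- tibble::tibble(species = as.character(species),
                        arm = as.character(arm),
                        length_mb = as.numeric(length_mb))
  if (any(out$length_mb <= 0)) stop("arm lengths must be positive")
  if (anyDuplicated(out[c("species", "arm")]) > 0) {
    stop("duplicate (species, arm) in arm length table")
  }
  out
}

marker_cols <- c("species", "arm", "marker", "homolog_group",
                 "position_mb", "source")

#' Validate a marker map
#'
#' Checks the invariants of an ordered marker map: positions within
#' `[0, arm_length]`, unique marker ids within each (species, arm), and at
#' most one marker per homolog group per species (single-copy assumption).
#' Rows are returned sorted by species, arm and position.
#'
#' @param markers Data frame with columns `species`, `arm`, `marker`,
#'   `homolog_group`, `position_mb`, `source` (`"physical"` or
#'   `"in-silico"`).
#' @param arm_len Arm-length table from [arm_lengths()].
#' @return A validated tibble with an additional `arm_length_mb` column.
#' @export
as_marker_map <- function(markers, arm_len) {
  markers <- tibble::as_tibble(markers)
  missing <- setdiff(marker_cols, names(markers))
  if (length(missing) > 0) {
    stop("marker table lacks column(s): ", paste(missing, collapse = ", "))
  }
  markers$position_mb <- as.numeric(markers$position_mb)
  bad_src <- !markers$source %in% c("physical", "in-silico")
  if (any(bad_src)) {
    stop("unknown marker source at row ", which(bad_src)[1])
  }
  markers <- dplyr::left_join(markers, arm_len, by = c("species", "arm"))
  if (anyNA(markers$length_mb)) {
    i <- which(is.na(markers$length_mb))[1]
    stop("unknown arm at row ", i, ": ",
         markers$species[i], " ", markers$arm[i])
  }
  out_of_range <- markers$position_mb < 0 |
    markers$position_mb > markers$length_mb
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("position ", markers$position_mb[i], " outside [0, ",
         markers$length_mb[i], "] at row ", i)
  }
  dup_m <- duplicated(markers[c("species", "arm", "marker")])
  if (any(dup_m)) {
    stop("duplicate marker id at row ", which(dup_m)[1])
  }
  dup_h <- duplicated(markers[c("species", "homolog_group")])
  if (any(dup_h)) {
    stop("duplicate (species, homolog_group) at row ", which(dup_h)[1],
         ": single-copy assumption violated")
  }
  markers <- dplyr::rename(markers, arm_length_mb = "length_mb")
  dplyr::arrange(markers, .data$species, .data$arm, .data$position_mb)
}

#' Read a marker map table
#'
#' Reads a tab-separated table of physically and in-silico mapped DNA
#' markers (one row per marker placement) and validates it against
#' [as_marker_map()] invariants. Parsing is order-independent; output is
#' sorted by position within each arm.
#'
#' @param path Path to a UTF-8 TSV file with header columns `species`,
#'   `arm`, `marker`, `homolog_group`, `position_mb`, `source`.
#' @param arm_len Arm-length table from [arm_lengths()].
#' @return A marker-map tibble (see [as_marker_map()]).
#' @export
read_marker_table <- function(path, arm_len) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    arm = readr::col_character(),
    marker = readr::col_character(),
    homolog_group = readr::col_character(),
    position_mb = readr::col_double(),
    source = readr::col_character()
  ))
  as_marker_map(raw, arm_len)
}

#' Write a marker map table
#'
#' Emits the same TSV dialect [read_marker_table()] consumes; positions are
#' written with fixed 4-decimal formatting so write/read round-trips are
#' exact at that precision.
#'
#' @param markers Marker-map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  out <- markers[marker_cols]
  out$position_mb <- sprintf("%.4f", out$position_mb)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Build an arm region set from inversion intervals
#'
#' Given the inversion intervals on each arm, synthesises the aggregate
#' "outside" region (the complement of the union of inversions, represented
#' as a single region whose length is `L` minus the union length) and
#' computes fractional lengths `f`. Inversions may overlap (e.g. the nested
#' 2R inversion systems), so the fractions need not sum to one.
#'
#' @param inversions Data frame with columns `species`, `arm`, `region_id`,
#'   `start_mb`, `end_mb`; may have zero rows.
#' @param arm_len Arm-length table from [arm_lengths()]; every arm listed
#'   here receives an outside region even when it carries no inversion.
#' @return A tibble with columns `species`, `arm`, `region_id`, `kind`
#'   (`"inversion"` or `"outside"`), `start_mb`, `end_mb`, `length_mb`, `f`,
#'   `arm_length_mb`. The outside region has `NA` coordinates (it is an
#'   aggregate, not an interval).
#' @export
as_region_set <- function(inversions, arm_len) {
  inversions <- tibble::as_tibble(inversions)
  if (nrow(inversions) > 0) {
    need <- c("species", "arm", "region_id", "start_mb", "end_mb")
    missing <- setdiff(need, names(inversions))
    if (length(missing) > 0) {
      stop("region table lacks column(s): ", paste(missing, collapse = ", "))
    }
    inversions <- dplyr::left_join(inversions, arm_len,
                                   by = c("species", "arm"))
    if (anyNA(inversions$length_mb)) {
      i <- which(is.na(inversions$length_mb))[1]
      stop("unknown arm at row ", i, ": ",
           inversions$species[i], " ", inversions$arm[i])
    }
    bad <- inversions$start_mb >= inversions$end_mb
    if (any(bad)) {
      stop("start >= end at row ", which(bad)[1])
    }
    bad <- inversions$start_mb < 0 | inversions$end_mb > inversions$length_mb
    if (any(bad)) {
      stop("region outside [0, L] at row ", which(bad)[1])
    }
    if (anyDuplicated(inversions[c("species", "arm", "region_id")]) > 0) {
      stop("duplicate region_id within an arm")
    }
    inv <- dplyr::mutate(inversions,
                         kind = "inversion",
                         region_length = .data$end_mb - .data$start_mb)
  } else {
    inv <- tibble::tibble(species = character(), arm = character(),
                          region_id = character(), start_mb = numeric(),
                          end_mb = numeric(), length_mb = numeric(),
                          kind = character(), region_length = numeric())
  }
  outside <- dplyr::mutate(
    arm_len,
    region_id = "outside", kind = "outside",
    start_mb = NA_real_, end_mb = NA_real_)
  outside$region_length <- purrr::map_dbl(seq_len(nrow(outside)), function(k) {
    sub <- inv[inv$species == outside$species[k] & inv$arm == outside$arm[k], ]
    outside$length_mb[k] - interval_union_length(sub$start_mb, sub$end_mb)
  })
  out <- dplyr::bind_rows(inv, outside)
  out <- dplyr::mutate(out,
                       f = .data$region_length / .data$length_mb,
                       arm_length_mb = .data$length_mb)
  out <- dplyr::select(out, "species", "arm", "region_id", "kind",
                       "start_mb", "end_mb",
                       length_mb = "region_length", "f", "arm_length_mb")
  dplyr::arrange(out, .data$species, .data$arm,
                 .data$kind, .data$start_mb)
}

# total length of the union of half-open intervals [start, end)
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= cur_e) {
      cur_e <- max(cur_e, end[k])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[k]; cur_e <- end[k]
    }
  }
  total + (cur_e - cur_s)
}

#' Read an inversion region table
#'
#' Reads a BED-like TSV of polymorphic inversion coordinates and returns a
#' full region set with the synthesised outside region per arm (see
#' [as_region_set()]).
#'
#' @param path TSV with header columns `species`, `arm`, `region_id`,
#'   `start_mb`, `end_mb`.
#' @inheritParams as_region_set
#' @return Region-set tibble.
#' @export
read_region_table <- function(path, arm_len) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    arm = readr::col_character(),
    region_id = readr::col_character(),
    start_mb = readr::col_double(),
    end_mb = readr::col_double()
  ))
  as_region_set(raw, arm_len)
}

#' Write an inversion region table
#'
#' Writes the inversion rows of a region set in the dialect
#' [read_region_table()] consumes (the synthesised outside region is not
#' written; it is rebuilt on read). Coordinates use fixed 4-decimal
#' formatting.
#'
#' @param regions Region-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  inv <- regions[regions$kind == "inversion",
                 c("species", "arm", "region_id", "start_mb", "end_mb")]
  inv$start_mb <- sprintf("%.4f", inv$start_mb)
  inv$end_mb <- sprintf("%.4f", inv$end_mb)
  readr::write_tsv(inv, path)
  invisible(path)
}

#' Homolog correspondence table
#'
#' Pivots one or more marker maps into one row per homolog group with the
#' marker id carried by each species (`NA` where a species lacks the
#' homolog).
#'
#' @param ... Marker-map tibbles (or one combined tibble).
#' @return A tibble with column `homolog_group` plus one marker-id column
#'   per species.
#' @export
homolog_table <- function(...) {
  all <- dplyr::bind_rows(...)
  tidyr::pivot_wider(all[c("homolog_group", "species", "marker")],
                     names_from = "species", values_from = "marker")
}

# membership of positions in one region row, honouring the half-open
# [start, end) convention; the aggregate outside region is "in no inversion"
region_membership <- function(pos, region_row, inversions) {
  if (region_row$kind == "inversion") {
    pos >= region_row$start_mb & pos < region_row$end_mb
  } else {
    inside_any <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(inversions))) {
      inside_any <- inside_any |
        (pos >= inversions$start_mb[k] & pos < inversions$end_mb[k])
    }
    !inside_any
  }
}

single_arm <- function(markers, what) {
  key <- unique(markers[c("species", "arm")])
  if (nrow(key) != 1) {
    stop(what, " must cover exactly one (species, arm); got ", nrow(key))
  }
  key
}

#' Count homolog pairs shared between region pairs of two species
#'
#' For two homologous arms of two species, counts for every region pair
#' (i on arm 1, j on arm 2) the number of homolog groups whose species-1
#' marker lies in region i and whose species-2 marker lies in region j.
#' Membership uses the half-open `[start, end)` convention; a marker inside
#' two overlapping inversions counts in each, so overlapping layouts carry
#' no sum constraint.
#'
#' @param markers1,markers2 Marker maps restricted to one arm each.
#' @param regions1,regions2 Region sets for the same arms (including the
#'   outside region).
#' @param homologs Optional homolog universe (character vector of
#'   `homolog_group` ids); defaults to the groups present in both maps.
#' @return A `shared_counts` tibble with one row per region pair: columns
#'   `region1`, `kind1`, `f1`, `region2`, `kind2`, `f2`, `O`; attributes
#'   `species1`, `arm1`, `species2`, `arm2`, `n_homologs`,
#'   `arm_length1`, `arm_length2`.
#' @export
count_shared <- function(markers1, markers2, regions1, regions2,
                         homologs = NULL) {
  k1 <- single_arm(markers1, "markers1")
  k2 <- single_arm(markers2, "markers2")
  r1 <- regions1[regions1$species == k1$species & regions1$arm == k1$arm, ]
  r2 <- regions2[regions2$species == k2$species & regions2$arm == k2$arm, ]
  if (nrow(r1) == 0 || nrow(r2) == 0) {
    stop("no regions found for the marker arms")
  }
  shared <- intersect(markers1$homolog_group, markers2$homolog_group)
  if (!is.null(homologs)) shared <- intersect(shared, homologs)
  n <- length(shared)
  if (n == 0) stop("no shared homologs on arm pair")
  pos1 <- markers1$position_mb[match(shared, markers1$homolog_group)]
  pos2 <- markers2$position_mb[match(shared, markers2$homolog_group)]
  inv1 <- r1[r1$kind == "inversion", ]
  inv2 <- r2[r2$kind == "inversion", ]
  m1 <- vapply(seq_len(nrow(r1)),
               function(i) region_membership(pos1, r1[i, ], inv1),
               logical(n))
  m2 <- vapply(seq_len(nrow(r2)),
               function(j) region_membership(pos2, r2[j, ], inv2),
               logical(n))
  m1 <- matrix(m1, nrow = n)
  m2 <- matrix(m2, nrow = n)
  grid <- tidyr::expand_grid(i = seq_len(nrow(r1)), j = seq_len(nrow(r2)))
  out <- tibble::tibble(
    region1 = r1$region_id[grid$i], kind1 = r1$kind[grid$i],
    f1 = r1$f[grid$i],
    region2 = r2$region_id[grid$j], kind2 = r2$kind[grid$j],
    f2 = r2$f[grid$j],
    O = purrr::map2_dbl(grid$i, grid$j,
                        function(i, j) sum(m1[, i] & m2[, j]))
  )
  structure(out,
            class = c("shared_counts", class(out)),
            species1 = k1$species, arm1 = k1$arm,
            species2 = k2$species, arm2 = k2$arm,
            n_homologs = n,
            arm_length1 = r1$arm_length_mb[1],
            arm_length2 = r2$arm_length_mb[1])
}
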