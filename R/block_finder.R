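empty_blocks <- function() {
  tibble::tibble(block_id = integer(), orientation = character(),
                 n_markers = integer(), members = list(),
                 start_a = numeric(), end_a = numeric(),
                 length_a = numeric(), start_b = numeric(),
                 end_b = numeric(), length_b = numeric())
}

# adjacency test between consecutive shared markers k and k+1 (A order):
# no intervening shared marker on either arm (rank difference of 1 in B),
# and the distance-conservation criterion on the adjacent gap pair
adjacent_ok <- function(rank_b, pos_a, pos_b, k, rel_tol) {
  dr <- rank_b[k + 1] - rank_b[k]
  if (abs(dr) != 1) return(0L)
  if (is.finite(rel_tol)) {
    g_a <- pos_a[k + 1] - pos_a[k]
    g_b <- abs(pos_b[k + 1] - pos_b[k])
    if (abs(g_a - g_b) > rel_tol * max(g_a, g_b)) return(0L)
  }
  as.integer(dr)
}

#' Find conserved gene blocks between two species
#'
#' Identifies maximal runs of at least two shared homologs that are
#' consecutive among shared homologs on both arms (no intervening shared
#' marker on either side), colinear in identical or fully reversed order,
#' and distance-conserved: every adjacent gap pair satisfies
#' `|g_A - g_B| <= rel_tol * max(g_A, g_B)`. A truly maximal forward run
#' and reversed run can share a boundary marker; ties are broken
#' left-to-right so that blocks never overlap in marker membership (the
#' earlier-starting block keeps the marker).
#'
#' @param map_a,map_b Ordered marker maps (one arm each) sharing homolog
#'   groups.
#' @param rel_tol Relative gap tolerance in `[0, Inf]`; `Inf` disables the
#'   distance criterion (pure colinearity).
#' @return A tibble of blocks (`block_id`, `orientation`, `n_markers`,
#'   `members` list-column in species-A order, spans per species), with the
#'   shared-marker table attached as attribute `"shared"` and the species
#'   labels as `"species_a"`/`"species_b"`. Fewer than two shared homologs
#'   give a zero-row result.
#' @export
find_pairwise_blocks <- function(map_a, map_b, rel_tol = 0.5) {
  if (rel_tol < 0) stop("rel_tol must be >= 0")
  ka <- single_arm(map_a, "map_a")
  kb <- single_arm(map_b, "map_b")
  shared_ids <- intersect(map_a$homolog_group, map_b$homolog_group)
  shared <- tibble::tibble(
    homolog_group = shared_ids,
    pos_a = map_a$position_mb[match(shared_ids, map_a$homolog_group)],
    pos_b = map_b$position_mb[match(shared_ids, map_b$homolog_group)])
  shared <- dplyr::arrange(shared, .data$pos_a)
  shared$rank_b <- rank(shared$pos_b)
  out <- empty_blocks()
  n <- nrow(shared)
  if (n >= 2) {
    dirs <- vapply(seq_len(n - 1), function(k) {
      adjacent_ok(shared$rank_b, shared$pos_a, shared$pos_b, k, rel_tol)
    }, 0L)
    blocks <- list()
    s <- 1L  # adjacency index: dirs[k] connects markers k and k + 1
    while (s <= n - 1L) {
      if (dirs[s] == 0L) { s <- s + 1L; next }
      d <- dirs[s]
      e <- s
      while (e + 1L <= n - 1L && dirs[e + 1L] == d) e <- e + 1L
      # block spans markers s..(e+1); the boundary marker e+1 is consumed
      # here (left-to-right tie-break), so the next block starts at e+2
      blocks[[length(blocks) + 1L]] <- list(s = s, e = e + 1L, dir = d)
      s <- e + 2L
    }
    if (length(blocks) > 0) {
      out <- purrr::map_dfr(seq_along(blocks), function(b) {
        bl <- blocks[[b]]
        idx <- bl$s:bl$e
        tibble::tibble(
          block_id = b,
          orientation = if (bl$dir > 0) "forward" else "reversed",
          n_markers = length(idx),
          members = list(shared$homolog_group[idx]),
          start_a = min(shared$pos_a[idx]), end_a = max(shared$pos_a[idx]),
          length_a = max(shared$pos_a[idx]) - min(shared$pos_a[idx]),
          start_b = min(shared$pos_b[idx]), end_b = max(shared$pos_b[idx]),
          length_b = max(shared$pos_b[idx]) - min(shared$pos_b[idx]))
      })
    }
  }
  structure(out,
            shared = shared,
            species_a = ka$species, arm_a = ka$arm,
            species_b = kb$species, arm_b = kb$arm,
            class = c("synteny_blocks", class(out)))
}

# block id containing each marker of `universe` (NA when in none)
block_of <- function(universe, blocks) {
  id <- rep(NA_integer_, length(universe))
  for (b in seq_len(nrow(blocks))) {
    id[universe %in% blocks$members[[b]]] <- blocks$block_id[b]
  }
  id
}

maximal_runs <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  purrr::map(idx, function(k) starts[k]:ends[k])
}

#' Classify blocks as fully or partially conserved across three species
#'
#' Takes the three pairwise block sets over a common homolog universe and
#' identifies (i) fully conserved blocks — maximal runs of at least two
#' markers contained in one block of every pairwise comparison — and (ii)
#' partially conserved blocks — the remainders (>= 2 markers) of pairwise
#' blocks after fully conserved runs are removed, labelled with the
#' species pair in which they survive. Spans are reported on the reference
#' species (species A of the A/B comparison).
#'
#' @param blocks_ab,blocks_ac,blocks_bc Outputs of
#'   [find_pairwise_blocks()] for species pairs A/B, A/C and B/C over the
#'   same homolog universe.
#' @return A tibble with columns `class` (`"fully_conserved"` or
#'   `"partial"`), `pair`, `members`, `n_markers`, `start_ref`, `end_ref`,
#'   `length_ref`; reference species recorded in attribute
#'   `"ref_species"`.
#' @export
classify_blocks <- function(blocks_ab, blocks_ac, blocks_bc) {
  sh_ab <- attr(blocks_ab, "shared")
  sh_ac <- attr(blocks_ac, "shared")
  sh_bc <- attr(blocks_bc, "shared")
  u <- sort(sh_ab$homolog_group)
  if (!identical(u, sort(sh_ac$homolog_group)) ||
      !identical(u, sort(sh_bc$homolog_group))) {
    stop("inconsistent homolog universes across the three block sets")
  }
  ord <- sh_ab  # species-A order with reference positions
  ids <- list(ab = block_of(ord$homolog_group, blocks_ab),
              ac = block_of(ord$homolog_group, blocks_ac),
              bc = block_of(ord$homolog_group, blocks_bc))
  pair_labels <- c(
    ab = paste(attr(blocks_ab, "species_a"), attr(blocks_ab, "species_b"),
               sep = "-"),
    ac = paste(attr(blocks_ac, "species_a"), attr(blocks_ac, "species_b"),
               sep = "-"),
    bc = paste(attr(blocks_bc, "species_a"), attr(blocks_bc, "species_b"),
               sep = "-"))
  n <- nrow(ord)
  triple <- paste(ids$ab, ids$ac, ids$bc)
  all_in <- !is.na(ids$ab) & !is.na(ids$ac) & !is.na(ids$bc)
  # maximal runs of consecutive reference-order markers sharing one block
  # in every pairwise comparison
  same_as_prev <- c(FALSE, all_in[-1] & all_in[-n] &
                      triple[-1] == triple[-n])
  run_id <- cumsum(!same_as_prev)
  full_runs <- split(seq_len(n), run_id)
  full_runs <- full_runs[vapply(full_runs, length, 0L) >= 2 &
                           vapply(full_runs, function(i) all_in[i[1]], NA)]
  fully_markers <- unlist(lapply(full_runs, function(i) ord$homolog_group[i]))
  mk_row <- function(markers, class, pair) {
    pos <- ord$pos_a[match(markers, ord$homolog_group)]
    tibble::tibble(class = class, pair = pair, members = list(markers),
                   n_markers = length(markers),
                   start_ref = min(pos), end_ref = max(pos),
                   length_ref = max(pos) - min(pos))
  }
  full_tbl <- purrr::map_dfr(full_runs, function(i) {
    mk_row(ord$homolog_group[i], "fully_conserved", NA_character_)
  })
  partial_tbl <- purrr::map_dfr(c("ab", "ac", "bc"), function(p) {
    blocks <- switch(p, ab = blocks_ab, ac = blocks_ac, bc = blocks_bc)
    purrr::map_dfr(seq_len(nrow(blocks)), function(b) {
      mem <- blocks$members[[b]]
      keep <- !(mem %in% fully_markers)
      runs <- maximal_runs(keep)
      runs <- runs[vapply(runs, length, 0L) >= 2]
      purrr::map_dfr(runs, function(i) {
        mk_row(mem[i], "partial", unname(pair_labels[p]))
      })
    })
  })
  out <- dplyr::bind_rows(full_tbl, partial_tbl)
  if (nrow(out) > 0) out <- dplyr::arrange(out, .data$start_ref)
  structure(out,
            ref_species = attr(blocks_ab, "species_a"),
            pair_labels = unname(pair_labels),
            class = c("classified_blocks", class(out)))
}

#' Summary statistics of conserved blocks on a reference arm
#'
#' Counts and length statistics for the fully conserved block set (`c`),
#' the partially conserved set (`d`), and their union (`c+d`), measured on
#' the reference species' span. Partially conserved blocks are counted
#' only for pairs involving the reference species (blocks conserved in the
#' two non-reference species alone carry no reference span comparable to
#' the others).
#'
#' @param classified Output of [classify_blocks()].
#' @param L Reference arm length in megabases (used downstream by the rate
#'   model; recorded in the output).
#' @return A tibble with one row per block set: `set`, `n_blocks`,
#'   `total_length_mb`, `mean_length_mb`, `arm_length_mb`.
#' @export
block_stats <- function(classified, L) {
  ref <- attr(classified, "ref_species")
  keep_pair <- is.na(classified$pair) |
    vapply(strsplit(classified$pair, "-", fixed = TRUE),
           function(x) ref %in% x, NA)
  cl <- classified[keep_pair, ]
  sets <- list(
    c = cl[cl$class == "fully_conserved", ],
    d = cl[cl$class == "partial", ],
    `c+d` = cl)
  purrr::map_dfr(names(sets), function(s) {
    b <- sets[[s]]
    tibble::tibble(set = s, n_blocks = nrow(b),
                   total_length_mb = sum(b$length_ref),
                   mean_length_mb = if (nrow(b) > 0)
                     mean(b$length_ref) else NA_real_,
                   arm_length_mb = L)
  })
}
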