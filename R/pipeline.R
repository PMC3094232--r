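default_params <- function() {
  list(n_draws = 10000, burnin = 20000, samples = 20000, chains = 4,
       rel_tol = 0.5, rate_samples = 10000,
       prior_shape = 0.001, prior_rate = 0.001)
}

records_to_tbl <- function(x) {
  if (is.data.frame(x)) tibble::as_tibble(x)
  else dplyr::bind_rows(lapply(x, tibble::as_tibble))
}

#' Run the full arm-dynamics pipeline
#'
#' Orchestrates count construction, the sharing test, the Bayesian
#' intensity model with its connectivity ratio, the three-species block
#' classification, and the compound-Poisson disruption-rate comparison,
#' from a single configuration. Every stage derives its seed from the
#' top-level seed, and the report records all seeds and parameters so a
#' run is replayable from the report alone.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   * `seed`: integer master seed.
#'   * `arm_lengths`: records with `species`, `arm`, `length_mb`.
#'   * `markers`: path to a marker TSV (or an in-memory data frame).
#'   * `regions`: path to an inversion TSV (or a data frame); optional
#'     when only block analyses are requested.
#'   * `sharing_pairs`: list of `{species1, arm1, species2, arm2}` arm
#'     pairings to test for nonrandom sharing.
#'   * `block_triples`: list of `{label, ref, others, arms}` where `arms`
#'     maps each species to its homologous arm for that comparison.
#'   * `params`: overrides of `n_draws`, `burnin`, `samples`, `chains`,
#'     `rel_tol`, `rate_samples`, `prior_shape`, `prior_rate`.
#' @return An `armdyn_report` list with `sharing`, `intensity`,
#'   `connectivity`, `blocks`, `rates`, `rank` tibbles plus `config_used`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    # table paths in a config file are relative to the file itself
    for (el in c("arm_lengths", "markers", "regions")) {
      if (is.character(config[[el]]) && !file.exists(config[[el]])) {
        config[[el]] <- file.path(base, config[[el]])
      }
    }
  }
  seed <- as.integer(config$seed %||% 1L)
  params <- utils::modifyList(default_params(), config$params %||% list())
  al <- if (is.character(config$arm_lengths)) {
    readr::read_tsv(config$arm_lengths, col_types = "ccd")
  } else {
    records_to_tbl(config$arm_lengths)
  }
  al <- arm_lengths(al$species, al$arm, al$length_mb)
  markers <- if (is.character(config$markers)) {
    read_marker_table(config$markers, al)
  } else {
    as_marker_map(records_to_tbl(config$markers), al)
  }
  regions <- if (is.null(config$regions)) NULL
  else if (is.character(config$regions)) read_region_table(config$regions, al)
  else as_region_set(records_to_tbl(config$regions), al)

  pick_map <- function(sp, arm) {
    m <- markers[markers$species == sp & markers$arm == arm, ]
    if (nrow(m) == 0) stop("no markers for ", sp, " ", arm)
    m
  }

  sharing <- tibble::tibble()
  connectivity <- tibble::tibble()
  intensity <- list()
  fits <- list()
  for (k in seq_along(config$sharing_pairs %||% list())) {
    pr <- config$sharing_pairs[[k]]
    m1 <- pick_map(pr$species1, pr$arm1)
    m2 <- pick_map(pr$species2, pr$arm2)
    st <- sharing_test(m1, m2, regions, regions,
                       n_draws = params$n_draws, seed = seed + 100L + k)
    fit <- fit_intensity_model(
      count_shared(m1, m2, regions, regions),
      burnin = params$burnin, samples = params$samples,
      chains = params$chains, seed = seed + 200L + k)
    cr <- connectivity_ratio(fit)
    lab <- paste0(pr$species1, " ", pr$arm1, " / ",
                  pr$species2, " ", pr$arm2)
    sharing <- dplyr::bind_rows(sharing,
                                dplyr::mutate(glance(st), pair = lab,
                                              .before = 1))
    connectivity <- dplyr::bind_rows(connectivity,
                                     dplyr::mutate(cr, pair = lab,
                                                   .before = 1))
    intensity[[lab]] <- tidy(fit)
    fits[[lab]] <- fit
  }

  blocks <- tibble::tibble()
  rates <- tibble::tibble()
  summaries <- list()
  for (k in seq_along(config$block_triples %||% list())) {
    tr <- config$block_triples[[k]]
    sp <- c(tr$ref, unlist(tr$others))
    maps <- lapply(sp, function(s) pick_map(s, tr$arms[[s]]))
    b_ab <- find_pairwise_blocks(maps[[1]], maps[[2]], params$rel_tol)
    b_ac <- find_pairwise_blocks(maps[[1]], maps[[3]], params$rel_tol)
    b_bc <- find_pairwise_blocks(maps[[2]], maps[[3]], params$rel_tol)
    cl <- classify_blocks(b_ab, b_ac, b_bc)
    L <- maps[[1]]$arm_length_mb[1]
    st <- block_stats(cl, L)
    lab <- tr$label %||% tr$arms[[tr$ref]]
    blocks <- dplyr::bind_rows(blocks,
                               dplyr::mutate(st, arm = lab, .before = 1))
    lens <- function(set) {
      keep <- switch(set,
                     c = cl$class == "fully_conserved",
                     `c+d` = rep(TRUE, nrow(cl)))
      ref <- attr(cl, "ref_species")
      in_ref <- is.na(cl$pair) |
        vapply(strsplit(cl$pair, "-", fixed = TRUE),
               function(x) ref %in% x, NA)
      pmax(cl$length_ref[keep & in_ref], 1e-6)
    }
    fit_for <- function(set, off) {
      l <- lens(set)
      fit_block_process(length(l), l, L, label = paste0(lab, " (", set, ")"),
                        prior_shape = params$prior_shape,
                        prior_rate = params$prior_rate,
                        n_samples = params$rate_samples,
                        seed = seed + 300L + 10L * k + off)
    }
    fit_c <- fit_for("c", 1L)
    fit_cd <- fit_for("c+d", 2L)
    ds <- disruption_difference(fit_c, fit_cd, label = lab)
    summaries[[lab]] <- ds
    rates <- dplyr::bind_rows(
      rates,
      dplyr::mutate(dplyr::bind_rows(
        dplyr::mutate(tidy(fit_cd), set = "c+d"),
        dplyr::mutate(tidy(fit_c), set = "c"),
        dplyr::mutate(tidy(ds), set = "diff")), arm = lab, .before = 1))
  }
  rank <- if (length(summaries) >= 2) rank_disruption(summaries) else
    tibble::tibble()

  structure(list(sharing = sharing, intensity = intensity,
                 connectivity = connectivity, blocks = blocks,
                 rates = rates, rank = rank,
                 fits = fits, summaries = summaries,
                 config_used = list(seed = seed, params = params)),
            class = "armdyn_report")
}

#' Write a pipeline report as JSON
#'
#' Serialises the tabular parts of an [run_pipeline()] report (sharing
#' tests, intensity summaries, connectivity ratios, block statistics,
#' rates and rank probabilities) together with the seed and parameters.
#'
#' @param report An `armdyn_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "armdyn_report"))
  payload <- list(
    sharing = report$sharing,
    intensity = report$intensity,
    connectivity = report$connectivity,
    blocks = report$blocks,
    rates = report$rates,
    rank = report$rank,
    config = report$config_used)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.armdyn_report <- function(x, ...) {
  cat("armdyn pipeline report (seed ", x$config_used$seed, ")\n", sep = "")
  if (nrow(x$sharing)) { cat("\nSharing tests:\n"); print(x$sharing) }
  if (nrow(x$connectivity)) {
    cat("\nOutside/inside connectivity ratios:\n"); print(x$connectivity)
  }
  if (nrow(x$blocks)) { cat("\nBlock statistics:\n"); print(x$blocks) }
  if (nrow(x$rank)) { cat("\nDisruption rank probabilities:\n")
    print(x$rank) }
  invisible(x)
}
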