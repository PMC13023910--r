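#' Define a toxicant panel
#'
#' A panel is the set of target toxicants together with the maximum (stock)
#' concentration assigned to each, in ppm. The maximum concentration is the
#' dose at which the biosensor is expected to respond with comparable
#' magnitude across toxicants, and it anchors the equivalent-concentration
#' (EC) scale: EC 10 of a setup corresponds to each component at its
#' volume-fraction share of its maximum.
#'
#' @param name Character vector of unique toxicant names.
#' @param c_max Positive numeric vector of maximum concentrations (ppm).
#' @return A tibble with columns `name` and `c_max`.
#' @examples
#' toxicant_panel(c("formaldehyde", "copper"), c(200, 100))
#' @export
toxicant_panel <- function(name, c_max) {
  if (length(name) < 1) {
    abort("a panel needs at least one toxicant")
  }
  if (anyDuplicated(name)) {
    abort("toxicant names must be unique within a panel")
  }
  if (length(c_max) != length(name) || any(!is.finite(c_max)) || any(c_max <= 0)) {
    abort("`c_max` must be finite, positive and match `name` in length")
  }
  tibble(name = as.character(name), c_max = as.numeric(c_max))
}

#' Default four-toxicant panel
#'
#' Formaldehyde (200 ppm), tetracycline (5 ppm), silver (as silver nitrate,
#' 100 ppm) and copper (as copper sulfate, 100 ppm): two organic and two
#' heavy-metal stressors with maximum concentrations chosen so that the
#' sensor responds with similar magnitude at EC 10.
#'
#' @return A panel tibble (see [toxicant_panel()]).
#' @export
default_panel <- function() {
  toxicant_panel(
    name  = c("formaldehyde", "tetracycline", "silver", "copper"),
    c_max = c(200, 5, 100, 100)
  )
}

#' Default volume-ratio sets per mixture order
#'
#' Binary mixtures are run at volume ratios 1:1, 2:1 and 1:2; ternary at
#' 1:1:1, 2:1:1, 1:2:1 and 1:1:2; quaternary at 1:1:1:1 plus the four
#' single-component double-ups. Singles always use the trivial ratio.
#'
#' @return A named list mapping mixture order (as character) to a list of
#'   integer ratio vectors.
#' @export
default_ratio_sets <- function() {
  list(
    `1` = list(c(1L)),
    `2` = list(c(1L, 1L), c(2L, 1L), c(1L, 2L)),
    `3` = list(c(1L, 1L, 1L), c(2L, 1L, 1L), c(1L, 2L, 1L), c(1L, 1L, 2L)),
    `4` = list(
      c(1L, 1L, 1L, 1L), c(2L, 1L, 1L, 1L), c(1L, 2L, 1L, 1L),
      c(1L, 1L, 2L, 1L), c(1L, 1L, 1L, 2L)
    )
  )
}

setup_id_for <- function(components, ratio) {
  paste0(paste(components, collapse = "+"), ":", paste(ratio, collapse = ":"))
}

#' Enumerate the full exposure design
#'
#' Builds every exposure setup for a panel: all single-toxicant exposures,
#' then every k-component combination crossed with the configured volume
#' ratios for that mixture order. With the default four-toxicant panel and
#' ratio sets this yields 4 singles, 18 binary, 16 ternary and 5 quaternary
#' setups (43 in total). Ordering is deterministic: by mixture order, then
#' lexicographically by component tuple, then by ratio tuple.
#'
#' @param panel A panel tibble from [toxicant_panel()].
#' @param ratio_sets Named list of ratio vectors per mixture order, as
#'   returned by [default_ratio_sets()]. Orders absent from the list are
#'   skipped (except order 1, which always uses the trivial ratio).
#' @return A tibble with columns `setup_id`, `n_components`, `components`
#'   (list of character vectors) and `ratio` (list of integer vectors).
#' @examples
#' nrow(enumerate_setups(default_panel())) # 43
#' @export
enumerate_setups <- function(panel, ratio_sets = default_ratio_sets()) {
  stopifnot(is.data.frame(panel), all(c("name", "c_max") %in% names(panel)))
  if (nrow(panel) < 1) abort("panel must contain at least one toxicant")
  if (anyDuplicated(panel$name)) abort("duplicate toxicant names in panel")

  nm <- sort(panel$name)
  out <- list()
  for (k in seq_len(nrow(panel))) {
    sets <- if (k == 1) {
      list(c(1L))
    } else {
      rs <- ratio_sets[[as.character(k)]]
      if (is.null(rs)) next
      # deterministic ratio order: lexicographic on the ratio tuple
      rs[order(vapply(rs, paste, character(1), collapse = ","))]
    }
    combs <- utils::combn(nm, k, simplify = FALSE)
    for (cc in combs) {
      for (r in sets) {
        if (length(r) != k || any(r <= 0) || any(r != as.integer(r))) {
          abort("volume ratios must be positive integers matching the component count")
        }
        out[[length(out) + 1L]] <- tibble(
          setup_id = setup_id_for(cc, r),
          n_components = k,
          components = list(cc),
          ratio = list(as.integer(r))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Expand a design into a per-sample manifest
#'
#' Crosses every setup with the equivalent-concentration (EC) gradient and
#' the replicate count, and resolves per-component concentrations in ppm.
#' The concentration rule assumes equal-strength stock mixing: component j
#' with volume ratio weight v_j receives
#' `c_max_j * (v_j / sum(v)) * (ec / 10)` ppm, so the summed toxic units
#' (ppm / c_max) of any manifest row equal `ec / 10`.
#'
#' @param setups Setup tibble from [enumerate_setups()].
#' @param panel The panel the setups were built from.
#' @param ec_levels Integer EC gradient; must lie in 1..10. Default
#'   `c(1, 3, 5, 7, 10)`.
#' @param n_replicates Number of parallel replicates per condition
#'   (default 6, giving 1290 rows for the default design).
#' @return A tibble with columns `sample_id`, `setup_id`, `ec_level`,
#'   `replicate` and one `ppm_<toxicant>` column per panel member.
#' @examples
#' man <- expand_manifest(enumerate_setups(default_panel()), default_panel())
#' nrow(man) # 1290
#' @export
expand_manifest <- function(setups, panel, ec_levels = c(1, 3, 5, 7, 10),
                            n_replicates = 6) {
  stopifnot(is.data.frame(setups), nrow(setups) >= 1)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  if (any(ec_levels < 1 | ec_levels > 10)) {
    abort("EC levels must lie in 1..10 (10 is the maximum concentration)")
  }

  grid <- tidyr::crossing(
    idx = seq_len(nrow(setups)),
    ec_level = sort(unique(ec_levels)),
    replicate = seq_len(n_replicates)
  ) |>
    arrange(.data$idx, .data$ec_level, .data$replicate)

  ppm_mat <- matrix(0, nrow(grid), nrow(panel),
                    dimnames = list(NULL, panel$name))
  for (i in seq_len(nrow(grid))) {
    s <- setups[grid$idx[i], ]
    comps <- s$components[[1]]
    w <- s$ratio[[1]] / sum(s$ratio[[1]])
    j <- match(comps, panel$name)
    if (anyNA(j)) abort("setup references a toxicant absent from the panel")
    ppm_mat[i, j] <- panel$c_max[j] * w * grid$ec_level[i] / 10
  }
  colnames(ppm_mat) <- paste0("ppm_", panel$name)

  dplyr::bind_cols(
    tibble(
      sample_id = sprintf("S%05d", seq_len(nrow(grid))),
      setup_id = setups$setup_id[grid$idx],
      ec_level = grid$ec_level,
      replicate = grid$replicate
    ),
    as_tibble(ppm_mat)
  )
}

#' Extract the ppm columns of a manifest as a named matrix
#'
#' @param manifest A manifest tibble from [expand_manifest()].
#' @return Numeric matrix, one column per toxicant (names without the
#'   `ppm_` prefix).
#' @keywords internal
manifest_ppm <- function(manifest) {
  cols <- grep("^ppm_", names(manifest), value = TRUE)
  m <- as.matrix(manifest[cols])
  colnames(m) <- sub("^ppm_", "", cols)
  m
}
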