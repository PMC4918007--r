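#' Default study design for the synthetic generator
#'
#' Describes a replicated design of sulfide-spring systems: each system pairs
#' one sulfidic site with one or more nearby non-sulfidic reference sites.
#' The default emulates the sampled complexes — four mosquitofish clades
#' (one *affinis*-type system, three *holbrooki*-type spring systems, one
#' *eurystoma/sexradiata* system, one *hubbsi* system) plus four molly
#' systems — for ten sulfidic systems in total, the sample size at which the
#' cross-system correlations are computed.
#'
#' @param clades A data frame (or tibble) with columns `clade`, `genus`,
#'   `n_systems`, and `n_nonsulfidic` (reference sites per system). The
#'   default gives 10 systems across 6 clades in 2 genera.
#' @param h2s_range Numeric length-2: range (in micromolar) from which each
#'   sulfidic site's H2S concentration is drawn. Field measurements across
#'   these systems span roughly 20–200 uM.
#' @return A list with class `study_design`.
#' @export
study_design <- function(clades = NULL, h2s_range = c(20, 200)) {
  if (is.null(clades)) {
    clades <- tibble::tribble(
      ~clade,        ~genus,     ~n_systems, ~n_nonsulfidic,
      "affinis",     "gambusia", 1L,         1L,
      "holbrooki",   "gambusia", 3L,         1L,
      "eurystoma",   "gambusia", 1L,         1L,
      "hubbsi",      "gambusia", 1L,         1L,
      "mexicana",    "poecilia", 2L,         1L,
      "sulphuraria", "poecilia", 2L,         1L
    )
  }
  clades <- tibble::as_tibble(clades)
  need <- c("clade", "genus", "n_systems", "n_nonsulfidic")
  if (!all(need %in% names(clades))) {
    stop("`clades` must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(clades) < 1L || any(clades$n_systems < 1L)) {
    stop("design must name at least one clade with at least one system each")
  }
  if (any(clades$n_nonsulfidic < 1L)) {
    stop("every system needs at least one non-sulfidic reference site")
  }
  if (length(h2s_range) != 2L || any(h2s_range < 0) ||
      h2s_range[2] < h2s_range[1]) {
    stop("`h2s_range` must be a non-negative increasing pair")
  }
  structure(list(clades = clades, h2s_range = as.numeric(h2s_range)),
            class = "study_design")
}

# rough geographic anchors per known clade; unknown clades get a hashed anchor
clade_anchor <- function(clade) {
  anchors <- list(
    affinis     = c(34.2, -96.9),  # southern Oklahoma
    holbrooki   = c(30.2, -84.2),  # Florida panhandle springs
    eurystoma   = c(17.5, -92.8),  # Tabasco, Mexico
    hubbsi      = c(24.1, -77.5),  # Bahamas blue holes
    mexicana    = c(17.4, -93.0),
    sulphuraria = c(17.45, -92.97)
  )
  a <- anchors[[clade]]
  if (is.null(a)) {
    h <- sum(utf8ToInt(clade))
    a <- c(15 + (h %% 25), -100 + (h %% 30))
  }
  a
}

#' Generate sampling sites for a synthetic study
#'
#' Lays out the sites implied by a [study_design()]: per system one sulfidic
#' site with an H2S concentration drawn uniformly from the design's range and
#' `n_nonsulfidic` reference sites with zero H2S, all with nearby coordinates
#' so that "geographically closest non-sulfidic site" is well defined.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with one row per site: `site_id`, `clade`, `genus`,
#'   `system_id`, `sulfidic`, `h2s_um`, `latitude`, `longitude`.
#' @examples
#' sites <- generate_sites(study_design(), seed = 1)
#' sum(sites$sulfidic)  # 10 sulfide-spring systems
#' @export
generate_sites <- function(design = study_design(), seed = 1) {
  stopifnot(inherits(design, "study_design"))
  with_seed(seed, {
    rows <- purrr::pmap(design$clades, function(clade, genus, n_systems,
                                                n_nonsulfidic) {
      anchor <- clade_anchor(clade)
      purrr::map(seq_len(n_systems), function(sys) {
        system_id <- sprintf("%s_%d", clade, sys)
        base_lat <- anchor[1] + runif(1, -0.5, 0.5)
        base_lon <- anchor[2] + runif(1, -0.5, 0.5)
        h2s <- runif(1, design$h2s_range[1], design$h2s_range[2])
        sulf <- tibble::tibble(
          site_id = paste0(system_id, "_S"), clade = clade, genus = genus,
          system_id = system_id, sulfidic = TRUE, h2s_um = h2s,
          latitude = base_lat, longitude = base_lon
        )
        ns <- purrr::map(seq_len(n_nonsulfidic), function(k) {
          tibble::tibble(
            site_id = sprintf("%s_N%d", system_id, k), clade = clade,
            genus = genus, system_id = system_id, sulfidic = FALSE,
            h2s_um = 0,
            latitude = base_lat + runif(1, 0.01, 0.15) * sample(c(-1, 1), 1),
            longitude = base_lon + runif(1, 0.01, 0.15) * sample(c(-1, 1), 1)
          )
        })
        dplyr::bind_rows(sulf, ns)
      })
    })
    dplyr::bind_rows(rows)
  })
}

#' Check the site-table invariants
#'
#' Each system must hold exactly one sulfidic site and at least one
#' non-sulfidic site, and `h2s_um` must be zero exactly for non-sulfidic
#' sites. Called by the generators; exported for validating user site tables.
#'
#' @param sites A site tibble as from [generate_sites()].
#' @return Invisibly `sites`; errors otherwise.
#' @export
validate_sites <- function(sites) {
  chk <- dplyr::summarise(dplyr::group_by(sites, .data$system_id),
                          n_s = sum(.data$sulfidic),
                          n_n = sum(!.data$sulfidic), .groups = "drop")
  if (any(chk$n_s != 1L)) {
    stop("each system must contain exactly one sulfidic site")
  }
  if (any(chk$n_n < 1L)) {
    stop("system(s) without a non-sulfidic reference site: ",
         paste(chk$system_id[chk$n_n < 1L], collapse = ", "))
  }
  if (any((sites$h2s_um == 0) != !sites$sulfidic)) {
    stop("h2s_um must be 0 exactly for non-sulfidic sites")
  }
  invisible(sites)
}
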