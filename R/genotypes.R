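# Microsatellite genotype generation (Balding-Nichols) and GenePop IO.
#
# Genotype tables are tidy/long: one row per individual x locus with two
# allele columns (positive integer labels, e.g. fragment sizes); both alleles
# present or both NA at a locus.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate microsatellite genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral allele-frequency vector is drawn from a flat
#' Dirichlet (or supplied); each site's allele frequencies are then drawn
#' from a Dirichlet with parameters `p_anc * (1 - F) / F` — the multiallelic
#' Balding-Nichols model, whose differentiation parameter `F` is the direct
#' estimand of the Weir-Cockerham estimator. Diploid genotypes are random
#' unions of gametes. With `fst_h2s_scaling = TRUE` a sulfidic site's `F`
#' scales with its H2S concentration (`F * h2s / h2s_ref`) and non-sulfidic
#' sites keep a background `0.15 * F`, so neutral differentiation grows with
#' divergence strength; with scaling off every site uses `F` as configured.
#' `F = 0` returns the ancestral frequencies unchanged (no drift).
#'
#' @inheritParams generate_traits
#' @param n_loci Number of loci (>= 1); the empirical study used 11.
#' @param n_alleles Alleles per locus (recycled).
#' @param ancestral Optional list of per-locus ancestral frequency vectors
#'   (named numeric vectors; names are allele labels).
#' @return A tibble `individual_id, site_id, locus, allele1, allele2` with
#'   attribute `loci` (locus names in order).
#' @export
generate_genotypes <- function(sites, effects = effect_config(),
                               n_per_site = 30, n_loci = 11,
                               seed = 1, n_alleles = 6, ancestral = NULL,
                               h2s_ref = NULL) {
  validate_sites(sites)
  if (n_loci < 1) stop("n_loci must be at least 1")
  f0 <- effects$divergence_F
  if (f0 < 0 || f0 >= 1) stop("divergence_F must lie in [0, 1)")
  h2s_ref <- h2s_ref %||% h2s_reference(sites)
  n_alleles <- rep_len(n_alleles, n_loci)
  loci <- sprintf("loc%02d", seq_len(n_loci))

  with_seed(seed, {
    if (is.null(ancestral)) {
      ancestral <- lapply(seq_len(n_loci), function(l) {
        p <- rdirichlet1(rep(1, n_alleles[l]))
        names(p) <- as.character(seq(120, by = 2, length.out = n_alleles[l]))
        p
      })
    }
    names(ancestral) <- loci

    site_f <- function(s) {
      if (f0 == 0) return(0)
      if (!effects$fst_h2s_scaling) return(f0)
      if (s$sulfidic) {
        min(0.99, f0 * s$h2s_um / h2s_ref)
      } else {
        0.15 * f0
      }
    }

    rows <- purrr::map(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      f <- site_f(s)
      ids <- sprintf("%s_g%03d", s$site_id, seq_len(n_per_site))
      per_locus <- purrr::map(loci, function(l) {
        p_anc <- ancestral[[l]]
        p <- if (f == 0) p_anc else {
          q <- rdirichlet1(p_anc * (1 - f) / f)
          names(q) <- names(p_anc)
          q
        }
        labs <- as.integer(names(p_anc))
        a1 <- sample(labs, n_per_site, replace = TRUE, prob = p)
        a2 <- sample(labs, n_per_site, replace = TRUE, prob = p)
        tibble::tibble(individual_id = ids, site_id = s$site_id, locus = l,
                       allele1 = a1, allele2 = a2)
      })
      dplyr::bind_rows(per_locus)
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "loci") <- loci
    attr(out, "ancestral") <- ancestral
    out
  })
}

genotype_loci <- function(gt) {
  attr(gt, "loci") %||% unique(gt$locus)
}

#' Read a GenePop genotype file
#'
#' Supports the standard dialect: a title line, one locus name per line (or
#' one comma-separated line), `Pop` separators, and sample lines
#' `id , 0101 0202 ...` with 2- or 3-digit allele coding. `00`/`000` alleles
#' are parsed as missing (both alleles set to `NA`). The sample identifier
#' before the comma is used as the site identifier.
#'
#' @param path File path.
#' @return A long genotype tibble as produced by [generate_genotypes()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) stop("not a GenePop file: too short")
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no Pop separator found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  n_loci <- length(loci)

  out <- list()
  pop_no <- 0L
  current <- NULL
  for (ln in seq(pop_idx[1], length(body))) {
    line <- body[ln]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("line %d: sample line without comma separator", ln + 1L))
    }
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(calls) != n_loci) {
      stop(sprintf("line %d: %d genotype fields but %d loci declared",
                   ln + 1L, length(calls), n_loci))
    }
    width <- nchar(calls[1]) / 2
    if (!width %in% c(2, 3)) {
      stop(sprintf("line %d: allele coding must be 2 or 3 digits", ln + 1L))
    }
    a1 <- as.integer(substr(calls, 1, width))
    a2 <- as.integer(substr(calls, width + 1, 2 * width))
    miss <- a1 == 0 | a2 == 0
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    out[[length(out) + 1L]] <- tibble::tibble(
      individual_id = sprintf("%s_%d", id, length(out) + 1L),
      site_id = id, locus = loci, allele1 = a1, allele2 = a2
    )
  }
  gt <- dplyr::bind_rows(out)
  attr(gt, "loci") <- loci
  gt
}

#' Write a GenePop genotype file
#'
#' @param gt Long genotype tibble.
#' @param path Output path.
#' @param digits Allele coding width: 2 or 3.
#' @param title Title line content.
#' @return Invisibly `path`.
#' @export
write_genepop <- function(gt, path, digits = 3, title = "sulfidiv genotypes") {
  stopifnot(digits %in% c(2, 3))
  loci <- genotype_loci(gt)
  fmt <- sprintf("%%0%dd%%0%dd", digits, digits)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(gt, call = sprintf(
      fmt, ifelse(is.na(.data$allele1), 0L, .data$allele1),
      ifelse(is.na(.data$allele2), 0L, .data$allele2)
    ))[, c("individual_id", "site_id", "locus", "call")],
    names_from = "locus", values_from = "call"
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (site in unique(wide$site_id)) {
    writeLines("Pop", con)
    rows <- wide[wide$site_id == site, ]
    writeLines(sprintf("%s ,  %s", rows$site_id,
                       apply(rows[, loci, drop = FALSE], 1, paste,
                             collapse = " ")), con)
  }
  invisible(path)
}
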