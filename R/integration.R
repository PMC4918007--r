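# Cross-system integration: per-system divergence scores, the two-suite
# PCA, and one-tailed divergence correlations.

#' Per-system divergence scores from individual divergence-vector scores
#'
#' For every sulfide system: mean score per site, non-sulfidic site means
#' averaged, then `mean(non-sulfidic) - mean(sulfidic)`. With divergence
#' vectors oriented sulfidic-positive this signed difference is typically
#' negative; the magnitude is reported alongside and used downstream, with
#' the signed value preserved. Systems missing scored individuals in either
#' habitat type are excluded with a warning.
#'
#' @param scores Tibble with columns `score`, `site_id`, `system_id`,
#'   `sulfidic` (e.g. `divergence_vector()$scores`, possibly augmented with
#'   projected individuals).
#' @return A tibble: `system_id, divergence (signed), divergence_abs`.
#' @export
system_divergence_scores <- function(scores) {
  site_means <- dplyr::summarise(
    dplyr::group_by(scores, .data$system_id, .data$site_id, .data$sulfidic),
    m = mean(.data$score), .groups = "drop"
  )
  per_sys <- dplyr::summarise(
    dplyr::group_by(site_means, .data$system_id),
    has_both = dplyr::n_distinct(.data$sulfidic) == 2,
    divergence = mean(.data$m[!.data$sulfidic]) - mean(.data$m[.data$sulfidic]),
    .groups = "drop"
  )
  if (any(!per_sys$has_both)) {
    warning("system(s) missing a habitat type excluded: ",
            paste(per_sys$system_id[!per_sys$has_both], collapse = ", "))
    per_sys <- per_sys[per_sys$has_both, ]
  }
  dplyr::mutate(per_sys[, c("system_id", "divergence")],
                divergence_abs = abs(.data$divergence))
}

#' Combine two divergence measures into one phenotypic axis
#'
#' Standardizes the life-history and morphological divergence measures,
#' eigen-decomposes their 2 x 2 correlation matrix, and returns the first
#' principal component. For two variables the leading eigenvalue is
#' `1 + |r|` and its variance fraction `(1 + |r|) / 2`; an eigenvalue of
#' 1.88 therefore corresponds to 94.0 % of the total variance. PC1 is
#' oriented to correlate positively with the mean of the standardized
#' inputs.
#'
#' @param lh,morph Numeric vectors of per-system divergence values (>= 3
#'   systems, matching order).
#' @return A list: `scores` (PC1 per system), `eigenvalue`,
#'   `variance_fraction`, `loadings`, `r` (the correlation).
#' @export
combine_divergence_pca <- function(lh, morph) {
  if (length(lh) != length(morph)) stop("measures must have equal length")
  ok <- is.finite(lh) & is.finite(morph)
  if (sum(ok) < 3) stop("need at least 3 systems with both measures")
  if (sd(lh[ok]) == 0 || sd(morph[ok]) == 0) {
    stop("zero variance in a divergence measure")
  }
  z <- cbind(lh = scale(lh)[, 1], morph = scale(morph)[, 1])
  cm <- cor(z[ok, ])
  ev <- eigen(cm, symmetric = TRUE)
  load <- ev$vectors[, 1]
  if (sum(load) < 0) load <- -load
  scores <- as.numeric(z %*% load)
  list(scores = scores, eigenvalue = ev$values[1],
       variance_fraction = ev$values[1] / 2, loadings = load,
       r = cm[1, 2])
}

# all permutations of 1..n (n <= 9), as a matrix with one row per perm
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

#' One-tailed correlation test
#'
#' Pearson or Spearman correlation with a one-tailed p-value in the
#' direction of the observed sign. `t_approx` uses
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df (Spearman uses average
#' ranks for ties); `exact_perm` enumerates all `n!` permutations
#' (feasible up to n = 10; p includes the identity permutation, so it is
#' never 0).
#'
#' @param x,y Numeric vectors.
#' @param kind `"spearman"` (default) or `"pearson"`.
#' @param method `"t_approx"` or `"exact_perm"`.
#' @return A tibble: `estimate, p_value, n, kind, method`.
#' @export
correlate_onetailed <- function(x, y, kind = c("spearman", "pearson"),
                                method = c("t_approx", "exact_perm")) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  r <- cor(x, y, method = kind)
  if (method == "t_approx") {
    p <- onetailed_p_from_r(r, n)
  } else {
    if (n > 10) stop("exact enumeration limited to n <= 10")
    xs <- if (kind == "spearman") rank(x) else x
    ys <- if (kind == "spearman") rank(y) else y
    stat_all <- if (n <= 9) {
      pm <- perms(n)
      as.numeric(cor(xs, t(matrix(ys[t(pm)], nrow(pm), n, byrow = TRUE))))
    } else {
      # chunk by first element to bound memory at n = 10
      sub <- perms(9L)
      unlist(lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        pm <- cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
        as.numeric(cor(xs, t(matrix(ys[t(pm)], nrow(pm), n, byrow = TRUE))))
      }))
    }
    p <- if (r >= 0) mean(stat_all >= r - 1e-12) else
      mean(stat_all <= r + 1e-12)
  }
  tibble::tibble(estimate = r, p_value = p, n = n, kind = kind,
                 method = method)
}

#' One-tailed p from a printed correlation coefficient
#'
#' The t-approximation `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df,
#' upper or lower tail following the sign of `r`. Useful for re-deriving
#' p-values from reported correlation coefficients.
#'
#' @param r Correlation coefficient.
#' @param n Sample size.
#' @return One-tailed p-value.
#' @export
onetailed_p_from_r <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  if (r >= 0) pt(t, n - 2, lower.tail = FALSE) else pt(t, n - 2)
}

#' Assemble the per-system divergence summary and headline correlations
#'
#' Joins the life-history and morphological per-system divergence scores,
#' forms the combined phenotypic axis (PCA on the divergence magnitudes),
#' attaches each sulfidic site's F_ST to its geographically closest
#' non-sulfidic site (great-circle distance on the site coordinates, or an
#' explicit `pairing` table `system_id -> site_id`), and computes the three
#' one-tailed Spearman correlations: life-history vs morphological
#' divergence, combined divergence vs F_ST, and combined divergence vs
#' H2S concentration. Systems without F_ST (or H2S) drop out of that
#' correlation only.
#'
#' @param lh_div,morph_div Tibbles from [system_divergence_scores()].
#' @param sites Site tibble.
#' @param fst Optional `pairwise_fst` object.
#' @param pairing Optional tibble `system_id, site_id` overriding the
#'   geographic choice of reference site.
#' @return A list of class `divergence_summary`: `table` (one row per
#'   sulfidic system) and `correlations` (tibble with `comparison,
#'   estimate, p_value, n`).
#' @export
build_divergence_summary <- function(lh_div, morph_div, sites, fst = NULL,
                                     pairing = NULL) {
  tab <- dplyr::inner_join(
    dplyr::rename(lh_div, lh_divergence = "divergence",
                  lh_divergence_abs = "divergence_abs"),
    dplyr::rename(morph_div, morph_divergence = "divergence",
                  morph_divergence_abs = "divergence_abs"),
    by = "system_id"
  )
  sulf <- sites[sites$sulfidic, c("system_id", "site_id", "h2s_um",
                                  "latitude", "longitude")]
  tab <- dplyr::left_join(tab, dplyr::rename(sulf, sulf_site = "site_id"),
                          by = "system_id")

  pca <- combine_divergence_pca(tab$lh_divergence_abs,
                                tab$morph_divergence_abs)
  tab$phen_pc1 <- pca$scores

  tab$fst_nearest <- NA_real_
  if (!is.null(fst)) {
    for (i in seq_len(nrow(tab))) {
      sys <- tab$system_id[i]
      ns <- sites[!sites$sulfidic & sites$system_id == sys, ]
      ref <- NULL
      if (!is.null(pairing) && sys %in% pairing$system_id) {
        ref <- pairing$site_id[match(sys, pairing$system_id)]
      } else if (nrow(ns) > 0 && !anyNA(ns$latitude)) {
        dd <- geosphere::distHaversine(
          cbind(tab$longitude[i], tab$latitude[i]),
          cbind(ns$longitude, ns$latitude)
        )
        ref <- ns$site_id[which.min(dd)]
      } else if (nrow(ns) > 0) {
        ref <- ns$site_id[1]
      }
      if (!is.null(ref) && tab$sulf_site[i] %in% rownames(fst$theta) &&
          ref %in% rownames(fst$theta)) {
        tab$fst_nearest[i] <- fst$theta[tab$sulf_site[i], ref]
      }
    }
  }

  cors <- list()
  cors$lh_vs_morph <- correlate_onetailed(tab$lh_divergence_abs,
                                          tab$morph_divergence_abs)
  if (any(is.finite(tab$fst_nearest))) {
    cors$phen_vs_fst <- correlate_onetailed(tab$phen_pc1, tab$fst_nearest)
  }
  if (any(is.finite(tab$h2s_um))) {
    cors$phen_vs_h2s <- correlate_onetailed(tab$phen_pc1, tab$h2s_um)
  }
  correlations <- dplyr::bind_rows(
    purrr::imap(cors, function(v, nm) dplyr::mutate(v, comparison = nm))
  )[, c("comparison", "estimate", "p_value", "n", "kind", "method")]

  structure(list(table = tab, correlations = correlations, pca = pca),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("<divergence_summary: %d systems>\n", nrow(x$table)))
  print(x$correlations)
  invisible(x)
}
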