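# Microsatellite summaries, Weir-Cockerham F_ST, and Mantel permutation
# tests -- the gene-flow proxy machinery.

#' Per-site, per-locus genetic variability
#'
#' Standard indicators per site and locus: genotyped sample size, allele
#' count, observed heterozygosity (fraction of heterozygous genotypes), and
#' unbiased expected heterozygosity `(2n / (2n - 1)) (1 - sum p^2)`.
#' Sites with no genotyped individuals at a locus get `NA` entries.
#'
#' @param gt Long genotype tibble (see [generate_genotypes()]).
#' @return A tibble: `site_id, locus, n, n_alleles, ho, he`.
#' @export
genetic_variability <- function(gt) {
  gt <- dplyr::filter(gt, !is.na(.data$allele1) & !is.na(.data$allele2))
  out <- dplyr::summarise(
    dplyr::group_by(gt, .data$site_id, .data$locus),
    n = dplyr::n(),
    n_alleles = length(unique(c(.data$allele1, .data$allele2))),
    ho = mean(.data$allele1 != .data$allele2),
    he = {
      p <- table(c(.data$allele1, .data$allele2))
      p <- as.numeric(p) / sum(p)
      nn <- dplyr::n()
      (2 * nn / (2 * nn - 1)) * (1 - sum(p^2))
    },
    .groups = "drop"
  )
  # flag site x locus combinations that were entirely missing
  full <- tidyr::expand_grid(site_id = unique(out$site_id),
                             locus = genotype_loci(out))
  dplyr::left_join(full, out, by = c("site_id", "locus"))
}

# Weir & Cockerham (1984) variance components for one allele at one locus
# across r populations. n: genotyped counts, p: allele frequencies, h:
# observed heterozygote frequencies (for this allele).
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Pairwise Weir-Cockerham F_ST between two sites
#'
#' Multilocus theta: per-allele, per-locus variance components a (among
#' populations), b (among individuals within populations), and c (within
#' individuals), combined as a ratio of sums `theta = sum(a) / sum(a+b+c)`.
#' Negative per-locus components are retained (no truncation at zero),
#' matching the original estimator. Genotypes missing at a locus are dropped
#' from that locus only.
#'
#' @param gt Long genotype tibble.
#' @param site_a,site_b Site identifiers.
#' @return A list: `theta` (multilocus), `per_locus` tibble with per-locus
#'   theta and summed components, `components` (total a, b, c sums).
#'   `theta` is `NA` with a warning when no locus shows any variation.
#' @export
pairwise_fst <- function(gt, site_a, site_b) {
  sub <- dplyr::filter(gt, .data$site_id %in% c(site_a, site_b),
                       !is.na(.data$allele1) & !is.na(.data$allele2))
  if (length(unique(sub$site_id)) < 2) {
    stop("both sites need genotyped individuals")
  }
  loci <- unique(sub$locus)
  per_locus <- purrr::map(loci, function(l) {
    d <- sub[sub$locus == l, ]
    ns <- c(sum(d$site_id == site_a), sum(d$site_id == site_b))
    if (any(ns < 2)) return(NULL)
    alleles <- sort(unique(c(d$allele1, d$allele2)))
    sums <- c(a = 0, b = 0, c = 0)
    for (al in alleles) {
      p <- vapply(c(site_a, site_b), function(s) {
        dd <- d[d$site_id == s, ]
        mean(c(dd$allele1, dd$allele2) == al)
      }, numeric(1))
      h <- vapply(c(site_a, site_b), function(s) {
        dd <- d[d$site_id == s, ]
        mean((dd$allele1 == al) != (dd$allele2 == al))
      }, numeric(1))
      sums <- sums + wc_components(ns, p, h)
    }
    tibble::tibble(locus = l, a = sums["a"], b = sums["b"], c = sums["c"],
                   theta = if (sum(sums) > 0) sums["a"] / sum(sums)
                           else NA_real_)
  })
  per_locus <- dplyr::bind_rows(per_locus)
  tot <- colSums(per_locus[, c("a", "b", "c")], na.rm = TRUE)
  denom <- sum(tot)
  theta <- if (nrow(per_locus) == 0 || denom == 0) {
    warning("no allelic variation in either site; theta undefined")
    NA_real_
  } else {
    tot[["a"]] / denom
  }
  list(theta = theta, per_locus = per_locus, components = tot)
}

#' All pairwise F_ST values as a labelled symmetric matrix
#'
#' @param gt Long genotype tibble.
#' @param sites Optional character vector restricting/ordering the sites.
#' @return An object of class `pairwise_fst`: `theta` (symmetric matrix,
#'   zero diagonal) and `pairs` (long tibble).
#' @export
fst_matrix <- function(gt, sites = NULL) {
  sites <- sites %||% unique(gt$site_id)
  n <- length(sites)
  m <- matrix(0, n, n, dimnames = list(sites, sites))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      th <- suppressWarnings(pairwise_fst(gt, sites[i], sites[j])$theta)
      m[i, j] <- m[j, i] <- th
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        site_a = sites[i], site_b = sites[j], theta = th
      )
    }
  }
  structure(list(theta = m, pairs = dplyr::bind_rows(pairs)),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat(sprintf("<pairwise_fst: %d sites, mean theta %.3f>\n",
              nrow(x$theta), mean(upper_vec(x$theta), na.rm = TRUE)))
  invisible(x)
}

check_square <- function(m, name) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(name, " must be square")
  if (max(abs(m - t(m))) > 1e-8) stop(name, " must be symmetric")
  m
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper off-diagonal triangles of two distance
#' matrices; the null distribution permutes rows and columns of one matrix
#' simultaneously. One-tailed p is `(#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`
#' (upper tail, add-one convention); the two-tailed version compares
#' absolute values.
#'
#' @param a,b Square symmetric matrices with matching dimensions.
#' @param n_perm Number of permutations.
#' @param tails 1 (upper tail) or 2.
#' @return A tibble: `r, p, n_perm, tails, partial`.
#' @export
mantel_test <- function(a, b, n_perm = 999, tails = 1) {
  a <- check_square(a, "a")
  b <- check_square(b, "b")
  if (nrow(a) != nrow(b)) stop("matrices must have the same dimension")
  va <- upper_vec(a)
  vb <- upper_vec(b)
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("constant distance matrix: Mantel r undefined")
  }
  r_obs <- cor(va, vb)
  n <- nrow(a)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    cor(upper_vec(a[idx, idx]), vb)
  }, numeric(1))
  p <- if (tails == 1) {
    (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  } else {
    (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  }
  tibble::tibble(r = r_obs, p = p, n_perm = n_perm, tails = tails,
                 partial = FALSE)
}

#' Partial Mantel test (residual-matrix permutation)
#'
#' Residualizes `a` and `b` on the covariate matrix `c_mat` by elementwise
#' linear regression over the upper triangles, rebuilds residual matrices,
#' and runs the Mantel permutation on them (rows/columns of the residualized
#' `a` are permuted). The observed statistic equals the closed-form partial
#' correlation of the vectorized triangles. A constant covariate matrix
#' falls back to the simple Mantel test with a warning.
#'
#' @param a Dependent distance matrix (e.g. pairwise F_ST).
#' @param b Predictor matrix (e.g. habitat difference, 0/1).
#' @param c_mat Covariate matrix (e.g. clade difference, 0/1).
#' @inheritParams mantel_test
#' @return A tibble as [mantel_test()], with `partial = TRUE`.
#' @export
partial_mantel <- function(a, b, c_mat, n_perm = 999, tails = 1) {
  a <- check_square(a, "a")
  b <- check_square(b, "b")
  c_mat <- check_square(c_mat, "c_mat")
  if (sd(upper_vec(c_mat)) == 0) {
    warning("covariate matrix is constant; running a simple Mantel test")
    return(mantel_test(a, b, n_perm = n_perm, tails = tails))
  }
  resid_mat <- function(m) {
    v <- upper_vec(m)
    vc <- upper_vec(c_mat)
    r <- stats::resid(stats::lm(v ~ vc))
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    out[upper.tri(out)] <- r
    out + t(out)
  }
  ra <- resid_mat(a)
  rb <- resid_mat(b)
  res <- mantel_test(ra, rb, n_perm = n_perm, tails = tails)
  res$partial <- TRUE
  res
}

#' Habitat- and clade-difference matrices for a site table
#'
#' Binary distance matrices used by the partial Mantel test: 0 when two
#' sites share the habitat type (or clade), 1 otherwise.
#'
#' @param sites Site tibble.
#' @return A list with `habitat` and `clade` matrices (site_id labels).
#' @export
site_difference_matrices <- function(sites) {
  lab <- sites$site_id
  hab <- outer(sites$sulfidic, sites$sulfidic, `!=`) * 1
  cla <- outer(sites$clade, sites$clade, `!=`) * 1
  dimnames(hab) <- dimnames(cla) <- list(lab, lab)
  list(habitat = hab, clade = cla)
}
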