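# shared fixtures, all generated in code

# a compact 2-clade, 4-system design used throughout the unit tests
small_design <- function(n_nonsulfidic = 1L) {
  study_design(clades = tibble::tibble(
    clade = c("cladeA", "cladeB"),
    genus = "gambusia",
    n_systems = 2L,
    n_nonsulfidic = n_nonsulfidic
  ))
}

# generate a small transformed trait table with habitat column ready for
# modelling
small_study_traits <- function(seed, effects = effect_config(),
                               n_per_site = 12,
                               design = small_design()) {
  sites <- generate_sites(design, seed = seed)
  tr <- generate_traits(sites, effects, n_per_site = n_per_site,
                        seed = seed + 1)
  tr$h2s <- ifelse(tr$sulfidic, "S", "NS")
  list(sites = sites, traits = tr)
}

offspring_spec <- function(interactions = c("clade:h2s", "sl_mm:h2s")) {
  mglm_spec(
    dependents = c("fecundity", "embryo_lean_weight_mg", "embryo_fat"),
    factors = c("clade", "h2s"),
    covariates = c("sl_mm", "embryo_stage"),
    interactions = interactions,
    nest_within = c("clade", "h2s")
  )
}

# two-group bivariate Gaussian toy data for discriminant checks
two_group_toy <- function(seed, n = 60, delta = c(2, 0.5),
                          sigma = diag(2)) {
  withr::with_seed(seed, {
    g <- rep(c("NS", "S"), each = n)
    z <- matrix(rnorm(2 * n * 2), ncol = 2) %*% chol(sigma)
    z[g == "S", ] <- sweep(z[g == "S", ], 2, delta, `+`)
    tibble::tibble(y1 = z[, 1], y2 = z[, 2], h2s = g,
                   sulfidic = g == "S",
                   site_id = paste0(g, rep(1:2, length.out = 2 * n)))
  })
}

# brute-force Procrustes distance via 1-D optimization over rotation angle
brute_procrustes <- function(a, b) {
  norm1 <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- norm1(a)
  b <- norm1(b)
  f <- function(th) {
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((a %*% r - b)^2)
  }
  sqrt(stats::optimize(f, c(-pi, pi), tol = 1e-12)$objective)
}
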