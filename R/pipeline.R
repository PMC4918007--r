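# Config-driven orchestration: generate (or read) -> morphometrics ->
# models -> popgen -> integration, with persisted intermediates and a
# machine-readable report.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_per_site Individuals per site for each data type.
#' @param n_loci Microsatellite loci.
#' @param n_warps Relative-warp axes used as shape variables.
#' @param n_perm Mantel permutations.
#' @param effects An [effect_config()].
#' @param design A [study_design()].
#' @param prune Apply P > 0.1 stepwise pruning to the MANCOVAs.
#' @return A list with class `run_config`.
#' @export
run_config <- function(seed = 1, n_per_site = 30, n_loci = 11,
                       n_warps = 7, n_perm = 999,
                       effects = effect_config(),
                       design = study_design(), prune = FALSE) {
  structure(list(seed = seed, n_per_site = n_per_site, n_loci = n_loci,
                 n_warps = n_warps, n_perm = n_perm, effects = effects,
                 design = design, prune = prune),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar settings (`seed`, `n_per_site`, `n_loci`, `n_warps`,
#' `n_perm`, `prune`) and any `effects:` overrides from a YAML file and
#' builds a [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- do.call(effect_config, y$effects %||% list())
  args <- y[intersect(names(y), c("seed", "n_per_site", "n_loci", "n_warps",
                                  "n_perm", "prune"))]
  do.call(run_config, c(args, list(effects = eff)))
}

model_specs_default <- function(n_warps) {
  list(
    adult_lh = mglm_spec(
      dependents = c("lean_weight_g", "fat_content", "gsi_or_ra"),
      factors = c("clade", "sex", "h2s"), covariates = "sl_mm",
      interactions = c("clade:sex", "clade:h2s", "sex:h2s",
                       "sl_mm:clade", "sl_mm:h2s", "clade:sex:h2s"),
      nest_within = c("clade", "h2s")
    ),
    offspring_lh = mglm_spec(
      dependents = c("fecundity", "embryo_lean_weight_mg", "embryo_fat"),
      factors = c("clade", "h2s"), covariates = c("sl_mm", "embryo_stage"),
      interactions = c("clade:h2s", "sl_mm:clade", "sl_mm:h2s",
                       "embryo_stage:clade", "embryo_stage:h2s"),
      nest_within = c("clade", "h2s")
    ),
    shape = mglm_spec(
      dependents = paste0("RW", seq_len(n_warps)),
      factors = c("clade", "sex", "h2s"), covariates = "centroid_size",
      interactions = c("clade:sex", "clade:h2s", "sex:h2s",
                       "centroid_size:h2s", "clade:sex:h2s"),
      nest_within = c("clade", "h2s")
    )
  )
}

#' Run the full divergence pipeline on a synthetic study
#'
#' Generates sites, traits, landmarks, and genotypes under the configured
#' design; aligns shapes and extracts relative warps; fits the offspring
#' life-history and body-shape MANCOVAs on the first (training) genus;
#' derives the habitat divergence vectors and scores every individual
#' (training genus via the model adjustment, any second genus by centered
#' projection with the training transformations); estimates pairwise F_ST
#' and the partial Mantel test of F_ST on habitat difference controlling
#' for clade; and assembles the per-system divergence summary with the
#' three headline Spearman correlations. All stage seeds derive from the
#' master seed, so identical configurations give identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every intermediate table
#'   is written as CSV/TPS/GenePop and the report as JSON, plus a manifest
#'   of seeds and parameters.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  sites <- generate_sites(config$design, seed = child_seed(seed, "sites"))
  traits <- generate_traits(sites, config$effects, config$n_per_site,
                            seed = child_seed(seed, "traits"))
  shapes <- generate_landmarks(sites, config$effects, config$n_per_site,
                               seed = child_seed(seed, "landmarks"))
  genos <- generate_genotypes(sites, config$effects, config$n_per_site,
                              n_loci = config$n_loci,
                              seed = child_seed(seed, "genotypes"))

  genera <- unique(sites$genus)
  train_genus <- genera[1]

  # --- morphometrics ---
  aligned <- gpa(shapes)
  rw <- relative_warps(aligned, n_keep = config$n_warps)
  shape_tab <- dplyr::mutate(rw$scores,
                             centroid_size = aligned$centroid_sizes,
                             h2s = ifelse(.data$sulfidic, "S", "NS"))

  # --- life-history models (training genus) ---
  traits <- dplyr::mutate(traits, h2s = ifelse(.data$sulfidic, "S", "NS"))
  train_raw <- dplyr::filter(traits, .data$genus == train_genus)
  train_tr <- transform_traits(train_raw)
  tmap <- attr(train_tr, "transform_map")

  specs <- model_specs_default(config$n_warps)
  fit_off <- fit_mglm(dplyr::filter(train_tr, .data$pregnant),
                      specs$offspring_lh)
  if (config$prune) fit_off <- prune_model(fit_off)
  vec_lh <- divergence_vector(fit_off, term = "h2s")

  fit_adult <- fit_mglm(train_tr, specs$adult_lh)
  if (config$prune) fit_adult <- prune_model(fit_adult)

  shape_train <- dplyr::filter(shape_tab, .data$genus == train_genus)
  fit_shape <- fit_mglm(shape_train, specs$shape)
  if (config$prune) fit_shape <- prune_model(fit_shape)
  vec_shape <- divergence_vector(fit_shape, term = "h2s")

  # --- score all individuals (second genus projected) ---
  lh_scores <- vec_lh$scores
  other_traits <- dplyr::filter(traits, .data$genus != train_genus,
                                .data$pregnant)
  if (nrow(other_traits) > 0) {
    other_tr <- apply_transform(other_traits, tmap)
    ok <- complete.cases(other_tr[, vec_lh$dependents])
    proj <- project_scores(vec_lh, other_tr[ok, ], adjust = "center")
    lh_scores <- dplyr::bind_rows(
      lh_scores,
      dplyr::mutate(other_tr[ok, intersect(names(lh_scores),
                                           names(other_tr))], score = proj)
    )
  }
  shape_scores <- vec_shape$scores
  shape_other <- dplyr::filter(shape_tab, .data$genus != train_genus)
  if (nrow(shape_other) > 0) {
    proj <- project_scores(vec_shape, shape_other, adjust = "center")
    shape_scores <- dplyr::bind_rows(
      shape_scores,
      dplyr::mutate(shape_other[, intersect(names(shape_scores),
                                            names(shape_other))],
                    score = proj)
    )
  }

  # --- population genetics ---
  fst <- fst_matrix(genos, sites = sites$site_id)
  diffs <- site_difference_matrices(sites)
  mantel_res <- with_seed(child_seed(seed, "mantel"), {
    partial_mantel(fst$theta, diffs$habitat, diffs$clade,
                   n_perm = config$n_perm)
  })

  # --- integration ---
  lh_div <- system_divergence_scores(lh_scores)
  morph_div <- system_divergence_scores(shape_scores)
  summary <- build_divergence_summary(lh_div, morph_div, sites, fst = fst)

  site_tests <- purrr::map(
    c("clade", "h2s", "clade:h2s"),
    function(tm) tryCatch(site_level_test(fit_off, tm),
                          warning = function(w) NULL,
                          error = function(e) NULL)
  )

  report <- structure(list(
    seed = seed,
    n_systems = sum(sites$sulfidic),
    sites = sites,
    term_tables = list(
      adult_lh = fit_adult$term_table,
      offspring_lh = fit_off$term_table,
      shape = fit_shape$term_table
    ),
    site_level_tests = dplyr::bind_rows(site_tests),
    divergence_vectors = list(lh = vec_lh$coefficients,
                              shape = vec_shape$coefficients),
    shape_variance_explained = sum(rw$variance_fractions[
      seq_len(config$n_warps)]),
    fst = fst,
    mantel = mantel_res,
    summary = summary,
    correlations = summary$correlations,
    config = config
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(report, traits, shapes, genos, lh_scores,
                             shape_scores, out_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d systems, seed %s>\n",
              x$n_systems, format(x$seed)))
  print(x$correlations)
  invisible(x)
}

write_pipeline_artifacts <- function(report, traits, shapes, genos,
                                     lh_scores, shape_scores, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f),
                                   row.names = FALSE)
  wcsv(report$sites, "sites.csv")
  wcsv(traits, "traits.csv")
  wcsv(lh_scores, "lh_scores.csv")
  wcsv(shape_scores, "shape_scores.csv")
  wcsv(report$summary$table, "divergence_summary.csv")
  wcsv(report$correlations, "correlations.csv")
  for (nm in names(report$term_tables)) {
    wcsv(report$term_tables[[nm]], paste0("terms_", nm, ".csv"))
  }
  write.csv(report$fst$theta, file.path(out_dir, "fst_matrix.csv"))
  write_tps(shapes, file.path(out_dir, "landmarks.tps"))
  write_genepop(genos, file.path(out_dir, "genotypes.gen"))
  cfg <- report$config
  yaml::write_yaml(list(seed = cfg$seed, n_per_site = cfg$n_per_site,
                        n_loci = cfg$n_loci, n_warps = cfg$n_warps,
                        n_perm = cfg$n_perm, prune = cfg$prune,
                        effects = unclass(cfg$effects)),
                   file.path(out_dir, "config.yaml"))
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# plain-list view of a report for JSON serialization
report_to_list <- function(report) {
  list(
    seed = report$seed,
    n_systems = report$n_systems,
    shape_variance_explained = report$shape_variance_explained,
    correlations = report$correlations,
    mantel = report$mantel,
    divergence_vectors = lapply(report$divergence_vectors, as.list),
    term_tables = report$term_tables,
    site_level_tests = report$site_level_tests,
    divergence_summary = report$summary$table,
    fst = as.data.frame(report$fst$theta)
  )
}

#' Write a miniature synthetic study bundle
#'
#' A small end-to-end fixture: 4 sulfide systems in 2 clades, 30
#' individuals per site, 8 loci at `divergence_F = 0.25`, written through
#' the package's own writers (sites/traits CSV, TPS landmarks, GenePop
#' genotypes, YAML config echo, JSON manifest).
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly the directory, with attribute `files`.
#' @export
make_fixture <- function(seed = 42, dir = tempfile("sulfidiv_fixture_")) {
  design <- study_design(clades = tibble::tibble(
    clade = c("cladeA", "cladeB"), genus = c("gambusia", "gambusia"),
    n_systems = c(2L, 2L), n_nonsulfidic = c(1L, 1L)
  ))
  effects <- effect_config(divergence_F = 0.25, fst_h2s_scaling = FALSE)
  sites <- generate_sites(design, seed = child_seed(seed, "sites"))
  traits <- generate_traits(sites, effects, 30,
                            seed = child_seed(seed, "traits"))
  shapes <- generate_landmarks(sites, effects, 30,
                               seed = child_seed(seed, "landmarks"))
  genos <- generate_genotypes(sites, effects, 30, n_loci = 8,
                              seed = child_seed(seed, "genotypes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write_tps(shapes, file.path(dir, "landmarks.tps"))
  write_genepop(genos, file.path(dir, "genotypes.gen"))
  yaml::write_yaml(list(seed = seed, n_per_site = 30, n_loci = 8,
                        effects = unclass(effects)),
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = seed,
         stage_seeds = list(sites = child_seed(seed, "sites"),
                            traits = child_seed(seed, "traits"),
                            landmarks = child_seed(seed, "landmarks"),
                            genotypes = child_seed(seed, "genotypes")),
         n_sites = nrow(sites), n_individuals = nrow(sites) * 30L,
         n_loci = 8L, divergence_F = 0.25),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  structure(invisible(dir),
            files = list.files(dir))
}
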