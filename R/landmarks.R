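#' Landmark shape data container
#'
#' Holds per-specimen landmark configurations: the raw digitized coordinates
#' and, after [gpa()], the Procrustes-aligned coordinates, centroid sizes,
#' and the consensus configuration.
#'
#' @param coords Numeric array `n x k x 2` of raw landmark coordinates.
#' @param meta Tibble with one row per specimen; must contain `specimen_id`.
#' @return An object of class `shape_data`.
#' @export
shape_data <- function(coords, meta) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L)
  meta <- tibble::as_tibble(meta)
  if (!"specimen_id" %in% names(meta)) stop("meta needs a specimen_id column")
  if (nrow(meta) != dim(coords)[1]) {
    stop("meta rows and coordinate array extent disagree")
  }
  dimnames(coords)[[1]] <- meta$specimen_id
  structure(list(coords = coords, meta = meta, aligned = NULL,
                 centroid_sizes = NULL, consensus = NULL),
            class = "shape_data")
}

#' @export
print.shape_data <- function(x, ...) {
  cat(sprintf("<shape_data: %d specimens x %d landmarks%s>\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (is.null(x$aligned)) "" else ", aligned"))
  invisible(x)
}

#' @export
dim.shape_data <- function(x) dim(x$coords)

#' Idealized 13-landmark mosquitofish configuration
#'
#' The lateral-view mean landmark configuration used as the basis of the
#' landmark generator: snout, head, fin insertions, caudal peduncle, and eye
#' positions of a generic poeciliid, in millimetres. This is a synthetic
#' stand-in constructed for simulation (file
#' `extdata/landmark_mean_synthetic.csv`), not a digitized consensus of real
#' specimens.
#'
#' @return A 13 x 2 numeric matrix with landmark names as row names.
#' @export
mean_landmark_config <- function() {
  path <- system.file("extdata", "landmark_mean_synthetic.csv",
                      package = "sulfidiv", mustWork = TRUE)
  df <- utils::read.csv(path)
  m <- as.matrix(df[, c("x", "y")])
  rownames(m) <- df$name
  m
}

# Head-enlargement deformation field: anterior landmarks displaced away from
# the body, unit Frobenius norm. Rows follow mean_landmark_config().
head_deformation <- function() {
  d <- matrix(0, 13, 2)
  d[1, ] <- c(-1.0, 0)      # snout forward
  d[2, ] <- c(-0.3, 0.8)    # crown up
  d[12, ] <- c(-0.3, -0.6)  # jaw down/forward
  d[13, ] <- c(-0.4, 0.1)   # eye forward
  d[11, ] <- c(-0.2, -0.2)  # pectoral girdle forward
  d / sqrt(sum(d^2))
}

centroid_size <- function(m) {
  cen <- colMeans(m)
  sqrt(sum(sweep(m, 2, cen)^2))
}

# Smooth low-order deformation fields (shear, arch, taper, ...) evaluated at
# a unit-size mean configuration; unit Frobenius norm each. Individual shape
# variation is concentrated on these few integrated modes -- as in real
# landmark data, where a handful of relative warps carry most variance --
# with only a small isotropic digitizing residual on top.
deformation_modes <- function(base) {
  x <- base[, 1]
  y <- base[, 2]
  fields <- list(
    cbind(y, 0),        # shear
    cbind(0, x^2),      # dorsoventral arch
    cbind(x * y, 0),    # taper
    cbind(0, x * y),    # asymmetric depth
    cbind(x^2, 0)       # anteroposterior compression
  )
  lapply(fields, function(f) {
    f <- sweep(f, 2, colMeans(f))
    f / sqrt(sum(f^2))
  })
}

#' Generate landmark configurations for a synthetic study
#'
#' Each specimen is the unit-centroid-size mean configuration plus a head
#' enlargement proportional to the site's H2S concentration (anterior
#' landmarks displaced; magnitude `head_shape_effect` in Procrustes units at
#' the reference concentration) plus individual shape variation: a few
#' smooth deformation modes with decreasing scale (so that, as in real
#' landmark data, the first several relative warps carry most of the shape
#' variance) and a small isotropic digitizing residual, all scaled by the
#' `landmark_sd` noise setting (0 gives identical shapes). The configuration
#' is then randomly scaled (body size), rotated, and translated -- nuisance
#' transforms that [gpa()] must remove.
#'
#' @inheritParams generate_traits
#' @param mean_config A `k x 2` landmark matrix; defaults to the bundled
#'   13-landmark configuration.
#' @return A `shape_data` object with site/sex metadata.
#' @export
generate_landmarks <- function(sites, effects = effect_config(),
                               n_per_site = 30, seed = 1,
                               mean_config = mean_landmark_config(),
                               h2s_ref = NULL) {
  validate_sites(sites)
  mean_config <- as.matrix(mean_config)
  if (!is.numeric(mean_config) || ncol(mean_config) != 2 ||
      nrow(mean_config) != 13) {
    stop("mean configuration must be a 13 x 2 coordinate matrix")
  }
  h2s_ref <- h2s_ref %||% h2s_reference(sites)
  base <- sweep(mean_config, 2, colMeans(mean_config))
  base <- base / centroid_size(base)
  defo <- head_deformation()
  modes <- deformation_modes(base)
  mode_sd <- c(3.5, 2.5, 1.8, 1.2, 0.8)
  k <- nrow(base)
  sdn <- effects$noise$landmark_sd

  with_seed(seed, {
    n_total <- nrow(sites) * n_per_site
    coords <- array(NA_real_, c(n_total, k, 2))
    meta <- vector("list", nrow(sites))
    idx <- 0L
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      s_eff <- if (s$sulfidic) h2s_scale(s$h2s_um, h2s_ref, effects) else 0
      n_f <- ceiling(n_per_site / 2)
      sex <- c(rep("f", n_f), rep("m", n_per_site - n_f))
      for (j in seq_len(n_per_site)) {
        indiv <- Reduce(`+`, purrr::map2(modes, mode_sd, function(m, s) {
          rnorm(1, 0, s * sdn) * m
        }))
        shp <- base + effects$head_shape_effect * s_eff * defo + indiv +
          matrix(rnorm(2 * k, 0, 0.3 * sdn), k, 2)
        # nuisance: scale to a body size, rotate, translate
        size <- exp(rnorm(1, log(25), 0.12))
        th <- runif(1, -pi / 6, pi / 6)
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        shp <- size * shp %*% rot
        shp <- sweep(shp, 2, runif(2, -10, 10), `+`)
        idx <- idx + 1L
        coords[idx, , ] <- shp
      }
      meta[[i]] <- tibble::tibble(
        specimen_id = sprintf("%s_m%03d", s$site_id, seq_len(n_per_site)),
        site_id = s$site_id, clade = s$clade, genus = s$genus,
        system_id = s$system_id, sulfidic = s$sulfidic, h2s_um = s$h2s_um,
        sex = sex
      )
    }
    shape_data(coords, dplyr::bind_rows(meta))
  })
}

#' Read a TPS landmark file
#'
#' Parses the `LM=` block dialect written by the common landmark digitizers:
#' each specimen is an `LM=k` line followed by `k` whitespace-separated
#' coordinate pairs, optionally followed by `ID=`, `IMAGE=`, and `SCALE=`
#' lines. `SCALE` is applied multiplicatively to the coordinates.
#'
#' @param path File path.
#' @return A `shape_data` object (metadata: `specimen_id` only).
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  starts <- grep("^LM\\s*=", lines)
  if (length(starts) == 0) stop("no LM= blocks found in ", path)
  specs <- vector("list", length(starts))
  ids <- character(length(starts))
  ends <- c(starts[-1] - 1L, length(lines))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", block[1]))
    coord_lines <- grep("^[-+0-9.]", block[-1], value = TRUE)
    if (length(coord_lines) != k) {
      stop(sprintf(
        "specimen block %d declares LM=%d but has %d coordinate lines",
        b, k, length(coord_lines)
      ))
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), function(p) {
      v <- as.numeric(p)
      if (length(v) != 2 || anyNA(v)) {
        stop(sprintf("malformed coordinate line in specimen block %d", b))
      }
      v
    }))
    id_line <- grep("^ID\\s*=", block, value = TRUE)
    sc_line <- grep("^SCALE\\s*=", block, value = TRUE)
    if (length(sc_line)) {
      xy <- xy * as.numeric(sub("^SCALE\\s*=\\s*", "", sc_line[1]))
    }
    ids[b] <- if (length(id_line)) {
      sub("^ID\\s*=\\s*", "", id_line[1])
    } else {
      sprintf("specimen_%d", b)
    }
    specs[[b]] <- xy
  }
  ks <- vapply(specs, nrow, integer(1))
  if (length(unique(ks)) != 1) {
    stop("specimens have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  }
  coords <- array(NA_real_, c(length(specs), ks[1], 2))
  for (b in seq_along(specs)) coords[b, , ] <- specs[[b]]
  shape_data(coords, tibble::tibble(specimen_id = ids))
}

#' Write a TPS landmark file
#'
#' @param shapes A `shape_data` object; raw coordinates are written.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_tps <- function(shapes, path) {
  stopifnot(inherits(shapes, "shape_data"))
  n <- dim(shapes$coords)[1]
  k <- dim(shapes$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    writeLines(sprintf("LM=%d", k), con)
    xy <- shapes$coords[i, , ]
    writeLines(sprintf("%.10g %.10g", xy[, 1], xy[, 2]), con)
    writeLines(sprintf("ID=%s", shapes$meta$specimen_id[i]), con)
  }
  invisible(path)
}
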