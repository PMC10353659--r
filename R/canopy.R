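#' Triangulated leaf surface
#'
#' Builds the triangle mesh of a single leaf. The midrib is a planar
#' arc in the vertical plane of `azimuth`: it leaves the base at
#' `inclination` degrees above horizontal and its tangent angle
#' decreases linearly with arc length, sweeping a total of `curvature`
#' radians from base to tip (a drooping blade; `curvature = 0` is a
#' straight midrib). The blade width rises linearly from 0 at the base
#' to `max_width` at 30% of the length, then tapers linearly to 0 at
#' the tip, so the analytic one-sided blade area is
#' `0.5 * max_width * length`. The width direction is horizontal and
#' perpendicular to the midrib plane, which keeps the mesh area equal
#' to the arc-length integral of the width profile up to chord
#' discretization (within 5% at the default segment count).
#'
#' @param length Midrib arc length (m, > 0).
#' @param max_width Maximum blade width (m, > 0).
#' @param inclination Base tangent angle above horizontal (degrees,
#'   0--90).
#' @param curvature Total tangent-angle sweep along the blade
#'   (radians, >= 0).
#' @param azimuth Heading of the midrib plane (degrees).
#' @param base Length-3 attachment point (m).
#' @param n_seg Number of segments along the midrib (>= 8); default
#'   grows with curvature so strongly drooped blades stay within the
#'   area tolerance.
#' @return A numeric matrix with 9 columns (`x1,y1,z1,x2,...,z3`), two
#'   triangles per segment.
#' @examples
#' tri <- leaf_surface(0.3, 0.01, inclination = 60, curvature = 1.5)
#' nrow(tri)
#' @export
leaf_surface <- function(length, max_width, inclination, curvature,
                         azimuth = 0, base = c(0, 0, 0), n_seg = NULL) {
  stopifnot_scalar_number(length, "length", lower = 1e-9)
  stopifnot_scalar_number(max_width, "max_width", lower = 1e-9)
  stopifnot_scalar_number(inclination, "inclination", lower = 0, upper = 90)
  stopifnot_scalar_number(curvature, "curvature", lower = 0)
  if (is.null(n_seg)) n_seg <- default_leaf_segments(curvature)
  leaf_mesh(
    base_x = base[1], base_y = base[2], base_z = base[3],
    azimuth = azimuth, inclination = inclination,
    curvature = curvature, len = length, width = max_width,
    n_seg = n_seg
  )
}

default_leaf_segments <- function(curvature) {
  max(8L, as.integer(ceiling(max(curvature) * 180 / pi / 10)))
}

# Vectorized mesh builder: all arguments may be length-K vectors; one
# shared segment count. Returns rbind-ed 9-column triangle matrix with
# attribute "leaf" mapping each triangle to its leaf index.
leaf_mesh <- function(base_x, base_y, base_z, azimuth, inclination,
                      curvature, len, width, n_seg = 12L) {
  K <- max(lengths(list(base_x, base_y, base_z, azimuth, inclination,
                        curvature, len, width)))
  rec <- function(v) rep_len(v, K)
  base_x <- rec(base_x); base_y <- rec(base_y); base_z <- rec(base_z)
  az <- rec(azimuth) * pi / 180
  th0 <- rec(inclination) * pi / 180
  cv <- rec(curvature)
  len <- rec(len)
  width <- rec(width)
  u <- seq(0, 1, length.out = n_seg + 1L)          # arc-length fraction

  # closed-form arc integrals; series limit at curvature -> 0
  th <- sweep(outer(-cv, u), 1, th0, `+`)           # th0 - cv * u, K x (n+1)
  small <- cv < 1e-9
  horiz <- matrix(0, K, n_seg + 1L)
  vert <- matrix(0, K, n_seg + 1L)
  if (any(!small)) {
    i <- which(!small)
    horiz[i, ] <- (sin(th0[i]) - sin(th[i, , drop = FALSE])) * (len[i] / cv[i])
    vert[i, ] <- (cos(th[i, , drop = FALSE]) - cos(th0[i])) * (len[i] / cv[i])
  }
  if (any(small)) {
    i <- which(small)
    horiz[i, ] <- outer(len[i] * cos(th0[i]), u)
    vert[i, ] <- outer(len[i] * sin(th0[i]), u)
  }

  mx <- base_x + horiz * cos(az)
  my <- base_y + horiz * sin(az)
  mz <- base_z + vert

  prof <- ifelse(u <= 0.3, u / 0.3, (1 - u) / 0.7)
  hw <- outer(width / 2, prof)                      # half width, K x (n+1)
  ex <- -sin(az)
  ey <- cos(az)
  lx <- mx - hw * ex; ly <- my - hw * ey
  rx <- mx + hw * ex; ry <- my + hw * ey

  i0 <- seq_len(n_seg)        # segment start column
  i1 <- i0 + 1L
  # triangle 1: (L_i, R_i, L_{i+1}); triangle 2: (R_i, R_{i+1}, L_{i+1})
  t1 <- cbind(
    as.vector(lx[, i0]), as.vector(ly[, i0]), as.vector(mz[, i0]),
    as.vector(rx[, i0]), as.vector(ry[, i0]), as.vector(mz[, i0]),
    as.vector(lx[, i1]), as.vector(ly[, i1]), as.vector(mz[, i1])
  )
  t2 <- cbind(
    as.vector(rx[, i0]), as.vector(ry[, i0]), as.vector(mz[, i0]),
    as.vector(rx[, i1]), as.vector(ry[, i1]), as.vector(mz[, i1]),
    as.vector(lx[, i1]), as.vector(ly[, i1]), as.vector(mz[, i1])
  )
  tri <- rbind(t1, t2)
  leaf_id <- rep(rep(seq_len(K), times = n_seg), 2L)
  ord <- order(leaf_id)
  tri <- tri[ord, , drop = FALSE]
  attr(tri, "leaf") <- leaf_id[ord]
  tri
}

#' Build a 3D canopy scene from one parameter point
#'
#' Places plants on a regular row grid (rows `row_spacing` apart,
#' within-row positions set so the realized plant count equals
#' `round(plant_density * plot area)`, plus seeded uniform jitter),
#' spawns `tillers_per_plant x leaves_per_tiller` leaf blades per plant
#' via the arc-midrib leaf model, and attaches a background descriptor:
#' flat specular light-gray water for rice, mottled soil for wheat.
#' Growth stage `g` of `n_stages` scales organ counts and sizes by
#' `g / n_stages`, so scene leaf area is non-decreasing in stage.
#' Deterministic given `params$seed`.
#'
#' @param params A one-row data frame or named list with the canopy
#'   parameters (see [sample_parameter_space()] for the fields) plus
#'   `growth_stage`, `n_stages` and `seed`.
#' @param plot_extent Length-2 plot size in metres, centred on the
#'   origin.
#' @param detail Segments per leaf midrib; lower values give a
#'   lower-fidelity (faster) mesh.
#' @param background Optional override: `"soil"` or `"water"`
#'   (defaults follow the crop: water for rice, soil for wheat).
#' @return A `canopy_scene`: triangle primitives (all tagged green
#'   vegetation), per-triangle colours, a background descriptor and the
#'   plot extent.
#' @examples
#' p <- list(crop = "wheat", plant_density = 50, row_spacing = 0.15,
#'           plant_jitter = 0.01, tillers_per_plant = 2,
#'           leaves_per_tiller = 3, leaf_length = 0.15,
#'           leaf_max_width = 0.008, leaf_inclination = 55,
#'           leaf_curvature = 1, plant_height = 0.3,
#'           green_hue = 0.5, green_sat = 0.6,
#'           growth_stage = 4, n_stages = 4, seed = 7)
#' sc <- build_canopy(p)
#' sc
#' @export
build_canopy <- function(params, plot_extent = c(2, 2), detail = 12L,
                         background = NULL) {
  p <- as.list(params)
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) abort("`params` must describe a single parameter point")
    p <- lapply(params, `[[`, 1L)
  }
  need <- c("crop", "plant_density", "row_spacing", "tillers_per_plant",
            "leaves_per_tiller", "leaf_length", "leaf_max_width",
            "leaf_inclination", "leaf_curvature", "plant_height")
  miss <- setdiff(need, names(p))
  if (length(miss)) abort(paste("missing canopy parameters:", paste(miss, collapse = ", ")))
  p$plant_jitter <- p$plant_jitter %||% 0
  p$green_hue <- p$green_hue %||% 0.5
  p$green_sat <- p$green_sat %||% 0.6
  p$growth_stage <- p$growth_stage %||% p$n_stages %||% 1
  p$n_stages <- p$n_stages %||% max(1, p$growth_stage)
  p$seed <- p$seed %||% 1L
  for (f in c("plant_density", "row_spacing", "tillers_per_plant",
              "leaves_per_tiller", "leaf_length", "leaf_max_width",
              "plant_height")) {
    if (p[[f]] < 0) abort(sprintf("`%s` must be >= 0", f))
  }
  if (p$row_spacing <= 0 || p$leaf_length <= 0 || p$leaf_max_width <= 0) {
    abort("row_spacing, leaf_length and leaf_max_width must be > 0")
  }
  if (p$leaf_inclination < 0 || p$leaf_inclination > 90) {
    abort("leaf_inclination must lie in [0, 90] degrees")
  }
  if (p$leaf_curvature < 0 || p$plant_jitter < 0) {
    abort("leaf_curvature and plant_jitter must be >= 0")
  }
  bg_type <- background %||% if (p$crop == "rice") "water" else "soil"
  bg <- if (bg_type == "water") {
    list(type = "water", base_gray = 0.72, specular_strength = 0.55,
         shininess = 120)
  } else {
    list(type = "soil", albedo = c(0.46, 0.34, 0.21),
         noise_scales = c(30, 140))
  }

  ex <- plot_extent[1]
  ey <- plot_extent[2]
  stage_f <- p$growth_stage / p$n_stages
  if (stage_f <= 0 || p$growth_stage > p$n_stages) {
    abort("growth_stage must lie in [1, n_stages]")
  }
  n_total <- round(p$plant_density * ex * ey)
  empty <- function() {
    structure(list(
      primitives = matrix(numeric(), 0, 9),
      colors = matrix(numeric(), 0, 3),
      organ_class = character(0),
      background = bg, plot_extent = plot_extent, params = p
    ), class = "canopy_scene")
  }
  if (n_total < 1) return(empty())

  tillers <- max(1L, as.integer(round(p$tillers_per_plant * stage_f)))
  leaves <- max(1L, as.integer(round(p$leaves_per_tiller * stage_f)))
  size_f <- 0.45 + 0.55 * stage_f
  len0 <- p$leaf_length * size_f
  wid0 <- p$leaf_max_width * size_f
  hgt0 <- p$plant_height * size_f

  with_seed(p$seed, {
    # row grid, centred on the origin
    n_rows <- max(1L, floor(ex / p$row_spacing))
    row_x <- (seq_len(n_rows) - (n_rows + 1) / 2) * p$row_spacing
    per_row <- rep(n_total %/% n_rows, n_rows)
    extra <- n_total %% n_rows
    if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L
    px <- rep(row_x, per_row)
    py <- unlist(lapply(per_row, function(k) {
      if (k == 0) numeric(0) else (seq_len(k) - 0.5) / k * ey - ey / 2
    }))
    px <- px + runif(n_total, -p$plant_jitter, p$plant_jitter)
    py <- py + runif(n_total, -p$plant_jitter, p$plant_jitter)

    n_leaves <- n_total * tillers * leaves
    plant_of <- rep(seq_len(n_total), each = tillers * leaves)
    tiller_of <- rep(rep(seq_len(tillers), each = leaves), times = n_total)
    rank_of <- rep(seq_len(leaves), times = n_total * tillers)

    # tillers fan out around the plant centre
    tiller_az <- runif(n_total * tillers, 0, 360)
    tiller_az_leaf <- rep(tiller_az, each = leaves)
    tiller_r <- 0.012
    bx <- px[plant_of] + tiller_r * cos(tiller_az_leaf * pi / 180)
    by <- py[plant_of] + tiller_r * sin(tiller_az_leaf * pi / 180)
    bz <- hgt0 * (0.05 + 0.30 * (rank_of - 1) / max(1, leaves))

    # leaf headings: golden-angle fan per tiller + jitter
    az <- (tiller_az_leaf + 137.5 * rank_of + runif(n_leaves, -25, 25)) %% 360
    incl <- pmin(89, pmax(5, p$leaf_inclination + rnorm(n_leaves, 0, 6)))
    cv <- pmax(0, p$leaf_curvature * runif(n_leaves, 0.7, 1.3))
    len <- len0 * runif(n_leaves, 0.8, 1.2)
    wid <- wid0 * runif(n_leaves, 0.85, 1.15)

    n_seg <- max(8L, as.integer(detail), default_leaf_segments(stats::quantile(cv, 0.9)))
    tri <- leaf_mesh(bx, by, bz, az, incl, cv, len, wid, n_seg = n_seg)
    leaf_id <- attr(tri, "leaf")

    # per-leaf colour: base green from the hue/sat scalars + seeded jitter
    base_hsv <- c(h = 0.21 + 0.12 * p$green_hue,
                  s = 0.45 + 0.50 * p$green_sat,
                  v = 0.55)
    hj <- base_hsv["h"] + runif(n_leaves, -0.02, 0.02)
    vj <- base_hsv["v"] * runif(n_leaves, 0.82, 1.12)
    cols <- t(grDevices::col2rgb(grDevices::hsv(hj, base_hsv["s"], pmin(1, vj)))) / 255
    colors <- cols[leaf_id, , drop = FALSE]

    structure(list(
      primitives = unname(tri[, , drop = FALSE]),
      colors = unname(colors),
      organ_class = rep("green_vegetation", nrow(tri)),
      background = bg, plot_extent = plot_extent, params = p
    ), class = "canopy_scene")
  })
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene: %d triangles, %s background, plot %.2g x %.2g m>\n",
              nrow(x$primitives), x$background$type,
              x$plot_extent[1], x$plot_extent[2]))
  invisible(x)
}

#' Total one-sided leaf area of a scene
#'
#' @param scene A `canopy_scene`.
#' @return Area in square metres.
#' @export
scene_leaf_area <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  tri <- scene$primitives
  if (nrow(tri) == 0) return(0)
  ux <- tri[, 4] - tri[, 1]; uy <- tri[, 5] - tri[, 2]; uz <- tri[, 6] - tri[, 3]
  vx <- tri[, 7] - tri[, 1]; vy <- tri[, 8] - tri[, 2]; vz <- tri[, 9] - tri[, 3]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Serialize a scene to a JSON mesh
#'
#' Writes triangles, organ tags, colours and the background descriptor
#' to a documented JSON layout for external inspection, and reads it
#' back.
#'
#' @param scene A `canopy_scene`.
#' @param path Output `.json` path.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "canopy_scene"))
  obj <- list(
    plot_extent = scene$plot_extent,
    background = scene$background,
    organ_class = scene$organ_class,
    colors = scene$colors,
    triangles = scene$primitives
  )
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tri <- obj$triangles
  if (is.null(dim(tri))) tri <- matrix(tri, ncol = 9)
  structure(list(
    primitives = matrix(as.numeric(tri), ncol = 9),
    colors = matrix(as.numeric(obj$colors), ncol = 3),
    organ_class = as.character(obj$organ_class),
    background = obj$background,
    plot_extent = as.numeric(obj$plot_extent),
    params = NULL
  ), class = "canopy_scene")
}
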