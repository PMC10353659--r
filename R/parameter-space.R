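#' Define a canopy simulation parameter space
#'
#' A parameter space is the set of structural and colour dimensions a
#' canopy is drawn from, together with the crop it describes and the
#' number of discrete growth stages it is paired with downstream. Each
#' dimension has a name, a lower and upper bound and a sampling scale
#' (`"linear"` or `"log"`).
#'
#' The default dimensions describe a transplanted paddy-rice stand
#' (sparse hills, long drooping leaves, flat water background) or a
#' drilled wheat stand (dense rows, shorter more erect leaves, soil
#' background). Ranges were fixed once to emulate ground-based canopy
#' photography: sensor about 1.5 m above the canopy, plants resolved at
#' a few millimetres per pixel. They are deliberately coarse — the goal
#' is structural diversity, not agronomic prediction — and can be
#' overridden or extended through `dims` or a YAML/JSON config (see
#' [read_parameter_space()]).
#'
#' @param crop `"rice"` or `"wheat"`.
#' @param n_stages Number of growth stages the samples are paired with
#'   (integer, >= 1). Stage `g` scales organ counts and sizes by
#'   `g / n_stages`, so leaf area is non-decreasing in stage.
#' @param dims Optional tibble/data frame with columns `name`, `lower`,
#'   `upper`, `scale` replacing the crop default.
#' @return An object of class `parameter_space`.
#' @examples
#' sp <- parameter_space("rice", n_stages = 4)
#' sample_parameter_space(sp, n = 3, seed = 1)
#' @export
parameter_space <- function(crop = c("rice", "wheat"), n_stages = 4L, dims = NULL) {
  crop <- match.arg(crop)
  if (!is.numeric(n_stages) || length(n_stages) != 1L || n_stages < 1 ||
      n_stages != round(n_stages)) {
    abort("`n_stages` must be a single integer >= 1.")
  }
  if (is.null(dims)) dims <- default_dims(crop)
  dims <- as_tibble(dims)
  validate_dims(dims)
  structure(
    list(crop = crop, n_stages = as.integer(n_stages), dims = dims),
    class = "parameter_space"
  )
}

default_dims <- function(crop) {
  if (crop == "rice") {
    tribble_dims(
      "plant_density",    14,   33,   "linear",  # hills m^-2 (transplanted)
      "row_spacing",      0.20, 0.33, "linear",  # m
      "plant_jitter",     0.00, 0.04, "linear",  # m
      "tillers_per_plant", 3,   12,   "linear",
      "leaves_per_tiller", 3,   6,    "linear",
      "leaf_length",      0.25, 0.60, "linear",  # m
      "leaf_max_width",   0.007, 0.016, "linear", # m
      "leaf_inclination", 35,   80,   "linear",  # deg above horizontal
      "leaf_curvature",   0.3,  2.8,  "linear",  # total droop, radians
      "plant_height",     0.35, 1.00, "linear",  # m
      "green_hue",        0,    1,    "linear",
      "green_sat",        0,    1,    "linear"
    )
  } else {
    tribble_dims(
      "plant_density",    120,  320,  "linear",  # plants m^-2 (drilled)
      "row_spacing",      0.12, 0.20, "linear",
      "plant_jitter",     0.00, 0.02, "linear",
      "tillers_per_plant", 1,   4,    "linear",
      "leaves_per_tiller", 2,   5,    "linear",
      "leaf_length",      0.10, 0.30, "linear",
      "leaf_max_width",   0.004, 0.012, "linear",
      "leaf_inclination", 30,   75,   "linear",
      "leaf_curvature",   0.2,  2.0,  "linear",
      "plant_height",     0.12, 0.60, "linear",
      "green_hue",        0,    1,    "linear",
      "green_sat",        0,    1,    "linear"
    )
  }
}

tribble_dims <- function(...) {
  v <- list(...)
  stopifnot(length(v) %% 4 == 0)
  idx <- seq(1, length(v), by = 4)
  tibble(
    name = vapply(idx, function(i) v[[i]], character(1)),
    lower = vapply(idx, function(i) as.numeric(v[[i + 1]]), numeric(1)),
    upper = vapply(idx, function(i) as.numeric(v[[i + 2]]), numeric(1)),
    scale = vapply(idx, function(i) v[[i + 3]], character(1))
  )
}

validate_dims <- function(dims) {
  need <- c("name", "lower", "upper", "scale")
  if (!all(need %in% names(dims))) {
    abort("`dims` needs columns name, lower, upper, scale.")
  }
  if (anyDuplicated(dims$name)) abort("dimension names must be unique")
  if (!all(dims$lower < dims$upper)) abort("every dimension needs lower < upper")
  if (!all(dims$scale %in% c("linear", "log"))) {
    abort('dimension `scale` must be "linear" or "log"')
  }
  if (any(dims$scale == "log" & dims$lower <= 0)) {
    abort("log-scaled dimensions need a positive lower bound")
  }
  invisible(dims)
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space: %s, %d dims, %d growth stages>\n",
              x$crop, nrow(x$dims), x$n_stages))
  print(x$dims)
  invisible(x)
}

#' Read / write a parameter space config
#'
#' Parameter spaces serialize to YAML (or JSON) with fields `crop`,
#' `n_stages` and a `dims` table, so a simulation run is fully
#' reproducible from its config file.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return A `parameter_space`.
#' @export
read_parameter_space <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  dims <- if (is.data.frame(cfg$dims)) cfg$dims else dplyr::bind_rows(cfg$dims)
  parameter_space(crop = cfg$crop, n_stages = cfg$n_stages %||% 4L, dims = dims)
}

#' @param space A `parameter_space`.
#' @rdname read_parameter_space
#' @export
write_parameter_space <- function(space, path) {
  stopifnot(inherits(space, "parameter_space"))
  obj <- list(crop = space$crop, n_stages = space$n_stages,
              dims = as.data.frame(space$dims))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Latin-hypercube sample of a parameter space
#'
#' Draws `n` parameter points by Latin-hypercube sampling: for every
#' dimension the `n` points occupy the `n` equal-probability strata of
#' its range with exactly one point per stratum. Sampling is
#' deterministic given `seed` and does not disturb the caller's RNG
#' stream. Stratification is delegated to [lhs::randomLHS()]; the unit
#' hypercube is then mapped to each dimension's range on its linear or
#' log scale.
#'
#' Growth stages are not part of the hypercube: pair each sampled point
#' with every stage via [with_growth_stages()], mirroring a design in
#' which one structural draw is observed at several stages.
#'
#' @param space A [parameter_space()].
#' @param n Number of points (>= 0).
#' @param seed Integer seed.
#' @return A tibble with one row per point: `sample_id`, `crop`, and one
#'   column per dimension.
#' @examples
#' sp <- parameter_space("wheat")
#' pts <- sample_parameter_space(sp, 5, seed = 42)
#' nrow(with_growth_stages(pts, n_stages = 4))  # 20 scene specs
#' @export
sample_parameter_space <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "parameter_space"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    abort("`n` must be a single integer >= 0.")
  }
  n <- as.integer(n)
  k <- nrow(space$dims)
  if (n == 0L) {
    empty <- c(list(sample_id = integer(), crop = character()),
               setNames(rep(list(numeric()), k), space$dims$name))
    return(as_tibble(empty))
  }
  u <- with_seed(seed, lhs::randomLHS(n, k))
  vals <- lapply(seq_len(k), function(j) {
    lo <- space$dims$lower[j]
    hi <- space$dims$upper[j]
    if (space$dims$scale[j] == "log") {
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      lo + u[, j] * (hi - lo)
    }
  })
  out <- c(list(sample_id = seq_len(n), crop = rep(space$crop, n)),
           setNames(vals, space$dims$name))
  as_tibble(out)
}

#' Pair parameter points with growth stages
#'
#' Replicates every sampled parameter point across `n_stages` discrete
#' growth stages and derives a per-scene seed, producing the full table
#' of scene specifications (`n` points x `n_stages` stages).
#'
#' @param params Tibble from [sample_parameter_space()].
#' @param n_stages Number of growth stages (>= 1).
#' @param base_seed Seed the per-scene seeds are derived from.
#' @return A tibble with added `growth_stage`, `n_stages` and `seed`
#'   columns, one row per scene.
#' @export
with_growth_stages <- function(params, n_stages = 4L, base_seed = 1L) {
  if (n_stages < 1 || n_stages != round(n_stages)) {
    abort("`n_stages` must be an integer >= 1.")
  }
  out <- tidyr::crossing(params, growth_stage = seq_len(n_stages))
  out$n_stages <- as.integer(n_stages)
  out$seed <- derive_seed(base_seed, out$sample_id * 31L + out$growth_stage)
  dplyr::arrange(out, .data$sample_id, .data$growth_stage)
}

# Deterministic seed fan-out, kept below 2^31.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
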