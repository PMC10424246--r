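#' Read a fluid/jet configuration from YAML or JSON
#'
#' Configuration files carry the fields of [fluid_jet_spec()]. Each field is
#' either a bare number (interpreted as SI) or a mapping with `value` and
#' `unit`, e.g. `viscosity: {value: 1.0, unit: mPa.s}`. Supported lab units:
#'
#' * viscosity: `Pa.s`, `mPa.s`, `cP`
#' * surface tension: `N/m`, `mN/m`, `dyn/cm`
#' * density: `kg/m3`, `g/ml`, `g/cm3`
#' * lengths: `m`, `mm`, `um`
#' * velocity: `m/s`, `mm/s`
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [fluid_jet_spec()].
#' @export
read_fluid_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported spec format: .", ext, " (use YAML or JSON)"))
  fields <- c("viscosity", "surface_tension", "density", "orifice_diameter",
              "droplet_velocity", "gravity")
  missing <- setdiff(c("viscosity", "surface_tension", "density",
                       "orifice_diameter"), names(raw))
  if (length(missing))
    stop("spec file missing required field(s): ",
         paste(missing, collapse = ", "))
  args <- list()
  for (f in intersect(fields, names(raw)))
    args[[f]] <- .to_si(f, raw[[f]])
  do.call(fluid_jet_spec, args)
}

.unit_factors <- list(
  viscosity = c("Pa.s" = 1, "mPa.s" = 1e-3, "cP" = 1e-3),
  surface_tension = c("N/m" = 1, "mN/m" = 1e-3, "dyn/cm" = 1e-3),
  density = c("kg/m3" = 1, "g/ml" = 1000, "g/cm3" = 1000),
  orifice_diameter = c("m" = 1, "mm" = 1e-3, "um" = 1e-6),
  droplet_velocity = c("m/s" = 1, "mm/s" = 1e-3),
  gravity = c("m/s2" = 1)
)

.to_si <- function(field, x) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.list(x) && !is.null(x$value)) {
    if (is.null(x$unit)) return(as.numeric(x$value))
    fac <- .unit_factors[[field]]
    if (!(x$unit %in% names(fac)))
      stop(sprintf("unknown unit '%s' for field '%s'", x$unit, field))
    return(as.numeric(x$value) * fac[[x$unit]])
  }
  stop("field '", field, "' must be a number or a {value, unit} mapping")
}

#' Read / write a single-channel T x H x W TIFF stack
#'
#' Stacks are stored as multi-page TIFF with 16-bit samples. Intensities are
#' scaled to the stack's full range on write; the original range is recorded
#' in a `<path>.meta.json` sidecar and restored on read, so the round trip
#' is faithful up to 16-bit quantization.
#'
#' @param stack numeric array with `dim = c(T, H, W)`.
#' @param path output file path.
#' @return `write_stack_tiff()`: the path, invisibly. `read_stack_tiff()`:
#'   a T x H x W array.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("'stack' must be a T x H x W array")
  rng <- range(stack)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  frames <- lapply(seq_len(dim(stack)[1]), function(i) {
    (stack[i, , , drop = TRUE] - rng[1]) / span
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  if (any(vapply(frames, function(f) !identical(dim(f), d), logical(1))))
    stop("non-uniform stack: frames differ in size")
  stack <- array(0, dim = c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) stack[i, , ] <- frames[[i]]
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    if (is.finite(meta$min) && is.finite(meta$max))
      stack <- stack * (meta$max - meta$min) + meta$min
  }
  stack
}

#' Write a single-frame image as TIFF
#' @param image numeric H x W matrix.
#' @inheritParams write_stack_tiff
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (!is.matrix(image)) stop("'image' must be an H x W matrix")
  write_stack_tiff(array(image, dim = c(1L, nrow(image), ncol(image))), path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  stack <- read_stack_tiff(path)
  stack[1, , , drop = TRUE]
}

#' Write ground-truth metadata next to a generated dataset
#'
#' Every synthetic dataset carries a `ground_truth` list (generator name,
#' parameters, seed). This serializes it as JSON so the dataset on disk is
#' self-describing and regeneration can be verified.
#'
#' @param ground_truth a ground-truth list as attached by the `gen_*`
#'   generators.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
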