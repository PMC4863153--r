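#' Voxel phantom
#'
#' A 3D grid of material indices with a per-voxel density scaling. Voxel
#' `(i, j, k)` occupies the half-open box
#' `[(i-1) dx, i dx) x [(j-1) dy, j dy) x [(k-1) dz, k dz)` in phantom
#' coordinates (mm); the beam axis is +z.
#'
#' @param material_index integer 3D array of indices into `materials`.
#' @param density_scale 3D array of positive multipliers on the nominal
#'   material density (same dim as `material_index`), default 1.
#' @param materials named list of [material()] objects.
#' @param spacing voxel spacing in mm, scalar or length-3 `(dx, dy, dz)`.
#' @return An object of class `voxel_phantom` with fields `shape`,
#'   `spacing`, `material_index`, `density_scale`, `materials`.
#' @export
voxel_phantom <- function(material_index, density_scale = NULL, materials, spacing) {
  stopifnot(length(dim(material_index)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (is.null(density_scale))
    density_scale <- array(1, dim = dim(material_index))
  stopifnot(identical(dim(density_scale), dim(material_index)),
            all(density_scale > 0))
  if (any(material_index < 1 | material_index > length(materials)))
    stop("voxel references an undefined material")
  structure(list(shape = dim(material_index), spacing = as.numeric(spacing),
                 material_index = material_index,
                 density_scale = density_scale, materials = materials),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("voxel_phantom:", paste(x$shape, collapse = " x "), "voxels,",
      paste(x$spacing, collapse = " x "), "mm spacing,",
      length(x$materials), "materials\n")
  invisible(x)
}

#' Layered slab phantom along the beam axis
#'
#' Builds a phantom of homogeneous transverse slabs stacked along +z,
#' e.g. water / bone / water. Thicknesses are rounded to the voxel grid
#' (each layer occupies `round(thickness / dz)` slices; the realized total
#' length is the sum of the rounded layers).
#'
#' @param layers list of `list(material = <name or material>, thickness = mm)`.
#' @param cross_section transverse extent in mm (scalar; the phantom is
#'   square in x/y).
#' @param spacing voxel spacing in mm (scalar or length-3).
#' @return A `voxel_phantom`.
#' @examples
#' ph <- make_slab_phantom(list(list(material = "water", thickness = 50)),
#'                         cross_section = 10, spacing = 1)
#' ph$shape
#' @export
make_slab_phantom <- function(layers, cross_section = 100, spacing = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  builtin <- .builtin_materials()
  mats <- list(); idx <- integer(0)
  n_slices <- integer(length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (is.null(ly$thickness) || ly$thickness <= 0)
      stop("layer ", i, " has non-positive thickness")
    m <- ly$material
    if (is.character(m)) {
      if (!m %in% names(builtin)) stop("unknown material name: ", m)
      m <- builtin[[m]]
    }
    stopifnot(inherits(m, "material"))
    if (is.null(mats[[m$name]])) mats[[m$name]] <- m
    n_slices[i] <- max(1L, as.integer(round(ly$thickness / spacing[3])))
    idx <- c(idx, rep(match(m$name, names(mats)), n_slices[i]))
  }
  nx <- max(1L, as.integer(round(cross_section / spacing[1])))
  ny <- max(1L, as.integer(round(cross_section / spacing[2])))
  nz <- length(idx)
  mi <- array(rep(idx, each = nx * ny), dim = c(nx, ny, nz))
  voxel_phantom(mi, materials = mats, spacing = spacing)
}

#' Write / read a phantom as raw array + JSON sidecar
#'
#' The grid is stored as a little-endian binary array of HU-independent
#' material indices and density scales, with a JSON header describing
#' shape, spacing, dtype and the material names.
#'
#' @param phantom a `voxel_phantom`.
#' @param path basename; writes `<path>.raw` and `<path>.json`.
#' @return `write_phantom` the path (invisibly); `read_phantom` a
#'   `voxel_phantom` (materials rebuilt from the built-in registry or the
#'   default HU calibration by name).
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(phantom$material_index), con, size = 4, endian = "little")
  writeBin(as.numeric(phantom$density_scale), con, size = 8, endian = "little")
  header <- list(shape = phantom$shape, spacing_mm = phantom$spacing,
                 dtype = c("int32", "float64"), order = "column-major",
                 materials = names(phantom$materials))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(header$shape)
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  mi <- readBin(con, "integer", n = n, size = 4, endian = "little")
  ds <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  builtin <- .builtin_materials()
  mats <- lapply(header$materials, function(nm) {
    if (!is.null(builtin[[nm]])) return(builtin[[nm]])
    cal <- build_default_calibration()
    if (!is.null(cal$materials[[nm]])) return(cal$materials[[nm]])
    stop("unknown material in phantom file: ", nm)
  })
  names(mats) <- header$materials
  voxel_phantom(array(mi, dim = header$shape), array(ds, dim = header$shape),
                mats, header$spacing_mm)
}
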