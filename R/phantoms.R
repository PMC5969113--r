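#' Voxelized phantom grids
#'
#' A `phantom_grid` is a 3-D array of material labels (stored as indices
#' into a materials table) with voxel spacing and origin. Geometry
#' convention: the beam travels along +z and enters at the grid front face
#' z = 0; the magnetic field points along +x; voxel centers are at
#' `origin + (index - 1) * spacing`. The default region of interest is a
#' crop of the full 400 mm cube around the beam and its bending plane
#' (x in \[-40, 40], y in \[-60, 160], z in \[0, 400], 1 mm voxels), chosen
#' so that a 240 MeV beam bent by a 3 T field stays inside; the full cube
#' is available via `extent`.
#'
#' @param material fill material name.
#' @param extent list or matrix of axis ranges in mm:
#'   `list(x = c(lo, hi), y = ..., z = ...)`.
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @return object of class `phantom_grid` with elements `labels` (integer
#'   3-D array), `materials` (data.frame snapshot of the registry rows
#'   used), `spacing`, `origin`.
#' @examples
#' ph <- build_homogeneous("water", extent = list(x = c(-20, 20),
#'   y = c(-20, 20), z = c(0, 100)))
#' dim(ph$labels)
#' @export
build_homogeneous <- function(material = "water", extent = default_extent(),
                              spacing = 1) {
  g <- .empty_grid(extent, spacing, material)
  g
}

#' @rdname build_homogeneous
#' @export
default_extent <- function() {
  list(x = c(-40, 40), y = c(-60, 160), z = c(0, 400))
}

.empty_grid <- function(extent, spacing, fill = "water") {
  spacing <- rep(spacing, length.out = 3)
  n <- vapply(seq_len(3), function(a) {
    rng <- extent[[a]]
    as.integer(round(diff(rng) / spacing[a]))
  }, integer(1))
  stopifnot(all(n >= 1))
  origin <- vapply(seq_len(3), function(a) extent[[a]][1] + spacing[a] / 2,
                   numeric(1))
  mats <- material_registry()
  idx <- match(fill, mats$name)
  if (is.na(idx)) stop("unknown material '", fill, "'", call. = FALSE)
  labels <- array(idx, dim = n)
  structure(list(labels = labels, materials = mats,
                 spacing = spacing, origin = origin),
            class = "phantom_grid")
}

#' Voxel center coordinates along one axis
#' @param phantom a `phantom_grid` or `dose_grid`.
#' @param axis 1 = x, 2 = y, 3 = z.
#' @return numeric vector of voxel centers (mm).
#' @export
voxel_centers <- function(phantom, axis) {
  n <- dim(phantom$labels %||% phantom$values)[axis]
  phantom$origin[axis] + (seq_len(n) - 1) * phantom$spacing[axis]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Entrance-region slab sandwich phantom
#'
#' Alternating 20-mm slabs of water with adipose, bone and air in the
#' entrance region along z (fixed documented order:
#' water 0-20, adipose 20-40, water 40-60, bone 60-80, water 80-100,
#' air 100-120 mm; water beyond), used to probe boundary effects on the
#' depth-dose and lateral profiles.
#'
#' @inheritParams build_homogeneous
#' @param slabs optional override: character vector of six 20-mm slab
#'   materials for z in \[0, 120].
#' @export
build_slab_sandwich <- function(extent = default_extent(), spacing = 1,
                                slabs = c("water", "adipose", "water",
                                          "bone", "water", "air")) {
  stopifnot(length(slabs) == 6L)
  g <- .empty_grid(extent, spacing, "water")
  z <- voxel_centers(g, 3)
  for (i in seq_along(slabs)) {
    idx <- match(slabs[i], g$materials$name)
    if (is.na(idx)) stop("unknown material '", slabs[i], "'", call. = FALSE)
    sel <- z > (i - 1) * 20 & z < i * 20
    if (any(sel)) g$labels[, , sel] <- idx
  }
  g
}

#' Opposing lateral bone/air slab phantom
#'
#' Two opposing 20-mm-thick slabs inserted at 20 mm depth in water,
#' splitting the bending plane: bone occupies y > 0 (the side the beam
#' bends toward) and air y < 0, for z in \[20, 40] mm. A beam centered at
#' y = 0 samples both materials, producing the double Bragg structure that
#' stresses subbeam splitting and center shifting.
#'
#' @inheritParams build_homogeneous
#' @param bone_side `"+y"` (default) or `"-y"`.
#' @export
build_lateral_opposing <- function(extent = default_extent(), spacing = 1,
                                   bone_side = c("+y", "-y")) {
  bone_side <- match.arg(bone_side)
  g <- .empty_grid(extent, spacing, "water")
  y <- voxel_centers(g, 2)
  z <- voxel_centers(g, 3)
  zi <- z > 20 & z < 40
  bone <- match("bone", g$materials$name)
  air <- match("air", g$materials$name)
  pos <- if (bone_side == "+y") bone else air
  neg <- if (bone_side == "+y") air else bone
  g$labels[, y > 0, zi] <- pos
  g$labels[, y < 0, zi] <- neg
  g
}

#' Material label at a position (nearest voxel, clamped to the grid)
#' @param phantom a `phantom_grid`.
#' @param x,y,z coordinates (mm), scalars.
#' @return material name.
#' @export
phantom_label_at <- function(phantom, x, y, z) {
  d <- dim(phantom$labels)
  i <- pmin(pmax(1L, as.integer(round((c(x, y, z) - phantom$origin) /
                                        phantom$spacing)) + 1L), d)
  phantom$materials$name[phantom$labels[i[1], i[2], i[3]]]
}

#' Per-voxel mass of a phantom
#' @param phantom a `phantom_grid`.
#' @return 3-D array of voxel masses (g).
#' @export
mass_per_voxel <- function(phantom) {
  vol_cm3 <- prod(phantom$spacing) / 1000
  rho <- phantom$materials$rho[phantom$labels]
  array(rho * vol_cm3, dim = dim(phantom$labels))
}

#' @export
print.phantom_grid <- function(x, ...) {
  d <- dim(x$labels)
  used <- sort(unique(as.vector(x$labels)))
  cat(sprintf("phantom_grid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x")))
  cat("  materials:", paste(x$materials$name[used], collapse = ", "), "\n")
  invisible(x)
}

# ---- dose grids -----------------------------------------------------------

#' Construct a dose grid
#'
#' A `dose_grid` carries a 3-D array of deposited energy (MeV, summed over
#' all simulated histories or per pencil beam for analytic results) on the
#' same geometry as its phantom, plus bookkeeping (number of histories,
#' energy-conservation totals).
#'
#' @param values 3-D array of deposited energy (MeV).
#' @param phantom the `phantom_grid` the energy was scored on.
#' @param n_histories number of histories the values sum over (1 for
#'   analytic pencil-beam output).
#' @param totals optional list of energy-accounting totals.
#' @param meta optional list of provenance (seed, config).
#' @export
dose_grid <- function(values, phantom, n_histories = 1, totals = NULL,
                      meta = NULL) {
  stopifnot(all(dim(values) == dim(phantom$labels)))
  structure(list(values = values, spacing = phantom$spacing,
                 origin = phantom$origin, phantom = phantom,
                 n_histories = n_histories, totals = totals, meta = meta),
            class = "dose_grid")
}

#' Dose values (MeV/g per history) of a dose grid
#' @param grid a `dose_grid`.
#' @return 3-D array of dose per history.
#' @export
dose_values <- function(grid) {
  grid$values / mass_per_voxel(grid$phantom) / grid$n_histories
}

#' Project a dose grid onto a coordinate plane
#'
#' Energy-deposition maps summed over one transverse axis, per history:
#' `"yz"` sums over x (the map in the bending plane), `"xz"` sums over y.
#'
#' @param grid a `dose_grid`.
#' @param plane `"yz"` or `"xz"`.
#' @return matrix (rows = lateral coordinate, cols = depth) with attributes
#'   `lat` (lateral voxel centers) and `z` (depth voxel centers).
#' @export
project_grid <- function(grid, plane = c("yz", "xz")) {
  plane <- match.arg(plane)
  m <- if (plane == "yz") apply(grid$values, c(2, 3), sum)
       else apply(grid$values, c(1, 3), sum)
  m <- m / grid$n_histories
  attr(m, "lat") <- voxel_centers(grid, if (plane == "yz") 2 else 1)
  attr(m, "z") <- voxel_centers(grid, 3)
  m
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dose_grid: %d x %d x %d voxels, %g histories, total %.4g MeV\n",
              d[1], d[2], d[3], x$n_histories, sum(x$values)))
  invisible(x)
}

#' Write / read a dose grid as plain text
#'
#' Column-oriented text export (one row per nonzero voxel: indices and
#' energy) with a header of grid geometry; full double precision, exact
#' round trip.
#'
#' @param grid a `dose_grid`.
#' @param path file path.
#' @export
write_dose_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(grid$values)
  writeLines(c(
    sprintf("# dose_grid dims %d %d %d", d[1], d[2], d[3]),
    sprintf("# spacing %s", paste(format(grid$spacing, digits = 17), collapse = " ")),
    sprintf("# origin %s", paste(format(grid$origin, digits = 17), collapse = " ")),
    sprintf("# n_histories %s", format(grid$n_histories, digits = 17)),
    "ix iy iz energy_MeV"), con)
  nz <- which(grid$values != 0)
  if (length(nz)) {
    idx <- arrayInd(nz, d)
    write.table(data.frame(idx[, 1], idx[, 2], idx[, 3],
                           format(grid$values[nz], digits = 17)),
                con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
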