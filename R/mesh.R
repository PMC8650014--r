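#' Triangulated boundary mesh with labelled patches
#'
#' A `surface_mesh` is a watertight triangulated boundary of a flow domain.
#' Every triangle carries a patch label, and the patch table maps each label
#' to a boundary role (`inlet`, `outlet` or `wall`) plus an anatomical region
#' tag and a side (`R`, `L` or `central`). All coordinates are metres.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (m).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param patch character vector, one patch label per triangle.
#' @param patch_table data.frame with columns `patch`, `role`, `region`,
#'   `side`. Exactly one patch may have role `inlet` and one `outlet`.
#' @param sweep optional list of sweep metadata (centerline stations) attached
#'   by the geometry generators; used by the prescribed-flow builders.
#' @param validate logical; run the watertightness/area invariants.
#'
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, patch, patch_table,
                         sweep = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L,
            length(patch) == nrow(triangles))
  patch <- as.character(patch)
  mesh <- structure(
    list(vertices = vertices, triangles = triangles, patch = patch,
         patch_table = patch_table, sweep = sweep),
    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Per-triangle areas of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of triangle areas (m^2).
#' @export
tri_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$triangles
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-patch areas
#' @param mesh a `surface_mesh`.
#' @return named numeric vector, area (m^2) per patch label.
#' @export
patch_areas <- function(mesh) {
  a <- tri_areas(mesh)
  vapply(split(a, mesh$patch), sum, numeric(1))
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return total area (m^2).
#' @export
mesh_area <- function(mesh) sum(tri_areas(mesh))

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume; positive when triangle winding is outward.
#' @param mesh a `surface_mesh`.
#' @return volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6)
}

#' Check that every edge is shared by exactly two triangles
#' @param mesh a `surface_mesh`.
#' @return TRUE if watertight, FALSE otherwise.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$triangles
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

validate_mesh <- function(mesh) {
  a <- tri_areas(mesh)
  if (any(a <= 0)) stop("mesh has degenerate (zero-area) triangles")
  pt <- mesh$patch_table
  if (!all(c("patch", "role", "region", "side") %in% names(pt)))
    stop("patch_table must have columns patch, role, region, side")
  if (!all(mesh$patch %in% pt$patch))
    stop("triangle patch labels missing from patch_table")
  pa <- patch_areas(mesh)
  if (any(pa <= 0)) stop("every patch must have positive area")
  if (abs(sum(pa) - sum(a)) > 1e-12 * sum(a))
    stop("patch areas do not sum to the total surface area")
  roles <- pt$role[match(names(pa), pt$patch)]
  if (sum(roles == "inlet") != 1L || sum(roles == "outlet") != 1L)
    stop("mesh must have exactly one inlet and one outlet patch")
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  invisible(TRUE)
}

#' @export
print.surface_mesh <- function(x, ...) {
  pa <- patch_areas(x)
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles,", length(pa), "patches\n")
  cat(sprintf("  total area %.2f mm^2, volume %.2f mL\n",
              mesh_area(x) * 1e6, mesh_volume(x) * 1e6))
  info <- x$patch_table[match(names(pa), x$patch_table$patch), ]
  for (i in seq_along(pa))
    cat(sprintf("  %-14s %-6s %-12s %8.1f mm^2\n", names(pa)[i],
                info$role[i], info$region[i], pa[i] * 1e6))
  invisible(x)
}

#' Name of the patch with a given boundary role
#' @param mesh a `surface_mesh`.
#' @param role one of "inlet", "outlet".
#' @return patch label.
#' @export
patch_with_role <- function(mesh, role) {
  p <- mesh$patch_table$patch[mesh$patch_table$role == role]
  if (length(p) != 1L) stop("expected exactly one patch with role ", role)
  p
}
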