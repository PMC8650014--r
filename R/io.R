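# File I/O: binary STL and legacy (ASCII) VTK for surfaces, point clouds and
# structured-points grids, plus the patch-table JSON sidecar. These are
# small fixed formats written/read directly; all coordinates are metres.

#' Write a surface mesh as binary STL
#'
#' 80-byte header, uint32 triangle count, then 50 bytes per triangle
#' (normal, three vertices as float32 little-endian, zero attribute).
#' Identical meshes produce byte-identical files.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$triangles
  m <- nrow(F)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c3 <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  dat <- cbind(n, a, b, c3)                      # m x 12
  fl <- writeBin(as.numeric(t(dat)), raw(), size = 4, endian = "little")
  fl <- matrix(fl, nrow = 48L)                   # 48 bytes per triangle
  rec <- rbind(fl, matrix(as.raw(0), 2L, m))     # + uint16 attribute
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "nasoaero binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(m), con, size = 4, endian = "little")
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Returns the triangle soup; with `weld = TRUE`, coincident vertices are
#' merged so watertightness checks can run on the result.
#' @param path STL file path.
#' @param weld merge coincident vertices.
#' @return list with `vertices` and `triangles`.
#' @export
read_stl_binary <- function(path, weld = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), n = 80))
  m <- readBin(con, integer(), size = 4, endian = "little")
  rec <- readBin(con, raw(), n = 50 * m)
  rec <- matrix(rec, nrow = 50L)
  fl <- readBin(as.vector(rec[1:48, ]), numeric(), n = 12L * m, size = 4,
                endian = "little")
  dat <- matrix(fl, ncol = 12L, byrow = TRUE)
  V <- rbind(dat[, 4:6, drop = FALSE], dat[, 7:9, drop = FALSE],
             dat[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * m), ncol = 3L)))
  V <- V[ord, , drop = FALSE]                    # per-triangle vertex order
  F <- matrix(seq_len(3L * m), ncol = 3L, byrow = TRUE)
  if (weld) {
    key <- paste(V[, 1], V[, 2], V[, 3])
    uid <- match(key, unique(key))
    V <- V[!duplicated(key), , drop = FALSE]
    F <- matrix(uid[F], ncol = 3L)
  }
  list(vertices = V, triangles = F)
}

#' Write a surface mesh as legacy VTK polydata
#'
#' ASCII legacy format with POINTS/POLYGONS and the patch id as CELL_DATA.
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$triangles
  plabels <- sort(unique(mesh$patch))
  pid <- match(mesh$patch, plabels) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("surface; patches:", paste(plabels, collapse = " ")),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V))), con)
  writeLines(apply(format(V, digits = 17, scientific = TRUE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)), con)
  writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(F)),
               "SCALARS patch_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(pid), con)
  invisible(path)
}

#' Write a deposited-parcel cloud as legacy VTK polydata
#'
#' Vertices-only polydata with per-point scalars (diameter, deposit time,
#' patch id).
#' @param result a `simulation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtk_parcels <- function(result, path) {
  p <- result$parcels[result$parcels$status == "deposited", , drop = FALSE]
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  plabels <- sort(unique(p$patch))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("deposited parcels; patches:",
                     paste(plabels, collapse = " ")),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  if (n > 0)
    writeLines(paste(format(p$x, digits = 17), format(p$y, digits = 17),
                     format(p$z, digits = 17)), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  if (n > 0) writeLines(paste(1L, seq_len(n) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS diameter_um double 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(as.character(p$d_um), con)
  writeLines(c("SCALARS deposit_time double 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(as.character(p$deposit_time), con)
  writeLines(c("SCALARS patch_id int 1", "LOOKUP_TABLE default"), con)
  if (n > 0) writeLines(as.character(match(p$patch, plabels) - 1L), con)
  invisible(path)
}

#' Write grid fields as legacy VTK structured points
#'
#' Cell-centered fields are written on the cell lattice (DIMENSIONS = cell
#' counts, ORIGIN at the first cell center). Scalar fields become SCALARS,
#' 4-d `[dims, 3]` arrays become VECTORS.
#'
#' @param grid a `flow_grid`.
#' @param path output path.
#' @param fields named list of arrays; defaults to the non-NULL grid fields.
#' @return `path`, invisibly.
#' @export
write_vtk_structured_points <- function(grid, path, fields = NULL) {
  if (is.null(fields)) {
    fields <- list()
    if (!is.null(grid$u)) fields$velocity <- grid$u
    if (!is.null(grid$ksgs)) fields$ksgs <- grid$ksgs
    if (!is.null(grid$C)) fields$C <- grid$C
    fields$inside <- grid$inside + 0
  }
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "nasoaero structured grid",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.17g %.17g %.17g",
                       grid$origin[1] + grid$dx / 2,
                       grid$origin[2] + grid$dx / 2,
                       grid$origin[3] + grid$dx / 2),
               sprintf("SPACING %.17g %.17g %.17g", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    A <- fields[[nm]]
    if (length(dim(A)) == 4L) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      M <- cbind(as.vector(A[, , , 1]), as.vector(A[, , , 2]),
                 as.vector(A[, , , 3]))
      writeLines(apply(format(M, digits = 17, trim = TRUE), 1, paste,
                       collapse = " "), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.vector(A), digits = 17, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read legacy VTK structured points
#'
#' Parses DIMENSIONS/ORIGIN/SPACING and all SCALARS/VECTORS fields; the
#' returned grid treats every cell as fluid unless an `inside` scalar field
#' is present.
#' @param path VTK file path.
#' @return a `flow_grid` with the stored fields attached.
#' @export
read_vtk_structured_points <- function(path) {
  ln <- readLines(path)
  gv <- function(pat) {
    i <- grep(pat, ln)[1]
    as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][-1])
  }
  d <- as.integer(gv("^DIMENSIONS"))
  org_ctr <- gv("^ORIGIN")
  sp <- gv("^SPACING")
  if (max(abs(sp - sp[1])) > 1e-12 * sp[1])
    stop("only isotropic spacing is supported")
  dx <- sp[1]
  ncell <- prod(d)
  grid <- flow_grid_box(d, dx, origin = org_ctr - dx / 2)

  i <- 1L
  fields <- list()
  while (i <= length(ln)) {
    if (grepl("^SCALARS", ln[i])) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      vals <- as.numeric(unlist(strsplit(trimws(
        ln[(i + 2L):(i + 1L + ncell)]), "\\s+")))
      fields[[nm]] <- array(vals[seq_len(ncell)], d)
      i <- i + 2L + ncell
    } else if (grepl("^VECTORS", ln[i])) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      vals <- matrix(as.numeric(unlist(strsplit(trimws(
        ln[(i + 1L):(i + ncell)]), "\\s+"))), ncol = 3L, byrow = TRUE)
      A <- array(0, c(d, 3L))
      for (c3 in 1:3) A[, , , c3] <- array(vals[, c3], d)
      fields[[nm]] <- A
      i <- i + 1L + ncell
    } else i <- i + 1L
  }
  if (!is.null(fields$inside)) grid$inside <- array(fields$inside > 0.5, d)
  if (!is.null(fields$velocity)) grid$u <- fields$velocity
  if (!is.null(fields$ksgs)) grid$ksgs <- fields$ksgs
  if (!is.null(fields$C)) grid$C <- fields$C
  attr(grid, "fields") <- fields
  grid
}

#' Write the patch-table JSON sidecar
#'
#' One record per patch: role, region, side and area in mm^2.
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patch_json <- function(mesh, path) {
  pa <- patch_areas(mesh) * 1e6
  pt <- mesh$patch_table
  recs <- lapply(names(pa), function(pn) {
    i <- match(pn, pt$patch)
    list(role = pt$role[i], region = pt$region[i], side = pt$side[i],
         area_mm2 = unname(pa[[pn]]))
  })
  names(recs) <- names(pa)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
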