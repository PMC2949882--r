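#' Write a labeled tetrahedral mesh to legacy VTK
#'
#' Writes an ASCII legacy-VTK unstructured grid holding the tetrahedra
#' followed by the boundary triangles, with integer cell-data arrays
#' `region` (boundary-region code on triangles, -1 on tetrahedra) and
#' `material` (material code on tetrahedra, -1 on triangles). Region codes:
#' 1 = FIXED, 2 = EXPOSED_RIM, 3 = EXPOSED_CENTER; material codes:
#' 1 = PARENCHYMA, 2 = TUMOR. An optional per-node displacement field is
#' stored as a point-data vector array `u`.
#'
#' Writes are atomic (temporary file then rename).
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param u optional n x 3 displacement matrix (m) written as point data.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, u = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets); b <- nrow(mesh$boundary_tris)
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "brainshift tetrahedral mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(sprintf("%.17g %.17g %.17g",
             mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]))
  ncell <- m + b
  wl(sprintf("CELLS %d %d", ncell, 5L * m + 4L * b))
  wl(apply(cbind(4L, mesh$tets - 1L), 1L, paste, collapse = " "))
  if (b > 0)
    wl(apply(cbind(3L, mesh$boundary_tris - 1L), 1L, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", ncell))
  wl(as.character(c(rep(10L, m), rep(5L, b))))  # 10 = tetra, 5 = triangle
  wl(sprintf("CELL_DATA %d", ncell))
  wl("SCALARS region int 1", "LOOKUP_TABLE default")
  wl(as.character(c(rep(-1L, m), as.integer(mesh$region))))
  wl("SCALARS material int 1", "LOOKUP_TABLE default")
  wl(as.character(c(as.integer(mesh$material), rep(-1L, b))))
  if (!is.null(u)) {
    u <- as.matrix(u)
    stopifnot(nrow(u) == n, ncol(u) == 3L)
    wl(sprintf("POINT_DATA %d", n))
    wl("VECTORS u double")
    wl(sprintf("%.17g %.17g %.17g", u[, 1], u[, 2], u[, 3]))
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a labeled tetrahedral mesh from legacy VTK
#'
#' Reads files written by [write_mesh()] (and equivalent hand-written legacy
#' VTK): an ASCII unstructured grid containing tetrahedra plus optional
#' boundary triangles, with `region` and `material` integer cell-data
#' arrays. A point-data vector array `u`, if present, is returned as an
#' attribute `"u"` on the mesh.
#'
#' @param path path to a legacy `.vtk` file.
#' @return A [tet_mesh()]; displacement (if stored) in `attr(mesh, "u")`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  find_kw <- function(kw) {
    hit <- grep(paste0("^", kw, "\\b"), lines)
    if (length(hit) == 0L) stop("VTK schema error: missing ", kw, " in ", path)
    hit[1L]
  }
  if (!any(grepl("UNSTRUCTURED_GRID", lines)))
    stop("unsupported VTK dataset (need UNSTRUCTURED_GRID): ", path)

  i <- find_kw("POINTS")
  n <- as.integer(toks_at(i)[2])
  nums <- scan(text = paste(lines[(i + 1):length(lines)], collapse = "\n"),
               what = double(), n = 3L * n, quiet = TRUE)
  nodes <- matrix(nums, n, 3L, byrow = TRUE)

  i <- find_kw("CELLS")
  ncell <- as.integer(toks_at(i)[2]); ntot <- as.integer(toks_at(i)[3])
  cellnums <- scan(text = paste(lines[(i + 1):length(lines)], collapse = "\n"),
                   what = integer(), n = ntot, quiet = TRUE)
  i <- find_kw("CELL_TYPES")
  ctypes <- scan(text = paste(lines[(i + 1):length(lines)], collapse = "\n"),
                 what = integer(), n = ncell, quiet = TRUE)
  if (any(!ctypes %in% c(5L, 10L)))
    stop("unsupported VTK cell types (only tetrahedra and triangles): ",
         paste(unique(setdiff(ctypes, c(5L, 10L))), collapse = ", "))
  if (!any(ctypes == 10L))
    stop("no tetrahedra in mesh file (triangles only?): ", path)

  tets <- matrix(0L, sum(ctypes == 10L), 4L)
  tris <- matrix(0L, sum(ctypes == 5L), 3L)
  pos <- 1L; it <- 1L; ib <- 1L
  cell_is_tet <- logical(ncell)
  for (c_ in seq_len(ncell)) {
    k <- cellnums[pos]
    ids <- cellnums[(pos + 1L):(pos + k)] + 1L
    if (ctypes[c_] == 10L) {
      if (k != 4L) stop("tetrahedron cell with ", k, " nodes")
      tets[it, ] <- ids; cell_is_tet[c_] <- TRUE; it <- it + 1L
    } else {
      if (k != 3L) stop("triangle cell with ", k, " nodes")
      tris[ib, ] <- ids; ib <- ib + 1L
    }
    pos <- pos + k + 1L
  }

  read_cell_scalars <- function(name) {
    hit <- grep(paste0("^SCALARS\\s+", name, "\\b"), lines)
    if (length(hit) == 0L)
      stop("VTK schema error: missing cell-data array '", name, "' in ", path)
    start <- hit[1L] + 2L  # skip LOOKUP_TABLE line
    scan(text = paste(lines[start:length(lines)], collapse = "\n"),
         what = integer(), n = ncell, quiet = TRUE)
  }
  region_raw <- read_cell_scalars("region")
  material_raw <- read_cell_scalars("material")
  region_codes <- region_raw[!cell_is_tet]
  if (any(!region_codes %in% 1:3))
    stop("VTK schema error: triangle region codes must be 1..3")
  material_codes <- material_raw[cell_is_tet]
  if (any(!material_codes %in% 1:2))
    stop("VTK schema error: tetrahedron material codes must be 1..2")

  mesh <- tet_mesh(nodes, tets, tris,
                   REGION_LEVELS[region_codes],
                   MATERIAL_LEVELS[material_codes])
  vhit <- grep("^VECTORS\\s+u\\b", lines)
  if (length(vhit) == 1L) {
    unums <- scan(text = paste(lines[(vhit + 1L):length(lines)],
                               collapse = "\n"),
                  what = double(), n = 3L * n, quiet = TRUE)
    attr(mesh, "u") <- matrix(unums, n, 3L, byrow = TRUE)
  }
  mesh
}
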