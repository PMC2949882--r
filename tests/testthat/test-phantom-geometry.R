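test_that("sphere phantom matches the analytic ball volume and is fully labeled", {
  for (edge in c(0.22 / 5, 0.22 / 7)) {
    mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = edge, seed = 1)
    vols <- tet_volumes(mesh$nodes, mesh$tets)
    expect_true(all(vols > 1e-12))
    vball <- 4 / 3 * pi * 0.11^3
    expect_lt(abs(sum(vols) - vball) / vball, 0.02)
    # labels partition the boundary
    expect_identical(sum(table(mesh$region)), nrow(mesh$boundary_tris))
    expect_true(all(table(mesh$region)[c("FIXED", "EXPOSED_CENTER")] > 0))
    # nodes stay within the inflated ball
    expect_true(all(sqrt(rowSums(mesh$nodes^2)) <= 0.11 + edge))
  }
})

test_that("element count is controlled by target_edge into the study's range", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.02, seed = 1)
  expect_gte(nrow(mesh$tets), 5000)
  expect_lte(nrow(mesh$tets), 15000)
})

test_that("phantom generation is deterministic for identical arguments", {
  m1 <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.03, seed = 7)
  m2 <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.03, seed = 7)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$region, m2$region)
})

test_that("boundary triangle centroids are labeled by polar angle", {
  cap <- cap_spec(theta_center = 12 * pi / 180, theta_rim = 30 * pi / 180)
  mesh <- make_sphere_phantom(0.22, cap, target_edge = 0.025, seed = 1)
  cent <- (mesh$nodes[mesh$boundary_tris[, 1], ] +
           mesh$nodes[mesh$boundary_tris[, 2], ] +
           mesh$nodes[mesh$boundary_tris[, 3], ]) / 3
  ang <- acos(pmin(1, cent[, 3] / sqrt(rowSums(cent^2))))
  expect_true(all(ang[mesh$region == "EXPOSED_CENTER"] < cap$theta_center))
  expect_true(all(ang[mesh$region == "EXPOSED_RIM"] >= cap$theta_center &
                  ang[mesh$region == "EXPOSED_RIM"] < cap$theta_rim))
  expect_true(all(ang[mesh$region == "FIXED"] >= cap$theta_rim))
})

test_that("a cap too small for the mesh raises the resolution error", {
  expect_error(
    make_sphere_phantom(0.22, cap_spec(theta_center = 0.005, theta_rim = 0.4),
                        target_edge = 0.04, seed = 1),
    "smallest representable cap")
  expect_error(cap_spec(theta_center = 0), "theta_center")
})

test_that("locate_point returns exact barycentric coordinates", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  # centroid of a tet -> equal weights
  k <- 17L
  cen <- colMeans(mesh$nodes[mesh$tets[k, ], ])
  loc <- locate_point(mesh, cen)
  expect_equal(loc$bary, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sort(mesh$tets[loc$tet, ]), sort(mesh$tets[k, ]))
  # a mesh node -> one barycentric coordinate equals 1
  j <- mesh$tets[3, 2]
  locn <- locate_point(mesh, mesh$nodes[j, ])
  expect_equal(max(locn$bary), 1, tolerance = 1e-9)
  expect_true(j %in% mesh$tets[locn$tet, ])
})

test_that("accelerated lookup agrees with brute-force containment", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  set.seed(42)
  # random interior points via random convex combinations inside random tets
  m <- nrow(mesh$tets)
  ks <- sample.int(m, 100, replace = TRUE)
  pts <- t(vapply(ks, function(k) {
    w <- stats::runif(4); w <- w / sum(w)
    as.numeric(w %*% mesh$nodes[mesh$tets[k, ], ])
  }, numeric(3)))
  loc <- locate_points(mesh, pts)
  for (q in seq_len(nrow(pts))) {
    # brute force: scan every tet for nonnegative barycentrics
    found <- FALSE
    for (e in seq_len(m)) {
      v <- mesh$nodes[mesh$tets[e, ], ]
      b234 <- solve(t(v[2:4, ]) - v[1, ], pts[q, ] - v[1, ])
      b <- c(1 - sum(b234), b234)
      if (min(b) >= -1e-10) { found <- TRUE; break }
    }
    expect_true(found)
    # the accelerated result reconstructs the point and is a containing tet
    verts <- mesh$nodes[mesh$tets[loc$tet[q], ], ]
    recon <- as.numeric(loc$bary[q, ] %*% verts)
    expect_lt(sqrt(sum((recon - pts[q, ])^2)), 1e-9)
    expect_gte(min(loc$bary[q, ]), 0)
    expect_equal(sum(loc$bary[q, ]), 1, tolerance = 1e-12)
  }
})

test_that("points far outside the mesh raise a not-found error", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 1)
  expect_error(locate_point(mesh, c(1, 1, 1)), "farther than")
})

test_that("VTK write -> read round-trip preserves the mesh exactly", {
  mesh <- make_sphere_phantom(0.22, cap_spec(), target_edge = 0.044, seed = 3)
  path <- withr::local_tempfile(fileext = ".vtk")
  u <- matrix(stats::rnorm(3 * nrow(mesh$nodes), sd = 1e-3),
              ncol = 3)
  write_mesh(mesh, path, u = u)
  back <- read_mesh(path)
  expect_lt(max(abs(back$nodes - mesh$nodes)) / max(abs(mesh$nodes)), 1e-12)
  expect_identical(back$tets, mesh$tets)
  expect_identical(back$boundary_tris, mesh$boundary_tris)
  expect_identical(back$region, mesh$region)
  expect_identical(back$material, mesh$material)
  expect_lt(max(abs(attr(back, "u") - u)), 1e-15)
})

test_that("hand-written single-tet VTK fixture parses exactly", {
  lines <- c(
    "# vtk DataFile Version 3.0", "one tet", "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    "POINTS 4 double",
    "0 0 0", "0.1 0 0", "0 0.1 0", "0 0 0.1",
    "CELLS 5 21",
    "4 0 1 2 3",
    "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2",
    "CELL_TYPES 5", "10", "5", "5", "5", "5",
    "CELL_DATA 5",
    "SCALARS region int 1", "LOOKUP_TABLE default",
    "-1 1 2 3 1",
    "SCALARS material int 1", "LOOKUP_TABLE default",
    "2 -1 -1 -1 -1")
  path <- withr::local_tempfile(fileext = ".vtk")
  writeLines(lines, path)
  mesh <- read_mesh(path)
  expect_identical(nrow(mesh$tets), 1L)
  expect_identical(mesh$tets[1, ], c(1L, 2L, 3L, 4L))
  expect_identical(as.character(mesh$region),
                   c("FIXED", "EXPOSED_RIM", "EXPOSED_CENTER", "FIXED"))
  expect_identical(as.character(mesh$material), "TUMOR")
  expect_equal(mesh$nodes[2, 1], 0.1)
})

test_that("triangle-only and unsupported-cell files are rejected", {
  path <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "tris", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               "POINTS 3 double", "0 0 0", "1 0 0", "0 1 0",
               "CELLS 1 4", "3 0 1 2", "CELL_TYPES 1", "5"), path)
  expect_error(read_mesh(path), "no tetrahedra")
  writeLines(c("# vtk DataFile Version 3.0", "hex", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               "POINTS 8 double",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "0 0 1", "1 0 1", "1 1 1", "0 1 1",
               "CELLS 1 9", "8 0 1 2 3 4 5 6 7", "CELL_TYPES 1", "12"), path)
  expect_error(read_mesh(path), "unsupported")
  # missing label arrays
  mesh <- two_tet_mesh()
  write_mesh(mesh, path)
  txt <- readLines(path)
  writeLines(txt[seq_len(grep("SCALARS region", txt) - 1L)], path)
  expect_error(read_mesh(path), "region")
})
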