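# Bone segmentation and surface reconstruction: HU-band thresholding into a
# binary matrix, marching-tetrahedra isosurface at level 0.5 (lateral
# zero-padding so shells touching the image border still close), and
# top/bottom capping to a watertight bone structure.

#' Threshold a CT volume into a binary bone mask
#'
#' Marks every voxel whose HU value lies in the closed interval
#' `[hu_low, hu_high]`. The defaults select the cortical bone band
#' 1150-1250 HU; both bounds are configurable (widening the interval never
#' removes foreground voxels).
#'
#' @param volume a [VolumeGrid].
#' @param hu_low,hu_high HU band bounds, `hu_low < hu_high`.
#' @return a [BoneMask] aligned voxel-for-voxel with `volume`.
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48, 48, 4), radius_outer = 14,
#'                                   radius_inner = 9, noise_sd = 0))
#' mask <- thresholdBone(ph$volume)
#' sum(voxels(mask)) == sum(ph$shell)
#' @export
thresholdBone <- function(volume, hu_low = 1150, hu_high = 1250) {
  stopifnot(is(volume, "VolumeGrid"))
  if (hu_low >= hu_high) .stopf("reversed bounds: hu_low must be < hu_high")
  v <- voxels(volume)
  mask <- array(0L, dim(v))
  mask[v >= hu_low & v <= hu_high] <- 1L
  sp <- pixelSpacing(volume)
  boneMask(mask, spacing = c(sp[["x"]], sp[["y"]], sliceThickness(volume)),
           hu_range = c(hu_low, hu_high), provenance = volumeId(volume))
}

#' Construct a BoneMask directly
#'
#' Builds a [BoneMask] from a 0/1 array, for masks that do not come from
#' thresholding a volume (synthetic shapes, imported segmentations).
#'
#' @param mask integer/logical 3-D array.
#' @param spacing length-3 voxel spacing in mm.
#' @param hu_range the HU interval the mask represents.
#' @param provenance source volume id; derived from the mask content if
#'   not supplied.
#' @return a validated [BoneMask].
#' @export
boneMask <- function(mask, spacing = c(1, 1, 1), hu_range = c(1150, 1250),
                     provenance = NULL) {
  storage.mode(mask) <- "integer"
  if (is.null(provenance)) {
    provenance <- .hash_obj(list(dim(mask), sum(mask), hu_range))
  }
  new("BoneMask", mask = mask, hu_range = as.numeric(hu_range),
      spacing = as.numeric(spacing), provenance = provenance)
}

# drop connected components below min_component voxels (thresholding specks)
.filter_components <- function(m, min_component) {
  if (min_component <= 1L) return(m)
  lab <- .cc_label3d_cpp(m)
  sizes <- tabulate(lab)
  small <- which(sizes < min_component)
  if (length(small)) {
    .msgf("dropping %d component(s) under %d voxel(s)",
          length(small), min_component)
    m[lab %in% small] <- 0L
  }
  m
}

#' Extract the bone surface from a binary mask
#'
#' Runs a marching-tetrahedra isosurface at level 0.5 of the binary field.
#' Vertices are in millimetres (voxel index times spacing; x along columns,
#' y along rows, z along slices), faces oriented outward. The field is
#' zero-padded laterally (rows and columns only) so bone touching the image
#' border still closes in-plane; open boundaries can remain only at the
#' first/last slice planes, which [capMesh()] closes. Connected components
#' below `min_component` voxels are dropped with a message (thresholding
#' noise produces specks too small to render).
#'
#' @param mask a [BoneMask].
#' @param min_component smallest component size kept, in voxels.
#' @return a [BoneMesh].
#' @seealso [capMesh()], [meshVolume()], [isWatertight()]
#' @export
extractSurface <- function(mask, min_component = 20L) {
  stopifnot(is(mask, "BoneMask"))
  m <- voxels(mask)
  if (sum(m) == 0L) .stopf("no bone found: the mask is empty")
  prov <- mask@provenance
  m <- .filter_components(m, min_component)
  if (sum(m) == 0L) .stopf("no bone found: all components below min_component")
  d <- dim(m)
  padded <- array(0L, d + c(2L, 2L, 0L))
  padded[2:(d[1L] + 1L), 2:(d[2L] + 1L), ] <- m
  res <- .march_tets_cpp(padded, as.numeric(mask@spacing), c(-1, -1, 0))
  new("BoneMesh", vertices = res$vertices,
      faces = matrix(as.integer(res$faces), ncol = 3L), provenance = prov)
}

#' Cap a bone surface at the first and last slice planes
#'
#' A shell spanning the full slice range leaves the surface open at the top
#' and bottom of the scanned volume. `capMesh()` closes those openings with
#' planar caps at the first/last slice planes (recomputing the surface with
#' the axial boundary treated as background), yielding a watertight mesh. A
#' mesh that is already closed is returned unchanged, with no new faces. If
#' the capped surface still fails the edge-manifold check, this is reported
#' rather than silently accepted.
#'
#' @param mesh a [BoneMesh] produced by [extractSurface()] from `mask`.
#' @param mask the same [BoneMask] the mesh was derived from.
#' @param min_component must match the value used in [extractSurface()].
#' @return a watertight [BoneMesh].
#' @export
capMesh <- function(mesh, mask, min_component = 20L) {
  stopifnot(is(mesh, "BoneMesh"), is(mask, "BoneMask"))
  if (!identical(mesh@provenance, mask@provenance)) {
    .stopf("mesh was not derived from this mask")
  }
  m <- .filter_components(voxels(mask), min_component)
  d <- dim(m)
  padded <- array(0L, d + c(2L, 2L, 2L))
  padded[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
  res <- .march_tets_cpp(padded, as.numeric(mask@spacing), c(-1, -1, -1))
  out <- new("BoneMesh", vertices = res$vertices,
             faces = matrix(as.integer(res$faces), ncol = 3L),
             provenance = mesh@provenance)
  if (!isWatertight(out)) {
    .warnf("capped mesh still has non-manifold edges (non-boundary holes?)")
  }
  out
}

#' Mesh integrity and volume
#'
#' `isWatertight()` checks the edge-manifold property: every undirected edge
#' is shared by exactly two faces. `meshVolume()` returns the enclosed
#' volume in cubic millimetres via the divergence theorem (sum of signed
#' tetrahedron volumes), valid for watertight outward-oriented meshes.
#' `meshEuler()` returns the Euler characteristic V - E + F (2 for a
#' topological sphere).
#'
#' @param mesh a [BoneMesh].
#' @return `isWatertight()`: logical; `meshVolume()`: volume in mm^3;
#'   `meshEuler()`: an integer.
#' @export
isWatertight <- function(mesh) {
  f <- meshFaces(mesh)
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' @rdname isWatertight
#' @export
meshVolume <- function(mesh) {
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  abs(sum(det6)) / 6
}

#' @rdname isWatertight
#' @export
meshEuler <- function(mesh) {
  f <- meshFaces(mesh)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  n_edges <- length(unique(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))))
  nrow(meshVertices(mesh)) - n_edges + nrow(f)
}

#' Export a mesh as PLY or STL
#'
#' Standard triangle-mesh interchange formats, ASCII or binary
#' little-endian variants.
#'
#' @param mesh a [BoneMesh].
#' @param path output file.
#' @param binary write the binary variant (default ASCII).
#' @return invisibly, `path`.
#' @export
writePLY <- function(mesh, path, binary = FALSE) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              "comment fracture3d bone surface",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(v)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    lines <- c(header,
               apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 9),
                                              collapse = " ")),
               apply(f - 1L, 1L, function(r) paste(c(3L, r), collapse = " ")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname writePLY
#' @export
writeSTL <- function(mesh, path, binary = FALSE) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  normals <- t(apply(f, 1L, function(tri) {
    u <- v[tri[2L], ] - v[tri[1L], ]
    w <- v[tri[3L], ] - v[tri[1L], ]
    n <- c(u[2L] * w[3L] - u[3L] * w[2L], u[3L] * w[1L] - u[1L] * w[3L],
           u[1L] * w[2L] - u[2L] * w[1L])
    len <- sqrt(sum(n^2))
    if (len > 0) n / len else c(0, 0, 0)
  }))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(formatC("fracture3d bone surface", width = -80))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(normals[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    lines <- c("solid fracture3d")
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("facet normal %g %g %g", normals[i, 1L], normals[i, 2L],
                         normals[i, 3L]),
                 " outer loop",
                 sprintf("  vertex %g %g %g", v[f[i, ], 1L], v[f[i, ], 2L],
                         v[f[i, ], 3L]),
                 " endloop", "endfacet")
    }
    writeLines(c(lines, "endsolid fracture3d"), path)
  }
  invisible(path)
}

#' Export a binary mask as compressed NIfTI
#'
#' Writes the 0/1 array with its voxel spacing (mm) as a `.nii.gz` volume.
#'
#' @param mask a [BoneMask] (or a [FractureMask3D] that has been voxelized).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return invisibly, `path`.
#' @export
writeMaskNifti <- function(mask, path) {
  arr <- voxels(mask)
  if (!length(arr)) .stopf("mask has no voxelized array")
  sp <- mask@spacing
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, sp, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
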