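# Lifting per-slice pixel boxes into physical-coordinate cuboids and
# stacking them into the 3-D fracture mask ("red mask") rendered over the
# bone surface. The coordinate frame is the scanner grid: origin at the
# corner of voxel (0, 0, 0), x along image columns, y along image rows, z
# along slices; a box on slice k occupies the half-open z-slab
# [k * thickness, (k + 1) * thickness).

#' Stable volume identity for coordinate-frame checks
#'
#' A content hash of a volume's dimensions and per-slice metadata, used to
#' refuse overlays of meshes and masks from different series.
#'
#' @param volume a [VolumeGrid].
#' @return a short hex string.
#' @export
volumeId <- function(volume) {
  stopifnot(is(volume, "VolumeGrid"))
  v <- volume@voxels
  sampled <- v[seq(1L, length(v), by = 7L)]
  .hash_obj(list(dim(v), sliceMeta(volume), sum(v), sum(sampled * 3)))
}

#' Lift 2-D pixel boxes into physical-coordinate cuboids
#'
#' Converts each box to a cuboid using the series geometry: origin
#' `(x_start * pixel_spacing_x, y_start * pixel_spacing_y,
#' slice_index * slice_thickness)` mm and extents
#' `(x_extent * pixel_spacing_x, y_extent * pixel_spacing_y,
#' slice_thickness)` mm. The mapping is exactly invertible given the
#' metadata; [cuboidToBox()] recovers the pixel boxes.
#'
#' @param bxs a [BoxSet]; every box must lie within the slice bounds.
#' @param volume the source [VolumeGrid] (carries spacing and thickness).
#' @return a cuboid `data.frame` (mm origin/extents plus the source pixel
#'   box, slice index and score), with the volume id attached as attribute
#'   `provenance`.
#' @examples
#' v <- volumeGrid(array(0, c(64, 64, 10)), pixel_spacing = c(0.5, 0.5),
#'                 slice_thickness = 2)
#' b <- boxSet(slice_index = 7, x_start = 10, y_start = 20,
#'             x_extent = 30, y_extent = 40)
#' boxToCuboid(b, v)[, c("origin_x", "origin_y", "origin_z", "dx", "dy", "dz")]
#' @export
boxToCuboid <- function(bxs, volume) {
  stopifnot(is(bxs, "BoxSet"), is(volume, "VolumeGrid"))
  m <- sliceMeta(volume)
  if (anyNA(m$pixel_spacing_x) || anyNA(m$slice_thickness)) {
    .stopf("missing spacing metadata")
  }
  b <- boxes(bxs)
  if (nrow(b)) {
    if (any(b$x_start + b$x_extent > m$cols[1L]) ||
        any(b$y_start + b$y_extent > m$rows[1L]) ||
        any(!b$slice_index %in% m$slice_index)) {
      .stopf("box outside slice bounds or on an absent slice")
    }
  }
  sx <- m$pixel_spacing_x[1L]; sy <- m$pixel_spacing_y[1L]
  t <- m$slice_thickness[1L]
  cu <- data.frame(
    origin_x = b$x_start * sx, origin_y = b$y_start * sy,
    origin_z = b$slice_index * t,
    dx = b$x_extent * sx, dy = b$y_extent * sy, dz = rep(t, nrow(b)),
    x_start = b$x_start, y_start = b$y_start,
    x_extent = b$x_extent, y_extent = b$y_extent,
    slice_index = b$slice_index, score = b$score,
    component = rep(NA_integer_, nrow(b)))
  attr(cu, "provenance") <- volumeId(volume)
  attr(cu, "spacing") <- c(sx, sy, t)
  cu
}

#' @param cu a cuboid `data.frame` from [boxToCuboid()].
#' @rdname boxToCuboid
#' @export
cuboidToBox <- function(cu) {
  sp <- attr(cu, "spacing")
  boxSet(slice_index = .round_half_away(cu$origin_z / sp[3L]),
         x_start = .round_half_away(cu$origin_x / sp[1L]),
         y_start = .round_half_away(cu$origin_y / sp[2L]),
         x_extent = .round_half_away(cu$dx / sp[1L]),
         y_extent = .round_half_away(cu$dy / sp[2L]),
         score = cu$score)
}

# union-find over cuboids: merge when pixel boxes overlap in-plane and the
# slice distance is at most merge_gap + 1 (a detector miss of up to
# merge_gap slices does not split one fracture into two components)
.group_cuboids <- function(b, merge_gap) {
  n <- nrow(b)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (abs(b$slice_index[i] - b$slice_index[j]) > merge_gap + 1L) next
      if (b$x_start[i] < b$x_start[j] + b$x_extent[j] &&
          b$x_start[j] < b$x_start[i] + b$x_extent[i] &&
          b$y_start[i] < b$y_start[j] + b$y_extent[j] &&
          b$y_start[j] < b$y_start[i] + b$y_extent[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

#' Stack lifted boxes into a 3-D fracture mask
#'
#' Groups cuboids into connected fracture components: cuboids whose pixel
#' boxes overlap in-plane and whose slices lie within `merge_gap + 1` of
#' each other share a component (with the default `merge_gap = 1`, a
#' single-slice detector miss does not split a fracture; `merge_gap = 0`
#' still merges directly adjacent slices). Call [voxelizeMask()] to
#' materialize the union on the source grid.
#'
#' @param cu a cuboid `data.frame` from [boxToCuboid()] (one series).
#' @param merge_gap tolerated gap between slices, in slices.
#' @return a [FractureMask3D] (not yet voxelized).
#' @export
stackMask <- function(cu, merge_gap = 1L) {
  sp <- attr(cu, "spacing")
  if (is.null(sp)) .stopf("cuboids lack spacing metadata; use boxToCuboid()")
  cu$component <- if (nrow(cu)) .group_cuboids(cu, merge_gap) else integer()
  new("FractureMask3D", cuboids = cu, voxels = array(0L, c(0L, 0L, 0L)),
      spacing = as.numeric(sp),
      provenance = as.character(attr(cu, "provenance") %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize a fracture mask on the source grid
#'
#' Materializes the union of the cuboids as a 0/1 array aligned with the
#' source volume. With the half-open pixel and z-slab conventions the
#' voxelized volume of pairwise-disjoint cuboids equals the sum of
#' `dx * dy * dz` exactly.
#'
#' @param mask3d a [FractureMask3D].
#' @param dims integer length-3 `(rows, cols, slices)` of the source volume.
#' @return the [FractureMask3D] with its `voxels` slot filled.
#' @seealso [maskVolume()]
#' @export
voxelizeMask <- function(mask3d, dims) {
  stopifnot(is(mask3d, "FractureMask3D"), length(dims) == 3L)
  arr <- array(0L, dims)
  b <- mask3d@cuboids
  for (i in seq_len(nrow(b))) {
    rows <- (b$y_start[i] + 1L):(b$y_start[i] + b$y_extent[i])
    cols <- (b$x_start[i] + 1L):(b$x_start[i] + b$x_extent[i])
    arr[rows, cols, b$slice_index[i] + 1L] <- 1L
  }
  initialize(mask3d, voxels = arr)
}

#' Physical volume of a voxelized fracture mask
#'
#' @param mask3d a voxelized [FractureMask3D].
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
maskVolume <- function(mask3d) {
  if (!length(mask3d@voxels)) .stopf("mask has not been voxelized")
  sum(mask3d@voxels) * prod(mask3d@spacing)
}

# triangulated axis-aligned box (8 vertices, 12 triangles)
.cuboid_mesh <- function(o, d) {
  v <- as.matrix(expand.grid(x = c(o[1L], o[1L] + d[1L]),
                             y = c(o[2L], o[2L] + d[2L]),
                             z = c(o[3L], o[3L] + d[3L])))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  list(vertices = v, faces = f)
}

# minimal glTF 2.0 writer: one node per (mesh, material) pair, positions as
# float32 and indices as uint32 in a single embedded base64 buffer
.write_gltf <- function(meshes, colors, alphas, path) {
  buf <- raw()
  views <- list(); accessors <- list(); prims <- list()
  for (i in seq_along(meshes)) {
    v <- meshes[[i]]$vertices
    f <- meshes[[i]]$faces
    pos <- writeBin(as.numeric(t(v)), raw(), size = 4L, endian = "little")
    idx <- writeBin(as.integer(t(f) - 1L), raw(), size = 4L, endian = "little")
    views[[length(views) + 1L]] <- list(buffer = 0L, byteOffset = length(buf),
                                        byteLength = length(pos), target = 34962L)
    buf <- c(buf, pos)
    views[[length(views) + 1L]] <- list(buffer = 0L, byteOffset = length(buf),
                                        byteLength = length(idx), target = 34963L)
    buf <- c(buf, idx)
    accessors[[length(accessors) + 1L]] <- list(
      bufferView = length(views) - 2L, componentType = 5126L,
      count = nrow(v), type = "VEC3",
      min = as.numeric(apply(v, 2L, min)), max = as.numeric(apply(v, 2L, max)))
    accessors[[length(accessors) + 1L]] <- list(
      bufferView = length(views) - 1L, componentType = 5125L,
      count = 3L * nrow(f), type = "SCALAR")
    prims[[i]] <- list(attributes = list(POSITION = length(accessors) - 2L),
                       indices = length(accessors) - 1L, material = i - 1L)
  }
  materials <- lapply(seq_along(meshes), function(i) {
    m <- list(pbrMetallicRoughness = list(
      baseColorFactor = c(colors[[i]], alphas[[i]]),
      metallicFactor = 0, roughnessFactor = 0.9))
    if (alphas[[i]] < 1) { m$alphaMode <- "BLEND"; m$doubleSided <- TRUE }
    m
  })
  gltf <- list(
    asset = list(version = "2.0", generator = "fracture3d"),
    scene = 0L,
    scenes = list(list(nodes = as.list(seq_along(meshes) - 1L))),
    nodes = lapply(seq_along(meshes) - 1L, function(i) list(mesh = i)),
    meshes = lapply(prims, function(p) list(primitives = list(p))),
    materials = materials,
    buffers = list(list(
      byteLength = length(buf),
      uri = paste0("data:application/octet-stream;base64,",
                   jsonlite::base64_enc(buf)))),
    bufferViews = views,
    accessors = accessors)
  writeLines(jsonlite::toJSON(gltf, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# orthographic axis-aligned projections used by the snapshot renderer
.camera_axes <- list(x = c(3L, 2L, 1L), y = c(1L, 3L, 2L), z = c(1L, 2L, 3L))

#' Overlay the fracture mask on the bone mesh
#'
#' Writes a glTF 2.0 scene (`<out>.gltf`: bone-coloured mesh plus one
#' semi-transparent red box mesh per fracture component) and a deterministic
#' PNG snapshot (`<out>.png`: orthographic z-buffer rendering along the
#' chosen camera axis with the red mask alpha-blended where it is not
#' occluded by bone). Inputs are never mutated. Meshes and masks from
#' different source volumes are refused.
#'
#' @param mesh a [BoneMesh].
#' @param mask3d a [FractureMask3D] in the same coordinate frame.
#' @param out output path prefix (without extension).
#' @param camera viewing axis for the snapshot: `"x"`, `"y"` or `"z"`.
#' @param snapshot_px snapshot image size in pixels (square).
#' @return invisibly, the two file paths written.
#' @export
overlayScene <- function(mesh, mask3d, out, camera = "x", snapshot_px = 400L) {
  stopifnot(is(mesh, "BoneMesh"), is(mask3d, "FractureMask3D"))
  if (nzchar(mesh@provenance) && nzchar(mask3d@provenance) &&
      !identical(mesh@provenance, mask3d@provenance)) {
    .stopf("coordinate-frame mismatch: mesh and mask come from different volumes")
  }
  ax <- .camera_axes[[match.arg(camera, names(.camera_axes))]]
  cu <- mask3d@cuboids

  scene <- list(list(vertices = meshVertices(mesh), faces = meshFaces(mesh)))
  colors <- list(c(0.88, 0.85, 0.78))
  alphas <- list(1)
  if (nrow(cu)) {
    for (comp in unique(cu$component)) {
      sub <- cu[cu$component == comp, , drop = FALSE]
      vs <- NULL; fs <- NULL
      for (i in seq_len(nrow(sub))) {
        bm <- .cuboid_mesh(c(sub$origin_x[i], sub$origin_y[i], sub$origin_z[i]),
                           c(sub$dx[i], sub$dy[i], sub$dz[i]))
        fs <- rbind(fs, bm$faces + if (is.null(vs)) 0L else nrow(vs))
        vs <- rbind(vs, bm$vertices)
      }
      scene[[length(scene) + 1L]] <- list(vertices = vs, faces = fs)
      colors[[length(colors) + 1L]] <- c(1, 0.05, 0.05)
      alphas[[length(alphas) + 1L]] <- 0.45
    }
  }
  gltf_path <- paste0(out, ".gltf")
  .write_gltf(scene, colors, alphas, gltf_path)

  # snapshot: project mesh orthographically, shade by face normal, then
  # alpha-blend each cuboid's projected rectangle where not behind bone
  v <- meshVertices(mesh)
  proj <- v[, ax, drop = FALSE]
  lo <- apply(proj[, 1:2, drop = FALSE], 2L, min)
  hi <- apply(proj[, 1:2, drop = FALSE], 2L, max)
  if (nrow(cu)) {
    corners <- rbind(as.matrix(cu[, c("origin_x", "origin_y", "origin_z")]),
                     as.matrix(cu[, c("origin_x", "origin_y", "origin_z")]) +
                       as.matrix(cu[, c("dx", "dy", "dz")]))[, ax, drop = FALSE]
    lo <- pmin(lo, apply(corners[, 1:2, drop = FALSE], 2L, min))
    hi <- pmax(hi, apply(corners[, 1:2, drop = FALSE], 2L, max))
  }
  margin <- 10
  sc <- (snapshot_px - 2 * margin) / max(hi - lo, 1e-9)
  verts2d <- cbind((proj[, 1L] - lo[1L]) * sc + margin,
                   (proj[, 2L] - lo[2L]) * sc + margin, proj[, 3L])
  f <- meshFaces(mesh)
  light <- c(0.45, -0.5, 0.74)
  shade <- vapply(seq_len(nrow(f)), function(i) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; cc <- v[f[i, 3L], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    len <- sqrt(sum(n^2))
    if (len == 0) return(0.3)
    0.25 + 0.65 * abs(sum(n / len * light))
  }, numeric(1L))
  rend <- .zbuffer_render_cpp(verts2d, f, shade, snapshot_px, snapshot_px, 0)
  img <- array(rep(rend$image, 3L), c(snapshot_px, snapshot_px, 3L))
  if (nrow(cu)) {
    alpha <- 0.45
    for (i in seq_len(nrow(cu))) {
      o <- c(cu$origin_x[i], cu$origin_y[i], cu$origin_z[i])[ax]
      e <- c(cu$dx[i], cu$dy[i], cu$dz[i])[ax]
      u0 <- max(1L, floor((o[1L] - lo[1L]) * sc + margin) + 1L)
      u1 <- min(snapshot_px, ceiling((o[1L] + e[1L] - lo[1L]) * sc + margin))
      v0 <- max(1L, floor((o[2L] - lo[2L]) * sc + margin) + 1L)
      v1 <- min(snapshot_px, ceiling((o[2L] + e[2L] - lo[2L]) * sc + margin))
      if (u1 < u0 || v1 < v0) next
      front <- o[3L]
      vis <- rend$depth[v0:v1, u0:u1] >= front  # not occluded by bone
      for (ch in 1:3) {
        tile <- img[v0:v1, u0:u1, ch]
        tgt <- if (ch == 1L) 1 else 0.05
        img[v0:v1, u0:u1, ch] <- ifelse(vis, (1 - alpha) * tile + alpha * tgt, tile)
      }
    }
  }
  png_path <- paste0(out, ".png")
  png::writePNG(pmin(pmax(img, 0), 1), png_path)
  invisible(c(gltf_path, png_path))
}
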