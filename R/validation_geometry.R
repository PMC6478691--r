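#' Analytic validation geometries
#'
#' Small labelled volumes with known closed-form properties, used as
#' oracles for the flow solver and the morphometry code.
#'
#' Kinds:
#' \describe{
#'   \item{`slab`}{all-interstitium block.}
#'   \item{`tube`}{straight cylindrical lumen along z through interstitium;
#'     voxels whose centre lies within `radius` of the axis (Gauss
#'     digitisation, volume-true).}
#'   \item{`sandwich`}{two parallel lumen slabs (blood low-z, lymph high-z)
#'     separated by interstitium of stated thickness.}
#'   \item{`y_tube`}{symmetric bifurcation: one stem along z splitting into
#'     two straight branches.}
#'   \item{`arc_tube`}{quarter-circle cylinder of stated centreline radius
#'     in the (z, y) plane.}
#'   \item{`box`}{all-air volume with an interior interstitium block.}
#' }
#'
#' @param kind one of `"tube"`, `"slab"`, `"sandwich"`, `"y_tube"`,
#'   `"arc_tube"`, `"box"`.
#' @param shape integer triple (nz, ny, nx), voxels.
#' @param voxel_pitch_um voxel pitch, micrometres.
#' @param radius lumen radius in voxels (tube, y_tube, arc_tube).
#' @param lumen_class `"blood"` or `"lymph"` for tubular lumens.
#' @param thickness interstitial gap in voxels (sandwich); also the lumen
#'   slab thickness.
#' @param arc_radius centreline radius in voxels (arc_tube).
#' @param block margin in voxels of the tissue block inside `box`.
#' @return a [label_volume()] without a pleural shell
#'   (`pleural_direction = NA`).
#' @export
generate_validation_geometry <- function(kind = c("tube", "slab", "sandwich",
                                                  "y_tube", "arc_tube", "box"),
                                         shape = c(64L, 32L, 32L),
                                         voxel_pitch_um = 13.2,
                                         radius = 8, lumen_class = "blood",
                                         thickness = 10, arc_radius = 20,
                                         block = 8) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) stop("shape must be >= 4 voxels")
  lum <- if (identical(lumen_class, "lymph")) LBL_LYMPH else LBL_BLOOD
  a <- array(LBL_TISSUE, shape)
  cz <- seq_len(shape[1]); cy <- seq_len(shape[2]); cx <- seq_len(shape[3])

  if (kind == "slab") {
    # all interstitium
  } else if (kind == "tube") {
    if (radius < 2) stop("tube radius < 2 voxels is unresolvable")
    y0 <- (shape[2] + 1) / 2; x0 <- (shape[3] + 1) / 2
    r2 <- outer((cy - y0)^2, (cx - x0)^2, "+")
    disk <- r2 <= radius^2
    for (k in cz) a[k, , ][disk] <- lum
  } else if (kind == "sandwich") {
    t <- as.integer(thickness)
    if (shape[1] < 2 * t + t) stop("sandwich does not fit the grid")
    a[seq_len(t), , ] <- LBL_BLOOD
    a[(t + 1):(2 * t), , ] <- LBL_TISSUE
    a[(2 * t + 1):(3 * t), , ] <- LBL_LYMPH
    if (shape[1] > 3 * t) a[(3 * t + 1):shape[1], , ] <- LBL_AIR
  } else if (kind == "y_tube") {
    if (radius < 2) stop("tube radius < 2 voxels is unresolvable")
    y0 <- (shape[2] + 1) / 2; x0 <- (shape[3] + 1) / 2
    zsplit <- floor(shape[1] / 2)
    paths <- list(
      cbind(seq(1, zsplit, by = 0.5), y0, x0),
      cbind(seq(zsplit, shape[1], by = 0.25),
            y0 + 0.55 * (seq(zsplit, shape[1], by = 0.25) - zsplit), x0),
      cbind(seq(zsplit, shape[1], by = 0.25),
            y0 - 0.55 * (seq(zsplit, shape[1], by = 0.25) - zsplit), x0))
    for (p in paths) a <- rasterize_brush(a, p, radius, lum, clamp = TRUE)
  } else if (kind == "arc_tube") {
    if (radius < 2) stop("tube radius < 2 voxels is unresolvable")
    R <- arc_radius
    z0 <- 3 + radius; y0 <- 3 + radius
    x0 <- (shape[3] + 1) / 2
    th <- seq(0, pi / 2, length.out = ceiling(pi * R))
    p <- cbind(z0 + R * sin(th), y0 + R * cos(th), x0)
    a <- rasterize_brush(a, p, radius, lum, clamp = TRUE)
  } else if (kind == "box") {
    a[] <- LBL_AIR
    a[(block + 1):(shape[1] - block),
      (block + 1):(shape[2] - block),
      (block + 1):(shape[3] - block)] <- LBL_TISSUE
  }
  label_volume(a, voxel_pitch_um)
}

# rasterize a polyline (matrix of (z,y,x) continuous coords, 1-based voxel
# space) into `arr` with a spherical brush of given radius (voxels),
# writing `value` over any existing label (or only over `over` labels).
rasterize_brush <- function(arr, pts, radius, value, over = NULL,
                            clamp = FALSE) {
  d <- dim(arr)
  r <- max(radius, 0)
  ri <- ceiling(r)
  off <- as.matrix(expand.grid(dz = -ri:ri, dy = -ri:ri, dx = -ri:ri))
  off <- off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  if (nrow(off) == 0L) off <- matrix(0, 1, 3)
  pts <- round(pts)
  vox <- unique(pts)
  coords <- cbind(rep(vox[, 1], each = nrow(off)) + off[, 1],
                  rep(vox[, 2], each = nrow(off)) + off[, 2],
                  rep(vox[, 3], each = nrow(off)) + off[, 3])
  if (clamp) {
    keep <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
      coords[, 2] >= 1 & coords[, 2] <= d[2] &
      coords[, 3] >= 1 & coords[, 3] <= d[3]
    coords <- coords[keep, , drop = FALSE]
  }
  lin <- (coords[, 3] - 1) * d[1] * d[2] + (coords[, 2] - 1) * d[1] + coords[, 1]
  lin <- unique(lin)
  if (!is.null(over)) lin <- lin[arr[lin] %in% over]
  arr[lin] <- value
  arr
}

# voxels a dense polyline would set (same brush as rasterize_brush), used
# for budget accounting before committing
brush_voxels <- function(d, pts, radius, clamp = TRUE) {
  r <- max(radius, 0)
  ri <- ceiling(r)
  off <- as.matrix(expand.grid(dz = -ri:ri, dy = -ri:ri, dx = -ri:ri))
  off <- off[rowSums(off^2) <= r^2 + 1e-9, , drop = FALSE]
  if (nrow(off) == 0L) off <- matrix(0, 1, 3)
  vox <- unique(round(pts))
  coords <- cbind(rep(vox[, 1], each = nrow(off)) + off[, 1],
                  rep(vox[, 2], each = nrow(off)) + off[, 2],
                  rep(vox[, 3], each = nrow(off)) + off[, 3])
  if (clamp) {
    keep <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
      coords[, 2] >= 1 & coords[, 2] <= d[2] &
      coords[, 3] >= 1 & coords[, 3] <= d[3]
    coords <- coords[keep, , drop = FALSE]
  }
  lin <- (coords[, 3] - 1) * d[1] * d[2] + (coords[, 2] - 1) * d[1] + coords[, 1]
  unique(lin)
}

# turn a polyline into a 6-connected (face-adjacent) voxel chain, so that
# one-voxel threads stay hydraulically conductive on the staggered grid
path_6connect <- function(way) {
  rp <- unique(round(densify(way)))
  out <- rp[1, , drop = FALSE]
  cur <- rp[1, ]
  for (i in seq_len(nrow(rp) - 1L)) {
    nxt <- rp[i + 1L, ]
    for (a in 1:3) {
      while (cur[a] != nxt[a]) {
        cur[a] <- cur[a] + sign(nxt[a] - cur[a])
        out <- rbind(out, cur)
      }
    }
  }
  out
}

# densely resample a polyline given as a matrix of waypoints
densify <- function(way, step = 0.5) {
  if (nrow(way) < 2) return(way)
  out <- list()
  for (s in seq_len(nrow(way) - 1)) {
    a <- way[s, ]; b <- way[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = n)
    out[[s]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}
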