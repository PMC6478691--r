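#' Pleural distance map
#'
#' Euclidean distance (micrometres) from every voxel to the nearest
#' pleural-surface voxel (label 4).  When the volume has no pleural shell
#' but declares a pleural face, the one-voxel layer adjacent to that face
#' is used as the reference (distance 0 on that layer).
#'
#' @param vol a [label_volume()].
#' @return 3D numeric array of distances in micrometres; 0 on the
#'   reference voxels.
#' @export
pleural_distance_map <- function(vol) {
  d <- dim(vol$labels)
  sites <- vol$labels == LBL_PLEURA
  if (!any(sites)) {
    if (is.na(vol$pleural_direction))
      stop("volume has no pleural-surface voxels and no declared pleural face")
    sites <- face_slice_index(d, vol$pleural_direction)
  }
  array(.cpp_edt3d(as.vector(sites), d), d) * vol$voxel_pitch_um
}

#' Sample non-overlapping square regions of interest
#'
#' Randomly places axis-aligned square ROIs of the given physical side on
#' one z-plane, within the in-plane bounding box of the tissue, rejecting
#' overlaps.  Placement stops when `n_target` ROIs are accepted or after
#' `max_iter` rejected attempts; a shortfall is flagged on the result.
#' Supplying no seed mirrors the original time-seeded behaviour (the
#' result is then not reproducible).
#'
#' @param vol a [label_volume()].
#' @param z_plane z index of the sampling plane.
#' @param roi_side_um ROI side, micrometres (converted to voxels by
#'   rounding).
#' @param n_target number of ROIs requested.
#' @param max_iter cap on rejected placement attempts.
#' @param seed integer seed, or `NULL` for a time-derived seed.
#' @return data.frame of class `roi_set` with columns `y0`, `x0` (1-based
#'   corner), `side_vox`, `z0`; attributes `shortfall` (logical) and
#'   `attempts`.
#' @export
sample_rois <- function(vol, z_plane, roi_side_um = 830, n_target = 25L,
                        max_iter = 500L, seed = NULL) {
  d <- dim(vol$labels)
  side <- max(1L, as.integer(round(roi_side_um / vol$voxel_pitch_um)))
  if (side > d[2] || side > d[3])
    stop("roi_side (", side, " voxels) exceeds the image extent")
  sl <- vol$labels[z_plane, , ]
  tis <- sl != LBL_AIR
  if (!any(tis)) stop("selected z-plane contains no tissue voxels")
  ry <- range(which(rowSums(tis) > 0))
  rx <- range(which(colSums(tis) > 0))
  ylo <- ry[1]; yhi <- ry[2] - side + 1L
  xlo <- rx[1]; xhi <- rx[2] - side + 1L
  if (is.null(seed)) seed <- as.integer(as.numeric(Sys.time()) %% 2147483647)
  acc <- matrix(0L, 0, 2)
  rejected <- 0L
  with_seed(seed, {
    while (nrow(acc) < n_target && rejected < max_iter &&
           ylo <= yhi && xlo <= xhi) {
      y <- as.integer(floor(runif(1, ylo, yhi + 1)))
      x <- as.integer(floor(runif(1, xlo, xhi + 1)))
      ok <- TRUE
      if (nrow(acc)) {
        ok <- all(abs(acc[, 1] - y) >= side | abs(acc[, 2] - x) >= side)
      }
      if (ok) acc <- rbind(acc, c(y, x)) else rejected <- rejected + 1L
    }
  })
  out <- data.frame(y0 = acc[, 1], x0 = acc[, 2],
                    side_vox = rep(side, nrow(acc)),
                    z0 = rep(as.integer(z_plane), nrow(acc)))
  class(out) <- c("roi_set", "data.frame")
  attr(out, "shortfall") <- nrow(acc) < n_target
  attr(out, "attempts") <- rejected
  attr(out, "seed") <- seed
  out
}

#' Classify ROIs as subpleural or intralobular
#'
#' Takes the median pleural distance over the tissue voxels inside each
#' ROI square (on its selected z-plane); ROIs with median distance
#' strictly below the threshold are subpleural, all others intralobular.
#'
#' @param rois a [sample_rois()] result (or compatible data.frame).
#' @param vol the [label_volume()] the ROIs were sampled from.
#' @param distance_map output of [pleural_distance_map()] for `vol`.
#' @param threshold_um classification threshold, micrometres.
#' @param depth_um VOI extension depth along z, micrometres.
#' @return data.frame of VOI records: ROI columns plus `depth_vox`,
#'   `median_pleural_distance_um`, `region_class`.
#' @export
classify_rois <- function(rois, vol, distance_map, threshold_um = 830,
                          depth_um = 500) {
  depth_vox <- max(1L, as.integer(round(depth_um / vol$voxel_pitch_um)))
  n <- nrow(rois)
  med <- numeric(n)
  for (i in seq_len(n)) {
    ys <- rois$y0[i] + seq_len(rois$side_vox[i]) - 1L
    xs <- rois$x0[i] + seq_len(rois$side_vox[i]) - 1L
    lab <- vol$labels[rois$z0[i], ys, xs]
    dd <- distance_map[rois$z0[i], ys, xs]
    tis <- lab != LBL_AIR
    if (!any(tis)) stop("ROI ", i, " contains no tissue voxels")
    med[i] <- stats::median(dd[tis])
  }
  out <- cbind(as.data.frame(rois), depth_vox = depth_vox,
               median_pleural_distance_um = med,
               region_class = ifelse(med < threshold_um, "subpleural",
                                     "intralobular"))
  out
}

# voi box index ranges (z, y, x) for a voi record row (or NULL for the
# whole volume)
voi_box <- function(vol, voi) {
  d <- dim(vol$labels)
  if (is.null(voi))
    return(list(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3])))
  zs <- voi$z0 + seq_len(voi$depth_vox) - 1L
  ys <- voi$y0 + seq_len(voi$side_vox) - 1L
  xs <- voi$x0 + seq_len(voi$side_vox) - 1L
  if (max(zs) > d[1] || max(ys) > d[2] || max(xs) > d[3])
    stop("VOI box extends outside the volume")
  list(z = zs, y = ys, x = xs)
}

#' Lymphatic volume and surface measures of a VOI
#'
#' Volumes by voxel counting (lymph; tissue = labels 1-4), surface area by
#' triangulating the 0.5 isosurface of the (lightly mean-smoothed) lymph
#' mask with marching tetrahedra.
#'
#' @param vol a [label_volume()].
#' @param voi one row of a [classify_rois()] result, or `NULL` for the
#'   whole volume.
#' @param smooth smooth the binary mask with a 3-cube mean before
#'   triangulating (reduces staircase bias on curved surfaces).
#' @return one-row data.frame: `lymph_volume_um3`, `tissue_volume_um3`,
#'   `volume_fraction`, `surface_area_um2`, `sa_per_tissue_volume_per_um`.
#' @export
measure_volume_surface <- function(vol, voi = NULL, smooth = TRUE) {
  bx <- voi_box(vol, voi)
  lab <- vol$labels[bx$z, bx$y, bx$x, drop = FALSE]
  pitch <- vol$voxel_pitch_um
  lymph <- lab == LBL_LYMPH
  n_tis <- sum(lab != LBL_AIR)
  if (n_tis == 0L) stop("VOI has zero tissue volume")
  lv <- sum(lymph) * pitch^3
  tv <- n_tis * pitch^3
  sa <- if (any(lymph)) {
    surface_area_um2(lymph, pitch, smooth = smooth)
  } else 0
  data.frame(lymph_volume_um3 = lv, tissue_volume_um3 = tv,
             volume_fraction = lv / tv, surface_area_um2 = sa,
             sa_per_tissue_volume_per_um = sa / tv)
}

# isosurface area of a binary mask in um^2
surface_area_um2 <- function(mask, pitch_um, smooth = TRUE) {
  d <- dim(mask)
  field <- array(as.numeric(mask), d)
  if (smooth) {
    # 3-cube box mean computed by separable running sums
    field <- box_mean3(field)
  }
  .cpp_isosurface_area(as.vector(field), d, 0.5) * pitch_um^2
}

# separable 3x3x3 box mean with zero padding
box_mean3 <- function(a) {
  d <- dim(a)
  sm1 <- function(m, ax) {
    n <- d[ax]
    pad0 <- function(x, by) {
      idx <- seq_len(n) + by
      idx[idx < 1 | idx > n] <- NA
      out <- switch(ax,
                    m[idx, , , drop = FALSE],
                    m[, idx, , drop = FALSE],
                    m[, , idx, drop = FALSE])
      out[is.na(out)] <- 0
      out
    }
    (pad0(m, -1L) + m + pad0(m, 1L)) / 3
  }
  # NA indexing keeps array shape; replace NA slices by zero
  a1 <- sm1(a, 1L); a2 <- sm1(a1, 2L); sm1(a2, 3L)
}

#' Box-counting fractal dimension
#'
#' 3D box counting over corner-aligned boxes of size 2, 4, 8, ... up to a
#' quarter of the smallest grid dimension; the dimension is minus the
#' least-squares slope of log(occupied boxes) against log(box size).
#' Degenerate inputs (empty mask, fewer than three usable box sizes,
#' counts that do not vary, or a mask whose bounding box is under 4 voxels
#' across) return an excluded flag instead of a value, mirroring the
#' exclusion of small partial vessel volumes.
#'
#' @param mask 3D logical array.
#' @return list: `fractal_dimension` (numeric or `NA`), `excluded`
#'   (logical), `n_scales`, `box_sizes`, `counts`.
#' @export
fractal_dimension <- function(mask) {
  d <- dim(mask)
  excl <- function(sizes = integer(), counts = integer())
    list(fractal_dimension = NA_real_, excluded = TRUE,
         n_scales = length(sizes), box_sizes = sizes, counts = counts)
  if (!any(mask)) return(excl())
  smax <- min(d) / 4
  sizes <- 2^(seq_len(max(0, floor(log2(smax)))))
  if (length(sizes) < 3L) return(excl(sizes))
  idx <- which(mask, arr.ind = TRUE)
  ext <- apply(idx, 2, function(v) diff(range(v)) + 1L)
  if (max(ext) < 4L) return(excl(sizes))
  counts <- vapply(sizes, function(s) {
    key <- (ceiling(idx[, 1] / s) - 1) +
      (ceiling(idx[, 2] / s) - 1) * ceiling(d[1] / s) +
      (ceiling(idx[, 3] / s) - 1) * ceiling(d[1] / s) * ceiling(d[2] / s)
    length(unique(key))
  }, numeric(1))
  if (stats::sd(log(counts)) == 0) return(excl(sizes, counts))
  fit <- stats::lm(log(counts) ~ log(sizes))
  list(fractal_dimension = -unname(coef(fit)[2]), excluded = FALSE,
       n_scales = length(sizes), box_sizes = sizes, counts = counts)
}

#' Skeleton graph and branch metrics
#'
#' Thins the mask to a 1-voxel curve skeleton (topology-preserving,
#' 26-connectivity), classifies skeleton voxels by neighbour count
#' (endpoints <= 1, junctions > 2), merges adjacent junction voxels into
#' junction nodes, traces maximal branches between end/junction nodes, and
#' reports branch count, junction count, and the unweighted mean branch
#' tortuosity (path length over Euclidean end-to-end length).  Branches
#' with zero Euclidean length (closed loops) are excluded from the
#' tortuosity mean and counted.
#'
#' @param mask 3D logical array.
#' @param voxel_pitch_um voxel pitch, micrometres.
#' @return list: `graph` (data.frame of branches: path/Euclidean lengths in
#'   micrometres, tortuosity, end coordinates), `branch_count`,
#'   `junction_count`, `mean_tortuosity` (`NA` when no measurable branch),
#'   `loop_count`, `skeleton` (logical array).
#' @export
skeleton_metrics <- function(mask, voxel_pitch_um = 1) {
  d <- dim(mask)
  empty <- list(graph = data.frame(), branch_count = 0L, junction_count = 0L,
                mean_tortuosity = NA_real_, loop_count = 0L,
                skeleton = array(FALSE, d),
                skeleton_voxel_count = 0L, covered_voxel_count = 0L)
  if (!any(mask)) return(empty)
  sk <- array(.cpp_thin3d(as.vector(mask), d), d)
  vox <- which(sk)
  nv <- length(vox)
  if (nv == 0L) return(empty)
  coord <- cbind((vox - 1) %% d[1] + 1,
                 ((vox - 1) %/% d[1]) %% d[2] + 1,
                 (vox - 1) %/% (d[1] * d[2]) + 1)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  ea <- integer(); eb <- integer()
  for (q in seq_len(nrow(off))) {
    pz <- coord[, 1] + off[q, 1]
    py <- coord[, 2] + off[q, 2]
    px <- coord[, 3] + off[q, 3]
    ok <- pz >= 1 & pz <= d[1] & py >= 1 & py <= d[2] & px >= 1 & px <= d[3]
    nb <- match((px - 1) * d[1] * d[2] + (py - 1) * d[1] + pz, vox)
    keep <- ok & !is.na(nb)
    ea <- c(ea, which(keep)); eb <- c(eb, nb[keep])
  }
  nbrs <- vector("list", nv)
  if (length(ea)) {
    sp <- split(eb, ea)
    nbrs[as.integer(names(sp))] <- sp
  }
  nbrs[vapply(nbrs, is.null, logical(1))] <- list(integer())
  deg <- lengths(nbrs)
  # junction nodes: 26-connected groups of voxels with degree > 2
  jmask <- deg > 2L
  jgroup <- integer(nv)
  gid <- 0L
  for (t in which(jmask)) {
    if (jgroup[t] != 0L) next
    gid <- gid + 1L
    stack <- t
    jgroup[t] <- gid
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      for (u in nbrs[[v]]) if (jmask[u] && jgroup[u] == 0L) {
        jgroup[u] <- gid
        stack <- c(stack, u)
      }
    }
  }
  junction_count <- gid
  node_of <- function(t) if (jmask[t]) paste0("J", jgroup[t]) else paste0("V", t)

  # trace branches: maximal paths of degree-<=2 voxels between nodes
  # (endpoints, junction voxels), plus junction-junction direct links
  edge_used <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  branches <- list()
  trace_from <- function(t, first) {
    # walk from node voxel t through slab voxel `first`
    path <- c(t, first)
    plen <- sqrt(sum((coord[t, ] - coord[first, ])^2))
    prev <- t; cur <- first
    while (!jmask[cur] && deg[cur] == 2L) {
      nxt <- setdiff(nbrs[[cur]], prev)
      if (!length(nxt)) break
      nxt <- nxt[1]
      plen <- plen + sqrt(sum((coord[cur, ] - coord[nxt, ])^2))
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (cur == t && !jmask[cur]) break  # pure cycle
    }
    list(path = path, plen = plen)
  }
  is_node <- jmask | deg != 2L   # junction voxels, endpoints, isolated
  for (t in which(is_node)) {
    for (u in nbrs[[t]]) {
      if (is_node[u]) {
        # direct node-node link
        k <- ekey(t, u)
        if (is.null(edge_used[[k]]) && node_of(t) != node_of(u)) {
          edge_used[[k]] <- TRUE
          plen <- sqrt(sum((coord[t, ] - coord[u, ])^2))
          branches[[length(branches) + 1L]] <-
            list(a = t, b = u, plen = plen, path = c(t, u))
        }
        next
      }
      k <- ekey(t, u)
      if (!is.null(edge_used[[k]])) next
      tr <- trace_from(t, u)
      path <- tr$path
      b <- path[length(path)]
      # mark both terminal steps so the branch is traced once
      edge_used[[k]] <- TRUE
      if (length(path) >= 2)
        edge_used[[ekey(path[length(path) - 1L], b)]] <- TRUE
      branches[[length(branches) + 1L]] <-
        list(a = t, b = b, plen = tr$plen, path = path)
    }
  }
  # pure cycles with no node voxel at all (every voxel degree 2): count as
  # single loop branches
  seen <- logical(nv)
  for (br in branches) seen[br$path] <- TRUE
  for (t in which(!seen & deg == 2L)) {
    if (seen[t]) next
    tr <- trace_from(t, nbrs[[t]][1])
    seen[tr$path] <- TRUE
    branches[[length(branches) + 1L]] <-
      list(a = t, b = t, plen = tr$plen +
             sqrt(sum((coord[tr$path[length(tr$path)], ] - coord[t, ])^2)) *
             (tr$path[length(tr$path)] != t),
           path = tr$path)
  }
  if (!length(branches)) {
    out <- empty
    out$skeleton <- sk
    out$junction_count <- junction_count
    out$skeleton_voxel_count <- nv
    out$covered_voxel_count <- length(unique(c(which(jmask),
                                               which(deg == 0L))))
    return(out)
  }
  # digital chain-code length overestimates smooth curves; measure branch
  # path length on a lightly smoothed polyline (moving average, endpoints
  # pinned, so straight branches and the tortuosity >= 1 bound are exact)
  smooth_len <- function(path) {
    pc <- coord[path, , drop = FALSE]
    np <- nrow(pc)
    if (np > 4) {
      sm <- pc
      for (a in 1:3)
        sm[, a] <- stats::filter(pc[, a], rep(1 / 5, 5), sides = 2)
      bad <- is.na(sm[, 1])
      sm[bad, ] <- pc[bad, ]
      sm[1, ] <- pc[1, ]; sm[np, ] <- pc[np, ]
      pc <- sm
    }
    sum(sqrt(rowSums((pc[-1, , drop = FALSE] -
                        pc[-np, , drop = FALSE])^2)))
  }
  gdf <- do.call(rbind, lapply(branches, function(br) {
    br$plen <- smooth_len(br$path)
    eu <- sqrt(sum((coord[br$a, ] - coord[br$b, ])^2))
    data.frame(path_length_um = br$plen * voxel_pitch_um,
               euclid_length_um = eu * voxel_pitch_um,
               tortuosity = ifelse(eu > 0, br$plen / eu, NA_real_),
               z1 = coord[br$a, 1], y1 = coord[br$a, 2], x1 = coord[br$a, 3],
               z2 = coord[br$b, 1], y2 = coord[br$b, 2], x2 = coord[br$b, 3])
  }))
  loops <- sum(gdf$euclid_length_um == 0)
  tort <- gdf$tortuosity[is.finite(gdf$tortuosity)]
  covered <- unique(c(unlist(lapply(branches, `[[`, "path")),
                      which(jmask), which(deg == 0L)))
  list(graph = gdf, branch_count = nrow(gdf),
       junction_count = junction_count,
       mean_tortuosity = if (length(tort)) mean(tort) else NA_real_,
       loop_count = loops, skeleton = sk,
       skeleton_voxel_count = nv, covered_voxel_count = length(covered))
}

#' Full morphometric record for one VOI
#'
#' Composes the volume/surface, fractal and skeleton measures into the
#' six-measure morphometric record.
#'
#' @inheritParams measure_volume_surface
#' @return one-row data.frame with the six morphometric measures plus the
#'   fractal exclusion flag (and, when `voi` carries them, the pleural
#'   distance and region class).
#' @export
measure_voi <- function(vol, voi = NULL) {
  vs <- measure_volume_surface(vol, voi)
  bx <- voi_box(vol, voi)
  lymph <- vol$labels[bx$z, bx$y, bx$x, drop = FALSE] == LBL_LYMPH
  fd <- fractal_dimension(lymph)
  sk <- if (any(lymph)) skeleton_metrics(lymph, vol$voxel_pitch_um)
  else list(branch_count = 0L, junction_count = 0L,
            mean_tortuosity = NA_real_)
  rec <- cbind(vs,
               data.frame(fractal_dimension = fd$fractal_dimension,
                          excluded_fractal = fd$excluded,
                          branch_count = sk$branch_count,
                          junction_count = sk$junction_count,
                          mean_tortuosity = sk$mean_tortuosity))
  if (!is.null(voi) && !is.null(voi$median_pleural_distance_um)) {
    rec$median_pleural_distance_um <- voi$median_pleural_distance_um
    rec$region_class <- voi$region_class
  }
  rec
}

#' Morphometry over a set of VOIs
#'
#' @param vol a [label_volume()].
#' @param vois data.frame from [classify_rois()].
#' @return data.frame, one row per VOI.
#' @export
measure_vois <- function(vol, vois) {
  do.call(rbind, lapply(seq_len(nrow(vois)), function(i)
    cbind(voi = i, measure_voi(vol, vois[i, ]))))
}
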