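#' Synthetic lung-tissue volume specification
#'
#' Parameters of the labelled-volume generator that stands in for the
#' segmented micro-CT + immunohistochemistry data: a pleural slab on one
#' face, a sparse blood-vessel tree with openings on specified cube faces,
#' alveolar airspaces, and a lymphatic network whose volume fraction
#' follows a linear depth model `vf(d) = vf0 + gradient * d` with a
#' configurable fraction of partially collapsed (1-voxel-thick sheet)
#' segments, perivascular segments, and optionally a lymphatic ring fully
#' encircling a blood vessel.
#'
#' @param shape integer triple (nz, ny, nx), voxels; each >= 32.
#' @param voxel_pitch_um voxel pitch, micrometres.
#' @param target_lymph_vf_at_pleura lymphatic volume fraction at zero
#'   pleural distance.
#' @param lymph_vf_gradient volume-fraction change per micrometre of
#'   pleural distance (<= 0 for lung-like tissue).
#' @param blood_tree list: `depth` (branching depth), `root_radius_um`,
#'   `taper` (radius factor per level).
#' @param lymph_network list: `radius_um` (length-2 range),
#'   `collapse_fraction` (fraction of segments rendered as 1-voxel sheets),
#'   `perivascular_fraction`, `encircling_ring` (logical),
#'   `ribbon_width_um` (length-2 range of sheet widths).
#' @param openings named list with elements `blood` and `lymph`, each a
#'   named integer vector of per-face lumen opening counts (face names
#'   `"z-"`, `"z+"`, `"y-"`, `"y+"`, `"x-"`, `"x+"`).
#' @param air_fraction target airspace fraction of the volume; airspaces
#'   are carved as overlapping spherical alveoli leaving thin septa.
#' @param pleural_slab add a 2-voxel pleural shell.
#' @param pleural_face which face carries the pleural shell: `"z-"`
#'   (default), `"y-"`, or `"x-"`.  Generation always happens with the
#'   pleura at `"z-"`; other choices permute the axes of the finished
#'   volume, so that ROI sampling on a z-plane can see a range of pleural
#'   distances (the pleura edge-on in the section, as in stained
#'   sections).  `shape` refers to the final, permuted volume.
#' @param depth_bin_um width of the depth bins used for volume-fraction
#'   accounting and ground-truth reporting.
#' @param seed integer seed; the generator is fully deterministic given
#'   the spec (including the seed).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(64L, 64L, 64L),
                           voxel_pitch_um = 13.2,
                           target_lymph_vf_at_pleura = 0.035,
                           lymph_vf_gradient = -8e-6,
                           blood_tree = list(depth = 2L, root_radius_um = 40,
                                             taper = 0.75),
                           lymph_network = list(radius_um = c(10, 30),
                                                collapse_fraction = 0.3,
                                                perivascular_fraction = 0.4,
                                                encircling_ring = TRUE,
                                                ribbon_width_um = c(40, 80)),
                           openings = list(blood = c("z+" = 2L, "y+" = 1L,
                                                     "x+" = 1L, "y-" = 1L,
                                                     "x-" = 1L),
                                           lymph = c("z+" = 1L, "y-" = 1L)),
                           air_fraction = 0.45,
                           pleural_slab = TRUE,
                           pleural_face = "z-",
                           depth_bin_um = 110,
                           seed = 1L) {
  spec <- structure(
    list(shape = as.integer(shape), voxel_pitch_um = voxel_pitch_um,
         target_lymph_vf_at_pleura = target_lymph_vf_at_pleura,
         lymph_vf_gradient = lymph_vf_gradient,
         blood_tree = blood_tree, lymph_network = lymph_network,
         openings = openings, air_fraction = air_fraction,
         pleural_slab = isTRUE(pleural_slab),
         pleural_face = pleural_face, depth_bin_um = depth_bin_um,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

# axis permutation mapping the generation frame (pleura at z-) onto the
# requested pleural face; perm[i] gives the generation-frame axis that
# becomes final axis i
pleural_perm <- function(pleural_face) {
  switch(pleural_face,
         "z-" = c(1L, 2L, 3L),
         "y-" = c(2L, 1L, 3L),
         "x-" = c(2L, 3L, 1L),
         stop("pleural_face must be one of z-, y-, x-"))
}

# translate a generation-frame face name into the final frame
map_face <- function(face, perm) {
  ax <- face_axis(face)
  newax <- which(perm == ax)
  paste0(c("z", "y", "x")[newax], substr(face, 2, 2))
}

#' @rdname synthetic_spec
#' @param spec a `synthetic_spec`.
#' @export
validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (length(shape) != 3L || any(shape < 32L))
      stop("infeasible spec: shape must be at least 32 voxels per axis")
    if (voxel_pitch_um <= 0) stop("voxel_pitch_um must be > 0")
    fr <- c(target_lymph_vf_at_pleura, air_fraction,
            lymph_network$collapse_fraction,
            lymph_network$perivascular_fraction)
    if (any(fr < 0 | fr > 1))
      stop("infeasible spec: fractions must lie in [0, 1]")
    rb <- round(blood_tree$root_radius_um / voxel_pitch_um)
    rl <- round(lymph_network$radius_um / voxel_pitch_um)
    if (rb < 1 || any(pmax(rl, 1) < 1))
      stop("infeasible spec: vessel radius below 1 voxel after conversion")
    for (cls in names(openings)) {
      op <- openings[[cls]]
      if (is.null(op) || !length(op)) next
      if (!all(names(op) %in% FACE_NAMES))
        stop("unknown face name in openings: ",
             paste(setdiff(names(op), FACE_NAMES), collapse = ", "))
      if (isTRUE(pleural_slab) && !is.null(pleural_face) &&
          any(names(op) == pleural_face & op > 0))
        stop("infeasible spec: ", cls, " openings requested on the ",
             "pleural face ", pleural_face)
      r <- if (cls == "blood") rb else max(1, max(rl))
      for (f in names(op)) {
        ext <- shape[setdiff(1:3, face_axis(f))]
        cap <- prod(pmax(0, floor((ext - 2 * (r + 3)) / (2 * r + 6)) + 1))
        if (op[[f]] > cap)
          stop("infeasible spec: ", op[[f]], " ", cls, " openings do not ",
               "fit on face ", f, " (capacity ", cap, ")")
      }
    }
  })
  invisible(spec)
}

# sample n well-separated points on a named face; returns (z,y,x) matrix.
# On lateral faces (axis != 1), the depth (z) coordinate can be restricted
# to a fractional range: supply openings enter deep, drainage openings
# shallow, mirroring pleura-ward vessel courses.
sample_face_points <- function(d, face, n, radius, zfrac = c(0, 1),
                               avoid = NULL, avoid_sep = 0) {
  ax <- face_axis(face)
  lat <- setdiff(1:3, ax)
  m <- radius + 3
  sep <- 2 * radius + 6
  lo <- rep(m + 1, 3); hi <- d - m
  if (ax != 1L) {
    lo[1] <- max(lo[1], zfrac[1] * d[1])
    hi[1] <- min(hi[1], zfrac[2] * d[1])
  }
  pts <- matrix(0, 0, 3)
  tries <- 0L
  far_enough <- function(ref, p, s) {
    !nrow(ref) || all(sqrt(rowSums((ref[, lat, drop = FALSE] -
      matrix(p[lat], nrow(ref), 2, byrow = TRUE))^2)) >= s)
  }
  avoid_here <- if (!is.null(avoid) && nrow(avoid))
    avoid[avoid[, ax] == (if (face_side(face) < 0) 1 else d[ax]), ,
          drop = FALSE]
  else matrix(0, 0, 3)
  while (nrow(pts) < n && tries < 500L) {
    tries <- tries + 1L
    p <- numeric(3)
    p[ax] <- if (face_side(face) < 0) 1 else d[ax]
    p[lat] <- round(runif(2, lo[lat], hi[lat]))
    if (far_enough(pts, p, sep) && far_enough(avoid_here, p, avoid_sep))
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < n)
    stop("infeasible spec: could not place ", n, " openings on face ", face)
  pts
}

# depth restriction for openings on a lateral face: "+" faces deep (they
# become distal inlets), "-" faces shallow (proximal outlets)
face_zfrac <- function(face) {
  if (face_axis(face) == 1L) c(0, 1)
  else if (face_side(face) > 0) c(0.55, 0.92) else c(0.08, 0.45)
}

# inward unit normal of a face
face_inward <- function(face) {
  v <- numeric(3)
  v[face_axis(face)] <- -face_side(face)
  v
}

#' Generate a synthetic labelled lung volume
#'
#' Realises a [synthetic_spec()]: pleural slab, blood-vessel tree
#' connecting the requested face openings through a central hub with
#' tapered interior branches, spherical alveolar airspaces carved to the
#' target air fraction, and a lymphatic network filled bin-by-bin to the
#' linear volume-fraction depth model (tubular, 1-voxel-sheet "collapsed",
#' and perivascular segments; optionally a ring fully encircling a blood
#' vessel).  Deterministic given the spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `volume` (a [label_volume()]) and `truth`
#'   (ground truth: per-depth-bin volume fractions, realized opening
#'   counts, centreline polylines, realized air fraction).
#' @export
generate_voi <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed, generate_voi_impl(spec))
}

generate_voi_impl <- function(spec) {
  pf <- if (is.null(spec$pleural_face)) "z-" else spec$pleural_face
  fperm <- pleural_perm(pf)
  invp <- order(fperm)
  # generation happens with the pleura at z-; spec shape and opening face
  # names are given in the final (possibly permuted) frame
  d <- spec$shape[invp]
  for (cls in names(spec$openings)) {
    op <- spec$openings[[cls]]
    if (!is.null(op) && length(op))
      names(spec$openings[[cls]]) <-
        vapply(names(op), map_face, character(1), perm = invp)
  }
  pitch <- spec$voxel_pitch_um
  arr <- array(LBL_TISSUE, d)
  if (spec$pleural_slab) arr[1:2, , ] <- LBL_PLEURA

  rb <- max(1, round(spec$blood_tree$root_radius_um / pitch))
  rl_rng <- pmax(1, round(sort(spec$lymph_network$radius_um) / pitch))
  wrib_rng <- pmax(2, round(sort(spec$lymph_network$ribbon_width_um) / pitch))

  hub <- round(d / 2 + runif(3, -0.08, 0.08) * d)
  hub <- pmin(pmax(hub, rb + 4), d - rb - 4)
  if (spec$pleural_slab) hub[1] <- max(hub[1], rb + 6)

  centrelines <- list(blood = list(), lymph = list())
  margin_clamp <- function(p, m) {
    if (is.matrix(p)) {
      for (a in 1:3) p[, a] <- pmin(pmax(p[, a], m), d[a] - m)
      p
    } else pmin(pmax(p, m), d - m)
  }
  sample1 <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

  # --- lymph opening stubs (sampled first so blood vessels and alveoli
  # keep clear of the entry corridors) --------------------------------------
  op_l <- spec$openings$lymph
  rl_max <- max(rl_rng)
  lymph_stubs <- list()
  stub_points <- matrix(0, 0, 3)
  corridor <- array(FALSE, d)
  if (!is.null(op_l) && length(op_l)) {
    for (f in names(op_l)) {
      pts <- sample_face_points(d, f, op_l[[f]], rl_max, face_zfrac(f))
      stub_points <- rbind(stub_points, pts)
      for (q in seq_len(nrow(pts))) {
        p0 <- pts[q, ]
        inw <- face_inward(f)
        len <- rl_max + 8   # short entry stub; depth bins stay on budget
        way <- rbind(p0, p0 + inw * (rl_max + 3),
                     margin_clamp(p0 + inw * len + runif(3, -2, 2),
                                  rl_max + 3))
        if (spec$pleural_slab)
          way[-1, 1] <- pmax(way[-1, 1], rl_max + 5)
        pl <- densify(way)
        lymph_stubs[[length(lymph_stubs) + 1L]] <- pl
        corridor[brush_voxels(d, pl, rl_rng[1] + 1)] <- TRUE
      }
    }
  }
  # --- lymphatic backbone: a collector path descending pleura-ward, so
  # the whole network can grow connected (lymph drains toward the pleura)
  bb_start <- if (length(lymph_stubs)) {
    st <- lymph_stubs[[1]]
    st[nrow(st), ]
  } else c(d[1] - 5, round(runif(2, 6, d[2:3] - 6)))
  zfloor_bb <- if (spec$pleural_slab) 4 else rl_rng[1] + 2
  zceil_bb <- d[1] - 4
  # the backbone spans the whole depth axis: up from the entry stub to the
  # distal side, then descending pleura-ward
  bb <- if (bb_start[1] < zceil_bb - 4)
    rbind(c(zceil_bb, min(max(bb_start[2] + runif(1, -4, 4), 5), d[2] - 5),
            min(max(bb_start[3] + runif(1, -4, 4), 5), d[3] - 5)),
          bb_start)
  else matrix(bb_start, 1)
  cur <- bb_start
  while (cur[1] > zfloor_bb + 4) {
    cur <- c(max(cur[1] - runif(1, 4, 7), zfloor_bb),
             min(max(cur[2] + runif(1, -4, 4), 5), d[2] - 5),
             min(max(cur[3] + runif(1, -4, 4), 5), d[3] - 5))
    bb <- rbind(bb, cur)
  }
  if (nrow(bb) < 2L)
    bb <- rbind(bb, pmax(bb[1, ] - c(4, 0, 0), c(zfloor_bb, 2, 2)))
  backbone <- densify(bb)
  corridor[brush_voxels(d, backbone, rl_rng[1] + 1)] <- TRUE
  # bridges joining the remaining entry stubs to the backbone, reserved
  # now so neither vessels nor alveoli can sever them
  stub_bridges <- list()
  if (length(lymph_stubs) > 1) {
    for (si in 2:length(lymph_stubs)) {
      tip <- lymph_stubs[[si]][nrow(lymph_stubs[[si]]), ]
      bnear <- backbone[which.min(colSums((t(backbone) - tip)^2)), ]
      br <- path_6connect(rbind(tip, bnear))
      stub_bridges[[length(stub_bridges) + 1L]] <- br
      corridor[brush_voxels(d, br, rl_rng[1] + 1)] <- TRUE
    }
  }
  # wide volumes additionally get lateral collector lines off the
  # backbone (interlobular-septum-like), so the network can span the
  # whole field while staying connected
  laterals <- list()
  n_lat <- max(0L, as.integer(round(prod(d[2:3]) / 140^2)) - 1L)
  if (n_lat > 0L) {
    bint <- backbone[backbone[, 1] >= zfloor_bb + 1 &
                       backbone[, 1] <= d[1] - 4, , drop = FALSE]
    for (q in seq_len(n_lat)) {
      at <- bint[sample.int(nrow(bint), 1), ]
      ang <- runif(1, 0, 2 * pi)
      dirl <- c(runif(1, -0.15, 0.15), cos(ang), sin(ang))
      dirl <- dirl / sqrt(sum(dirl^2))
      len <- runif(1, 0.35, 0.6) * max(d[2:3])
      way <- rbind(at,
                   margin_clamp(at + dirl * len / 3 + runif(3, -4, 4), 5),
                   margin_clamp(at + dirl * 2 * len / 3 + runif(3, -4, 4), 5),
                   margin_clamp(at + dirl * len, 5))
      way[, 1] <- pmin(pmax(way[, 1], zfloor_bb + 1), d[1] - 4)
      pl <- densify(way)
      laterals[[q]] <- pl
      corridor[brush_voxels(d, pl, rl_rng[1] + 1)] <- TRUE
    }
  }

  # sentinel keeps blood out of the lymph corridors
  sent <- corridor & arr == LBL_TISSUE
  arr[sent] <- 9L

  # --- blood tree ----------------------------------------------------------
  op_b <- spec$openings$blood
  ring_host <- NULL
  if (!is.null(op_b) && length(op_b)) {
    first <- TRUE
    for (f in names(op_b)) {
      pts <- sample_face_points(d, f, op_b[[f]], rb, face_zfrac(f),
                                avoid = stub_points,
                                avoid_sep = rb + rl_max + 6)
      for (q in seq_len(nrow(pts))) {
        p0 <- pts[q, ]
        if (first && f == "z+") {
          # nudge the ring host laterally so the encircling ring clears
          # the volume faces
          rho <- rb + 2
          p0[2:3] <- pmin(pmax(p0[2:3], rho + 3), d[2:3] - rho - 3)
        }
        inw <- face_inward(f)
        papp <- p0 + inw * (rb + 3)
        if (first && f == "z+") {
          # straight axial approach so a lymphatic ring can encircle it
          pdeep <- p0 + inw * (rb + 14)
          way <- rbind(p0, papp, pdeep,
                       margin_clamp((pdeep + hub) / 2 +
                                      runif(3, -3, 3), rb + 3), hub)
          ring_host <- list(z = round(p0[1] - rb - 8), y = p0[2], x = p0[3])
          first <- FALSE
        } else {
          mid <- margin_clamp((papp + hub) / 2 + runif(3, -4, 4), rb + 3)
          way <- rbind(p0, papp, mid, hub)
        }
        way[-1, ] <- margin_clamp(way[-1, , drop = FALSE], rb + 3)
        if (spec$pleural_slab)
          way[-1, 1] <- pmax(way[-1, 1], rb + 5)
        pl <- densify(way)
        arr <- rasterize_brush(arr, pl, rb, LBL_BLOOD,
                               over = LBL_TISSUE, clamp = TRUE)
        centrelines$blood <- c(centrelines$blood, list(pl))
        # reserve the encircling-ring corridor as soon as the host path
        # exists, before any other vessel path can cross it
        if (isTRUE(spec$lymph_network$encircling_ring) &&
            !is.null(ring_host) && is.null(ring_host$pts)) {
          rho <- rb + 2
          th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rho * 2))
          ring_pts <- cbind(ring_host$z, ring_host$y + rho * cos(th),
                            ring_host$x + rho * sin(th))
          ring_zone <- brush_voxels(d, ring_pts, 2)
          arr[ring_zone[arr[ring_zone] == LBL_TISSUE]] <- 9L
          corridor[ring_zone] <- TRUE
          ring_host$pts <- ring_pts
          # reserve a bridge from the ring to the backbone so the ring
          # stays part of the connected network
          bnear <- backbone[which.min(abs(backbone[, 1] - ring_host$z)), ]
          rnear <- ring_pts[which.min((ring_pts[, 2] - bnear[2])^2 +
                                        (ring_pts[, 3] - bnear[3])^2), ]
          bridge <- path_6connect(rbind(rnear, bnear))
          bridge_zone <- brush_voxels(d, bridge, rl_rng[1] + 1)
          arr[bridge_zone[arr[bridge_zone] == LBL_TISSUE]] <- 9L
          corridor[bridge_zone] <- TRUE
          ring_host$bridge <- bridge
        }
      }
    }
    # interior tapered branches
    depth <- spec$blood_tree$depth
    if (depth >= 2 && length(centrelines$blood)) {
      for (lev in 2:depth) {
        rbr <- max(1, round(rb * spec$blood_tree$taper^(lev - 1)))
        for (b in seq_len(2^(lev - 2))) {
          src <- centrelines$blood[[sample.int(length(centrelines$blood), 1)]]
          at <- src[sample.int(nrow(src), 1), ]
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          len <- round(min(d) / 4)
          way <- rbind(at, margin_clamp(at + dir * len / 2, rbr + 3),
                       margin_clamp(at + dir * len, rbr + 3))
          pl <- densify(way)
          arr <- rasterize_brush(arr, pl, rbr, LBL_BLOOD,
                                 over = LBL_TISSUE, clamp = TRUE)
          centrelines$blood <- c(centrelines$blood, list(pl))
        }
      }
    }
  }

  # blood tree finished: release the corridor sentinel
  arr[arr == 9L] <- LBL_TISSUE

  # --- alveolar airspaces --------------------------------------------------
  air_target <- round(spec$air_fraction * prod(d))
  realized_air <- 0L
  if (air_target > 0) {
    # distance to blood/pleura keeps septa and the ring zone around
    # vessels intact; the (already dilated) lymph corridors need only a
    # small clearance
    forbidden <- arr == LBL_BLOOD | arr == LBL_PLEURA
    dist_forb <- if (any(forbidden))
      array(.cpp_edt3d(as.vector(forbidden), d), d)
    else array(Inf, d)
    dist_corr <- if (any(corridor))
      array(.cpp_edt3d(as.vector(corridor), d), d)
    else array(Inf, d)
    centres <- matrix(0, 0, 3)
    radii <- numeric()
    attempts <- 0L
    r_rng_um <- c(65, 105)  # alveolus radius range
    # alveoli may be clipped by the volume boundary (as in a real VOI);
    # neighbouring alveoli may merge (ducts / pores), leaving thin septa
    while (realized_air < air_target && attempts < 20000L) {
      attempts <- attempts + 1L
      r <- max(2, runif(1, r_rng_um[1], r_rng_um[2]) / pitch)
      c0 <- round(runif(3, 3, d - 2))
      if (dist_forb[c0[1], c0[2], c0[3]] <= r + 1.5) next
      if (dist_corr[c0[1], c0[2], c0[3]] <= r + 1.5) next
      if (nrow(centres)) {
        dd <- sqrt(rowSums((centres - matrix(c0, nrow(centres), 3,
                                             byrow = TRUE))^2))
        if (any(dd < 0.6 * (radii + r) + 1)) next
      }
      vox <- brush_voxels(d, matrix(c0, 1), r)
      vox <- vox[arr[vox] == LBL_TISSUE]
      arr[vox] <- LBL_AIR
      realized_air <- realized_air + length(vox)
      centres <- rbind(centres, c0)
      radii <- c(radii, r)
    }
  }

  # --- lymphatic network ---------------------------------------------------
  # pleural distance reference: the pleural shell when present, else the z-
  # face layer
  pl_mask <- arr == LBL_PLEURA
  if (any(pl_mask)) {
    dist_um <- array(.cpp_edt3d(as.vector(pl_mask), d), d) * pitch
  } else {
    dist_um <- array(rep((seq_len(d[1]) - 1) * pitch, prod(d[2:3])), d)
  }
  binw <- spec$depth_bin_um
  bin_of <- pmin(array(as.integer(dist_um %/% binw), d),
                 as.integer(max(dist_um[arr != LBL_AIR]) %/% binw))
  bins <- sort(unique(as.vector(bin_of[arr != LBL_AIR])))
  # actual z-extent of a depth bin (accounts for the pleural offset)
  slice_has_bin <- function(b) which(vapply(seq_len(d[1]), function(z)
    any(bin_of[z, , ] == b & arr[z, , ] != LBL_AIR), logical(1)))
  # a sliver bin confined to the face-adjacent layers cannot receive any
  # lymph (face protection); merge it into its neighbour
  while (length(bins) > 1L) {
    wz <- slice_has_bin(max(bins))
    if (all(wz > d[1] - 2L)) {
      bin_of[bin_of == max(bins)] <- max(bins) - 1L
      bins <- bins[-length(bins)]
    } else break
  }
  vf_at <- function(dmid) spec$target_lymph_vf_at_pleura +
    spec$lymph_vf_gradient * dmid
  mids <- (bins + 0.5) * binw
  targets <- vf_at(mids)
  if (any(targets < 0))
    stop("infeasible spec: lymph_vf_gradient drives the target volume ",
         "fraction negative at depth ", mids[which(targets < 0)[1]], " um")

  tissue_per_bin <- vapply(bins, function(b)
    sum(bin_of == b & arr != LBL_AIR), integer(1))
  budget <- round(targets * tissue_per_bin)
  placed <- integer(length(bins))
  # commit candidate voxels, optionally truncating along the path so a
  # depth bin's budget is met exactly (no overshoot)
  add_lymph <- function(vox, bin_idx = NULL, origin = NULL) {
    vox <- vox[arr[vox] == LBL_TISSUE]
    if (!length(vox)) return(invisible(NULL))
    if (!is.null(bin_idx)) {
      remaining <- budget[bin_idx] - placed[bin_idx]
      inb <- bin_of[vox] == bins[bin_idx]
      if (sum(inb) > remaining && !is.null(origin)) {
        ii <- (vox - 1) %% d[1] + 1
        jj <- ((vox - 1) %/% d[1]) %% d[2] + 1
        kk <- (vox - 1) %/% (d[1] * d[2]) + 1
        o <- order((ii - origin[1])^2 + (jj - origin[2])^2 +
                     (kk - origin[3])^2)
        vox <- vox[o]; inb <- inb[o]
        cut <- which(cumsum(inb) >= remaining)[1]
        vox <- vox[seq_len(cut)]
      }
    }
    arr[vox] <<- LBL_LYMPH
    tb <- tabulate(match(bin_of[vox], bins), nbins = length(bins))
    placed <<- placed + tb
    invisible(NULL)
  }

  # truncate a polyline at the first point obstructed by air or blood, so
  # committed paths stay connected to their starting structure
  trim_at_obstruction <- function(pts) {
    rp <- round(pts)
    inb <- rp[, 1] >= 1 & rp[, 1] <= d[1] & rp[, 2] >= 1 & rp[, 2] <= d[2] &
      rp[, 3] >= 1 & rp[, 3] <= d[3]
    lab <- rep(-1L, nrow(rp))
    lab[inb] <- arr[rp[inb, , drop = FALSE]]
    good <- lab %in% c(LBL_TISSUE, LBL_LYMPH)
    bad1 <- which(!good)[1]
    if (is.na(bad1)) pts else pts[seq_len(bad1 - 1L), , drop = FALSE]
  }
  anchors <- matrix(NA_real_, 0, 3)
  commit_lymph_path <- function(pts, radius, bin_idx = NULL,
                                origin = NULL) {
    if (is.null(pts) || nrow(pts) < 2L) return(invisible(FALSE))
    add_lymph(brush_voxels(d, pts, radius), bin_idx, origin)
    anchors <<- rbind(anchors, pts)
    centrelines$lymph <<- c(centrelines$lymph, list(pts))
    invisible(TRUE)
  }

  # collectors entering at the requested face openings, then the backbone
  # they drain into
  for (pl in lymph_stubs) commit_lymph_path(pl, rl_rng[1])
  commit_lymph_path(backbone, rl_rng[1])
  for (pl in laterals) commit_lymph_path(pl, rl_rng[1])
  # remaining collectors join the backbone through the reserved bridges
  # (thin threads: they are plumbing, and low-VF depth bins stay on budget)
  for (pl in stub_bridges) commit_lymph_path(pl, 0)

  # encircling perivascular ring (corridor reserved during tree growth);
  # rendered one voxel thick, like the collapsed sheet morphology of real
  # perivascular lymphatics
  ring_ok <- FALSE
  if (isTRUE(spec$lymph_network$encircling_ring) &&
      !is.null(ring_host$pts)) {
    commit_lymph_path(ring_host$pts, 0)
    if (!is.null(ring_host$bridge))
      commit_lymph_path(trim_at_obstruction(ring_host$bridge), 0)
    ring_ok <- TRUE
  }

  # bin filling with tubular / collapsed / perivascular segments.
  # Tubular growth is geodesic: a BFS distance field from the existing
  # network through interior tissue, and new segments walking downhill
  # from a sampled target back to the network -- connected by construction
  # and threading the septa around airspaces, as real lymphatics do.
  blood_pts <- if (length(centrelines$blood))
    do.call(rbind, centrelines$blood) else NULL
  geo_arr <- NULL
  geo_age <- Inf
  geo_interior <- {
    gi <- array(TRUE, d)
    gi[c(1:3, (d[1] - 2):d[1]), , ] <- FALSE
    gi[, c(1:3, (d[2] - 2):d[2]), ] <- FALSE
    gi[, , c(1:3, (d[3] - 2):d[3])] <- FALSE
    gi
  }
  # the walk field is restricted to the bin's z-slab, so sprouts cannot
  # spill into neighbouring depth bins; the backbone crosses every slab
  # and provides the in-slab seeds
  refresh_geo <- function(zlo, zhi) {
    slab <- geo_interior
    if (zlo > 1L) slab[1:(zlo - 1L), , ] <- FALSE
    if (zhi < d[1]) slab[(zhi + 1L):d[1], , ] <- FALSE
    geo_arr <<- array(.cpp_geodesic(
      as.vector((arr == LBL_TISSUE | arr == LBL_LYMPH) & slab),
      as.vector(arr == LBL_LYMPH), d), d)
    geo_age <<- 0
  }
  geo_interval <- max(6, round(prod(d) / 2e4))
  geodesic_path <- function(zfloor, zceil, m, zlo, zhi) {
    if (geo_age > geo_interval) refresh_geo(zlo, zhi)
    target <- NULL
    for (try in 1:8) {
      tg <- c(sample1(as.integer(zfloor), as.integer(zceil)),
              round(runif(1, m + 1, d[2] - m)),
              round(runif(1, m + 1, d[3] - m)))
      gv <- geo_arr[tg[1], tg[2], tg[3]]
      if (arr[tg[1], tg[2], tg[3]] == LBL_TISSUE && gv >= 3) {
        target <- tg
        break
      }
    }
    if (is.null(target)) return(NULL)
    g <- geo_arr[target[1], target[2], target[3]]
    path <- matrix(target, 1)
    cur <- target
    steps <- 0L
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    while (g > 0L && steps < 800L) {
      steps <- steps + 1L
      nb <- sweep(offs, 2, cur, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      gv <- geo_arr[nb]
      down <- which(gv == g - 1L)
      if (!length(down)) return(NULL)
      pick <- down[sample1(1L, length(down))]
      cur <- nb[pick, ]
      g <- g - 1L
      path <- rbind(path, cur)
    }
    if (g > 0L) return(NULL)
    path
  }
  for (bi in seq_along(bins)) {
    wz <- slice_has_bin(bins[bi])
    if (!length(wz)) next
    zlo <- min(wz); zhi <- max(wz)
    geo_age <- Inf   # the walk field is per-slab
    # geodesic walk window leaves room for the brush on both sides
    zfw <- zlo + max(rl_rng) + 1L
    zcw <- zhi - max(rl_rng) - 1L
    geo_ok <- zcw >= zfw
    walk_lo <- zfw; walk_hi <- zcw
    if (geo_ok) {
      # thin slabs of wide volumes can be laterally disconnected by
      # alveoli spanning the slab; pad the walk field until most in-slab
      # tissue is geodesically reachable (bounded spill, counted per bin)
      pad <- 0L
      repeat {
        walk_lo <- max(zfw - pad, 2L)
        walk_hi <- min(zcw + pad, d[1] - 1L)
        refresh_geo(walk_lo, walk_hi)
        tis <- arr[zfw:zcw, , , drop = FALSE] == LBL_TISSUE
        reach <- geo_arr[zfw:zcw, , , drop = FALSE] >= 0L
        frac <- if (any(tis)) mean(reach[tis]) else 0
        if (frac >= 0.5 || pad >= 12L) break
        pad <- pad + 4L
      }
    }
    guard <- 0L
    guard_max <- max(400L, as.integer(ceiling(budget[bi] / 4)))
    while (placed[bi] < budget[bi] && guard < guard_max) {
      guard <- guard + 1L
      remaining <- budget[bi] - placed[bi]
      collapsed <- runif(1) < spec$lymph_network$collapse_fraction
      rl <- sample1(rl_rng[1], rl_rng[2])
      m <- (if (collapsed) max(wrib_rng) / 2 else rl) + 2
      periv <- !is.null(blood_pts) &&
        runif(1) < spec$lymph_network$perivascular_fraction
      if (periv) {
        inbin <- blood_pts[, 1] >= zlo & blood_pts[, 1] <= zhi
        if (!any(inbin)) periv <- FALSE
      }
      brushr <- if (collapsed) 1 else rl
      # depth kept inside the bin; only the brush needs z clearance (the
      # lateral margin m does not apply to the depth axis)
      zfloor <- max(zlo + brushr + 1,
                    if (spec$pleural_slab) 3 + brushr else brushr + 2)
      zceil <- min(zhi - brushr - 1, d[1] - brushr - 1)
      if (zceil < zfloor) {
        mid <- round((zlo + zhi) / 2)
        zfloor <- min(max(mid, if (spec$pleural_slab) 3 + brushr
                          else brushr + 2), d[1] - brushr - 1)
        zceil <- zfloor
      }
      # sprout from an existing interior lymph anchor so the network stays
      # connected and the brush cannot touch a volume face
      interior <- anchors[, 1] >= brushr + 3 & anchors[, 1] <= d[1] - brushr - 2 &
        anchors[, 2] >= brushr + 3 & anchors[, 2] <= d[2] - brushr - 2 &
        anchors[, 3] >= brushr + 3 & anchors[, 3] <= d[3] - brushr - 2
      if (!any(interior)) next
      aint <- anchors[interior, , drop = FALSE]
      inz <- which(aint[, 1] >= zlo & aint[, 1] <= zhi)
      start <- if (length(inz)) aint[inz[sample.int(length(inz), 1)], ]
      else aint[which.min(abs(aint[, 1] - (zlo + zhi) / 2)), ]
      lcap <- max(40, round(max(d[2:3]) / 8))
      if (collapsed) {
        w <- sample1(wrib_rng[1], wrib_rng[2])
        len <- max(4, min(lcap, round(remaining / w)))
      } else {
        len <- max(4, min(lcap, round(remaining / (pi * (rl + 0.5)^2))))
      }
      if (periv) {
        cand <- blood_pts[inbin, , drop = FALSE]
        at <- cand[which.min(colSums((t(cand) - start)^2)), ]
        lat <- rnorm(3); lat[1] <- 0.2 * lat[1]
        lat <- lat / sqrt(sum(lat^2))
        target <- margin_clamp(at + lat * (rb + 2 + rl), m)
        dir <- target - start
        nd <- sqrt(sum(dir^2))
        dir <- if (nd > 1e-8) dir / nd else c(0, 1, 0)
        way <- rbind(start, target,
                     margin_clamp(target + dir * len / 2, m))
      } else if (!collapsed && geo_ok && runif(1) < 0.7) {
        # geodesic sprout through the septa back to the network
        gp <- geodesic_path(zfw, zcw, m, walk_lo, walk_hi)
        if (is.null(gp)) next
        netend <- gp[nrow(gp), ]
        vox <- brush_voxels(d, gp, rl)
        # where the walk traverses a depth bin that is already on budget,
        # keep only the centreline thread (connectivity without overshoot)
        bidx <- match(bin_of[vox], bins)
        under <- !is.na(bidx) & placed[bidx] < budget[bidx]
        keep <- bidx == bi | under | vox %in% brush_voxels(d, gp, 0)
        add_lymph(vox[keep | is.na(bidx)], bin_idx = bi, origin = netend)
        geo_age <- geo_age + 1L
        anchors <- rbind(anchors, gp)
        centrelines$lymph <- c(centrelines$lymph, list(gp))
        next
      } else {
        dir <- rnorm(3); dir[1] <- 0.35 * dir[1]  # stay within the bin
        dir <- dir / sqrt(sum(dir^2))
        way <- rbind(start,
                     margin_clamp(start + dir * len / 2 + runif(3, -2, 2),
                                  m),
                     margin_clamp(start + dir * len, m))
      }
      way[-1, 1] <- pmin(pmax(way[-1, 1], zfloor), zceil)
      pl <- trim_at_obstruction(densify(way))
      if (nrow(pl) < 2L) next
      if (collapsed) {
        lat <- rnorm(3); lat <- lat - sum(lat * dir) * dir
        lat[1] <- 0.3 * lat[1]   # sheets lie mostly within the depth bin
        nl <- sqrt(sum(lat^2))
        if (nl < 1e-8) { lat <- c(0, dir[3], -dir[2]); nl <- sqrt(sum(lat^2)) }
        if (nl < 1e-8) next
        lat <- lat / nl
        offs <- seq(-w / 2, w / 2, by = 0.5)
        sheet <- do.call(rbind, lapply(offs, function(t)
          sweep(pl, 2, t * lat, "+")))
        sheet <- sheet[sheet[, 1] >= max(zlo, 3) &
                         sheet[, 1] <= min(zhi, d[1] - 2) &
                         sheet[, 2] >= 2 & sheet[, 2] <= d[2] - 1 &
                         sheet[, 3] >= 2 & sheet[, 3] <= d[3] - 1, ,
                       drop = FALSE]
        if (!nrow(sheet)) next
        vox <- brush_voxels(d, sheet, 0)
        add_lymph(vox, bin_idx = bi, origin = start)
        anchors <- rbind(anchors, pl)
        centrelines$lymph <- c(centrelines$lymph, list(pl))
      } else {
        commit_lymph_path(pl, rl, bin_idx = bi, origin = start)
      }
    }
    if (placed[bi] < 0.8 * budget[bi] && budget[bi] > 0)
      stop("infeasible spec: depth bin ", bins[bi], " reached only ",
           placed[bi], " of ", budget[bi],
           " lymph voxels (tissue too sparse at the requested radii)")
  }

  # depth-bin and connectivity accounting (generation frame)
  lymph_per_bin <- vapply(bins, function(b)
    sum(bin_of == b & arr == LBL_LYMPH), integer(1))
  conn_frac <- {
    ly <- arr == LBL_LYMPH
    if (any(ly)) {
      cc <- .cpp_label_components(as.vector(ly), d, 26L)
      max(tabulate(cc[cc > 0L])) / sum(ly)
    } else NA_real_
  }

  # permute the finished grid so the pleura sits on the requested face
  if (!identical(pf, "z-")) {
    arr <- aperm(arr, fperm)
    centrelines <- lapply(centrelines, function(lst)
      lapply(lst, function(p) p[, fperm, drop = FALSE]))
  }
  vol <- label_volume(arr, pitch,
                      if (spec$pleural_slab) pf else NA_character_)

  # realized opening counts per face per class (final frame)
  realized <- realized_openings(vol)
  for (cls in c("blood", "lymph")) {
    req <- spec$openings[[cls]]
    req <- if (is.null(req)) integer() else req[req > 0]
    if (length(req))
      names(req) <- vapply(names(req), map_face, character(1), perm = fperm)
    got <- realized[realized$class == cls, ]
    got_v <- stats::setNames(got$patches, got$face)
    all_faces <- union(names(req), names(got_v))
    for (f in all_faces) {
      r <- if (f %in% names(req)) req[[f]] else 0L
      g <- if (f %in% names(got_v)) got_v[[f]] else 0L
      if (r != g)
        stop("generator failed to realize opening counts for ", cls,
             " on face ", f, ": requested ", r, ", realized ", g)
    }
  }

  truth <- list(
    bins = data.frame(bin = bins, depth_lo_um = bins * binw,
                      depth_hi_um = (bins + 1) * binw, depth_mid_um = mids,
                      target_vf = targets,
                      realized_vf = lymph_per_bin / tissue_per_bin,
                      tissue_vox = tissue_per_bin, lymph_vox = lymph_per_bin,
                      budget_vox = budget, placed_vox = placed),
    openings = realized,
    centrelines = centrelines,
    air_fraction_realized = realized_air / prod(d),
    lymph_connected_fraction = conn_frac,
    encircling_ring = ring_ok)
  list(volume = vol, truth = truth)
}

#' Realized lumen openings per volume face
#'
#' Counts the connected lumen patches (in-plane 8-connectivity) of each
#' vessel class on each of the six volume faces.
#'
#' @param vol a [label_volume()].
#' @return data.frame with columns `class`, `face`, `patches`.
#' @export
realized_openings <- function(vol) {
  d <- dim(vol$labels)
  out <- list()
  for (cls in c("blood", "lymph")) {
    lab <- if (cls == "blood") LBL_BLOOD else LBL_LYMPH
    for (f in FACE_NAMES) {
      sl <- face_slab(vol$labels, f) == lab
      if (!any(sl)) next
      dd <- dim(sl)
      cc <- .cpp_label_components(as.vector(sl), dd, 26L)
      out[[length(out) + 1L]] <-
        data.frame(class = cls, face = f,
                   patches = attr(cc, "n_components"))
    }
  }
  if (!length(out))
    return(data.frame(class = character(), face = character(),
                      patches = integer()))
  do.call(rbind, out)
}

# one-voxel-deep slab array at a named face, kept 3D with the face axis
# collapsed to thickness 1
face_slab <- function(labels, face) {
  d <- dim(labels)
  ax <- face_axis(face)
  pos <- if (face_side(face) < 0) 1L else d[ax]
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax]] <- pos
  sl <- labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  sl
}

#' Slices containing a blood-enclosing lymphatic ring
#'
#' For each z-slice, flood-fills the non-lymph background from the slice
#' border; interior regions enclosed by lymph that contain blood-lumen
#' voxels indicate a lymphatic ring fully encircling a blood vessel.
#'
#' @param vol a [label_volume()].
#' @return integer vector of z-slice indices with at least one enclosing
#'   ring (empty when none).
#' @export
ring_slices <- function(vol) {
  d <- dim(vol$labels)
  hit <- integer()
  for (k in seq_len(d[1])) {
    sl <- vol$labels[k, , ]
    bg <- sl != LBL_LYMPH
    if (all(bg)) next
    cc <- array(.cpp_label_components(as.vector(bg), c(d[2], d[3], 1L), 6L),
                c(d[2], d[3]))
    border_labs <- unique(c(cc[1, ], cc[d[2], ], cc[, 1], cc[, d[3]]))
    border_labs <- border_labs[border_labs != 0L]
    enclosed <- bg & !(cc %in% border_labs)
    if (any(enclosed & sl == LBL_BLOOD)) hit <- c(hit, k)
  }
  hit
}

#' Generate a cohort of volumes at known pleural distances
#'
#' Emulates the study's sampling of volumes of interest at a range of
#' pleural distances: each volume's true lymphatic volume fraction follows
#' `vf = intercept + gradient * distance + noise` (intercept =
#' `base_spec$target_lymph_vf_at_pleura`, Gaussian noise truncated to
#' \[0, 1\]), and a volume is generated with that uniform target fraction.
#'
#' @param base_spec a [synthetic_spec()]; its `target_lymph_vf_at_pleura`
#'   is the model intercept.
#' @param n_voi number of volumes (>= 3).
#' @param gradient volume-fraction change per micrometre (<= 0 lung-like).
#' @param noise_sd standard deviation of the volume-fraction noise.
#' @param seed integer seed for distances, noise, and per-volume streams.
#' @param max_distance_um largest sampled pleural distance.
#' @return list with `volumes` (list of [label_volume()]), `truth`
#'   (data.frame: `voi`, `distance_um`, `true_vf`).
#' @export
generate_cohort <- function(base_spec, n_voi = 25L, gradient = -8e-6,
                            noise_sd = 0.005, seed = 1L,
                            max_distance_um = 4000) {
  if (n_voi < 3L) stop("n_voi must be >= 3")
  vf0 <- base_spec$target_lymph_vf_at_pleura
  if (vf0 + gradient * max_distance_um < 0)
    stop("infeasible cohort: gradient drives the volume fraction negative ",
         "within the sampled distance range")
  with_seed(seed, {
    dist <- sort(runif(n_voi, 0, max_distance_um))
    true_vf <- vf0 + gradient * dist + rnorm(n_voi, 0, noise_sd)
    true_vf <- pmin(pmax(true_vf, 0), 1)
    vols <- vector("list", n_voi)
    for (i in seq_len(n_voi)) {
      sp <- base_spec
      sp$target_lymph_vf_at_pleura <- true_vf[i]
      sp$lymph_vf_gradient <- 0
      sp$pleural_slab <- FALSE
      sp$lymph_network$encircling_ring <- FALSE
      sp$seed <- derive_seed(seed, i)
      vols[[i]] <- generate_voi(sp)$volume
    }
    list(volumes = vols,
         truth = data.frame(voi = seq_len(n_voi), distance_um = dist,
                            true_vf = true_vf))
  })
}
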