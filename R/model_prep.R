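#' Prepare a solver-ready model volume
#'
#' Transforms a labelled VOI into the per-class binary model the flow
#' solver consumes: extract a cubic box, upsample each class mask by
#' nearest-neighbour replication, smooth each with a cubic binary median
#' filter, remove lumen components not 26-connected to a domain face,
#' resolve overlaps with lymph-over-blood-over-tissue precedence (the two
#' image subtractions), and rescale the voxel pitch (upsampling divides
#' it; `shrinkage_scale` multiplies it to emulate fixation-shrinkage
#' correction without changing voxel counts).
#'
#' @param vol a [label_volume()].
#' @param voi optional VOI record (row of [classify_rois()] output); the
#'   cubic box uses the ROI square and extends `side_vox` deep from `z0`.
#'   `NULL` takes the whole volume, which must then be cubic.
#' @param upsample integer replication factor per axis.
#' @param median_window odd cubic median window (1 disables filtering).
#' @param shrinkage_scale geometric scale factor applied to the pitch.
#' @return object of class `model_volume`: logical masks `interstitium`,
#'   `blood`, `lymph`, `air` (pairwise disjoint, jointly covering the
#'   grid), `voxel_pitch_um`, `pleural_direction`, and `provenance`.
#' @export
prepare_model_volume <- function(vol, voi = NULL, upsample = 3L,
                                 median_window = 3L, shrinkage_scale = 1) {
  if (upsample < 1L || upsample != round(upsample))
    stop("upsample must be a positive integer")
  if (median_window %% 2 == 0L) stop("median_window must be odd")
  d <- dim(vol$labels)
  if (is.null(voi)) {
    # whole-volume pass-through (validation geometries may be non-cubic);
    # the study-style path below always extracts a cube
    lab <- vol$labels
  } else {
    side <- voi$side_vox
    zs <- voi$z0 + seq_len(side) - 1L
    ys <- voi$y0 + seq_len(side) - 1L
    xs <- voi$x0 + seq_len(side) - 1L
    if (max(zs) > d[1] || max(ys) > d[2] || max(xs) > d[3])
      stop("cubic VOI extends outside the volume")
    lab <- vol$labels[zs, ys, xs, drop = FALSE]
  }

  up <- function(m, f) {
    if (f == 1L) return(m)
    dd <- dim(m)
    m[rep(seq_len(dd[1]), each = f),
      rep(seq_len(dd[2]), each = f),
      rep(seq_len(dd[3]), each = f)]
  }
  tissue <- up(lab != LBL_AIR, upsample)
  blood <- up(lab == LBL_BLOOD, upsample)
  lymph <- up(lab == LBL_LYMPH, upsample)
  dd <- dim(tissue)

  filt <- function(m) {
    if (median_window <= 1L) return(m)
    array(.cpp_median_binary(as.vector(m), dd, as.integer(median_window)), dd)
  }
  tissue <- filt(tissue); blood <- filt(blood); lymph <- filt(lymph)

  # lymph over blood over tissue (the two boolean subtractions)
  blood <- blood & !lymph
  tissue <- tissue | blood | lymph

  # remove lumen components not 26-connected to a domain face
  removed <- c(blood = 0L, lymph = 0L)
  prune <- function(m) {
    if (!any(m)) return(list(m = m, removed = 0L))
    cc <- array(.cpp_label_components(as.vector(m), dd, 26L), dd)
    onface <- unique(c(cc[1, , ], cc[dd[1], , ], cc[, 1, ], cc[, dd[2], ],
                       cc[, , 1], cc[, , dd[3]]))
    onface <- onface[onface != 0L]
    drop <- m & !(cc %in% onface)
    list(m = m & !drop, removed = sum(drop))
  }
  pb <- prune(blood); blood <- pb$m; removed["blood"] <- pb$removed
  pl <- prune(lymph); lymph <- pl$m; removed["lymph"] <- pl$removed

  interstitium <- tissue & !blood & !lymph
  air <- !tissue

  structure(list(
    interstitium = interstitium, blood = blood, lymph = lymph, air = air,
    voxel_pitch_um = vol$voxel_pitch_um / upsample * shrinkage_scale,
    pleural_direction = vol$pleural_direction,
    provenance = list(upsample_factor = upsample,
                      filter_applied = median_window > 1L,
                      median_window = median_window,
                      shrinkage_scale = shrinkage_scale,
                      removed_component_voxels = removed)),
    class = "model_volume")
}

#' @exportS3Method base::print
print.model_volume <- function(x, ...) {
  dd <- dim(x$interstitium)
  cat(sprintf("model_volume %d^3, pitch %.4g um\n", dd[1], x$voxel_pitch_um))
  cat(sprintf("  interstitium %d, blood %d, lymph %d, air %d voxels\n",
              sum(x$interstitium), sum(x$blood), sum(x$lymph), sum(x$air)))
  invisible(x)
}

#' Refine a model volume by one grid-halving step
#'
#' Nearest-neighbour upsampling by 2 per axis with the pitch halved;
#' geometry (and therefore the continuum problem) is unchanged, so the
#' difference between solutions at the two resolutions estimates the
#' discretisation error.
#'
#' @param model a [prepare_model_volume()] result.
#' @return a `model_volume` at twice the grid resolution.
#' @export
refine_model <- function(model) {
  up2 <- function(m) {
    dd <- dim(m)
    m[rep(seq_len(dd[1]), each = 2L),
      rep(seq_len(dd[2]), each = 2L),
      rep(seq_len(dd[3]), each = 2L)]
  }
  out <- model
  out$interstitium <- up2(model$interstitium)
  out$blood <- up2(model$blood)
  out$lymph <- up2(model$lymph)
  out$air <- up2(model$air)
  out$voxel_pitch_um <- model$voxel_pitch_um / 2
  out$provenance$refined_from_pitch_um <- model$voxel_pitch_um
  out
}

#' Identify vessel inlet and outlet openings
#'
#' Splits the lumen patches on the six cube faces into inlets (patches on
#' the three faces furthest from the pleural surface: the face opposite
#' the pleural face plus the two lateral faces whose lumen openings lie at
#' greater mean pleural-plane distance, with a fixed face order breaking
#' ties) and outlets (all remaining lumen boundary patches).
#'
#' @param model a [prepare_model_volume()] result.
#' @param pleural_direction pleural face name; defaults to the model's.
#' @param distal_faces optional explicit character vector of three distal
#'   face names, overriding the rule.
#' @return object of class `boundary_spec`: `distal_faces`, `patches`
#'   (data.frame: class, face, patch id, voxel count, role), and
#'   `cells` (data.frame: class, face, role, patch id, linear cell index
#'   of each boundary lumen voxel).
#' @export
identify_vessel_openings <- function(model, pleural_direction = NULL,
                                     distal_faces = NULL) {
  if (is.null(pleural_direction)) pleural_direction <- model$pleural_direction
  if (is.null(distal_faces)) {
    if (is.na(pleural_direction))
      stop("pleural_direction unknown; supply it or give distal_faces")
    opp <- opposite_face(pleural_direction)
    lats <- setdiff(FACE_NAMES, c(pleural_direction, opp))
    sc <- vapply(lats, function(f)
      mean_opening_pleural_distance(model, f, pleural_direction), numeric(1))
    distal_faces <- c(opp, lats[order(-sc, match(lats, FACE_NAMES))][1:2])
  }
  if (length(distal_faces) != 3L)
    stop("exactly three distal faces are required")

  dd <- dim(model$interstitium)
  patches <- list(); cells <- list()
  for (cls in c("blood", "lymph")) {
    m <- model[[cls]]
    for (f in FACE_NAMES) {
      ax <- face_axis(f)
      pos <- if (face_side(f) < 0) 1L else dd[ax]
      idx <- list(seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]))
      idx[[ax]] <- pos
      sl <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      if (!any(sl)) next
      cc <- array(.cpp_label_components(as.vector(sl), dim(sl), 26L), dim(sl))
      role <- if (f %in% distal_faces) "inlet" else "outlet"
      npat <- attr(.cpp_label_components(as.vector(sl), dim(sl), 26L),
                   "n_components")
      # linear indices in the full grid of the face-slab lumen voxels
      grid <- expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]])
      lin <- (grid$x - 1) * dd[1] * dd[2] + (grid$y - 1) * dd[1] + grid$z
      sel <- as.vector(sl)
      pid <- as.vector(cc)[sel]
      patches[[length(patches) + 1L]] <-
        data.frame(class = cls, face = f,
                   patch = seq_len(npat),
                   n_vox = as.vector(table(factor(pid, seq_len(npat)))),
                   role = role)
      cells[[length(cells) + 1L]] <-
        data.frame(class = cls, face = f, role = role, patch = pid,
                   cell = lin[sel])
    }
  }
  patches <- if (length(patches)) do.call(rbind, patches)
  else data.frame(class = character(), face = character(),
                  patch = integer(), n_vox = integer(), role = character())
  cells <- if (length(cells)) do.call(rbind, cells)
  else data.frame(class = character(), face = character(),
                  role = character(), patch = integer(), cell = integer())
  for (cls in c("blood", "lymph")) {
    if (!any(model[[cls]])) next
    pr <- patches[patches$class == cls, ]
    if (!any(pr$role == "inlet"))
      stop("vessel class '", cls, "' has no inlet opening on the distal ",
           "faces; the flow model is unforced for this class")
    if (!any(pr$role == "outlet"))
      warning("vessel class '", cls, "' has inlets but no outlet; steady ",
              "state relies on membrane leakage")
  }
  structure(list(pleural_direction = pleural_direction,
                 distal_faces = distal_faces, patches = patches,
                 cells = cells),
            class = "boundary_spec")
}

# mean distance (in voxels) from the pleural face plane of the lumen
# voxels opening on face f; -Inf when no lumen opens there
mean_opening_pleural_distance <- function(model, f, pleural_direction) {
  dd <- dim(model$interstitium)
  ax <- face_axis(f)
  pos <- if (face_side(f) < 0) 1L else dd[ax]
  idx <- list(seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]))
  idx[[ax]] <- pos
  lum <- (model$blood | model$lymph)[idx[[1]], idx[[2]], idx[[3]],
                                     drop = FALSE]
  if (!any(lum)) return(-Inf)
  pax <- face_axis(pleural_direction)
  grid <- expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]])
  coordp <- grid[[c("z", "y", "x")[pax]]][as.vector(lum)]
  if (face_side(pleural_direction) < 0) mean(coordp - 1)
  else mean(dd[pax] - coordp)
}
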