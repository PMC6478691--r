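#' Labelled 3D voxel volume
#'
#' Container for a segmented tissue volume: a 3D integer array of class
#' labels over \{0 = airspace/paraffin, 1 = interstitial tissue, 2 =
#' blood-vessel lumen, 3 = lymphatic lumen, 4 = pleural surface\}, the
#' isotropic voxel pitch in micrometres, and the direction of the pleural
#' face.  Array axis order is fixed as (z, y, x): the first array index is
#' the sectioning/depth axis.
#'
#' @param labels integer 3D array with values in 0:4, dim = (nz, ny, nx).
#' @param voxel_pitch_um positive voxel pitch, micrometres.
#' @param pleural_direction which volume face carries the pleural surface;
#'   one of `"z-"`, `"z+"`, `"y-"`, `"y+"`, `"x-"`, `"x+"`, or `NA` when
#'   the volume has no pleural reference.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_pitch_um,
                         pleural_direction = NA_character_) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  vol <- structure(
    list(labels = labels,
         voxel_pitch_um = as.numeric(voxel_pitch_um),
         pleural_direction = pleural_direction),
    class = "label_volume")
  validate_label_volume(vol)
  vol
}

#' Validate a label volume
#'
#' Checks the label-volume invariants: a non-empty 3D grid, positive voxel
#' pitch, labels drawn only from the declared set, and -- when pleural
#' voxels are present -- that they form one face-connected shell touching
#' exactly the declared pleural face.
#'
#' @param vol a [label_volume()].
#' @return `vol`, invisibly; errors describe the violated invariant.
#' @export
validate_label_volume <- function(vol) {
  if (!inherits(vol, "label_volume")) stop("not a label_volume")
  d <- dim(vol$labels)
  if (length(d) != 3L || any(d < 1L)) stop("labels must be a non-empty 3D array")
  if (!is.finite(vol$voxel_pitch_um) || vol$voxel_pitch_um <= 0)
    stop("voxel_pitch_um must be > 0")
  bad <- setdiff(unique(as.vector(vol$labels)), LABEL_SET)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  if (!is.na(vol$pleural_direction) &&
      !vol$pleural_direction %in% FACE_NAMES)
    stop("pleural_direction must be one of ", paste(FACE_NAMES, collapse = ", "))
  pl <- vol$labels == LBL_PLEURA
  if (any(pl)) {
    if (is.na(vol$pleural_direction))
      stop("pleural voxels present but pleural_direction not declared")
    lab <- .cpp_label_components(as.vector(pl), dim(vol$labels), 6L)
    if (attr(lab, "n_components") > 1L)
      stop("pleural voxels do not form a single face-connected shell")
    # the shell must cover the declared face and stay clear of the
    # opposite face (rim contact with lateral faces is geometrically
    # unavoidable for a full-width pleural slab)
    if (!any(pl[face_slice_index(d, vol$pleural_direction)]))
      stop("pleural shell does not touch the declared pleural face ",
           vol$pleural_direction)
    if (any(pl[face_slice_index(d, opposite_face(vol$pleural_direction))]))
      stop("pleural shell touches the face opposite pleural_direction")
  }
  invisible(vol)
}

# index list selecting the one-voxel-deep slab at a named domain face
face_slice_index <- function(d, face) {
  ax <- match(substr(face, 1, 1), c("z", "y", "x"))
  pos <- if (substr(face, 2, 2) == "-") 1L else d[ax]
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax]] <- pos
  arr <- array(FALSE, d)
  arr[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  arr
}

# axis (1..3) and side (-1 / +1) of a face name
face_axis <- function(face) match(substr(face, 1, 1), c("z", "y", "x"))
face_side <- function(face) if (substr(face, 2, 2) == "-") -1L else 1L
opposite_face <- function(face) {
  paste0(substr(face, 1, 1), if (face_side(face) < 0) "+" else "-")
}

#' @exportS3Method base::print
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume %d x %d x %d (z,y,x), pitch %.3g um, pleura %s\n",
              d[1], d[2], d[3], x$voxel_pitch_um,
              ifelse(is.na(x$pleural_direction), "none", x$pleural_direction)))
  tab <- table(factor(as.vector(x$labels), levels = LABEL_SET,
                      labels = c("air", "interstitium", "blood", "lymph",
                                 "pleura")))
  print(tab)
  invisible(x)
}

label_map_json <- function() {
  list(air = LBL_AIR, interstitium = LBL_TISSUE, blood = LBL_BLOOD,
       lymph = LBL_LYMPH, pleura = LBL_PLEURA)
}

#' Write a label volume
#'
#' Serialises a [label_volume()] to disk.  Supported formats: NRRD
#' (attached raw uint8, text header carrying pitch and pleural metadata),
#' raw uint8 with a JSON sidecar (`<stem>.raw` + `<stem>.json`), and
#' multi-page TIFF with a JSON sidecar (requires the `tiff` package).
#'
#' @param vol a [label_volume()].
#' @param path output path; the extension (`.nrrd`, `.raw`, `.tif`/`.tiff`)
#'   selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  validate_label_volume(vol)
  ext <- tolower(tools::file_ext(path))
  d <- dim(vol$labels)
  if (ext == "nrrd") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c(
      "NRRD0004",
      "# pulmolymph label volume",
      "type: uint8",
      "dimension: 3",
      sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
      "encoding: raw",
      "endian: little",
      sprintf("spacings: %.17g %.17g %.17g", vol$voxel_pitch_um,
              vol$voxel_pitch_um, vol$voxel_pitch_um),
      "space units: \"um\" \"um\" \"um\"",
      sprintf("pulmolymph:pleural_direction:=%s",
              ifelse(is.na(vol$pleural_direction), "none",
                     vol$pleural_direction)),
      "")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.raw(as.vector(vol$labels)), con)
  } else if (ext == "raw") {
    writeBin(as.raw(as.vector(vol$labels)), path)
    side <- sub("\\.raw$", ".json", path)
    jsonlite::write_json(
      list(shape = d, voxel_pitch_um = vol$voxel_pitch_um,
           axis_order = c("z", "y", "x"),
           pleural_direction = ifelse(is.na(vol$pleural_direction),
                                      "none", vol$pleural_direction),
           dtype = "uint8", label_map = label_map_json()),
      side, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    pages <- lapply(seq_len(d[1]), function(k)
      matrix(vol$labels[k, , ] / 255, nrow = d[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    side <- sub("\\.tiff?$", ".json", path)
    jsonlite::write_json(
      list(shape = d, voxel_pitch_um = vol$voxel_pitch_um,
           axis_order = c("z", "y", "x"),
           pleural_direction = ifelse(is.na(vol$pleural_direction),
                                      "none", vol$pleural_direction),
           label_map = label_map_json()),
      side, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Read a label volume
#'
#' Inverse of [write_volume()]: reads NRRD, raw + JSON sidecar, or TIFF +
#' JSON sidecar, validates the labels against the declared label set and
#' requires voxel pitch metadata.
#'
#' @param path file path (`.nrrd`, `.raw`, `.tif`/`.tiff`).
#' @return a [label_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character()
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) stop("truncated NRRD header")
      if (ln == "") break
      hdr <- c(hdr, ln)
    }
    getf <- function(key) {
      ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
      if (!length(ln)) return(NA_character_)
      trimws(sub(paste0("^", key, ":=?"), "", ln[1]))
    }
    if (!identical(getf("type"), "uint8") ||
        !identical(getf("encoding"), "raw"))
      stop("only raw uint8 NRRD volumes are supported")
    d <- as.integer(strsplit(getf("sizes"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(getf("spacings"), "\\s+")[[1]])
    pd <- getf("pulmolymph:pleural_direction")
    if (is.na(sp[1])) stop("NRRD header missing voxel pitch (spacings)")
    raw <- readBin(con, "raw", n = prod(d))
    labels <- array(as.integer(raw), dim = d)
    label_volume(labels, sp[1],
                 if (is.na(pd) || pd == "none") NA_character_ else pd)
  } else if (ext == "raw") {
    side <- sub("\\.raw$", ".json", path)
    if (!file.exists(side)) stop("missing JSON sidecar: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$voxel_pitch_um)) stop("sidecar missing voxel_pitch_um")
    d <- as.integer(meta$shape)
    raw <- readBin(path, "raw", n = prod(d))
    labels <- array(as.integer(raw), dim = d)
    pd <- meta$pleural_direction
    label_volume(labels, meta$voxel_pitch_um,
                 if (is.null(pd) || pd == "none") NA_character_ else pd)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF input")
    side <- sub("\\.tiff?$", ".json", path)
    if (!file.exists(side)) stop("missing JSON sidecar: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$voxel_pitch_um)) stop("sidecar missing voxel_pitch_um")
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- c(length(pages), dim(pages[[1]]))
    labels <- array(0L, d)
    for (k in seq_along(pages))
      labels[k, , ] <- as.integer(round(pages[[k]] * 255))
    pd <- meta$pleural_direction
    label_volume(labels, meta$voxel_pitch_um,
                 if (is.null(pd) || pd == "none") NA_character_ else pd)
  } else stop("unsupported volume format: .", ext)
}
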