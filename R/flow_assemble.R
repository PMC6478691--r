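# Finite-volume discretisation of the coupled steady flow model on the
# voxel grid:
#   interstitium: Darcy continuity, face flux -(k/mu) grad p;
#   vessel lumens: marker-and-cell (staggered) Stokes, face-normal
#     velocities unknown, cell pressures unknown;
#   lumen-interstitium faces: membrane condition u.n = K (p_lumen - p),
#     tangential no-slip;
#   external interstitial faces: Dirichlet pressure (half-cell ghost);
#   lumen boundary faces: prescribed inlet velocity, outlet Dirichlet
#     pressure (via the face-normal momentum equation), or sealed wall;
#   air-adjacent faces: no flux / no slip.  No gravity term.
#
# Every pressure-coupled face carries a velocity of the affine form
#   u = cst + clo * p(lo) + chi * p(hi)
# which makes continuity assembly uniform across Darcy, membrane,
# Dirichlet-ghost and inlet faces, and lets the viscous stencil of the
# Stokes momentum equations substitute membrane/inlet neighbour faces
# algebraically.

# face codes
FC_NONE <- 0L; FC_DARCY <- 1L; FC_MEMB <- 2L; FC_STOKES <- 4L
FC_WALL <- 5L; FC_EXT <- 6L; FC_INLET <- 7L; FC_OUTLET <- 8L

#' Assemble the discrete flow system
#'
#' Builds the sparse linear system for the coupled Stokes-Darcy model on a
#' prepared model volume with identified vessel openings.
#'
#' Unknown ordering: interstitial cell pressures, then lumen cell
#' pressures, then lumen face-normal velocities.  Interstitial continuity
#' rows are symmetric positive definite in the interstitial pressure
#' block, which the block solver exploits.
#'
#' Fluid regions with no pressure reference anywhere (no Dirichlet face,
#' no outlet) cannot reach a steady state: if such a region carries an
#' inlet the system is unforced/inconsistent and assembly errors;
#' otherwise the region is excluded from the unknowns and counted.
#'
#' @param model a [prepare_model_volume()] result.
#' @param boundaries a [identify_vessel_openings()] result (or
#'   [openings_by_face()] for validation geometries).
#' @param params a [fluid_parameters()].
#' @param interstitial_bc optional named list/vector over face names: a
#'   number gives that face's Dirichlet pressure (default `params$p_int`
#'   on all faces), the string `"sealed"` makes the face no-flux.
#' @param outlet_pressures optional named numeric over face names,
#'   overriding the class outlet pressure for outlet patches on that face.
#' @param suppressed optional data.frame (`axis`, `fpos`) of outlet faces
#'   converted to walls by backflow suppression.
#' @return object of class `flow_system`: sparse matrix `A`, right-hand
#'   side `b`, index maps and face tables for flux accounting.
#' @export
assemble_flow_system <- function(model, boundaries, params,
                                 interstitial_bc = NULL,
                                 outlet_pressures = NULL,
                                 suppressed = NULL) {
  dd <- dim(model$interstitium)
  N <- prod(dd)
  h <- model$voxel_pitch_um * 1e-6
  Afc <- h^2
  Td <- params$k / (params$mu * h)
  T2 <- 2 * Td
  gcoef <- h / params$mu

  tc <- array(0L, dd)
  tc[model$interstitium] <- 1L
  tc[model$blood] <- 2L
  tc[model$lymph] <- 3L

  # per-face interstitial boundary condition
  ibc <- stats::setNames(as.list(rep(params$p_int, 6)), FACE_NAMES)
  if (!is.null(interstitial_bc))
    for (f in names(interstitial_bc)) ibc[[f]] <- interstitial_bc[[f]]
  sealed <- vapply(ibc, function(v) identical(v, "sealed"), logical(1))

  # ---- pressure-reference reachability -----------------------------------
  # sources: interstitial cells on non-sealed boundary faces; lumen cells
  # carrying an outlet face.  Regions of the fluid graph (6-adjacency;
  # wall-separated adjacency is a harmless over-connection here) without a
  # source are excluded -- with an inlet that is an unforced system.
  src <- array(FALSE, dd)
  for (f in FACE_NAMES) {
    if (sealed[[f]]) next
    sl <- face_slice_index(dd, f)
    src[sl & tc == 1L] <- TRUE
  }
  bcells <- boundaries$cells
  if (!is.null(suppressed) && nrow(suppressed)) {
    # suppressed outlets no longer pin pressure
    sup_key <- paste(suppressed$class, suppressed$cell, suppressed$face)
    keep <- !(paste(bcells$class, bcells$cell, bcells$face) %in% sup_key &
                bcells$role == "outlet")
    bcells_roles <- bcells
    bcells_roles$role[!keep] <- "wall"
  } else bcells_roles <- bcells
  out_cells <- bcells_roles$cell[bcells_roles$role == "outlet"]
  src[out_cells] <- TRUE
  fluid <- tc > 0L
  cc <- array(.cpp_label_components(as.vector(fluid), dd, 6L), dd)
  src_comp <- unique(cc[src])
  unreachable <- fluid & !(cc %in% src_comp)
  excluded_cells <- sum(unreachable)
  if (excluded_cells) {
    in_cells <- bcells_roles$cell[bcells_roles$role == "inlet"]
    if (any(unreachable[in_cells]))
      stop("unforced system: a vessel region carries an inlet but has no ",
           "pressure reference (no outlet and no Dirichlet face reachable)")
    tc[unreachable] <- 0L
  }
  if (!any(tc == 1L) && !length(out_cells) && all(sealed))
    stop("unforced system: no Dirichlet pressure condition and no outlet")

  # ---- unknown numbering --------------------------------------------------
  pidx <- array(0L, dd)
  NI <- sum(tc == 1L)
  pidx[tc == 1L] <- seq_len(NI)
  NLum <- sum(tc >= 2L)
  pidx[tc >= 2L] <- NI + seq_len(NLum)
  NP <- NI + NLum

  # role lookup for boundary lumen faces: key "class|face|cell"
  role_env <- new.env(hash = TRUE, size = max(16L, nrow(bcells_roles) * 2L))
  if (nrow(bcells_roles))
    for (r in seq_len(nrow(bcells_roles)))
      assign(paste(bcells_roles$class[r], bcells_roles$face[r],
                   bcells_roles$cell[r], sep = "|"),
             bcells_roles$role[r], envir = role_env)
  face_of_boundary <- function(ax, q) {
    if (q == 1L) FACE_NAMES[2L * ax - 1L] else FACE_NAMES[2L * ax]
  }

  CI <- array(seq_len(N), dd)
  axes <- vector("list", 3)
  nu_total <- 0L

  for (d in 1:3) {
    fd <- dd; fd[d] <- dd[d] + 1L
    nF <- prod(fd)
    loc <- array(NA_integer_, fd); hic <- array(NA_integer_, fd)
    if (d == 1L) {
      loc[2:fd[1], , ] <- CI; hic[1:dd[1], , ] <- CI
    } else if (d == 2L) {
      loc[, 2:fd[2], ] <- CI; hic[, 1:dd[2], ] <- CI
    } else {
      loc[, , 2:fd[3]] <- CI; hic[, , 1:dd[3]] <- CI
    }
    loc <- as.vector(loc); hic <- as.vector(hic)
    tlo <- ifelse(is.na(loc), -1L, tc[pmax(loc, 1L)])
    thi <- ifelse(is.na(hic), -1L, tc[pmax(hic, 1L)])

    code <- integer(nF)
    cls <- integer(nF)   # lumen class a face involves (2/3), else 0
    clo <- numeric(nF); chi <- numeric(nF); cst <- numeric(nF)
    pext <- numeric(nF)

    # interior faces
    darcy <- tlo == 1L & thi == 1L
    code[darcy] <- FC_DARCY; clo[darcy] <- Td; chi[darcy] <- -Td

    memb <- (tlo == 1L & thi >= 2L) | (tlo >= 2L & thi == 1L)
    lcls <- ifelse(tlo >= 2L, tlo, thi)
    Kf <- ifelse(lcls == 2L, params$K_B, params$K_L)
    code[memb] <- FC_MEMB; cls[memb] <- lcls[memb]
    clo[memb] <- Kf[memb]; chi[memb] <- -Kf[memb]

    stok <- tlo >= 2L & thi >= 2L & tlo == thi
    code[stok] <- FC_STOKES; cls[stok] <- tlo[stok]

    wall <- (tlo >= 2L & thi == 0L) | (tlo == 0L & thi >= 2L) |
      (tlo >= 2L & thi >= 2L & tlo != thi)
    code[wall] <- FC_WALL
    wcls <- pmax(ifelse(tlo >= 2L, tlo, 0L), ifelse(thi >= 2L, thi, 0L))
    cls[wall] <- wcls[wall]

    # boundary faces
    for (side in c("lo", "hi")) {
      bnd <- if (side == "lo") is.na(loc) else is.na(hic)
      cellv <- if (side == "lo") hic else loc
      tcv <- if (side == "lo") thi else tlo
      q <- if (side == "lo") 1L else fd[d]
      fname <- face_of_boundary(d, q)
      w <- which(bnd & tcv == 1L)
      if (length(w)) {
        if (sealed[[fname]]) {
          code[w] <- FC_NONE
        } else {
          code[w] <- FC_EXT
          pv <- as.numeric(ibc[[fname]])
          pext[w] <- pv
          if (side == "lo") { chi[w] <- -T2; cst[w] <- T2 * pv }
          else { clo[w] <- T2; cst[w] <- -T2 * pv }
        }
      }
      wl <- which(bnd & tcv >= 2L)
      if (length(wl)) {
        cls[wl] <- tcv[wl]
        for (v in wl) {
          cl <- if (tcv[v] == 2L) "blood" else "lymph"
          role <- role_env[[paste(cl, fname, cellv[v], sep = "|")]]
          if (is.null(role)) role <- "wall"
          if (role == "inlet") {
            code[v] <- FC_INLET
            uin <- if (cl == "blood") params$u_B else params$u_L
            cst[v] <- if (side == "lo") uin else -uin
          } else if (role == "outlet") {
            code[v] <- FC_OUTLET
            pv <- if (!is.null(outlet_pressures) &&
                      fname %in% names(outlet_pressures))
              outlet_pressures[[fname]]
            else if (cl == "blood") params$p_B else params$p_L
            pext[v] <- pv
          } else code[v] <- FC_WALL
        }
      }
    }

    uidx <- integer(nF)
    unk <- which(code == FC_STOKES | code == FC_OUTLET)
    uidx[unk] <- nu_total + seq_along(unk)
    nu_total <- nu_total + length(unk)

    loP <- ifelse(is.na(loc), 0L, pidx[pmax(loc, 1L)])
    hiP <- ifelse(is.na(hic), 0L, pidx[pmax(hic, 1L)])
    axes[[d]] <- list(fd = fd, code = code, cls = cls, clo = clo, chi = chi,
                      cst = cst, pext = pext, uidx = uidx,
                      loP = loP, hiP = hiP, loc = loc, hic = hic)
  }
  # velocity unknowns come after all pressures
  for (d in 1:3) {
    u <- axes[[d]]$uidx
    axes[[d]]$uidx <- ifelse(u > 0L, u + NP, 0L)
  }
  n_unknowns <- NP + nu_total

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  b <- numeric(n_unknowns)
  push <- function(i, j, x) {
    k <- length(trip_i) + 1L
    trip_i[[k]] <<- i; trip_j[[k]] <<- j; trip_x[[k]] <<- x
    invisible(NULL)
  }

  # ---- continuity rows (all fluid cells) ---------------------------------
  fl <- which(tc > 0L)
  ci <- (fl - 1L) %% dd[1] + 1L
  cj <- ((fl - 1L) %/% dd[1]) %% dd[2] + 1L
  ck <- (fl - 1L) %/% (dd[1] * dd[2]) + 1L
  rows <- pidx[fl]
  for (d in 1:3) {
    ax <- axes[[d]]
    fd <- ax$fd
    cf <- switch(d, ci, cj, ck)
    # face-grid linear index of the cell's low face (coordinate = cell's)
    # and high face (coordinate + 1 along d)
    base1 <- ci; base2 <- cj; base3 <- ck
    flin <- function(add) {
      a1 <- base1; a2 <- base2; a3 <- base3
      if (d == 1L) a1 <- a1 + add
      if (d == 2L) a2 <- a2 + add
      if (d == 3L) a3 <- a3 + add
      (a3 - 1L) * fd[1] * fd[2] + (a2 - 1L) * fd[1] + a1
    }
    for (side in c(-1, 1)) {
      fpos <- if (side < 0) flin(0L) else flin(1L)
      s <- side
      cd <- ax$code[fpos]
      # affine faces
      aff <- cd %in% c(FC_DARCY, FC_MEMB, FC_EXT, FC_INLET)
      if (any(aff)) {
        w <- which(aff)
        lo <- ax$loP[fpos[w]]; hi <- ax$hiP[fpos[w]]
        cl <- ax$clo[fpos[w]]; ch <- ax$chi[fpos[w]]; cs <- ax$cst[fpos[w]]
        ok <- lo > 0L & cl != 0
        if (any(ok)) push(rows[w][ok], lo[ok], s * cl[ok])
        ok <- hi > 0L & ch != 0
        if (any(ok)) push(rows[w][ok], hi[ok], s * ch[ok])
        bb <- s * cs
        nz <- bb != 0
        if (any(nz)) b[rows[w][nz]] <- b[rows[w][nz]] - bb[nz]
      }
      unk <- cd %in% c(FC_STOKES, FC_OUTLET)
      if (any(unk)) {
        w <- which(unk)
        push(rows[w], ax$uidx[fpos[w]], rep(s, length(w)))
      }
    }
  }

  # ---- momentum rows ------------------------------------------------------
  memb_tab <- list(); outlet_tab <- list(); inlet_tab <- list()
  ext_tab <- list()
  for (d in 1:3) {
    ax <- axes[[d]]
    fd <- ax$fd
    unk <- which(ax$code == FC_STOKES | ax$code == FC_OUTLET)
    if (length(unk)) {
      rows_u <- ax$uidx[unk]
      f1 <- (unk - 1L) %% fd[1] + 1L
      f2 <- ((unk - 1L) %/% fd[1]) %% fd[2] + 1L
      f3 <- (unk - 1L) %/% (fd[1] * fd[2]) + 1L
      diag_acc <- numeric(length(unk))
      clsf <- ax$cls[unk]
      for (a in 1:3) for (sgn in c(-1L, 1L)) {
        n1 <- f1; n2 <- f2; n3 <- f3
        if (a == 1L) n1 <- n1 + sgn
        if (a == 2L) n2 <- n2 + sgn
        if (a == 3L) n3 <- n3 + sgn
        inside <- n1 >= 1L & n1 <= fd[1] & n2 >= 1L & n2 <= fd[2] &
          n3 >= 1L & n3 <= fd[3]
        npos <- (pmax(n3, 1L) - 1L) * fd[1] * fd[2] +
          (pmax(n2, 1L) - 1L) * fd[1] + pmax(n1, 1L)
        ncode <- ifelse(inside, ax$code[npos], FC_NONE)
        ncls <- ifelse(inside, ax$cls[npos], 0L)
        if (a == d) {
          # normal-direction neighbour missing => one-sided (d2u/dn2 = 0)
          skip <- !inside
          ghost <- rep(FALSE, length(unk))
        } else {
          skip <- rep(FALSE, length(unk))
          # ghost when the neighbour face has no lumen side of this class
          ghost <- !inside | !(ncls == clsf &
                                 ncode %in% c(FC_STOKES, FC_OUTLET, FC_MEMB,
                                              FC_INLET, FC_WALL))
        }
        active <- !skip
        # unknown neighbours of matching class
        isu <- active & !ghost & ncode %in% c(FC_STOKES, FC_OUTLET) &
          ncls == clsf
        if (any(isu)) {
          w <- which(isu)
          push(rows_u[w], ax$uidx[npos[w]], rep(1, length(w)))
        }
        # affine neighbours (membrane of this class, inlet of this class)
        isa <- active & !ghost & ncode %in% c(FC_MEMB, FC_INLET) &
          ncls == clsf
        if (any(isa)) {
          w <- which(isa)
          lo <- ax$loP[npos[w]]; hi <- ax$hiP[npos[w]]
          cl <- ax$clo[npos[w]]; ch <- ax$chi[npos[w]]; cs <- ax$cst[npos[w]]
          ok <- lo > 0L & cl != 0
          if (any(ok)) push(rows_u[w][ok], lo[ok], cl[ok])
          ok <- hi > 0L & ch != 0
          if (any(ok)) push(rows_u[w][ok], hi[ok], ch[ok])
          nz <- cs != 0
          if (any(nz)) b[rows_u[w][nz]] <- b[rows_u[w][nz]] - cs[nz]
        }
        # wall-of-this-class neighbours contribute value 0 (diag only)
        diag_acc <- diag_acc - as.numeric(active) - as.numeric(active & ghost)
      }
      push(rows_u, rows_u, diag_acc)
      # pressure gradient
      lo <- ax$loP[unk]; hi <- ax$hiP[unk]
      interior <- ax$code[unk] == FC_STOKES
      w <- which(interior)
      if (length(w)) {
        push(rows_u[w], lo[w], rep(gcoef, length(w)))
        push(rows_u[w], hi[w], rep(-gcoef, length(w)))
      }
      wo <- which(!interior)  # outlet faces
      if (length(wo)) {
        po <- ax$pext[unk[wo]]
        has_lo <- lo[wo] > 0L
        if (any(has_lo)) {
          push(rows_u[wo][has_lo], lo[wo][has_lo],
               rep(2 * gcoef, sum(has_lo)))
          b[rows_u[wo][has_lo]] <- b[rows_u[wo][has_lo]] +
            2 * gcoef * po[has_lo]
        }
        if (any(!has_lo)) {
          push(rows_u[wo][!has_lo], hi[wo][!has_lo],
               rep(-2 * gcoef, sum(!has_lo)))
          b[rows_u[wo][!has_lo]] <- b[rows_u[wo][!has_lo]] -
            2 * gcoef * po[!has_lo]
        }
      }
    }
    # flux bookkeeping tables
    wm <- which(ax$code == FC_MEMB)
    if (length(wm)) {
      lum_lo <- !is.na(ax$loc[wm]) & tc[pmax(ax$loc[wm], 1L)] >= 2L
      p_lum <- ifelse(lum_lo, ax$loP[wm], ax$hiP[wm])
      p_int <- ifelse(lum_lo, ax$hiP[wm], ax$loP[wm])
      memb_tab[[d]] <- data.frame(
        axis = d, fpos = wm,
        class = ifelse(ax$cls[wm] == 2L, "blood", "lymph"),
        p_lum = p_lum, p_int = p_int, K = abs(ax$clo[wm]))
    }
    wi <- which(ax$code == FC_INLET)
    if (length(wi))
      inlet_tab[[d]] <- data.frame(
        axis = d, fpos = wi,
        class = ifelse(ax$cls[wi] == 2L, "blood", "lymph"),
        u_in = abs(ax$cst[wi]))
    wo <- which(ax$code == FC_OUTLET)
    if (length(wo)) {
      out_sign <- ifelse(is.na(ax$loc[wo]), -1, 1)
      cell <- ifelse(is.na(ax$loc[wo]), ax$hic[wo], ax$loc[wo])
      fname <- ifelse(is.na(ax$loc[wo]), FACE_NAMES[2L * d - 1L],
                      FACE_NAMES[2L * d])
      outlet_tab[[d]] <- data.frame(
        axis = d, fpos = wo, uidx = ax$uidx[wo], out_sign = out_sign,
        class = ifelse(ax$cls[wo] == 2L, "blood", "lymph"),
        p_out = ax$pext[wo], cell = cell, face = fname)
    }
    we <- which(ax$code == FC_EXT)
    if (length(we)) {
      cell <- ifelse(is.na(ax$loc[we]), ax$hic[we], ax$loc[we])
      ext_tab[[d]] <- data.frame(axis = d, fpos = we, p_cell = pidx[cell],
                                 pext = ax$pext[we])
    }
  }

  if (!length(trip_i) || n_unknowns == 0L)
    stop("unforced system: no equations could be assembled")
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = as.numeric(unlist(trip_x)),
                            dims = c(n_unknowns, n_unknowns))
  bind_or_empty <- function(lst, proto) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst)) do.call(rbind, lst) else proto
  }
  structure(list(
    A = A, b = b, dims = dd, h = h, face_area = Afc,
    NI = NI, NP = NP, NU = nu_total, pidx = pidx, tc = tc,
    axes = lapply(axes, function(ax)
      ax[c("fd", "code", "cls", "clo", "chi", "cst", "pext", "uidx",
           "loP", "hiP")]),
    membrane = bind_or_empty(memb_tab,
      data.frame(axis = integer(), fpos = integer(), class = character(),
                 p_lum = integer(), p_int = integer(), K = numeric())),
    inlets = bind_or_empty(inlet_tab,
      data.frame(axis = integer(), fpos = integer(), class = character(),
                 u_in = numeric())),
    outlets = bind_or_empty(outlet_tab,
      data.frame(axis = integer(), fpos = integer(), uidx = integer(),
                 out_sign = numeric(), class = character(),
                 p_out = numeric(), cell = integer(), face = character())),
    externals = bind_or_empty(ext_tab,
      data.frame(axis = integer(), fpos = integer(), p_cell = integer(),
                 pext = numeric())),
    excluded_cells = excluded_cells,
    params = params,
    call_args = list(model = model, boundaries = boundaries, params = params,
                     interstitial_bc = interstitial_bc,
                     outlet_pressures = outlet_pressures,
                     suppressed = suppressed)),
    class = "flow_system")
}

#' Manual opening roles for validation geometries
#'
#' Builds a boundary specification by assigning one role per volume face
#' and vessel class, instead of the pleural-distance rule of
#' [identify_vessel_openings()].  Faces not named get `"wall"`.
#'
#' @param model a [prepare_model_volume()] result (or any object with
#'   logical `blood`/`lymph` masks).
#' @param roles named list per class, e.g.
#'   `list(blood = c("z-" = "outlet", "z+" = "inlet"))`; values are
#'   `"inlet"`, `"outlet"`, or `"wall"`.
#' @return a `boundary_spec`-compatible object.
#' @export
openings_by_face <- function(model, roles) {
  dd <- dim(model$interstitium)
  cells <- list()
  for (cls in c("blood", "lymph")) {
    m <- model[[cls]]
    if (!any(m)) next
    rl <- roles[[cls]]
    for (f in FACE_NAMES) {
      ax <- face_axis(f)
      pos <- if (face_side(f) < 0) 1L else dd[ax]
      idx <- list(seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]))
      idx[[ax]] <- pos
      sl <- m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      if (!any(sl)) next
      role <- if (!is.null(rl) && f %in% names(rl)) rl[[f]] else "wall"
      grid <- expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]])
      lin <- (grid$x - 1) * dd[1] * dd[2] + (grid$y - 1) * dd[1] + grid$z
      cells[[length(cells) + 1L]] <-
        data.frame(class = cls, face = f, role = role, patch = 1L,
                   cell = lin[as.vector(sl)])
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells)
  else data.frame(class = character(), face = character(),
                  role = character(), patch = integer(), cell = integer())
  structure(list(pleural_direction = NA_character_,
                 distal_faces = character(), patches = NULL, cells = cells),
            class = "boundary_spec")
}
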