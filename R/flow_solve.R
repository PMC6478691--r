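#' Solve the discrete flow system
#'
#' Solves the assembled sparse system, then iteratively suppresses
#' backflow: outlet faces whose computed normal velocity points into the
#' domain are converted to sealed walls and the system is reassembled and
#' re-solved until no face changes or `max_backflow_iters` is reached.
#'
#' Small systems are solved by a direct sparse LU after row equilibration.
#' Larger systems use a block iteration that exploits the structure of the
#' problem: the symmetric positive definite interstitial Darcy pressure
#' block is factored once with a supernodal Cholesky, the (small) Stokes
#' lumen block with a sparse LU, and the two are alternated
#' (block Gauss-Seidel) through the weak membrane coupling until the full
#' monolithic residual drops below `tol`.
#'
#' @param system a [assemble_flow_system()] result.
#' @param tol relative residual tolerance of the block iteration.
#' @param max_backflow_iters cap on backflow-suppression passes.
#' @param method `"auto"` (direct below `direct_limit` unknowns, block
#'   above), `"direct"`, or `"block"`.
#' @param direct_limit unknown-count threshold for the direct path.
#' @param max_block_iters cap on block Gauss-Seidel sweeps.
#' @return object of class `flow_solution`: solution vector `x`, pressure
#'   array `p` (Pa, `NA` outside the fluid), cell-centred velocity arrays
#'   `u` (list of 3 components, m/s), residual norms per equation block,
#'   membrane fluxes `Q_L_in` and `Q_B_out` (m^3/s), per-domain mass
#'   balance, suppressed outlet face count and backflow convergence flag.
#' @export
solve_flow <- function(system, tol = 1e-10, max_backflow_iters = 20L,
                       method = c("auto", "direct", "block"),
                       direct_limit = 30000L, max_block_iters = 400L) {
  method <- match.arg(method)
  sys <- system
  suppressed <- sys$call_args$suppressed
  n_suppressed <- if (is.null(suppressed)) 0L else nrow(suppressed)
  bf_iter <- 0L
  bf_converged <- TRUE
  repeat {
    x <- solve_linear(sys, tol, method, direct_limit, max_block_iters)
    # backflow check: outward normal velocity at outlet faces
    ot <- sys$outlets
    if (!nrow(ot) || bf_iter >= max_backflow_iters) {
      if (nrow(ot)) {
        uscale <- max(abs(x[ot$uidx]), 1e-30)
        if (any(ot$out_sign * x[ot$uidx] < -1e-10 * uscale))
          bf_converged <- FALSE
      }
      break
    }
    uout <- ot$out_sign * x[ot$uidx]
    uscale <- max(abs(uout), abs(sys$inlets$u_in), 1e-30)
    bad <- uout < -1e-10 * uscale
    # a class with no inlet must keep at least one outlet face as its
    # pressure reference; spare its least-backflowing face
    for (cls in unique(ot$class)) {
      sel <- ot$class == cls
      if (!any(sys$inlets$class == cls) && all(bad[sel])) {
        spare <- which(sel)[which.max(uout[sel])]
        bad[spare] <- FALSE
        bf_converged <- FALSE
      }
    }
    if (!any(bad)) break
    bf_iter <- bf_iter + 1L
    newsup <- ot[bad, c("class", "cell", "face", "axis", "fpos")]
    suppressed <- if (is.null(suppressed)) newsup else
      unique(rbind(suppressed, newsup))
    n_suppressed <- nrow(suppressed)
    ca <- sys$call_args
    sys <- assemble_flow_system(ca$model, ca$boundaries, ca$params,
                                interstitial_bc = ca$interstitial_bc,
                                outlet_pressures = ca$outlet_pressures,
                                suppressed = suppressed)
  }

  res <- residual_norms(sys, x)
  sol <- structure(list(x = x, system = sys,
                        residuals = res,
                        suppressed_outlet_faces = n_suppressed,
                        backflow_iterations = bf_iter,
                        backflow_converged = bf_converged),
                   class = "flow_solution")
  sol$p <- pressure_field(sol)
  sol$u <- velocity_field(sol)
  fx <- domain_fluxes(sol)
  sol$Q_L_in <- fx$Q_L_in
  sol$Q_B_out <- fx$Q_B_out
  sol$mass_balance <- fx$balance
  sol
}

# one linear solve of the current system.
#
# The unknowns mix pressures (~1e3 Pa) and velocities (~1e-9 m/s), so a
# plain factor-and-solve leaves the small continuity rows with a poor
# relative residual.  Both paths therefore work in correction form
# (iterative refinement): solve for dx from the current residual and
# update, which drives the row-wise residual to the rounding floor.
solve_linear <- function(sys, tol, method, direct_limit, max_block_iters) {
  A <- sys$A; b <- sys$b
  n <- length(b)
  if (n == 0L) stop("empty flow system (no unknowns)")
  rowscale <- function(M) {
    rs <- row_abs_max(M)
    rs[rs == 0] <- 1
    rs
  }
  colscale <- function(M) {
    cs <- row_abs_max(Matrix::t(M))
    cs[cs == 0] <- 1
    cs
  }
  # componentwise backward error with per-variable-type scales: every
  # equation -- including the tiny-magnitude interstitial continuity rows
  # -- must be satisfied relative to its own coefficient scale times the
  # typical magnitude of its variable kind (pressure vs velocity), which
  # keeps the large momentum rows from masking the small ones while not
  # penalising rows whose exact solution is zero
  absA <- abs(A)
  NPp <- sys$NP
  backward_err <- function(x, r) {
    ps <- if (NPp > 0L) max(abs(x[seq_len(NPp)]), 1e-300) else 1e-300
    us <- if (n > NPp) max(abs(x[(NPp + 1L):n]), 1e-300) else 1e-300
    xs <- c(rep(ps, NPp), rep(us, n - NPp))
    max(abs(r) / (as.vector(absA %*% xs) + abs(b) + 1e-300))
  }
  use_direct <- method == "direct" ||
    (method == "auto" && n <= direct_limit) || sys$NI == 0L
  if (use_direct) {
    rs <- rowscale(A)
    As <- Matrix::Diagonal(x = 1 / rs) %*% A
    cs <- colscale(As)
    As <- As %*% Matrix::Diagonal(x = 1 / cs)
    LU <- Matrix::lu(As)
    x <- numeric(n)
    for (it in 1:8) {
      r <- b - as.vector(A %*% x)
      if (it > 1L && backward_err(x, r) <= max(tol, 1e-14)) break
      dx <- as.vector(Matrix::solve(LU, r / rs)) / cs
      x <- x + dx
    }
    return(x)
  }
  I <- seq_len(sys$NI)
  S <- (sys$NI + 1L):n
  A_II <- Matrix::forceSymmetric(A[I, I, drop = FALSE])
  F_I <- Matrix::Cholesky(A_II, perm = TRUE, super = TRUE)
  A_SS <- A[S, S, drop = FALSE]
  rsS <- rowscale(A_SS)
  AsS <- Matrix::Diagonal(x = 1 / rsS) %*% A_SS
  csS <- colscale(AsS)
  AsS <- AsS %*% Matrix::Diagonal(x = 1 / csS)
  LU_S <- Matrix::lu(AsS)
  x <- numeric(n)
  omega <- Inf
  for (it in seq_len(max_block_iters)) {
    r <- b - as.vector(A %*% x)
    omega <- backward_err(x, r)
    if (omega <= tol && it > 1L) break
    x[I] <- x[I] + as.vector(Matrix::solve(F_I, r[I]))
    r <- b - as.vector(A %*% x)
    x[S] <- x[S] + as.vector(Matrix::solve(LU_S, r[S] / rsS)) / csS
  }
  if (omega > tol)
    stop(sprintf(paste0("flow solver did not converge: componentwise ",
                        "backward error %.3e after %d block iterations"),
                 omega, max_block_iters))
  x
}

# max |entry| per row of a sparse matrix
row_abs_max <- function(A) {
  s <- Matrix::summary(A)
  out <- numeric(nrow(A))
  ag <- tapply(abs(s$x), s$i, max)
  out[as.integer(names(ag))] <- ag
  out
}

residual_norms <- function(sys, x) {
  r <- sys$b - as.vector(sys$A %*% x)
  nI <- sys$NI; nP <- sys$NP
  list(
    interstitial_continuity = if (nI) sqrt(sum(r[seq_len(nI)]^2)) else 0,
    lumen_continuity = if (nP > nI) sqrt(sum(r[(nI + 1):nP]^2)) else 0,
    momentum = if (length(r) > nP) sqrt(sum(r[(nP + 1):length(r)]^2)) else 0,
    total_relative = sqrt(sum(r^2)) / max(sqrt(sum(sys$b^2)), 1e-300))
}

pressure_field <- function(sol) {
  sys <- sol$system
  p <- array(NA_real_, sys$dims)
  sel <- sys$pidx > 0L
  p[sel] <- sol$x[sys$pidx[sel]]
  p
}

# face velocity values (m/s, + along the axis) for one axis
face_velocities <- function(sys, x, d) {
  ax <- sys$axes[[d]]
  u <- numeric(length(ax$code))
  aff <- ax$code %in% c(FC_DARCY, FC_MEMB, FC_EXT, FC_INLET)
  if (any(aff)) {
    w <- which(aff)
    plo <- ifelse(ax$loP[w] > 0L, x[pmax(ax$loP[w], 1L)], 0)
    phi <- ifelse(ax$hiP[w] > 0L, x[pmax(ax$hiP[w], 1L)], 0)
    u[w] <- ax$cst[w] + ax$clo[w] * plo + ax$chi[w] * phi
  }
  unk <- ax$uidx > 0L
  u[unk] <- x[ax$uidx[unk]]
  u
}

# cell-centred velocity components from staggered face values
velocity_field <- function(sol) {
  sys <- sol$system
  dd <- sys$dims
  out <- vector("list", 3)
  names(out) <- c("z", "y", "x")
  for (d in 1:3) {
    fv <- face_velocities(sys, sol$x, d)
    fd <- sys$axes[[d]]$fd
    fv <- array(fv, fd)
    lo <- if (d == 1L) fv[1:dd[1], , , drop = FALSE]
    else if (d == 2L) fv[, 1:dd[2], , drop = FALSE]
    else fv[, , 1:dd[3], drop = FALSE]
    hi <- if (d == 1L) fv[2:fd[1], , , drop = FALSE]
    else if (d == 2L) fv[, 2:fd[2], , drop = FALSE]
    else fv[, , 2:fd[3], drop = FALSE]
    v <- (lo + hi) / 2
    v[sys$tc == 0L] <- NA_real_
    out[[d]] <- array(v, dd)
  }
  out
}

#' Volumetric flux accounting
#'
#' Computes, from a converged solution: the net membrane flux into the
#' lymphatic domain (`Q_L_in`) and out of the blood domain (`Q_B_out`),
#' inlet/outlet throughputs per vessel class, the external interstitial
#' exchange, and the per-domain mass-balance defect relative to the gross
#' flux through the domain.
#'
#' @param sol a [solve_flow()] result.
#' @return list with `Q_L_in`, `Q_B_out`, `throughput` (data.frame), and
#'   `balance` (per-domain defect and gross flux).
#' @export
domain_fluxes <- function(sol) {
  sys <- sol$system
  x <- sol$x
  Afc <- sys$face_area
  mt <- sys$membrane
  memb_out <- if (nrow(mt))
    Afc * mt$K * (x[mt$p_lum] - x[mt$p_int]) else numeric()
  Q_L_in <- -sum(memb_out[mt$class == "lymph"])
  Q_B_out <- sum(memb_out[mt$class == "blood"])
  it <- sys$inlets
  Q_in <- if (nrow(it)) Afc * it$u_in else numeric()
  ot <- sys$outlets
  Q_out <- if (nrow(ot)) Afc * ot$out_sign * x[ot$uidx] else numeric()
  et <- sys$externals
  Q_ext_out <- if (nrow(et))
    Afc * 2 * sys$params$k / (sys$params$mu * sys$h) *
      (x[et$p_cell] - et$pext) else numeric()

  dom_balance <- function(inflow, outflow) {
    gross <- sum(abs(inflow)) + sum(abs(outflow))
    defect <- abs(sum(inflow) - sum(outflow))
    c(defect = defect, gross = gross,
      relative = if (gross > 0) defect / gross else 0)
  }
  bal <- list(
    interstitium = dom_balance(
      c(memb_out[mt$class == "blood"], memb_out[mt$class == "lymph"]),
      Q_ext_out),
    blood = dom_balance(Q_in[it$class == "blood"],
                        c(Q_out[ot$class == "blood"],
                          memb_out[mt$class == "blood"])),
    lymph = dom_balance(Q_in[it$class == "lymph"],
                        c(Q_out[ot$class == "lymph"],
                          memb_out[mt$class == "lymph"])))
  list(Q_L_in = Q_L_in, Q_B_out = Q_B_out,
       throughput = data.frame(
         what = c("blood_inlet", "blood_outlet", "lymph_inlet",
                  "lymph_outlet", "interstitial_exchange_out"),
         Q_m3_s = c(sum(Q_in[it$class == "blood"]),
                    sum(Q_out[ot$class == "blood"]),
                    sum(Q_in[it$class == "lymph"]),
                    sum(Q_out[ot$class == "lymph"]),
                    sum(Q_ext_out))),
       balance = bal)
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d unknowns, Q_L_in %.4g m^3/s, Q_B_out %.4g m^3/s\n",
              length(x$x), x$Q_L_in, x$Q_B_out))
  cat(sprintf("  suppressed outlet faces: %d (converged: %s)\n",
              x$suppressed_outlet_faces, x$backflow_converged))
  cat(sprintf("  relative residual: %.3e\n", x$residuals$total_relative))
  invisible(x)
}

#' Export pressure and velocity fields as legacy VTK
#'
#' Writes the cell data (pressure, velocity vector, domain label) of a
#' converged solution as an ASCII legacy-VTK structured-points file, the
#' visual analogue of the study's streamline figures.
#'
#' @param sol a [solve_flow()] result.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
export_fields <- function(sol, path) {
  if (is.null(sol$p) || all(is.na(sol$p)))
    stop("refusing to export an empty solution")
  dd <- sol$system$dims
  h <- sol$system$h
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "pulmolymph steady flow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               # VTK x-fastest ordering = our z-fastest array order; axis
               # names swap but geometry is preserved
               sprintf("DIMENSIONS %d %d %d", dd[1], dd[2], dd[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.10g %.10g %.10g", h, h, h),
               sprintf("POINT_DATA %d", prod(dd)),
               "SCALARS pressure double 1",
               "LOOKUP_TABLE default"), con)
  pv <- as.vector(sol$p); pv[is.na(pv)] <- 0
  writeLines(format_rows(pv), con)
  writeLines("VECTORS velocity double", con)
  vz <- as.vector(sol$u$z); vy <- as.vector(sol$u$y); vx <- as.vector(sol$u$x)
  vz[is.na(vz)] <- 0; vy[is.na(vy)] <- 0; vx[is.na(vx)] <- 0
  writeLines(sprintf("%.10g %.10g %.10g", vz, vy, vx), con)
  writeLines(c("SCALARS domain int 1", "LOOKUP_TABLE default"), con)
  writeLines(format_rows(as.vector(sol$system$tc)), con)
  invisible(path)
}

format_rows <- function(v) sprintf("%.10g", v)

#' Read back a legacy VTK structured-points file
#'
#' Minimal reader for files produced by [export_fields()], used for
#' round-trip verification.
#'
#' @param path `.vtk` path.
#' @return list: `dims`, `spacing`, `pressure` (array), `velocity`
#'   (list z/y/x arrays), `domain` (integer array).
#' @export
read_vtk_fields <- function(path) {
  ln <- readLines(path)
  dl <- strsplit(grep("^DIMENSIONS", ln, value = TRUE), "\\s+")[[1]]
  dd <- as.integer(dl[2:4])
  sp <- as.numeric(strsplit(grep("^SPACING", ln, value = TRUE),
                            "\\s+")[[1]][2:4])
  N <- prod(dd)
  i_p <- grep("^SCALARS pressure", ln) + 2L
  p <- as.numeric(ln[i_p:(i_p + N - 1L)])
  i_v <- grep("^VECTORS velocity", ln) + 1L
  vm <- do.call(rbind, lapply(strsplit(ln[i_v:(i_v + N - 1L)], "\\s+"),
                              as.numeric))
  i_d <- grep("^SCALARS domain", ln) + 2L
  dom <- as.integer(ln[i_d:(i_d + N - 1L)])
  list(dims = dd, spacing = sp,
       pressure = array(p, dd),
       velocity = list(z = array(vm[, 1], dd), y = array(vm[, 2], dd),
                       x = array(vm[, 3], dd)),
       domain = array(dom, dd))
}
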