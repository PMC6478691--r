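#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples.  With both group sizes at
#' most 12 and no ties the two-sided p-value is exact, from the null
#' distribution of U computed by the standard counting recurrence;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.  The method actually applied is recorded.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative only `"two.sided"` is provided.
#' @return list: `U` (statistic for `x`), `p`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("empty group")
  if (!identical(alternative, "two.sided"))
    stop("only the two-sided alternative is implemented")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 <= 12L && n2 <= 12L) {
    cnt <- u_null_counts(n1, n2)       # counts of U = 0..n1*n2
    tot <- sum(cnt)
    # two-sided: double the smaller tail (distribution is symmetric)
    lo <- sum(cnt[seq_len(U + 1)])     # P(U <= u)
    hi <- sum(cnt[(U + 1):length(cnt)])
    p <- min(1, 2 * min(lo, hi) / tot)
    return(list(U = U, p = p, method = "exact", n1 = n1, n2 = n2))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal_approx",
                               n1 = n1, n2 = n2))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p = p, method = "normal_approx", n1 = n1, n2 = n2)
}

# null distribution of U: number of interleavings of a x's and b y's with
# statistic u, by the counting recurrence
#   c(a, b, u) = c(a-1, b, u-b) + c(a, b-1, u)
# (the largest remaining observation is an x, beating all b y's, or a y)
u_null_counts <- function(n1, n2) {
  maxu <- n1 * n2
  cnt <- array(0, dim = c(n1 + 1L, n2 + 1L, maxu + 1L))
  cnt[1L, 1L, 1L] <- 1
  for (a in 0:n1) for (b in 0:n2) {
    if (a == 0 && b == 0) next
    for (u in 0:maxu) {
      v <- 0
      if (a > 0 && u - b >= 0) v <- v + cnt[a, b + 1L, u - b + 1L]
      if (b > 0) v <- v + cnt[a + 1L, b, u + 1L]
      cnt[a + 1L, b + 1L, u + 1L] <- v
    }
  }
  cnt[n1 + 1L, n2 + 1L, ]
}

#' Correlation of a morphometric measure with pleural distance
#'
#' Pearson correlation, its two-sided p-value from the t distribution
#' (`t = r sqrt((n-2)/(1-r^2))`), and the least-squares line, after
#' dropping excluded records (counted).
#'
#' @param distance_um pleural distances, micrometres.
#' @param value measure values (may contain `NA`).
#' @param excluded optional logical vector of records to drop (e.g. failed
#'   fractal fits).
#' @param measure name carried into the result.
#' @return one-row data.frame: `measure`, `n`, `r`, `abs_r`, `p`, `slope`,
#'   `intercept`, `n_excluded`.
#' @export
correlate_with_distance <- function(distance_um, value, excluded = NULL,
                                    measure = "measure") {
  drop <- is.na(value) | is.na(distance_um)
  if (!is.null(excluded)) drop <- drop | excluded
  n_exc <- sum(drop)
  d <- distance_um[!drop]; v <- value[!drop]
  if (length(d) < 3L) stop("fewer than 3 usable records")
  if (stats::sd(d) == 0 || stats::sd(v) == 0)
    stop("zero variance in distance or measure")
  ct <- stats::cor.test(d, v, method = "pearson")
  fit <- stats::lm(v ~ d)
  data.frame(measure = measure, n = length(d),
             r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
             p = ct$p.value,
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             n_excluded = n_exc)
}

MORPHOMETRY_MEASURES <- c("volume_fraction", "sa_per_tissue_volume_per_um",
                          "fractal_dimension", "branch_count",
                          "junction_count", "mean_tortuosity")

#' Compare two cohorts across the six morphometric measures
#'
#' Mann-Whitney U per measure between two morphometry tables (one row per
#' VOI), with group medians and sizes.  No multiple-testing correction is
#' applied by default; an optional Bonferroni column can be added.
#'
#' @param control_records,diseased_records data.frames with the
#'   morphometric measure columns (as produced by [measure_vois()]).
#' @param measures measure column names to compare.
#' @param bonferroni add a Bonferroni-adjusted p column.
#' @return data.frame, one row per measure: `U`, `p`, medians, group sizes
#'   (and `p_bonferroni` when requested).
#' @export
compare_groups <- function(control_records, diseased_records,
                           measures = MORPHOMETRY_MEASURES,
                           bonferroni = FALSE) {
  if (!nrow(control_records) || !nrow(diseased_records))
    stop("both cohorts must be non-empty")
  rows <- lapply(measures, function(m) {
    xc <- control_records[[m]]; xd <- diseased_records[[m]]
    xc <- xc[!is.na(xc)]; xd <- xd[!is.na(xd)]
    mw <- mann_whitney_u(xc, xd)
    data.frame(measure = m, U = mw$U, p = mw$p, method = mw$method,
               median_control = stats::median(xc),
               median_diseased = stats::median(xd),
               n_control = length(xc), n_diseased = length(xd))
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * length(measures))
  out
}

#' Parameter sensitivity of the lymphatic uptake
#'
#' Re-solves the flow model with each target parameter multiplied by each
#' factor (default 100 and 1/100, the protocol applied to the membrane
#' conductivities and the lymphatic inlet velocity) and reports the change
#' in net membrane flux into the lymphatic domain, `Q_L_in`, against a
#' discretisation-error estimate obtained from one grid-halving refinement
#' of the base case.
#'
#' @param model a [prepare_model_volume()] result.
#' @param boundaries matching boundary spec.
#' @param params base [fluid_parameters()].
#' @param factors multiplicative perturbations.
#' @param targets parameter names to perturb.
#' @param refine compute the grid-refinement error estimate (one solve at
#'   half the voxel pitch).
#' @param tol,method passed to [solve_flow()].
#' @return object of class `sensitivity_report`: data.frame `runs` with
#'   `parameter`, `factor`, `Q_L_in`, `abs_change`, `pct_change`,
#'   `below_error`; plus `base_Q_L_in` and `discretization_error`.
#' @export
run_sensitivity <- function(model, boundaries, params,
                            factors = c(100, 0.01),
                            targets = c("K_L", "K_B", "u_L"),
                            refine = TRUE, tol = 1e-10, method = "auto") {
  base <- solve_flow(assemble_flow_system(model, boundaries, params),
                     tol = tol, method = method)
  q0 <- base$Q_L_in
  disc_err <- NA_real_
  if (refine) {
    rmodel <- refine_model(model)
    rbnd <- rescale_boundaries(boundaries, model, rmodel)
    rsol <- solve_flow(assemble_flow_system(rmodel, rbnd, params),
                       tol = tol, method = method)
    disc_err <- abs(rsol$Q_L_in - q0)
  }
  rows <- list()
  for (tg in targets) for (fc in factors) {
    p2 <- params
    p2[[tg]] <- params[[tg]] * fc
    sol <- tryCatch(
      solve_flow(assemble_flow_system(model, boundaries, p2),
                 tol = tol, method = method),
      error = function(e) e)
    if (inherits(sol, "error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = tg, factor = fc, Q_L_in = NA_real_,
                   abs_change = NA_real_, pct_change = NA_real_,
                   below_error = NA, status = conditionMessage(sol))
      next
    }
    q <- sol$Q_L_in
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = tg, factor = fc, Q_L_in = q,
                 abs_change = q - q0,
                 pct_change = 100 * (q - q0) / q0,
                 below_error = if (is.na(disc_err)) NA
                 else abs(q - q0) <= disc_err,
                 status = "ok")
  }
  structure(list(runs = do.call(rbind, rows), base_Q_L_in = q0,
                 discretization_error = disc_err,
                 base_residual = base$residuals$total_relative),
            class = "sensitivity_report")
}

# map a boundary spec onto a refined (2x) model: boundary cell indices are
# re-derived per face from roles, which are per-face uniform in our specs
rescale_boundaries <- function(boundaries, model, rmodel) {
  roles <- list()
  bc <- boundaries$cells
  for (cls in unique(bc$class)) {
    sub <- unique(bc[bc$class == cls, c("face", "role")])
    roles[[cls]] <- stats::setNames(sub$role, sub$face)
  }
  openings_by_face(rmodel, roles)
}

#' @exportS3Method base::print
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report: base Q_L_in %.4g m^3/s, grid-refinement\n",
              x$base_Q_L_in))
  cat(sprintf("  error estimate %.4g m^3/s\n", x$discretization_error))
  print(x$runs)
  invisible(x)
}
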