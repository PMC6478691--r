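# shared fixtures, built once per run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixtures, inherits = FALSE))
    assign(name, builder(), .fixtures)
  get(name, .fixtures, inherits = FALSE)
}

# the default intralobular-like synthetic volume used across tests
std_voi <- function() fixture("std_voi", function()
  generate_voi(synthetic_spec(shape = c(40L, 40L, 40L), seed = 2L)))

# a small intralobular flow case: model + boundaries (no upsampling; the
# synthetic geometry has no segmentation noise to smooth)
std_flow_case <- function() fixture("std_flow_case", function() {
  g <- generate_voi(synthetic_spec(shape = c(32L, 32L, 32L), seed = 3L))
  model <- prepare_model_volume(g$volume, voi = NULL, upsample = 1L,
                                median_window = 1L)
  list(g = g, model = model, boundaries = identify_vessel_openings(model))
})

# cohort spec kept small for parameter-recovery simulations
cohort_base_spec <- function()
  synthetic_spec(shape = c(32L, 32L, 32L),
                 openings = list(blood = c("z+" = 1L, "y-" = 1L),
                                 lymph = c("z+" = 1L)))

# digital sphere mask of given radius centred in a cube
sphere_mask <- function(radius, n = 2L * radius + 11L) {
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  array(sqrt(rowSums((idx - ctr)^2)) <= radius, c(n, n, n))
}

# brute-force two-sided exact Mann-Whitney p by full enumeration
exact_p_enum <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(n, n1)
  Us <- apply(cmb, 2, function(ix) sum(seq_len(n)[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
}

# flux through the outlet faces on one named face of a solved system
outlet_face_flux <- function(sol, face) {
  ot <- sol$system$outlets
  sum((sol$system$face_area * ot$out_sign * sol$x[ot$uidx])[ot$face == face])
}

prep1 <- function(vol) prepare_model_volume(vol, voi = NULL, upsample = 1L,
                                            median_window = 1L)
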