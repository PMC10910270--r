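# Shared fixtures, built once on demand and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fix, inherits = FALSE)) {
    val <- switch(
      name,
      sph = reference_spheroid(),
      # ~35-sensor triaxial array: cheap, used for geometry/metrics checks
      arr_small = generate_scalp_array(fixture("sph"), spacing = 0.032,
                                       axes = 3, seed = 1),
      # ~65-sensor triaxial array: well-posed SSS (195 channels > 107 harmonics)
      arr_tri = generate_scalp_array(fixture("sph"), spacing = 0.025,
                                     axes = 3, seed = 1),
      bas_small = suppressWarnings(build_basis(fixture("arr_small"),
                                               fixture("sph"))),
      bas_tri = suppressWarnings(build_basis(fixture("arr_tri"),
                                             fixture("sph"))),
      P_amm = amm_projector(fixture("bas_tri")),
      P_sss = suppressWarnings(sss_projector(fixture("bas_tri"))),
      lf_tri = simulate_leadfields(fixture("arr_tri"), fixture("sph"),
                                   n_src = 100, seed = 2),
      # dense single- and dual-axis arrays for the interference/neuronal
      # protocols (the densest sampling drives the worst-case statistics)
      arr_rad_dense = generate_scalp_array(fixture("sph"), spacing = 0.014,
                                           axes = 1, seed = 1),
      arr_dual_dense = generate_scalp_array(fixture("sph"), spacing = 0.014,
                                            axes = 2, seed = 1),
      bas_rad_dense = suppressWarnings(build_basis(fixture("arr_rad_dense"),
                                                   fixture("sph"))),
      bas_dual_dense = suppressWarnings(build_basis(fixture("arr_dual_dense"),
                                                    fixture("sph"))),
      # ~100-sensor triaxial array for the neuronal-space protocol
      arr_t7 = array_with_channel_count(fixture("sph"), 300, axes = 3),
      bas_t7 = suppressWarnings(build_basis(fixture("arr_t7"),
                                            fixture("sph"))),
      stop("unknown fixture: ", name)
    )
    assign(name, val, envir = .fix)
  }
  get(name, envir = .fix)
}

# Synthetic basis object with prescribed internal/external blocks, for
# projector algebra tests that need controlled span geometry.
make_synthetic_basis <- function(Hin, Hout) {
  meta <- data.frame(
    kind = c(rep("internal", ncol(Hin)), rep("external", ncol(Hout))),
    l = 1, m = 0, family = "spherical")
  structure(list(matrix = cbind(Hin, Hout), meta = meta,
                 scales = rep(1, ncol(Hin) + ncol(Hout)),
                 frame = NULL, channel_names = NULL),
            class = "harmonic_basis")
}

with_seed_test <- function(seed, expr) ammr:::with_seed(seed, expr)

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
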