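#' Ring geometry of the network
#'
#' Principal cells (E) and interneurons (I) live on separate rings; each
#' neuron is labelled by its angular position in degrees. Positions are
#' uniformly spaced, `theta_i = i * 360 / N` for `i = 0 .. N-1`.
#'
#' @param n_E number of principal cells (default 1024).
#' @param n_I number of interneurons (default 256).
#' @return An object of class `ring_geometry` with elements `n_E`, `n_I`,
#'   `theta_E`, `theta_I` (positions in degrees, in `[0, 360)`).
#' @export
ring_geometry <- function(n_E = 1024L, n_I = 256L) {
  n_E <- as.integer(n_E); n_I <- as.integer(n_I)
  stopifnot(n_E >= 2L, n_I >= 2L)
  structure(
    list(
      n_E = n_E, n_I = n_I,
      theta_E = (seq_len(n_E) - 1) * 360 / n_E,
      theta_I = (seq_len(n_I) - 1) * 360 / n_I
    ),
    class = "ring_geometry"
  )
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("<ring_geometry> %d principal cells, %d interneurons\n",
              x$n_E, x$n_I))
  invisible(x)
}

#' Circular angular difference
#'
#' Distance between two angles on the ring, in degrees. Inputs outside
#' `[0, 360)` are wrapped. The result lies in `[0, 180]` and is symmetric
#' in its arguments.
#'
#' @param theta_a,theta_b angles in degrees (vectorised).
#' @return circular distance in degrees, in `[0, 180]`.
#' @export
angular_difference <- function(theta_a, theta_b) {
  d <- abs((theta_a %% 360) - (theta_b %% 360))
  pmin(d, 360 - d)
}

#' Connectivity parameters
#'
#' Angular profiles of synaptic coupling. E-to-I coupling is a Gaussian of
#' the circular angular difference peaked at zero on a baseline,
#' `W(d) = J_minus + (J_plus - J_minus) exp(-d^2 / (2 sigma_EI^2))`;
#' I-to-E coupling is an off-centre Gaussian,
#' `W(d) = G exp(-(d - mu_IE)^2 / (2 sigma_IE^2))`. The baseline `J_minus`
#' and gain `G` are not free: they are fixed by the normalization condition
#' that the mean of the profile over angular differences equals one (see
#' [normalization_constants()]). I-to-I coupling is uniform by default;
#' unimodal and bimodal structured variants are available. An optional
#' E-to-E profile (Gaussian peaked at zero, no autapse) supports the
#' recurrent-excitation variant.
#'
#' @param J_plus_EI peak E-to-I coupling at zero angular difference (1.6).
#' @param sigma_EI width of the E-to-I Gaussian, degrees (30).
#' @param mu_IE offset of the I-to-E Gaussian peak, degrees (90).
#' @param sigma_IE width of the I-to-E Gaussian, degrees (30).
#' @param w_II_mode `"uniform"` (all entries 1), `"unimodal"` (Gaussian
#'   peaked at 0) or `"bimodal"` (Gaussians peaked at 0 and 180).
#' @param sigma_II width of structured I-to-I profiles, degrees.
#' @param ee_enabled build an E-to-E profile as well.
#' @param sigma_EE width of the E-to-E Gaussian, degrees.
#' @param normalization `"discrete"` normalises on the actual angular grid
#'   of the network (the profile mean over the grid is exactly 1);
#'   `"integral"` uses the continuous 0-360 degree integral instead. The
#'   two differ by O(1/N).
#' @return An object of class `connectivity_params`.
#' @export
connectivity_params <- function(J_plus_EI = 1.6, sigma_EI = 30,
                                mu_IE = 90, sigma_IE = 30,
                                w_II_mode = c("uniform", "unimodal", "bimodal"),
                                sigma_II = 30,
                                ee_enabled = FALSE, sigma_EE = 30,
                                normalization = c("discrete", "integral")) {
  w_II_mode <- match.arg(w_II_mode)
  normalization <- match.arg(normalization)
  stopifnot(sigma_EI > 0, sigma_IE > 0, sigma_II > 0, sigma_EE > 0,
            mu_IE >= 0, mu_IE <= 180)
  structure(
    list(J_plus_EI = J_plus_EI, sigma_EI = sigma_EI,
         mu_IE = mu_IE, sigma_IE = sigma_IE,
         w_II_mode = w_II_mode, sigma_II = sigma_II,
         ee_enabled = ee_enabled, sigma_EE = sigma_EE,
         normalization = normalization),
    class = "connectivity_params"
  )
}

# Angular-difference grid used for normalization: circular distances of n
# uniformly spaced presynaptic positions from a reference at 0 degrees.
delta_theta_grid <- function(n) {
  angular_difference((seq_len(n) - 1) * 360 / n, 0)
}

# Mean of a profile over angular difference, either as the discrete mean on
# an n-point uniform grid or as the continuous 0-360 integral (with the
# circular-distance convention, i.e. integrating f(|d|_circ) d theta / 360).
profile_mean <- function(f, n, normalization) {
  if (normalization == "discrete") {
    mean(f(delta_theta_grid(n)))
  } else {
    stats::integrate(function(d) f(angular_difference(d, 0)), 0, 360,
                     subdivisions = 1000L, rel.tol = 1e-12)$value / 360
  }
}

#' Normalization constants of the connectivity profiles
#'
#' Solves for the derived constants `J_minus_EI` (baseline of the E-to-I
#' profile) and `G_IE` (gain of the I-to-E profile) so that the mean of
#' each profile over the angular-difference grid equals exactly one. With
#' the discrete convention the grid is the actual grid of presynaptic
#' positions of the network, so the row means of the built matrices are 1
#' up to rounding.
#'
#' @param geom a [ring_geometry()].
#' @param params a [connectivity_params()].
#' @return list with `J_minus_EI`, `G_IE` and, when enabled, `G_EE` and
#'   structured-I gains.
#' @export
normalization_constants <- function(geom, params) {
  nrm <- params$normalization
  # E -> I: presynaptic grid has n_E points
  m_EI <- profile_mean(function(d) exp(-d^2 / (2 * params$sigma_EI^2)),
                       geom$n_E, nrm)
  if (m_EI >= 1) stop("E->I profile too flat: normalization has no solution")
  J_minus <- (1 - params$J_plus_EI * m_EI) / (1 - m_EI)
  # I -> E: presynaptic grid has n_I points
  m_IE <- profile_mean(
    function(d) exp(-(d - params$mu_IE)^2 / (2 * params$sigma_IE^2)),
    geom$n_I, nrm)
  out <- list(J_minus_EI = J_minus, G_IE = 1 / m_IE)
  if (params$w_II_mode == "unimodal") {
    m <- profile_mean(function(d) exp(-d^2 / (2 * params$sigma_II^2)),
                      geom$n_I, nrm)
    out$G_II <- 1 / m
  } else if (params$w_II_mode == "bimodal") {
    m <- profile_mean(function(d) {
      exp(-d^2 / (2 * params$sigma_II^2)) +
        exp(-(d - 180)^2 / (2 * params$sigma_II^2))
    }, geom$n_I, nrm)
    out$G_II <- 1 / m
  }
  if (params$ee_enabled) {
    m_EE <- profile_mean(function(d) exp(-d^2 / (2 * params$sigma_EE^2)),
                         geom$n_E, nrm)
    out$G_EE <- 1 / m_EE
  }
  out
}

# Profile value as a function of circular angular difference (vectorised),
# for each projection. `consts` comes from normalization_constants().
connectivity_kernel <- function(which, d, params, consts) {
  switch(which,
    EI = consts$J_minus_EI +
      (params$J_plus_EI - consts$J_minus_EI) *
        exp(-d^2 / (2 * params$sigma_EI^2)),
    IE = consts$G_IE * exp(-(d - params$mu_IE)^2 / (2 * params$sigma_IE^2)),
    II = switch(params$w_II_mode,
      uniform = rep(1, length(d)),
      unimodal = consts$G_II * exp(-d^2 / (2 * params$sigma_II^2)),
      bimodal = consts$G_II * (exp(-d^2 / (2 * params$sigma_II^2)) +
                               exp(-(d - 180)^2 / (2 * params$sigma_II^2)))
    ),
    EE = consts$G_EE * exp(-d^2 / (2 * params$sigma_EE^2)),
    stop("unknown projection: ", which)
  )
}

#' Build all connectivity matrices
#'
#' Dense weight matrices for every projection in the network, indexed
#' `[postsynaptic, presynaptic]`. Every entry is a function of the circular
#' angular difference between the two neurons only, so each matrix is
#' circulant up to the mapping between the E and I index grids. Row means
#' of `W_EI` and `W_IE` equal 1 exactly (discrete normalization); in
#' uniform mode `W_II` is the all-ones matrix. The optional `W_EE`
#' (recurrent-excitation variant) is peaked at zero angular difference
#' with the diagonal (autapse) zeroed.
#'
#' The matrices are evaluated from profiles on the fine angular grid of
#' the principal-cell ring (both rings must be commensurate,
#' `n_E` a multiple of `n_I`). For the I-to-E projection the presynaptic
#' grid seen by a principal cell depends on its offset from the nearest
#' interneuron; because the circular-distance profile has folds at 0 and
#' 180 degrees, offset classes are normalised separately (relative spread
#' of order 1e-5) so that every row mean is exactly 1. Symmetric offsets
#' have identical normalisation, so the matrix remains an even function
#' of the angular difference.
#'
#' @inheritParams normalization_constants
#' @return An object of class `connectivity_matrices`: list with `W_EI`
#'   (`n_I x n_E`), `W_IE` (`n_E x n_I`), `W_II` (`n_I x n_I`), optional
#'   `W_EE` (`n_E x n_E`), the derived `constants`, and the kernels
#'   evaluated on the common angular grid (used by the circular
#'   convolution evaluation path of the integrator).
#' @export
build_connectivity <- function(geom, params = connectivity_params()) {
  if (geom$n_E %% geom$n_I != 0)
    stop("the principal-cell ring must be commensurate with the ",
         "interneuron ring (n_E a multiple of n_I)")
  consts <- normalization_constants(geom, params)
  n_E <- geom$n_E; n_I <- geom$n_I
  r <- n_E %/% n_I
  d_fine <- delta_theta_grid(n_E)
  d_I <- delta_theta_grid(n_I)

  kEI <- connectivity_kernel("EI", d_fine, params, consts)
  kIE <- connectivity_kernel("IE", d_fine, params, consts)
  if (params$normalization == "discrete" && r > 1) {
    # per-offset-class row normalization of the I->E kernel
    cls <- (seq_len(n_E) - 1) %% r
    for (c in unique(cls)) {
      idx <- cls == c
      kIE[idx] <- kIE[idx] / mean(kIE[idx])
    }
  }
  kII <- connectivity_kernel("II", d_I, params, consts)
  kEE <- if (params$ee_enabled)
    connectivity_kernel("EE", d_fine, params, consts)

  # dense matrices from the kernels by circular index arithmetic
  idx_mod <- function(q) (q %% n_E) + 1L
  i_E <- seq_len(n_E) - 1L
  i_I <- (seq_len(n_I) - 1L) * r
  W_EI <- matrix(kEI[idx_mod(outer(i_I, i_E, "-"))], n_I, n_E)
  W_IE <- matrix(kIE[idx_mod(outer(i_E, i_I, "-"))], n_E, n_I)
  W_II <- matrix(kII[((outer(seq_len(n_I), seq_len(n_I), "-")) %% n_I) + 1L],
                 n_I, n_I)
  out <- list(W_EI = W_EI, W_IE = W_IE, W_II = W_II,
              constants = consts, geom = geom, params = params)
  if (params$ee_enabled) {
    W_EE <- matrix(kEE[idx_mod(outer(i_E, i_E, "-"))], n_E, n_E)
    diag(W_EE) <- 0
    out$W_EE <- W_EE
  }
  out$kernels <- list(EI_fine = kEI, IE_fine = kIE, II = kII,
                      EE_fine = kEE)
  structure(out, class = "connectivity_matrices")
}

#' @export
print.connectivity_matrices <- function(x, ...) {
  cat(sprintf(
    "<connectivity_matrices> E->I %dx%d, I->E %dx%d, I->I %s%s\n",
    nrow(x$W_EI), ncol(x$W_EI), nrow(x$W_IE), ncol(x$W_IE),
    x$params$w_II_mode,
    if (!is.null(x$W_EE)) sprintf(", E->E enabled (sigma %g deg)",
                                  x$params$sigma_EE) else ""))
  cat(sprintf("  J+ = %g, J- = %.6g, G(I->E) = %.6g\n",
              x$params$J_plus_EI, x$constants$J_minus_EI, x$constants$G_IE))
  invisible(x)
}

#' Write connectivity matrices to CSV files
#'
#' @param conn a [build_connectivity()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_connectivity_csv <- function(conn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- intersect(c("W_EI", "W_IE", "W_II", "W_EE"), names(conn))
  paths <- vapply(nms, function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.table(conn[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
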