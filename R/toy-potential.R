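# Synthetic 2D multi-well potential with analytically locatable critical
# points.  A stand-in landscape for validating the string method: a curve
# refined on it can be compared against grid/Newton-located minima and
# saddles, which a molecular free-energy surface never allows.

#' Create a 2D Gaussian multi-well potential
#'
#' V(r) = sum_m A_m exp(-(r-c_m)' P_m (r-c_m) / 2) + kconf/2 |r - c0|^2.
#' Negative amplitudes are wells, positive ones bumps.  Analytic gradient
#' and Hessian are available everywhere and the potential is bounded below.
#'
#' @param amps amplitudes (kcal/mol), negative for wells.
#' @param centers M x 2 matrix of term centres.
#' @param precs list of 2 x 2 inverse-covariance matrices.
#' @param kconf quadratic confinement constant (kcal/mol/A^2).
#' @param conf_center confinement centre (2-vector).
#' @return An object of class `ToyPotential2D`.
#' @export
toy_potential_2d <- function(amps, centers, precs, kconf = 0.2,
                             conf_center = c(0, 0)) {
  centers <- matrix(centers, ncol = 2)
  stopifnot(length(amps) == nrow(centers), length(precs) == length(amps))
  structure(list(amps = as.numeric(amps), centers = centers, precs = precs,
                 kconf = kconf, conf_center = as.numeric(conf_center)),
            class = "ToyPotential2D")
}

#' Two-well validation potential
#'
#' Two Gaussian wells separated along x, a Gaussian bump displaced along +y
#' between them (so the minimum-energy path bends away from the straight
#' line), and weak quadratic confinement.  The barrier from either well to
#' the saddle is approximately `barrier_height`.  `seed` draws a small
#' (3 percent) deterministic depth asymmetry between the wells unless
#' `asymmetry` is given explicitly; `asymmetry = 0` gives a potential
#' exactly symmetric under x -> -x, placing the saddle on the symmetry
#' axis.
#'
#' @param barrier_height approximate well-to-saddle barrier (kcal/mol), > 0.
#' @param well_separation distance between the well centres (Angstrom).
#' @param seed integer seed for the depth asymmetry draw.
#' @param asymmetry optional fractional depth difference between wells.
#' @return A [toy_potential_2d()].
#' @export
make_two_well_potential <- function(barrier_height = 5,
                                    well_separation = 4, seed = 1,
                                    asymmetry = NULL) {
  if (barrier_height <= 0)
    stop("barrier_height must be positive")
  if (is.null(asymmetry)) {
    set.seed(as.integer(seed))
    asymmetry <- runif(1, -0.03, 0.03)
  }
  d <- well_separation
  A <- barrier_height
  sw <- d / 4                      # well width
  pw <- diag(2) / sw^2
  bump_amp <- 0.8 * A
  bump_center <- c(0, 0.45 * sw * 2)
  pb <- diag(2) / (0.55 * d / 2)^2
  toy_potential_2d(
    amps = c(-A * (1 + asymmetry), -A * (1 - asymmetry), bump_amp),
    centers = rbind(c(-d / 2, 0), c(d / 2, 0), bump_center),
    precs = list(pw, pw, pb),
    kconf = 0.08 * A / (d / 2)^2,
    conf_center = c(0, 0))
}

#' Evaluate a 2D toy potential
#' @param pot a [toy_potential_2d()].
#' @param xy 2-vector or n x 2 matrix of positions.
#' @return Potential value(s) in kcal/mol.
#' @export
pot2d_value <- function(pot, xy) {
  xy <- matrix(xy, ncol = 2)
  out <- numeric(nrow(xy))
  for (m in seq_along(pot$amps)) {
    d <- sweep(xy, 2, pot$centers[m, ])
    q <- rowSums((d %*% pot$precs[[m]]) * d)
    out <- out + pot$amps[m] * exp(-0.5 * q)
  }
  d0 <- sweep(xy, 2, pot$conf_center)
  out + 0.5 * pot$kconf * rowSums(d0^2)
}

#' Analytic gradient of a 2D toy potential
#' @param pot a [toy_potential_2d()].
#' @param xy 2-vector.
#' @return Gradient 2-vector (kcal/mol/A).
#' @export
pot2d_grad <- function(pot, xy) {
  g <- pot$kconf * (xy - pot$conf_center)
  for (m in seq_along(pot$amps)) {
    d <- xy - pot$centers[m, ]
    Pd <- as.numeric(pot$precs[[m]] %*% d)
    g <- g - pot$amps[m] * exp(-0.5 * sum(Pd * d)) * Pd
  }
  g
}

#' Analytic Hessian of a 2D toy potential
#' @param pot a [toy_potential_2d()].
#' @param xy 2-vector.
#' @return 2 x 2 Hessian matrix.
#' @export
pot2d_hessian <- function(pot, xy) {
  H <- diag(pot$kconf, 2)
  for (m in seq_along(pot$amps)) {
    d <- xy - pot$centers[m, ]
    P <- pot$precs[[m]]
    Pd <- as.numeric(P %*% d)
    e <- exp(-0.5 * sum(Pd * d))
    H <- H + pot$amps[m] * e * (Pd %o% Pd - P)
  }
  H
}

#' Locate the critical points of a 2D toy potential
#'
#' Brute-force oracle: a grid scan for local minima of the gradient norm,
#' Newton refinement from each candidate, deduplication, and Hessian
#' eigenvalue classification.
#'
#' @param pot a [toy_potential_2d()].
#' @param grid_resolution grid spacing (Angstrom).
#' @param xlim,ylim scan window; defaults bracket all term centres.
#' @return data.frame with `x`, `y`, `value`, `type`
#'   (minimum/saddle/maximum).
#' @export
locate_critical_points <- function(pot, grid_resolution = 0.05,
                                   xlim = NULL, ylim = NULL) {
  pad <- 2.5
  if (is.null(xlim))
    xlim <- range(pot$centers[, 1]) + c(-pad, pad)
  if (is.null(ylim))
    ylim <- range(pot$centers[, 2]) + c(-pad, pad)
  xs <- seq(xlim[1], xlim[2], by = grid_resolution)
  ys <- seq(ylim[1], ylim[2], by = grid_resolution)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  gn <- matrix(NA_real_, length(xs), length(ys))
  for (j in seq_along(ys))
    for (i in seq_along(xs))
      gn[i, j] <- sqrt(sum(pot2d_grad(pot, c(xs[i], ys[j]))^2))
  cand <- list()
  for (i in 2:(length(xs) - 1)) {
    for (j in 2:(length(ys) - 1)) {
      nb <- gn[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (gn[i, j] <= min(nb)) cand[[length(cand) + 1]] <- c(xs[i], ys[j])
    }
  }
  found <- list()
  for (p0 in cand) {
    p <- p0
    ok <- TRUE
    for (it in 1:60) {
      g <- pot2d_grad(pot, p)
      if (sqrt(sum(g^2)) < 1e-11) break
      H <- pot2d_hessian(pot, p)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) { ok <- FALSE; break }
      if (sqrt(sum(step^2)) > 2) step <- step * 2 / sqrt(sum(step^2))
      p <- p - step
      if (p[1] < xlim[1] - 1 || p[1] > xlim[2] + 1 ||
          p[2] < ylim[1] - 1 || p[2] > ylim[2] + 1) { ok <- FALSE; break }
    }
    if (!ok || sqrt(sum(pot2d_grad(pot, p)^2)) > 1e-8) next
    dup <- any(vapply(found, function(q)
      sqrt(sum((q - p)^2)) < 1e-4, logical(1)))
    if (!dup) found[[length(found) + 1]] <- p
  }
  if (length(found) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                      type = character(0)))
  out <- do.call(rbind, lapply(found, function(p) {
    ev <- eigen(pot2d_hessian(pot, p), symmetric = TRUE)$values
    type <- if (all(ev > 0)) "minimum"
            else if (all(ev < 0)) "maximum" else "saddle"
    data.frame(x = p[1], y = p[2], value = pot2d_value(pot, p), type = type)
  }))
  out[order(out$value), ]
}

#' @export
print.ToyPotential2D <- function(x, ...) {
  cat("ToyPotential2D:", length(x$amps), "Gaussian terms, kconf =",
      x$kconf, "\n")
  invisible(x)
}

# Engine representation: single particle, 2D terms + z confinement.
as_engine_model.ToyPotential2D <- function(x, ...) {
  m <- list(
    natoms = 1L,
    p2_amps = x$amps,
    p2_centers = x$centers,
    p2_precs = do.call(rbind, lapply(x$precs, function(P)
      c(P[1, 1], P[1, 2], P[2, 1], P[2, 2]))),
    p2_kconf = x$kconf,
    p2_kz = 10,
    p2_conf_center = x$conf_center)
  attr(m, "atoms") <- data.frame(atom_name = "P", residue_name = "PRT",
                                 residue_index = 1L, chain_id = "A",
                                 element = "P", stringsAsFactors = FALSE)
  attr(m, "mass") <- 12
  m
}

#' Convert a model object to its dynamics-engine representation
#' @param x a model object ([toy_potential_2d()], [build_toy_loop()], ...).
#' @param ... passed to methods.
#' @return Engine term list (internal format).
#' @export
as_engine_model <- function(x, ...) UseMethod("as_engine_model")

#' @export
as_engine_model.default <- function(x, ...) x
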