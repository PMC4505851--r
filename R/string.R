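# String-method pathway refinement: images sampled under Cartesian-harmonic
# restraints with Hamiltonian replica exchange between neighbours, path
# updates by averaging + piecewise smoothing-spline curve fitting +
# even-arc-length reparametrisation, and free-energy profiles by
# integrating the tangent projection of the mean forces.

#' Create a StringPath
#'
#' @param images ordered list of n_rep x 3 reference coordinate matrices
#'   (representative atoms), first and last being the fixed endpoints.
#' @param k per-atom spring constant of the image restraints
#'   (kcal/mol/A^2).
#' @param sel indices of the representative atoms within the full system
#'   (default: the images cover all model atoms).
#' @param alignment_reference optional n_rep x 3 common reference frame;
#'   image means are superposed onto it before curve fitting.
#' @param endpoints_fixed keep images 1 and n pinned during updates.
#' @return An object of class `StringPath`.
#' @export
string_path <- function(images, k = 2, sel = NULL,
                        alignment_reference = NULL,
                        endpoints_fixed = TRUE) {
  stopifnot(length(images) >= 2)
  images <- lapply(images, as.matrix)
  n <- nrow(images[[1]])
  for (im in images) stopifnot(nrow(im) == n, ncol(im) == 3)
  structure(list(images = images, k = k,
                 sel = if (is.null(sel)) seq_len(n) else
                   resolve_indices(sel),
                 alignment_reference = alignment_reference,
                 endpoints_fixed = endpoints_fixed),
            class = "StringPath")
}

#' @export
print.StringPath <- function(x, ...) {
  s <- path_arc_lengths(x)
  cat("StringPath:", length(x$images), "images,", nrow(x$images[[1]]),
      "representative atoms, k =", x$k, "kcal/mol/A^2, length",
      sprintf("%.3f A\n", s[length(s)]))
  invisible(x)
}

#' Cumulative arc length along a path's images
#' @param path a [string_path()].
#' @return Numeric vector (first element 0), Angstrom (Frobenius distance
#'   between consecutive images).
#' @export
path_arc_lengths <- function(path) {
  m <- length(path$images)
  d <- vapply(seq_len(m - 1), function(i)
    sqrt(sum((path$images[[i + 1]] - path$images[[i]])^2)), numeric(1))
  c(0, cumsum(d))
}

#' Initialise a path by linear interpolation between two endpoints
#'
#' Endpoint B is first superposed onto endpoint A (Kabsch) so the
#' interpolation does not encode rigid-body motion; images are then evenly
#' spaced linear combinations with exact endpoints.
#'
#' @param endpoint_a,endpoint_b n_rep x 3 matrices (or [conformation()]s).
#' @param n_images number of images including the two ends (>= 2).
#' @param k image spring constant.
#' @param sel representative-atom indices within the full system.
#' @param align superpose b onto a first (default TRUE).
#' @return A [string_path()] with `alignment_reference = endpoint_a`.
#' @export
init_path_linear <- function(endpoint_a, endpoint_b, n_images, k = 2,
                             sel = NULL, align = TRUE) {
  xa <- if (inherits(endpoint_a, "Conformation")) endpoint_a$xyz
        else as.matrix(endpoint_a)
  xb <- if (inherits(endpoint_b, "Conformation")) endpoint_b$xyz
        else as.matrix(endpoint_b)
  if (align) xb <- kabsch_superpose(xb, xa)$xyz_fit
  ts <- seq(0, 1, length.out = n_images)
  images <- lapply(ts, function(t) (1 - t) * xa + t * xb)
  images[[1]] <- xa
  images[[n_images]] <- xb
  string_path(images, k = k, sel = sel, alignment_reference = xa)
}

#' Pick starting coordinates for each image from a driven trajectory
#'
#' For each image, the trajectory frame whose representative atoms have the
#' smallest RMSD (after superposition onto the path's alignment reference,
#' when one is set) is taken as that image's starting coordinates; ties go
#' to the earliest frame.
#'
#' @param traj a [trajectory()] (full-system frames).
#' @param path a [string_path()].
#' @return List with `frame_indices` and `coords` (full-system starting
#'   coordinates per image).
#' @export
init_images_from_trajectory <- function(traj, path) {
  if (length(traj$frames) == 0) stop("empty trajectory")
  sel <- path$sel
  ref_frame <- path$alignment_reference
  rep_list <- lapply(traj$frames, function(fr) {
    x <- fr[sel, , drop = FALSE]
    if (!is.null(ref_frame)) kabsch_superpose(x, ref_frame)$xyz_fit else x
  })
  m <- length(path$images)
  frame_indices <- integer(m)
  for (i in seq_len(m)) {
    d <- vapply(rep_list, function(x)
      sqrt(mean(rowSums((x - path$images[[i]])^2))), numeric(1))
    frame_indices[i] <- which(d <= min(d) + 1e-12)[1]
  }
  coords <- lapply(frame_indices, function(f) {
    fr <- traj$frames[[f]]
    if (!is.null(ref_frame)) {
      fit <- kabsch_superpose(fr[sel, , drop = FALSE], ref_frame)
      cm <- colMeans(fr[sel, , drop = FALSE])
      sweep(sweep(fr, 2, cm) %*% t(fit$rotation), 2,
            colMeans(ref_frame), FUN = "+")
    } else fr
  })
  list(frame_indices = frame_indices, coords = coords)
}

#' Sample all images with Hamiltonian replica exchange
#'
#' Each image is sampled under its Cartesian-harmonic restraint.  After
#' every sweep of `steps_per_sweep` dynamics steps, adjacent image pairs
#' (alternating odd/even sweeps) attempt a configuration swap accepted with
#' the Metropolis probability min(1, exp(-beta * Delta)), where Delta =
#' (U_i(x_j) + U_j(x_i)) - (U_i(x_i) + U_j(x_j)) involves only the two
#' image restraint energies.  All randomness derives from `group_seed`.
#'
#' @param model a model object.
#' @param path a [string_path()].
#' @param config list: `steps_per_sweep`, `n_sweeps`, `equil_sweeps`
#'   (sweeps discarded from the averages), `params` (a
#'   [langevin_params()]), optional `freeze` (no dynamics; configurations
#'   only move by exchange — used for closed-form acceptance checks),
#'   optional `record_snapshots` (keep the per-sweep end configurations of
#'   every image, for occupancy checks).
#' @param group_seed integer seed for this sampling group.
#' @param states0 optional list of per-image starting states (each a list
#'   with `coords` and optional `vel`); default: the image references
#'   themselves (full-system coordinates required when the model has atoms
#'   outside the path selection).
#' @return List: `mean_positions` (per image, representative atoms),
#'   `mean_forces` (k * (mean - ref)), `var_mean` (per-coordinate variance
#'   of the mean from sweep-block scatter), `exchange` (per-pair attempt /
#'   acceptance counts), `states`, `block_means`.
#' @export
sample_images_with_exchange <- function(model, path, config, group_seed,
                                        states0 = NULL) {
  em <- as_engine_model(model)
  natoms <- em$natoms
  sel <- path$sel
  m <- length(path$images)
  p <- config$params
  beta <- 1 / (KB_KCAL * p$temperature)
  freeze <- isTRUE(config$freeze)
  n_sweeps <- config$n_sweeps
  equil_sweeps <- if (is.null(config$equil_sweeps))
    ceiling(0.2 * n_sweeps) else config$equil_sweeps
  mass <- model_masses(model, natoms)

  states <- vector("list", m)
  for (i in seq_len(m)) {
    if (!is.null(states0)) {
      states[[i]] <- states0[[i]]
      if (is.null(states[[i]]$vel)) states[[i]]$vel <- NULL
    } else {
      if (length(sel) != natoms)
        stop("states0 required: path selection does not cover the model")
      states[[i]] <- list(coords = path$images[[i]], vel = NULL)
    }
  }
  restr <- lapply(seq_len(m), function(i)
    list(kind = 1L, sel = sel, k = path$k, ref = path$images[[i]]))
  u_img <- function(i, coords)
    0.5 * path$k * sum((coords[sel, , drop = FALSE] -
                        path$images[[i]])^2)

  attempts <- integer(m - 1)
  accepts <- integer(m - 1)
  block_means <- lapply(seq_len(m), function(i) list())
  record <- isTRUE(config$record_snapshots)
  snapshots <- if (record) lapply(seq_len(m), function(i) list()) else NULL
  set.seed(as.integer(group_seed))
  for (sweep in seq_len(n_sweeps)) {
    for (i in seq_len(m)) {
      if (!freeze && config$steps_per_sweep > 0) {
        out <- cpp_run(em, states[[i]]$coords,
                       if (is.null(states[[i]]$vel)) NULL else
                         states[[i]]$vel,
                       list(restr[[i]]), mass, p$temperature, p$friction,
                       p$timestep, as.integer(config$steps_per_sweep),
                       0, 0L, as.integer(sel), 0L)
        states[[i]] <- list(coords = out$coords, vel = out$vel)
        cm <- out$mean_pos
      } else {
        cm <- states[[i]]$coords[sel, , drop = FALSE]
      }
      if (sweep > equil_sweeps) {
        block_means[[i]][[length(block_means[[i]]) + 1]] <- cm
        if (record)
          snapshots[[i]][[length(snapshots[[i]]) + 1]] <-
            states[[i]]$coords[sel, , drop = FALSE]
      }
    }
    first <- if (sweep %% 2 == 1) 1L else 2L
    pair_starts <- if (first <= m - 1) seq(first, m - 1, by = 2) else
      integer(0)
    for (i in pair_starts) {
      j <- i + 1L
      delta <- u_img(i, states[[j]]$coords) + u_img(j, states[[i]]$coords) -
        u_img(i, states[[i]]$coords) - u_img(j, states[[j]]$coords)
      attempts[i] <- attempts[i] + 1L
      if (runif(1) < exp(-beta * delta)) {
        accepts[i] <- accepts[i] + 1L
        tmp <- states[[i]]; states[[i]] <- states[[j]]; states[[j]] <- tmp
      }
    }
  }
  mean_positions <- vector("list", m)
  var_mean <- vector("list", m)
  for (i in seq_len(m)) {
    bm <- block_means[[i]]
    nb <- length(bm)
    arr <- array(unlist(bm), dim = c(length(sel), 3, nb))
    mu <- apply(arr, c(1, 2), mean)
    mean_positions[[i]] <- mu
    var_mean[[i]] <- if (nb > 1)
      apply(arr, c(1, 2), stats::var) / nb else mu * 0
  }
  mean_forces <- lapply(seq_len(m), function(i)
    path$k * (mean_positions[[i]] - path$images[[i]]))
  list(mean_positions = mean_positions, mean_forces = mean_forces,
       var_mean = var_mean,
       exchange = data.frame(pair = paste(seq_len(m - 1), 2:m, sep = "-"),
                             attempts = attempts, accepts = accepts,
                             rate = ifelse(attempts > 0,
                                           accepts / attempts, NA)),
       states = states, block_means = block_means,
       snapshots = snapshots)
}

#' Average the image means of two sampling groups
#' @param means_a,means_b per-image mean position lists.
#' @return Per-image pooled means.
#' @export
pool_group_means <- function(means_a, means_b) {
  stopifnot(length(means_a) == length(means_b))
  lapply(seq_along(means_a), function(i) (means_a[[i]] + means_b[[i]]) / 2)
}

#' Update a path through its sampled image means
#'
#' (1) superpose the means onto the alignment reference, (2) fit one cubic
#' smoothing spline per Cartesian coordinate against a chordal parameter
#' for each section between consecutive `minima_breaks` (direction kinks
#' allowed only there), with the whole-path endpoints pinned to the input
#' endpoint conformations, (3) re-sample `n_images_out` images at even arc
#' length along the fitted curve.
#'
#' @param mean_positions per-image mean representative-atom coordinates
#'   (pool the groups first, e.g. with [pool_group_means()]).
#' @param path the current [string_path()].
#' @param minima_breaks strictly increasing interior image indices at which
#'   the curve may kink (free-energy minima between partial transitions).
#' @param df_frac smoothing-spline flexibility: degrees of freedom as a
#'   fraction of the points in each section.
#' @param n_images_out number of images in the updated path (default:
#'   unchanged).
#' @param k_out spring constant of the updated path (default: unchanged).
#' @return The refined [string_path()].
#' @export
update_path <- function(mean_positions, path, minima_breaks = integer(0),
                        df_frac = 0.6, n_images_out = NULL, k_out = NULL) {
  m <- length(path$images)
  stopifnot(length(mean_positions) == m)
  if (length(minima_breaks) > 0) {
    if (is.unsorted(minima_breaks, strictly = TRUE) ||
        any(minima_breaks <= 1) || any(minima_breaks >= m))
      stop("breaks out of order (need strictly increasing interior indices)")
  }
  means <- lapply(mean_positions, as.matrix)
  if (!is.null(path$alignment_reference)) {
    means <- lapply(means, function(x)
      kabsch_superpose(x, path$alignment_reference)$xyz_fit)
  }
  if (path$endpoints_fixed) {
    means[[1]] <- path$images[[1]]
    means[[m]] <- path$images[[m]]
  }
  Y <- t(vapply(means, as.vector, numeric(length(means[[1]]))))  # m x 3n
  chord <- sqrt(rowSums((Y[-1, , drop = FALSE] -
                         Y[-m, , drop = FALSE])^2))
  u <- c(0, cumsum(chord))
  u <- u / max(u[m], 1e-12)
  bounds <- c(1, minima_breaks, m)
  dense <- list()
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    npts <- b - a + 1
    useg <- u[a:b]
    ufine <- seq(useg[1], useg[npts], length.out = max(20 * (npts - 1), 2))
    seg <- matrix(0, length(ufine), ncol(Y))
    w <- rep(1, npts)
    if (a == 1) w[1] <- 1e4
    if (b == m) w[npts] <- 1e4
    for (cc in seq_len(ncol(Y))) {
      yy <- Y[a:b, cc]
      if (npts >= 5 && diff(range(useg)) > 1e-10) {
        df <- max(4, min(npts - 1, ceiling(df_frac * npts)))
        fit <- smooth.spline(useg, yy, w = w, df = df, cv = FALSE,
                             all.knots = TRUE)
        seg[, cc] <- predict(fit, ufine)$y
      } else if (npts >= 2 && diff(range(useg)) > 1e-10) {
        seg[, cc] <- approx(useg, yy, xout = ufine)$y
      } else {
        seg[, cc] <- yy[1]
      }
    }
    dense[[s]] <- if (s == 1) seg else seg[-1, , drop = FALSE]
  }
  curve <- do.call(rbind, dense)
  darc <- sqrt(rowSums((curve[-1, , drop = FALSE] -
                        curve[-nrow(curve), , drop = FALSE])^2))
  arc <- c(0, cumsum(darc))
  n_out <- if (is.null(n_images_out)) m else n_images_out
  s_targets <- seq(0, arc[length(arc)], length.out = n_out)
  new_images <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    krow <- findInterval(s_targets[i], arc, rightmost.closed = TRUE)
    krow <- min(max(krow, 1), nrow(curve) - 1)
    f <- (s_targets[i] - arc[krow]) / max(arc[krow + 1] - arc[krow], 1e-12)
    v <- (1 - f) * curve[krow, ] + f * curve[krow + 1, ]
    new_images[[i]] <- matrix(v, ncol = 3)
  }
  if (path$endpoints_fixed) {
    new_images[[1]] <- path$images[[1]]
    new_images[[n_out]] <- path$images[[m]]
  }
  string_path(new_images, k = if (is.null(k_out)) path$k else k_out,
              sel = path$sel,
              alignment_reference = path$alignment_reference,
              endpoints_fixed = path$endpoints_fixed)
}

#' Free-energy profile by mean-force integration
#'
#' The mean system force on image i is estimated by the restraint balance
#' k (<x>_i - x_i^ref); its projection on the unit path tangent (central
#' differences, one-sided at the ends) is integrated over arc length by the
#' trapezoidal rule, anchored to zero at the first image.
#'
#' @param mean_positions per-image mean representative-atom coordinates.
#' @param path the sampled [string_path()].
#' @param var_mean optional per-image per-coordinate variances of the means
#'   (as returned by [sample_images_with_exchange()]) for error bars.
#' @param group label stored in the profile.
#' @return A data.frame of class `FreeEnergyProfile`: `image`,
#'   `arc_length` (A), `free_energy` (kcal/mol, starts at 0), `se`,
#'   `group`.
#' @export
integrate_mean_forces <- function(mean_positions, path, var_mean = NULL,
                                  group = 1L) {
  m <- length(path$images)
  refs <- lapply(path$images, as.vector)
  mus <- lapply(mean_positions, as.vector)
  arc <- path_arc_lengths(path)
  tangents <- vector("list", m)
  for (i in seq_len(m)) {
    lo <- max(1, i - 1); hi <- min(m, i + 1)
    tv <- unlist(refs[[hi]]) - unlist(refs[[lo]])
    tangents[[i]] <- tv / sqrt(sum(tv^2))
  }
  dGds <- vapply(seq_len(m), function(i) {
    f <- path$k * (mus[[i]] - refs[[i]])
    -sum(f * tangents[[i]])
  }, numeric(1))
  G <- c(0, cumsum(diff(arc) * (head(dGds, -1) + tail(dGds, -1)) / 2))
  se <- rep(NA_real_, m)
  if (!is.null(var_mean)) {
    var_dGds <- vapply(seq_len(m), function(i)
      path$k^2 * sum(tangents[[i]]^2 * as.vector(var_mean[[i]])),
      numeric(1))
    varG <- c(0, cumsum((diff(arc) / 2)^2 *
                        (head(var_dGds, -1) + tail(var_dGds, -1))))
    se <- sqrt(varG)
  }
  out <- data.frame(image = seq_len(m), arc_length = arc,
                    free_energy = G, se = se, group = group)
  class(out) <- c("FreeEnergyProfile", "data.frame")
  out
}

#' Interior free-energy minima with a prominence threshold
#'
#' Finds the metastable intermediate states that divide a pathway into
#' partial transitions: interior local minima whose depth relative to the
#' lower of the two flanking maxima is at least `min_depth`.
#'
#' @param profile a [integrate_mean_forces()] profile (or numeric vector).
#' @param min_depth minimum prominence (kcal/mol).
#' @return Sorted integer image indices (possibly empty).
#' @export
detect_metastable_states <- function(profile, min_depth) {
  G <- if (is.data.frame(profile)) profile$free_energy else
    as.numeric(profile)
  m <- length(G)
  if (m < 3) stop("profile must have at least 3 images")
  out <- integer(0)
  for (i in 2:(m - 1)) {
    if (G[i] <= G[i - 1] && G[i] <= G[i + 1] &&
        (G[i] < G[i - 1] || G[i] < G[i + 1])) {
      left <- max(G[1:i]) - G[i]
      right <- max(G[i:m]) - G[i]
      if (min(left, right) >= min_depth) out <- c(out, i)
    }
  }
  sort(out)
}

#' Iterative string-method refinement with two independent groups
#'
#' Runs `n_iterations` of sample-and-update, with two sampling groups
#' started from different coordinates but confined to the common path; each
#' update pools the means of both groups.  A final (typically longer)
#' sampling pass produces one free-energy profile per group — their
#' agreement is the convergence/hysteresis check.
#'
#' @param model a model object.
#' @param path0 the initial [string_path()].
#' @param config list: `n_iterations` (default 5), `sampling` (config for
#'   [sample_images_with_exchange()]), `final_sampling` (default: the
#'   sampling config), `seeds` (length 2, one per group),
#'   `breaks_min_depth` (enable piecewise fitting at detected metastable
#'   minima; NULL = single smooth curve), `df_frac`, `n_images_final`,
#'   `k_final`.
#' @param states0_a,states0_b optional per-image starting states for the
#'   two groups (e.g. from [init_images_from_trajectory()] on the two
#'   opposite-direction driven trajectories).
#' @return List: `path`, `profiles` (list of two `FreeEnergyProfile`s),
#'   `displacement` (per-iteration mean image displacement), `exchange`,
#'   `means` (per group), `converged`.
#' @export
refine <- function(model, path0, config, states0_a = NULL,
                   states0_b = NULL) {
  n_iter <- if (is.null(config$n_iterations)) 5L else config$n_iterations
  seeds <- if (is.null(config$seeds)) c(101L, 202L) else config$seeds
  df_frac <- if (is.null(config$df_frac)) 0.6 else config$df_frac
  path <- path0
  st <- list(a = states0_a, b = states0_b)
  disp <- numeric(0)
  last_exchange <- NULL
  for (iter in seq_len(n_iter)) {
    res_a <- sample_images_with_exchange(model, path, config$sampling,
                                         seeds[1] + 1000L * iter, st$a)
    res_b <- sample_images_with_exchange(model, path, config$sampling,
                                         seeds[2] + 1000L * iter, st$b)
    st <- list(a = res_a$states, b = res_b$states)
    pooled <- pool_group_means(res_a$mean_positions, res_b$mean_positions)
    breaks <- integer(0)
    if (!is.null(config$breaks_min_depth)) {
      prof <- integrate_mean_forces(pooled, path)
      breaks <- detect_metastable_states(prof, config$breaks_min_depth)
    }
    newpath <- update_path(pooled, path, minima_breaks = breaks,
                           df_frac = df_frac)
    disp[iter] <- mean(vapply(seq_along(path$images), function(i)
      sqrt(mean(rowSums((newpath$images[[i]] - path$images[[i]])^2))),
      numeric(1)))
    path <- newpath
    last_exchange <- res_a$exchange
  }
  converged <- TRUE
  if (n_iter >= 4) {
    last3 <- tail(disp, 3)
    if (all(diff(last3) >= 0)) {
      converged <- FALSE
      warning("path displacement not decreasing over the last 3 ",
              "iterations; refinement may not be converged")
    }
  }
  # final profile pass (optionally more images / stiffer springs)
  if (!is.null(config$n_images_final) &&
      config$n_images_final != length(path$images)) {
    old_m <- length(path$images)
    path <- update_path(path$images, path,
                        n_images_out = config$n_images_final,
                        k_out = config$k_final, df_frac = 0.95)
    remap <- function(states) {
      if (is.null(states)) return(NULL)
      lapply(seq_len(config$n_images_final), function(i) {
        frac <- (i - 1) / (config$n_images_final - 1)
        states[[round(frac * (old_m - 1)) + 1]]
      })
    }
    st <- list(a = remap(st$a), b = remap(st$b))
  } else if (!is.null(config$k_final)) {
    path$k <- config$k_final
  }
  fin_cfg <- if (is.null(config$final_sampling)) config$sampling else
    config$final_sampling
  res_a <- sample_images_with_exchange(model, path, fin_cfg,
                                       seeds[1] + 999983L, st$a)
  res_b <- sample_images_with_exchange(model, path, fin_cfg,
                                       seeds[2] + 999983L, st$b)
  profiles <- list(
    integrate_mean_forces(res_a$mean_positions, path, res_a$var_mean,
                          group = 1L),
    integrate_mean_forces(res_b$mean_positions, path, res_b$var_mean,
                          group = 2L))
  list(path = path, profiles = profiles, displacement = disp,
       exchange = res_a$exchange,
       means = list(a = res_a$mean_positions, b = res_b$mean_positions),
       converged = converged)
}
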