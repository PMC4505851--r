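# Toy loop-chain model: a peptide-like chain of N/H/CA/C/O sites per residue
# whose backbone phi/psi terms are bistable (minima 180 degrees apart), with
# one switchable helical H-bond-like contact.  Its two designed endpoint
# states emulate a loop wrapped onto, or unwrapped from, a helix end.

TOY_GEOM <- list(
  b_NH = 1.00, b_NCA = 1.46, b_CAC = 1.52, b_CO = 1.23, b_CN = 1.33,
  a_NCAC = 111, a_CACN = 114, a_CNCA = 123, a_CACO = 121, a_OCN = 125,
  a_CNH = 119, a_HNCA = 118, kb = 100, ka = 40)

#' Build a toy loop-chain model
#'
#' Each residue carries N, H, CA, C, O sites (H omitted for proline-like
#' residues).  Energy terms: harmonic bonds and angles, stiff trans
#' peptide-plane torsions, bistable phi/psi torsions (an n = 2 cosine giving
#' minima at the design target and 180 degrees away, plus a weaker n = 1
#' term deepening the target), a switchable helical contact (attractive
#' Gaussian well between a donor amide H and the acceptor carbonyl O four
#' residues earlier), and bounded soft-core repulsion between atoms more
#' than three bonds apart.  The last helical turn (the five residues ending
#' at the contact donor) has helical phi/psi targets; the rest are extended.
#'
#' @param n_residues number of residues, >= 5.
#' @param proline_like residue indices built without an amide H.
#' @param seed integer; draws a small deterministic jitter (+-4 degrees) on
#'   the phi/psi targets so different seeds give distinct but reproducible
#'   models.
#' @param contact_donor_res residue donating the contact H (default
#'   `n_residues - 1`); the acceptor O sits four residues earlier.
#' @param temperature reference temperature (K) stored with the model.
#' @return An object of class `ToyLoopModel`.
#' @export
build_toy_loop <- function(n_residues, proline_like = integer(0), seed = 1,
                           contact_donor_res = n_residues - 1,
                           temperature = 300) {
  if (n_residues < 5) stop("need at least 5 residues")
  if (contact_donor_res - 4 < 1 || contact_donor_res > n_residues)
    stop("contact donor residue out of range")
  if (contact_donor_res %in% proline_like)
    stop("contact donor cannot be proline-like (it has no amide H)")
  set.seed(as.integer(seed))
  g <- TOY_GEOM
  helix <- seq(contact_donor_res - 4, contact_donor_res)
  phi0 <- ifelse(seq_len(n_residues) %in% helix, -57, -120) +
    runif(n_residues, -4, 4)
  psi0 <- ifelse(seq_len(n_residues) %in% helix, -47, 130) +
    runif(n_residues, -4, 4)

  atoms <- list()
  for (r in seq_len(n_residues)) {
    nm <- c("N", if (!(r %in% proline_like)) "H", "CA", "C", "O")
    atoms[[r]] <- data.frame(
      atom_name = nm,
      residue_name = if (r %in% proline_like) "PRO" else "GLY",
      residue_index = r, chain_id = "A",
      element = substr(nm, 1, 1), stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  idx <- function(r, nm) {
    i <- which(atoms$residue_index == r & atoms$atom_name == nm)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  has_h <- function(r) !is.na(idx(r, "H"))

  bonds <- list(); angles <- list(); torsions <- list()
  deg <- pi / 180
  bnd <- function(i, j, r0) bonds[[length(bonds) + 1]] <<- c(i, j, r0, g$kb)
  ang <- function(i, j, k, th) angles[[length(angles) + 1]] <<-
      c(i, j, k, th * deg, g$ka)
  tor <- function(i, j, k, l, n, kt, p0) torsions[[length(torsions) + 1]] <<-
      c(i, j, k, l, n, kt, p0 * deg)

  # n = 2 amplitude: with the bias terms below the rotation barrier is
  # ~8 kcal/mol, chosen so that an unbiased run is overwhelmingly unlikely
  # to flip spontaneously over the tens-of-ps observation windows used
  # here (rate ~ nu exp(-dU/kT): ~2e-5/ps per torsion at 300 K) while a
  # driven run crosses easily
  k_flip <- 4.0
  k_bias <- 0.6   # n = 1 amplitude: deepens the design target
  # n = 1 term centred 90 deg past the target: leaves both minima equally
  # deep but raises one rotation direction's saddle by ~2*k_dir, so the
  # designed flip pathway has a knowable, non-degenerate barrier ordering
  # (a +180 and a -180 rotation would otherwise be exactly equivalent)
  k_dir <- 0.75
  for (r in seq_len(n_residues)) {
    N <- idx(r, "N"); CA <- idx(r, "CA"); C <- idx(r, "C"); O <- idx(r, "O")
    bnd(N, CA, g$b_NCA); bnd(CA, C, g$b_CAC); bnd(C, O, g$b_CO)
    ang(N, CA, C, g$a_NCAC); ang(CA, C, O, g$a_CACO)
    if (has_h(r)) {
      H <- idx(r, "H")
      bnd(N, H, g$b_NH)
      ang(H, N, CA, g$a_HNCA)
    }
    if (r < n_residues) {
      N2 <- idx(r + 1, "N"); CA2 <- idx(r + 1, "CA")
      bnd(C, N2, g$b_CN)
      ang(CA, C, N2, g$a_CACN); ang(O, C, N2, g$a_OCN)
      ang(C, N2, CA2, g$a_CNCA)
      # psi (bistable) and omega / peptide-plane torsions
      tor(N, CA, C, N2, 2, k_flip, psi0[r])
      tor(N, CA, C, N2, 1, k_bias, psi0[r])
      tor(N, CA, C, N2, 1, k_dir, psi0[r] + 90)
      tor(CA, C, N2, CA2, 1, 8, 180)
      tor(O, C, N2, CA2, 1, 4, 0)
      if (has_h(r + 1)) {
        H2 <- idx(r + 1, "H")
        ang(C, N2, H2, g$a_CNH)
        tor(CA, C, N2, H2, 1, 4, 0)
      }
    } else {
      tor(N, CA, C, O, 1, 2, psi0[r] + 180)  # pin the terminal carbonyl
    }
    if (r > 1) {
      Cp <- idx(r - 1, "C")
      tor(Cp, N, CA, C, 2, k_flip, phi0[r])
      tor(Cp, N, CA, C, 1, k_bias, phi0[r])
      tor(Cp, N, CA, C, 1, k_dir, phi0[r] + 90)
    } else if (has_h(1)) {
      tor(idx(1, "H"), N, CA, C, 1, 2, phi0[1] + 180)
    }
  }
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles)
  torsions <- do.call(rbind, torsions)

  don <- idx(contact_donor_res, "H")
  acc <- idx(contact_donor_res - 4, "O")
  contacts <- matrix(c(don, acc, 3.0, 2.0, 0.35), nrow = 1)

  # repulsion between atoms more than 3 bonds apart (graph distance)
  nat <- nrow(atoms)
  dist <- matrix(Inf, nat, nat)
  diag(dist) <- 0
  for (b in seq_len(nrow(bonds))) {
    dist[bonds[b, 1], bonds[b, 2]] <- 1
    dist[bonds[b, 2], bonds[b, 1]] <- 1
  }
  for (k in seq_len(nat))  # Floyd-Warshall; nat <= ~100 so this is cheap
    dist <- pmin(dist, outer(dist[, k], dist[k, ], "+"))
  rp <- which(upper.tri(dist) & dist >= 4, arr.ind = TRUE)
  drop <- (rp[, 1] == don & rp[, 2] == acc) |
          (rp[, 1] == acc & rp[, 2] == don)
  rep_pairs <- unname(rp[!drop, , drop = FALSE])

  model <- structure(list(
    n_residues = n_residues, proline_like = proline_like, seed = seed,
    atoms = atoms, targets = data.frame(residue_index = seq_len(n_residues),
                                        phi0 = phi0, psi0 = psi0),
    bonds = bonds, angles = angles, torsions = torsions,
    contacts = contacts,
    contact = list(donor_res = contact_donor_res,
                   acceptor_res = contact_donor_res - 4,
                   donor_idx = don, acceptor_idx = acc),
    rep_pairs = rep_pairs, rep_eps = 10, rep_rc = 2.5,
    temperature = temperature), class = "ToyLoopModel")
  model$coords_ideal <- toy_ideal_coords(model)
  model
}

#' @export
print.ToyLoopModel <- function(x, ...) {
  cat("ToyLoopModel:", x$n_residues, "residues,", nrow(x$atoms), "sites,",
      "contact", x$contact$acceptor_res, "O ...", x$contact$donor_res,
      "H\n")
  invisible(x)
}

# engine matrices carry 0-based atom indices; R objects stay 1-based
zero_index <- function(mat, cols) {
  if (is.null(mat) || nrow(mat) == 0) return(mat)
  for (c in cols) mat[, c] <- ifelse(mat[, c] >= 1, mat[, c] - 1, mat[, c])
  mat
}

#' @export
as_engine_model.ToyLoopModel <- function(x, ..., contact_scale = 1) {
  m <- list(natoms = nrow(x$atoms),
            bonds = zero_index(x$bonds, 1:2),
            angles = zero_index(x$angles, 1:3),
            torsions = zero_index(x$torsions, 1:4),
            contacts = zero_index(x$contacts, 1:2),
            rep_pairs = zero_index(x$rep_pairs, 1:2),
            rep_eps = x$rep_eps,
            rep_rc = x$rep_rc, contact_scale = contact_scale)
  attr(m, "atoms") <- x$atoms
  attr(m, "mass") <- rep(12, nrow(x$atoms))
  m
}

# NeRF internal-coordinate placement: new atom bonded to c, with bond
# length, angle a(b, c, new) and dihedral (a, b, c, new).
place_next <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal-geometry coordinates at the model's design targets (state A shape).
toy_ideal_coords <- function(model) {
  g <- TOY_GEOM
  at <- model$atoms
  n <- model$n_residues
  phi0 <- model$targets$phi0
  psi0 <- model$targets$psi0
  xyz <- matrix(NA_real_, nrow(at), 3)
  idx <- function(r, nm) {
    i <- which(at$residue_index == r & at$atom_name == nm)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  set1 <- function(i, p) if (!is.na(i)) xyz[i, ] <<- p
  set1(idx(1, "N"), c(0, 0, 0))
  set1(idx(1, "CA"), c(g$b_NCA, 0, 0))
  aN <- g$a_NCAC * pi / 180
  set1(idx(1, "C"), xyz[idx(1, "CA"), ] +
         g$b_CAC * c(cos(pi - aN), sin(pi - aN), 0))
  for (r in seq_len(n)) {
    N <- idx(r, "N"); CA <- idx(r, "CA"); C <- idx(r, "C")
    if (r == 1 && !is.na(idx(1, "H")))
      set1(idx(1, "H"), place_next(xyz[C, ], xyz[CA, ], xyz[N, ], g$b_NH,
                                   g$a_HNCA, wrap180(phi0[1] + 180)))
    set1(idx(r, "O"), place_next(xyz[N, ], xyz[CA, ], xyz[C, ], g$b_CO,
                                 g$a_CACO, wrap180(psi0[r] + 180)))
    if (r < n) {
      N2 <- idx(r + 1, "N"); CA2 <- idx(r + 1, "CA")
      set1(N2, place_next(xyz[N, ], xyz[CA, ], xyz[C, ], g$b_CN,
                          g$a_CACN, psi0[r]))
      set1(CA2, place_next(xyz[CA, ], xyz[C, ], xyz[N2, ], g$b_NCA,
                           g$a_CNCA, 180))
      if (!is.na(idx(r + 1, "H")))
        set1(idx(r + 1, "H"), place_next(xyz[CA, ], xyz[C, ], xyz[N2, ],
                                         g$b_NH, g$a_CNH, 0))
      set1(idx(r + 1, "C"), place_next(xyz[C, ], xyz[N2, ], xyz[CA2, ],
                                       g$b_CAC, g$a_NCAC, phi0[r + 1]))
    }
  }
  xyz
}

#' Toy-model potential energy and analytic forces
#' @param model a [build_toy_loop()] model (or any engine model).
#' @param xyz n x 3 coordinate matrix (or a [conformation()]).
#' @param contact_scale scale factor on the switchable contact (0 = off).
#' @return List with `energy` (kcal/mol) and `forces` (kcal/mol/A).
#' @export
toy_energy_forces <- function(model, xyz, contact_scale = 1) {
  if (inherits(xyz, "Conformation")) xyz <- xyz$xyz
  em <- if (inherits(model, "ToyLoopModel"))
    as_engine_model(model, contact_scale = contact_scale)
  else as_engine_model(model)
  out <- cpp_energy_forces(em, xyz, list(), 0)
  list(energy = out$U_model, forces = out$forces_model)
}

# L-BFGS minimisation of an engine model; returns coords + convergence info.
minimize_coords <- function(engine_model, xyz, max_restarts = 6,
                            maxit = 4000, gtol = 1e-3) {
  x <- as.vector(xyz)
  fn <- function(v) cpp_energy_forces(engine_model,
                                      matrix(v, ncol = 3), list(), 0)$U_model
  gr <- function(v) -as.vector(cpp_energy_forces(
    engine_model, matrix(v, ncol = 3), list(), 0)$forces)
  gmax <- Inf
  for (r in seq_len(max_restarts)) {
    res <- optim(x, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 10, pgtol = 1e-9))
    x <- res$par
    G <- matrix(gr(x), ncol = 3)
    gmax <- max(sqrt(rowSums(G^2)))
    if (gmax < gtol) break
  }
  list(xyz = matrix(x, ncol = 3), energy = fn(x), grad_max = gmax,
       converged = gmax < gtol)
}

# Rotate a backbone torsion of residue `res` by delta degrees, moving the
# downstream atoms (the carbonyl O travels with its peptide plane).
rotate_torsion <- function(model, xyz, res, torsion = c("phi", "psi"),
                           delta) {
  torsion <- match.arg(torsion)
  at <- model$atoms
  idx <- function(r, nm) which(at$residue_index == r & at$atom_name == nm)[1]
  if (torsion == "phi") {
    p1 <- xyz[idx(res, "N"), ]; p2 <- xyz[idx(res, "CA"), ]
    movers <- c(idx(res, "C"), idx(res, "O"),
                which(at$residue_index > res))
  } else {
    p1 <- xyz[idx(res, "CA"), ]; p2 <- xyz[idx(res, "C"), ]
    movers <- c(idx(res, "O"), which(at$residue_index > res))
  }
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  a <- delta * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  xyz[movers, ] <- sweep(sweep(xyz[movers, , drop = FALSE], 2, p2) %*% t(R),
                         2, p2, FUN = "+")
  xyz
}

# phi or psi of one residue from coordinates
toy_torsion <- function(model, xyz, res, torsion = c("phi", "psi")) {
  torsion <- match.arg(torsion)
  at <- model$atoms
  idx <- function(r, nm) which(at$residue_index == r & at$atom_name == nm)[1]
  if (torsion == "phi") {
    if (res == 1) return(NA_real_)
    dihedral(xyz[idx(res - 1, "C"), ], xyz[idx(res, "N"), ],
             xyz[idx(res, "CA"), ], xyz[idx(res, "C"), ])
  } else {
    if (res == model$n_residues) return(NA_real_)
    dihedral(xyz[idx(res, "N"), ], xyz[idx(res, "CA"), ],
             xyz[idx(res, "C"), ], xyz[idx(res + 1, "N"), ])
  }
}

#' Generate the wrapped/unwrapped endpoint pair of a toy loop
#'
#' State A ("wrapped") is minimised from the model's design geometry with
#' the helical contact engaged.  State B ("unwrapped") starts from state A
#' with the listed torsions rotated by their deltas and the contact
#' released, is minimised, then polished under the full model so that both
#' states are genuine local minima of the same energy (max per-atom
#' gradient below `gtol`).  State B is finally superposed onto state A.
#'
#' @param model a [build_toy_loop()] model.
#' @param flips data.frame (or list of `c(residue, torsion, delta)`) with
#'   columns `residue`, `torsion` ("phi"/"psi"), `delta` (degrees,
#'   `abs(delta) <= 180`).
#' @param gtol convergence threshold on the max per-atom gradient norm
#'   (kcal/mol/A).
#' @return An object of class `EndpointPair`: `state_a`, `state_b`
#'   ([conformation()]s), `flipped_torsions`, `energies`, `model`.
#' @export
generate_endpoint_conformations <- function(model, flips, gtol = 1e-3) {
  if (is.data.frame(flips)) {
    fl <- flips
  } else {
    fl <- do.call(rbind, lapply(flips, function(f)
      data.frame(residue = as.integer(f[[1]]), torsion = as.character(f[[2]]),
                 delta = as.numeric(f[[3]]), stringsAsFactors = FALSE)))
    if (is.null(fl))
      fl <- data.frame(residue = integer(0), torsion = character(0),
                       delta = numeric(0))
  }
  if (any(abs(fl$delta) > 180)) stop("flip deltas must satisfy |delta| <= 180")
  if (any(fl$residue < 1 | fl$residue > model$n_residues))
    stop("flip residue out of range")
  em_on <- as_engine_model(model, contact_scale = 1)
  em_off <- as_engine_model(model, contact_scale = 0)

  resA <- minimize_coords(em_on, model$coords_ideal, gtol = gtol)
  if (!resA$converged)
    stop("state A minimisation did not converge: max gradient ",
         signif(resA$grad_max, 3), " kcal/mol/A")
  xa <- resA$xyz

  xb0 <- xa
  for (i in seq_len(nrow(fl)))
    xb0 <- rotate_torsion(model, xb0, fl$residue[i], fl$torsion[i],
                          fl$delta[i])
  resB1 <- minimize_coords(em_off, xb0, gtol = gtol)
  resB <- minimize_coords(em_on, resB1$xyz, gtol = gtol)
  if (!resB$converged)
    stop("state B minimisation did not converge: max gradient ",
         signif(resB$grad_max, 3), " kcal/mol/A")
  xb <- resB$xyz

  # verify prescribed torsion differences
  for (i in seq_len(nrow(fl))) {
    ta <- toy_torsion(model, xa, fl$residue[i], fl$torsion[i])
    tb <- toy_torsion(model, xb, fl$residue[i], fl$torsion[i])
    realized <- angle_deviation(tb, ta + fl$delta[i])
    if (is.na(realized) || realized > 10)
      stop("flip at residue ", fl$residue[i], " (", fl$torsion[i],
           ") realised ", signif(angle_deviation(tb, ta), 3),
           " deg instead of ", fl$delta[i], " deg")
  }
  # superpose B onto A for a common frame
  fit <- kabsch_superpose(xb, xa)
  xb <- fit$xyz_fit
  structure(list(
    state_a = conformation(model$atoms, xa),
    state_b = conformation(model$atoms, xb),
    flipped_torsions = fl,
    energies = c(state_a = resA$energy, state_b = resB$energy),
    model = model), class = "EndpointPair")
}

#' @export
print.EndpointPair <- function(x, ...) {
  cat("EndpointPair:", nrow(x$flipped_torsions), "flipped torsion(s);",
      sprintf("E_A = %.2f, E_B = %.2f kcal/mol\n",
              x$energies[1], x$energies[2]))
  invisible(x)
}

#' Couple a driven toy loop to a follower layer
#'
#' Adds one follower particle per residue, tethered to that residue's CA at
#' a fixed offset.  Followers of `uncoupled_residues` are instead anchored
#' to the residue's state-A CA position, so they cannot follow a driven
#' transition: the deliberate negative control.
#'
#' @param pair an [generate_endpoint_conformations()] EndpointPair.
#' @param coupling_k tether spring constant (kcal/mol/A^2).
#' @param uncoupled_residues residues whose followers are anchored to
#'   state A.
#' @param offset follower offset from the CA (Angstrom).
#' @return An object of class `CoupledLoopSystem` with the merged engine
#'   model, atom table, start/target coordinates and index bookkeeping.
#' @export
build_coupled_system <- function(pair, coupling_k = 5,
                                 uncoupled_residues = integer(0),
                                 offset = c(0, 0, 6)) {
  model <- pair$model
  at <- model$atoms
  nl <- nrow(at)
  nres <- model$n_residues
  ca_idx <- vapply(seq_len(nres), function(r)
    which(at$residue_index == r & at$atom_name == "CA")[1], integer(1))
  fol <- data.frame(atom_name = "F", residue_name = "FOL",
                    residue_index = seq_len(nres), chain_id = "B",
                    element = "X", stringsAsFactors = FALSE)
  atoms <- rbind(at, fol)
  tethers <- matrix(0, nres, 6)
  ca_a <- pair$state_a$xyz[ca_idx, , drop = FALSE]
  ca_b <- pair$state_b$xyz[ca_idx, , drop = FALSE]
  for (r in seq_len(nres)) {
    fi <- nl + r
    if (r %in% uncoupled_residues) {
      tethers[r, ] <- c(fi - 1, -1, coupling_k, ca_a[r, ] + offset)
    } else {
      tethers[r, ] <- c(fi - 1, ca_idx[r] - 1, coupling_k, offset)
    }
  }
  em <- as_engine_model(model)
  em$natoms <- nrow(atoms)
  em$tethers <- tethers
  attr(em, "atoms") <- atoms
  attr(em, "mass") <- rep(12, nrow(atoms))
  coords_a <- rbind(pair$state_a$xyz, sweep(ca_a, 2, offset, FUN = "+"))
  coords_b <- rbind(pair$state_b$xyz, sweep(ca_b, 2, offset, FUN = "+"))
  structure(list(engine = em, atoms = atoms, pair = pair,
                 loop_idx = seq_len(nl),
                 follower_idx = nl + seq_len(nres),
                 ca_idx = ca_idx, coupling_k = coupling_k,
                 uncoupled_residues = uncoupled_residues, offset = offset,
                 coords_a = coords_a, coords_b = coords_b),
            class = "CoupledLoopSystem")
}

#' @export
as_engine_model.CoupledLoopSystem <- function(x, ...) x$engine
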