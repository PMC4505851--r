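# Shared fixtures, built in code and memoised across test files.

find_atom <- loopstring:::find_atom
toy_torsion <- loopstring:::toy_torsion

.toy_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.toy_cache[[key]])) .toy_cache[[key]] <- force(expr)
  .toy_cache[[key]]
}

toy_model <- function() memo("model", build_toy_loop(11, seed = 1))

# the canonical two-flip wrapped/unwrapped endpoint pair
toy_pair <- function() memo("pair", generate_endpoint_conformations(
  toy_model(), data.frame(residue = c(7, 8), torsion = "psi",
                          delta = 180)))

# single-flip pair: a transition with one well-defined pathway tube
toy_pair_single <- function() memo("pair1", generate_endpoint_conformations(
  toy_model(), data.frame(residue = 7, torsion = "psi", delta = 180)))

fast_workflow <- function() memo("wf", cmd_full_toy_workflow(
  seed = 7, config = toy_workflow_config("fast")))

toy_params <- function(seed = 1)
  langevin_params(temperature = 300, friction = 2, timestep = 0.004,
                  seed = seed)

# minimal PDB fixture writer (PDB v3.3 fixed columns)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1.00, alt = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resname, chain, resno, x, y, z, occ, 0.0,
          element)
}

write_fixture_pdb <- function(path, altloc = FALSE) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2.500, 2.000, 3.000),
    pdb_atom_line(3, "C", "ALA", "A", 1, 3.000, 3.400, 3.000))
  if (altloc) {
    lines <- c(lines,
      pdb_atom_line(4, "O", "ALA", "A", 1, 4.000, 3.500, 3.000,
                    occ = 0.60, alt = "A"),
      pdb_atom_line(5, "O", "ALA", "A", 1, 4.100, 3.600, 3.100,
                    occ = 0.40, alt = "B"))
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

# independent dihedral oracle: explicit plane normals, acos magnitude and
# triple-product sign (a different formulation than the atan2 route)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ca <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, ca))) * 180 / pi
  s <- sum(cr(n1, n2) * b2)
  if (s >= 0) ang else -ang
}

rand_rotation <- function(angle_deg, axis = NULL) {
  if (is.null(axis)) axis <- rnorm(3)
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  list(R = diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K), axis = u)
}
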