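# End-to-end commands: crystal-structure pair analysis, and the full toy
# workflow (endpoints -> TMD both ways -> two-group string refinement ->
# free-energy profiles -> driving path -> loop-driven runs -> follower
# reports), with a seeded manifest for reproducibility.

#' Analyse a pair of structures of the same polypeptide
#'
#' Emits the per-residue combined torsion deviation (with the contiguous
#' high-deviation loops), optional H-bond distances (hydrogens are built
#' first), and the heavy-atom RMSD over the shared atoms.
#'
#' @param pdb_a,pdb_b PDB paths or [conformation()]s of the two states.
#' @param hbonds optional list of `list(structure = "a"|"b", donor =
#'   c(res, atom), acceptor = c(res, atom))` distance monitors.
#' @param peak_threshold combined deviation (degrees) above which a residue
#'   counts as part of a high-deviation loop.
#' @param out_dir optional directory for tab-separated report files.
#' @return List: `deviation` (per-residue table), `peaks` (data.frame of
#'   contiguous loops), `hbonds` (data.frame), `heavy_atom_rmsd` (A),
#'   `n_shared_atoms`.
#' @export
cmd_analyze_structures <- function(pdb_a, pdb_b, hbonds = NULL,
                                   peak_threshold = 60, out_dir = NULL) {
  ca <- if (inherits(pdb_a, "Conformation")) pdb_a else read_pdb(pdb_a)
  cb <- if (inherits(pdb_b, "Conformation")) pdb_b else read_pdb(pdb_b)
  shared <- intersect(unique(ca$atoms$residue_index),
                      unique(cb$atoms$residue_index))
  if (length(shared) == 0) stop("no shared residues between the structures")
  dev <- torsion_deviation_profile(ca, cb)

  high <- dev$residue_index[!is.na(dev$combined) &
                            dev$combined >= peak_threshold]
  peaks <- NULL
  if (length(high) > 0) {
    grp <- cumsum(c(1, diff(high) > 1))
    peaks <- do.call(rbind, lapply(split(high, grp), function(rs)
      data.frame(first_res = min(rs), last_res = max(rs),
                 max_combined = max(dev$combined[
                   dev$residue_index %in% rs], na.rm = TRUE))))
    rownames(peaks) <- NULL
  } else {
    peaks <- data.frame(first_res = integer(0), last_res = integer(0),
                        max_combined = numeric(0))
  }

  hb <- NULL
  if (!is.null(hbonds)) {
    ha <- place_amide_hydrogens(ca)
    hbb <- place_amide_hydrogens(cb)
    hb <- do.call(rbind, lapply(hbonds, function(h) {
      conf <- if (identical(h$structure, "b")) hbb else ha
      data.frame(structure = h$structure,
                 donor = paste0(h$donor[1], ":", h$donor[2]),
                 acceptor = paste0(h$acceptor[1], ":", h$acceptor[2]),
                 distance = hbond_distance_series(conf, h$donor,
                                                  h$acceptor))
    }))
  }

  # heavy-atom RMSD over atoms present (by residue + name) in both
  key_a <- paste(ca$atoms$residue_index, ca$atoms$atom_name)
  key_b <- paste(cb$atoms$residue_index, cb$atoms$atom_name)
  heavy_a <- ca$atoms$element != "H"
  common <- intersect(key_a[heavy_a], key_b[cb$atoms$element != "H"])
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  rmsd_heavy <- if (length(common) >= 3)
    kabsch_superpose(ca$xyz[ia, , drop = FALSE],
                     cb$xyz[ib, , drop = FALSE])$rmsd else NA_real_

  out <- list(deviation = dev, peaks = peaks, hbonds = hb,
              heavy_atom_rmsd = rmsd_heavy, n_shared_atoms = length(common))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(dev, file.path(out_dir, "torsion_deviation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(peaks, file.path(out_dir, "deviation_peaks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(hb))
      utils::write.table(hb, file.path(out_dir, "hbond_distances.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Write / read a string path as a plain-text block file
#'
#' Header line `n_images k n_atoms`, then per image a line `image <i>`
#' followed by one `x y z` row per representative atom.
#'
#' @param path a [string_path()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_string_path <- function(path, file) {
  con <- base::file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %.6f %d", length(path$images), path$k,
                     nrow(path$images[[1]])), con)
  for (i in seq_along(path$images)) {
    writeLines(sprintf("image %d", i), con)
    writeLines(sprintf("%.6f %.6f %.6f", path$images[[i]][, 1],
                       path$images[[i]][, 2], path$images[[i]][, 3]), con)
  }
  invisible(file)
}

#' @rdname write_string_path
#' @param sel,alignment_reference passed to [string_path()] on read.
#' @export
read_string_path <- function(file, sel = NULL,
                             alignment_reference = NULL) {
  lines <- readLines(file)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  m <- hdr[1]; k <- hdr[2]; n <- hdr[3]
  images <- vector("list", m)
  pos <- 2
  for (i in seq_len(m)) {
    stopifnot(grepl("^image", lines[pos]))
    block <- lines[(pos + 1):(pos + n)]
    images[[i]] <- matrix(as.numeric(unlist(strsplit(trimws(block),
                                                     "\\s+"))),
                          ncol = 3, byrow = TRUE)
    pos <- pos + n + 1
  }
  string_path(images, k = k, sel = sel,
              alignment_reference = alignment_reference)
}

#' Sizes and schedules for the toy workflow
#'
#' The `"default"` preset mirrors the production-style protocol (60 images
#' at 2 kcal/mol/A^2 for refinement, 120 at 4 for the final profile pass)
#' at toy-scale sampling times; `"fast"` shrinks everything for smoke
#' tests.
#'
#' @param preset `"default"` or `"fast"`.
#' @return List of workflow sizes.
#' @export
toy_workflow_config <- function(preset = c("default", "fast")) {
  preset <- match.arg(preset)
  if (preset == "default") {
    list(n_residues = 11, n_images = 60, n_images_final = 120, k = 2,
         k_final = 4, n_iterations = 4, steps_per_sweep = 60,
         n_sweeps = 12, final_n_sweeps = 24, tmd_duration = 60,
         tmd_k = 500, time_per_frame = 0.6, n_drive_frames = 60,
         friction = 2, temperature = 300)
  } else {
    list(n_residues = 11, n_images = 16, n_images_final = 24, k = 2,
         k_final = 4, n_iterations = 2, steps_per_sweep = 30,
         n_sweeps = 6, final_n_sweeps = 8, tmd_duration = 30,
         tmd_k = 500, time_per_frame = 0.3, n_drive_frames = 20,
         friction = 2, temperature = 300)
  }
}

#' Run the full toy workflow
#'
#' Builds the toy loop and its wrapped/unwrapped endpoints, runs targeted
#' MD in both directions, refines the transition pathway with two
#' independent string-method groups initialised from the two opposite
#' drives, integrates the free-energy profiles, builds the combined
#' driving pathway, runs loop-driven simulations in both directions on the
#' coupled system, and reports the follower response.  All stage seeds
#' derive from `seed`; a manifest records seeds and file checksums.
#'
#' @param seed master integer seed.
#' @param out_dir optional output directory for artifact files.
#' @param config a [toy_workflow_config()].
#' @param flips endpoint torsion flips (default: psi of the two central
#'   helical-turn residues, 180 degrees each).
#' @param uncoupled_residues follower negative controls; the default is
#'   the contact donor residue, whose CA moves several Angstrom between
#'   the states (an anchored follower of a residue that barely moves
#'   would be a vacuous control).
#' @return List with every stage's results plus `manifest`.
#' @export
cmd_full_toy_workflow <- function(seed = 1, out_dir = NULL,
                                  config = toy_workflow_config(),
                                  flips = NULL,
                                  uncoupled_residues = NULL) {
  seed <- as.integer(seed)
  stage_seed <- function(i) (seed * 97L + i * 1009L) %% 2147483647L
  cfg <- config

  # 1. model + endpoints
  model <- build_toy_loop(cfg$n_residues, seed = stage_seed(1))
  don <- model$contact$donor_res
  if (is.null(flips))
    flips <- data.frame(residue = c(don - 3, don - 2),
                        torsion = "psi", delta = 180)
  pair <- generate_endpoint_conformations(model, flips)
  if (is.null(uncoupled_residues)) uncoupled_residues <- don
  rep_sel <- select_representative_atoms(pair$state_a, 1, cfg$n_residues)

  params <- langevin_params(temperature = cfg$temperature,
                            friction = cfg$friction)

  # 2. targeted MD in both directions
  params$seed <- stage_seed(2)
  tmd_ab <- run_tmd(model, pair$state_a, pair$state_b, rep_sel, cfg$tmd_k,
                    cfg$tmd_duration, params)
  params$seed <- stage_seed(3)
  tmd_ba <- run_tmd(model, pair$state_b, pair$state_a, rep_sel, cfg$tmd_k,
                    cfg$tmd_duration, params)

  # 3. string refinement: two groups from the two opposite drives
  xa <- pair$state_a$xyz[rep_sel$indices, , drop = FALSE]
  xb <- pair$state_b$xyz[rep_sel$indices, , drop = FALSE]
  path0 <- init_path_linear(xa, xb, cfg$n_images, k = cfg$k,
                            sel = rep_sel)
  init_a <- init_images_from_trajectory(tmd_ab$trajectory, path0)
  init_b <- init_images_from_trajectory(tmd_ba$trajectory, path0)
  sampling <- list(steps_per_sweep = cfg$steps_per_sweep,
                   n_sweeps = cfg$n_sweeps,
                   params = params)
  ref <- refine(model, path0,
                config = list(
                  n_iterations = cfg$n_iterations, sampling = sampling,
                  final_sampling = utils::modifyList(sampling,
                                              list(n_sweeps =
                                                     cfg$final_n_sweeps)),
                  seeds = c(stage_seed(4), stage_seed(5)),
                  breaks_min_depth = NULL,
                  n_images_final = cfg$n_images_final,
                  k_final = cfg$k_final),
                states0_a = lapply(init_a$coords, function(x)
                  list(coords = x)),
                states0_b = lapply(init_b$coords, function(x)
                  list(coords = x)))

  # 4. driving pathway (internal string + centre lerp + orientation slerp)
  pose_a <- pose_of(xa, ref$path$images[[1]])
  pose_b <- pose_of(xb, ref$path$images[[length(ref$path$images)]])
  dpath <- build_driving_path(ref$path, pose_a, pose_b,
                              n_frames = cfg$n_drive_frames,
                              state_a = xa, state_b = xb)

  # 5. loop-driven runs on the coupled system, both directions
  sys <- build_coupled_system(pair, uncoupled_residues = uncoupled_residues)
  dcfg <- driven_config(time_per_frame = cfg$time_per_frame,
                        seed = stage_seed(6))
  drive_ab <- run_loop_driven(sys, sys$coords_a, dpath, dcfg,
                              sys$coords_a, params)
  dpath_rev <- structure(list(frames = rev(dpath$frames),
                              poses = rev(dpath$poses),
                              progress = rev(1 - dpath$progress),
                              sel = dpath$sel), class = "DrivingPath")
  dcfg$seed <- stage_seed(7)
  drive_ba <- run_loop_driven(sys, sys$coords_b, dpath_rev, dcfg,
                              sys$coords_b, params)

  rep_ab <- follower_response(drive_ab$trajectory, sys$coords_a,
                              sys$coords_b, dpath$sel, sys$follower_idx)
  rep_ba <- follower_response(drive_ba$trajectory, sys$coords_b,
                              sys$coords_a, dpath$sel, sys$follower_idx)

  manifest <- list(seed = seed,
                   stage_seeds = vapply(1:7, stage_seed, integer(1)),
                   parameters = cfg, files = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb(pair$state_a, file.path(out_dir, "toy_state_a.pdb"))
    write_pdb(pair$state_b, file.path(out_dir, "toy_state_b.pdb"))
    write_trajectory(tmd_ab$trajectory, file.path(out_dir, "tmd_ab.xyz"))
    write_trajectory(tmd_ba$trajectory, file.path(out_dir, "tmd_ba.xyz"))
    write_string_path(ref$path, file.path(out_dir, "refined_path.txt"))
    for (g in 1:2)
      utils::write.table(ref$profiles[[g]],
                         file.path(out_dir,
                                   sprintf("free_energy_group%d.tsv", g)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    pose_rows <- do.call(rbind, lapply(dpath$poses, function(p)
      c(p$center, p$q)))
    colnames(pose_rows) <- c("cx", "cy", "cz", "qw", "qx", "qy", "qz")
    utils::write.table(pose_rows, file.path(out_dir, "driving_poses.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest$files <- data.frame(file = basename(files),
                                 md5 = unname(tools::md5sum(files)))
    mf <- file.path(out_dir, "manifest.txt")
    writeLines(c(sprintf("seed %d", seed),
                 sprintf("stage_seed_%d %d", 1:7,
                         manifest$stage_seeds),
                 sprintf("%s %s", manifest$files$file,
                         manifest$files$md5)), mf)
  }
  list(model = model, pair = pair, rep_sel = rep_sel, tmd_ab = tmd_ab,
       tmd_ba = tmd_ba, refinement = ref, driving_path = dpath,
       system = sys, drive_ab = drive_ab, drive_ba = drive_ba,
       follower_ab = rep_ab, follower_ba = rep_ba, manifest = manifest)
}
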