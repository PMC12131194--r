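#' Generate noisy Hill-shaped dose-response replicates
#'
#' Responses are `hill_fraction_blocked(c, ic50, h)` plus additive
#' Gaussian noise truncated to [0, 1]; byte-identical for a fixed seed.
#' The default concentration grid is the oocyte voltage-clamp series used
#' for TASK-1 and Nav1.5 titrations.
#'
#' @param ic50 Generating IC50 (uM).
#' @param h Generating Hill coefficient.
#' @param concentrations Concentration grid (uM).
#' @param sigma Noise SD on the fraction scale (default 0.05, matching the
#'   spread of replicate inhibition measurements at high concentrations).
#' @param n_reps Replicates per concentration.
#' @param seed Integer seed.
#' @param compound,channel Labels carried into the output.
#' @return data.frame: compound, channel, concentration_uM, replicate,
#'   response_fraction.
#' @export
gen_dose_response <- function(ic50, h = 1,
                              concentrations = c(0.01, 0.1, 1, 10, 100, 1000),
                              sigma = 0.05, n_reps = 6, seed = 1,
                              compound = "6f", channel = "TASK-1") {
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      concentration_uM = concentrations)
  mu <- hill_fraction_blocked(grid$concentration_uM, ic50, h)
  resp <- mu + stats::rnorm(nrow(grid), 0, sigma)
  resp <- pmin(pmax(resp, 0), 1)
  data.frame(compound = compound, channel = channel,
             concentration_uM = grid$concentration_uM,
             replicate = grid$replicate,
             response_fraction = resp)
}

# minimal PDB writer: receptor CA atoms (ATOM) + ligand carbons (HETATM)
.write_pose_pdb <- function(path, receptor, ligand) {
  fmt_atom <- function(serial, type, name, resname, chain, resno, x, y, z) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, "", resname, chain, resno, "",
            x, y, z, 1.00, 0.00, substr(trimws(name), 1, 1))
  }
  lines <- character(0)
  s <- 1L
  for (i in seq_len(nrow(receptor))) {
    lines <- c(lines, fmt_atom(s, "ATOM", "CA", "ALA",
                               receptor$chain[i], receptor$resno[i],
                               receptor$x[i], receptor$y[i], receptor$z[i]))
    s <- s + 1L
  }
  for (i in seq_len(nrow(ligand))) {
    lines <- c(lines, fmt_atom(s, "HETATM", sprintf("C%d", i), "LIG", "L",
                               1L, ligand$x[i], ligand$y[i], ligand$z[i]))
    s <- s + 1L
  }
  writeLines(c(lines, "END"), path)
}

#' Generate a synthetic docking-pose set with a planted winner
#'
#' Builds pose records for `n_compounds` across the packaged channels and
#' sites, with the planted winner receiving strictly dominant (more
#' negative) binding energies and strictly higher contact counts in every
#' channel. When `pdb_dir` is given, a minimal synthetic pose structure
#' (receptor CA atoms at the packaged site residues plus ligand
#' pseudo-atoms) is written per pose, geometrically arranged so that
#' [count_contacts()] reproduces the planted contact count exactly:
#' contacted residues sit 4 Angstrom from a ligand atom, the rest 20.
#'
#' @param n_compounds Number of compounds (>= 2).
#' @param n_poses Poses per compound per site.
#' @param winner Compound id of the planted winner (default "C01").
#' @param seed Integer seed.
#' @param sites Binding-site table.
#' @param pdb_dir Optional directory for synthetic pose PDB files.
#' @return data.frame of pose records (compound, channel, site, pose_id,
#'   dg_bind, n_contacts[, pdb_path]).
#' @export
gen_pose_set <- function(n_compounds = 5, n_poses = 3, winner = NULL,
                         seed = 1, sites = binding_sites(),
                         pdb_dir = NULL) {
  if (n_compounds < 2) stop("need >= 2 compounds")
  set.seed(seed)
  compounds <- sprintf("C%02d", seq_len(n_compounds))
  if (is.null(winner)) winner <- compounds[1]
  if (!winner %in% compounds) stop("winner must be one of the compounds")
  keys <- unique(sites[c("channel", "site")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    st <- sites[sites$channel == keys$channel[k] & sites$site == keys$site[k], ]
    n_res <- nrow(st)
    for (cmp in compounds) {
      is_w <- cmp == winner
      # losers: energies in [-45, -30], contacts up to n_res - 2;
      # winner: strictly dominant in both criteria
      for (po in seq_len(n_poses)) {
        if (is_w) {
          dg <- stats::runif(1, -60, -50)
          nc <- n_res - sample(0:1, 1)
        } else {
          dg <- stats::runif(1, -45, -30)
          nc <- sample(0:max(0, n_res - 3), 1)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cmp, channel = keys$channel[k], site = keys$site[k],
          pose_id = sprintf("%s_%s_%s_p%d", cmp, keys$channel[k],
                            keys$site[k], po),
          dg_bind = dg, n_contacts = nc)
      }
    }
  }
  poses <- do.call(rbind, rows)
  rownames(poses) <- NULL
  if (!is.null(pdb_dir)) {
    dir.create(pdb_dir, showWarnings = FALSE, recursive = TRUE)
    poses$pdb_path <- NA_character_
    for (i in seq_len(nrow(poses))) {
      st <- sites[sites$channel == poses$channel[i] &
                    sites$site == poses$site[i], ]
      n_res <- nrow(st)
      # residue i sits at x = 30*i; a contacted residue gets a ligand atom
      # 4 A away, non-contacted residues have no ligand atom within 20 A
      receptor <- data.frame(chain = st$chain, resno = st$resno,
                             x = 30 * seq_len(n_res), y = 0, z = 0)
      k <- poses$n_contacts[i]
      lig_x <- if (k > 0) 30 * seq_len(k) + 4 else 30 * n_res + 100
      ligand <- data.frame(x = lig_x, y = 0, z = 0)
      path <- file.path(pdb_dir, paste0(poses$pose_id[i], ".pdb"))
      .write_pose_pdb(path, receptor, ligand)
      poses$pdb_path[i] <- path
    }
  }
  poses
}

#' Generate a calibrated population fixture
#'
#' Runs the full population workflow: Latin Hypercube sampling of `n_lhs`
#' scaling vectors, steady-state pacing and biomarker calibration against
#' the packaged phenotype ranges, then subsampling to at most `n_target`
#' accepted models (uniformly at random under the run seed). If fewer
#' than `n_target` pass, all accepted models are returned with a warning.
#'
#' @param n_target Requested population size (45 in the trial design).
#' @param phenotype "SR" or "AF".
#' @param seed Integer seed (drives both the LHS and the subsample).
#' @param n_lhs Latin Hypercube sample size (100 in the trial design).
#' @param cycle_length Calibration pacing cycle length (ms).
#' @param max_beats,tol,dt Passed to [calibrate_population()].
#' @return List with `scalings` (accepted, subsampled), `biomarkers`,
#'   `calibration` (the full audit), `seed`.
#' @export
gen_population_fixture <- function(n_target = 45, phenotype = "AF",
                                   seed = 1, n_lhs = 100,
                                   cycle_length = 1000, max_beats = 40,
                                   tol = 1, dt = 0.02) {
  if (n_target < 1) stop("n_target must be >= 1")
  scal <- lhs_sample(n_lhs, 8, seed = seed)
  ranges <- calibration_ranges(phenotype)
  base <- crn_params(phenotype)
  calib <- calibrate_population(scal, ranges, params_base = base,
                                cycle_length = cycle_length,
                                max_beats = max_beats, tol = tol, dt = dt)
  idx <- which(calib$accepted)
  if (length(idx) > n_target) {
    set.seed(seed + 1L)
    idx <- sort(sample(idx, n_target))
  } else if (length(idx) < n_target) {
    warning(sprintf("only %d of %d sampled models passed calibration",
                    length(idx), n_lhs))
  }
  list(scalings = calib$scalings[idx, , drop = FALSE],
       biomarkers = calib$biomarkers[idx, , drop = FALSE],
       model_ids = idx,
       calibration = calib,
       phenotype = phenotype,
       seed = seed)
}
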