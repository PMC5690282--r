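# Synthetic ground-truth generators: toy two-domain complexes with a known
# inter-domain pose, cross-link tables with controlled decoy contamination,
# SAXS curves from the Debye equation, and HDX tables with interface
# protection. Every generator is a pure function of its seed; sub-seeds are
# split per generator (seed, seed+1, ...) so adding links never perturbs
# structure generation.

#' Describe a synthetic ground-truth scenario
#'
#' A scenario is a plain, fully serializable list of generator settings;
#' regenerating from the same scenario is bit-identical.
#'
#' @param seed Master seed (sub-generators use seed, seed+1, ...).
#' @param n_receptor,n_mobile Domain sizes in residues (>= 20).
#' @param n_links Number of unique simulated cross-links.
#' @param decoy_fraction Fraction of links that are decoys (violated at the
#'   true pose), in [0, 1).
#' @param chemistry Cross-link chemistry for simulated links.
#' @param saxs_noise Multiplicative Gaussian noise fraction on intensities.
#' @param hdx_effect Interface protection effect in delta-percent-D
#'   (negative = protection).
#' @return List of class \code{"scenario"}.
#' @export
scenario <- function(seed = 2017, n_receptor = 100, n_mobile = 80,
                     n_links = 20, decoy_fraction = 0.1, chemistry = "BS3",
                     saxs_noise = 0.02, hdx_effect = -15) {
  if (n_receptor < 20 || n_mobile < 20) stop("domain sizes must be >= 20",
                                             call. = FALSE)
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("decoy_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_receptor = as.integer(n_receptor),
                 n_mobile = as.integer(n_mobile),
                 n_links = as.integer(n_links),
                 decoy_fraction = decoy_fraction, chemistry = chemistry,
                 saxs_noise = saxs_noise, hdx_effect = hdx_effect),
            class = "scenario")
}

# compact self-avoiding Calpha walk: 3.8 A steps, >= 4.0 A non-bonded
# separation, bias toward the globular Rg ~ 2.2 n^0.38 scaling
.ca_walk <- function(n, n_candidates = 60, bias_sd = 0.25, max_restarts = 50) {
  target_rg <- function(k) 2.2 * k^0.38
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:n) {
      u <- matrix(stats::rnorm(3 * n_candidates), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      cand <- sweep(u * 3.8, 2, xyz[i - 1, ], "+")
      if (i > 2) {
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        mind <- apply(cand, 1, function(p)
          min(sqrt(colSums((t(prev) - p)^2))))
        cand <- cand[mind >= 4.0, , drop = FALSE]
      }
      if (nrow(cand) == 0L) { ok <- FALSE; break }
      done <- xyz[seq_len(i - 1), , drop = FALSE]
      rg_new <- apply(cand, 1, function(p)
        radius_of_gyration(rbind(done, p)))
      w <- exp(-(rg_new - target_rg(i))^2 / (2 * bias_sd^2))
      if (sum(w) <= 0) w <- rep(1, length(w))
      pick <- sample.int(nrow(cand), 1, prob = w)
      xyz[i, ] <- cand[pick, ]
    }
    if (ok) return(xyz)
  }
  stop("self-avoiding walk failed after ", max_restarts,
       " restarts; try a different domain size", call. = FALSE)
}

.ca_structure <- function(xyz, chain, id) {
  n <- nrow(xyz)
  new_structure(data.frame(
    chain = chain, resno = seq_len(n), inscode = "", resname = "ALA",
    atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    stringsAsFactors = FALSE), id = id)
}

#' Generate a toy two-domain complex with a known pose
#'
#' Each domain is a compact self-avoiding Calpha walk (3.8 Angstrom steps,
#' minimum 4.0 Angstrom non-bonded separation, compactness bias toward
#' Rg = 2.2 n^0.38). The mobile domain is placed at a random orientation in
#' contact with the receptor: no inter-domain Calpha pair closer than 4
#' Angstrom and at least 30 pairs within 12 Angstrom.
#'
#' @param scn A \code{\link{scenario}}.
#' @return List: \code{receptor} (chain A), \code{mobile} (chain B, in its
#'   own frame centered near the origin), \code{true_transform} (the pose
#'   placing the mobile onto the receptor), \code{assembly} (the true
#'   complex).
#' @export
make_toy_complex <- function(scn) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(scn$seed)
  rec_xyz <- .ca_walk(scn$n_receptor)
  rec_xyz <- sweep(rec_xyz, 2, colMeans(rec_xyz))
  mob_xyz <- .ca_walk(scn$n_mobile)
  mob_xyz <- sweep(mob_xyz, 2, colMeans(mob_xyz))

  place <- function() {
    for (try in seq_len(200L)) {
      R <- random_rotation()
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rot <- mob_xyz %*% t(R)
      for (d in seq(1, 120, by = 0.5)) {
        shift <- sweep(rot, 2, u * d, "+")
        dd <- cpp_cross_distances(rec_xyz, shift)
        if (min(dd) >= 4.0) {
          if (sum(dd < 12) >= 30) {
            return(rigid_transform(R, u * d))
          }
          break  # first clash-free separation has too few contacts
        }
      }
    }
    stop("failed to place domains in contact; try different sizes",
         call. = FALSE)
  }
  tr <- place()
  receptor <- .ca_structure(rec_xyz, "A", "receptor")
  mobile <- .ca_structure(mob_xyz, "B", "mobile")
  asm <- new_assembly(list(receptor = receptor, mobile = mobile),
                      transforms = list(receptor = transform_identity(),
                                        mobile = tr),
                      roles = c(receptor = "receptor", mobile = "mobile"))
  list(receptor = receptor, mobile = mobile, true_transform = tr,
       assembly = asm)
}

#' Simulate a cross-link spectrum-match table from a true assembly
#'
#' True links are drawn uniformly from inter-domain residue pairs whose
#' Calpha-Calpha distance at the true pose is within the chemistry's upper
#' bound; decoys from pairs farther than upper bound + 20 Angstrom. Scores
#' are N(9, 2) truncated at 3. Some links are duplicated into multiple CSMs.
#' The decoy flag is carried only in \code{attr(, "truth")}, for evaluation;
#' the docking stage never sees it.
#'
#' @param assembly True two-component assembly (components
#'   \code{receptor}/\code{mobile}).
#' @param n_links Number of unique links.
#' @param chemistry Link chemistry (default \code{"BS3"}).
#' @param decoy_fraction Fraction of decoy links; the decoy count is
#'   \code{round(n_links * decoy_fraction)}.
#' @param seed RNG seed.
#' @param chemistry_params See \code{\link{default_chemistry_params}}.
#' @return A \code{"csm_table"} with attribute \code{"truth"}: a data frame
#'   of unique simulated links with their true distances and decoy flags.
#' @export
simulate_crosslinks <- function(assembly, n_links = 20, chemistry = "BS3",
                                decoy_fraction = 0.1, seed = 1,
                                chemistry_params = default_chemistry_params()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  upper <- chemistry_params[[chemistry]]$upper_bound
  rec <- component_structure(assembly, "receptor")
  mob <- component_structure(assembly, "mobile")
  rec_ca <- ca_matrix(rec); mob_ca <- ca_matrix(mob)
  dd <- matrix(cpp_cross_distances(rec_ca, mob_ca), nrow = nrow(rec_ca))
  n_decoy <- round(n_links * decoy_fraction)
  n_true <- n_links - n_decoy
  true_pool <- which(dd <= upper, arr.ind = TRUE)
  decoy_pool <- which(dd > upper + 20, arr.ind = TRUE)
  if (nrow(true_pool) < n_true) stop("not enough close inter-domain pairs",
                                     call. = FALSE)
  if (n_decoy > 0 && nrow(decoy_pool) < n_decoy) {
    stop("not enough distant inter-domain pairs for decoys", call. = FALSE)
  }
  # BS3-like distance distribution at the true pose: draw target distances
  # from N(11.4, 4) truncated to the eligible range, then take the unused
  # pair nearest each draw, so the realized mean tracks the chemistry's
  # 11.4 A Calpha-Calpha mean rather than the pair-count density
  d_true <- dd[true_pool]
  mu <- chemistry_params[[chemistry]]$target
  draws <- stats::rnorm(n_true, mu, 4.0)
  draws <- pmin(pmax(draws, min(d_true)), upper)
  avail <- rep(TRUE, nrow(true_pool))
  sel <- integer(n_true)
  for (k in seq_len(n_true)) {
    cand <- which(avail)
    sel[k] <- cand[which.min(abs(d_true[cand] - draws[k]))]
    avail[sel[k]] <- FALSE
  }
  pick_t <- true_pool[sel, , drop = FALSE]
  pick_d <- if (n_decoy > 0) {
    decoy_pool[sample.int(nrow(decoy_pool), n_decoy), , drop = FALSE]
  } else {
    matrix(integer(), 0, 2)
  }
  picks <- rbind(pick_t, pick_d)
  is_decoy <- rep(c(FALSE, TRUE), c(n_true, n_decoy))
  rscore <- function(n) {
    s <- stats::rnorm(n, 9, 2)
    while (any(s < 3)) s[s < 3] <- stats::rnorm(sum(s < 3), 9, 2)
    s
  }
  scores <- rscore(n_links)
  n_csm <- 1L + stats::rbinom(n_links, 2, 0.2)  # some links seen repeatedly
  rows <- data.frame(
    protein_a = "receptor", restype_a = "K",
    residue_a = rec$resno[rec$atom == "CA"][picks[, 1]],
    protein_b = "mobile", restype_b = "K",
    residue_b = mob$resno[mob$atom == "CA"][picks[, 2]],
    score = scores, chemistry = chemistry, stringsAsFactors = FALSE)
  out <- rows[rep(seq_len(n_links), n_csm), ]
  rownames(out) <- NULL
  out <- .as_csm(out)
  attr(out, "truth") <- data.frame(
    residue_a = rows$residue_a, residue_b = rows$residue_b,
    distance = dd[picks], is_decoy = is_decoy, stringsAsFactors = FALSE)
  out
}

#' Simulate a SAXS curve from an assembly
#'
#' Debye-equation intensities on the given s grid with multiplicative
#' Gaussian noise (sigma = noise_fraction * I); at noise 0 the curve equals
#' the Debye profile exactly and carries no sigma column.
#'
#' @param assembly An assembly (or structure).
#' @param s_grid Momentum transfer grid (default 150 points over
#'   0.003-0.497 1/Angstrom).
#' @param noise_fraction Relative noise level.
#' @param seed RNG seed.
#' @return A \code{"saxs_curve"}.
#' @export
simulate_saxs <- function(assembly, s_grid = seq(0.003, 0.497,
                                                 length.out = 150),
                          noise_fraction = 0.02, seed = 1) {
  ideal <- debye_profile(assembly, s_grid)
  if (noise_fraction == 0) return(ideal)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sig <- noise_fraction * ideal$intensity
  I <- ideal$intensity + stats::rnorm(length(sig), 0, sig)
  saxs_curve(s_grid, I, sig)
}

#' Simulate an HDX deuteration-change table
#'
#' Overlapping peptides (lengths 5-13) tile the protein \code{coverage}
#' times, so every residue is covered by at least \code{coverage} peptides.
#' Peptides overlapping the interface receive a deuteration change of
#' \code{effect} plus N(0, 2) noise; background peptides get N(0, 2). The
#' two timepoints are generated with correlation 0.8.
#'
#' @param x A structure, assembly component, or residue count.
#' @param interface_residues Residues carrying the protection effect.
#' @param effect Interface delta-percent-D (negative = protection).
#' @param len_range Peptide length range (default 5-13).
#' @param coverage Number of tiling passes (default 2).
#' @param seed RNG seed.
#' @param protein Protein label on the output rows.
#' @return An \code{"hdx_peptides"} data frame.
#' @export
simulate_hdx <- function(x, interface_residues, effect = -15,
                         len_range = c(5, 13), coverage = 2, seed = 1,
                         protein = "receptor") {
  n <- if (is.numeric(x)) as.integer(x) else
    sum((if (inherits(x, "assembly")) flatten_assembly(x) else x)$atom == "CA")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (pass in seq_len(coverage)) {
    pos <- 1L
    while (pos <= n) {
      len <- sample(len_range[1]:len_range[2], 1)
      end <- min(pos + len - 1L, n)
      if (n - end < len_range[1] && end < n) end <- n  # absorb short tail
      rows[[length(rows) + 1L]] <- c(pos, end)
      pos <- end + 1L
    }
  }
  pep <- do.call(rbind, rows)
  hits <- vapply(seq_len(nrow(pep)), function(i)
    any(pep[i, 1]:pep[i, 2] %in% interface_residues), TRUE)
  mu <- ifelse(hits, effect, 0)
  e1 <- stats::rnorm(nrow(pep))
  e2 <- 0.8 * e1 + sqrt(1 - 0.8^2) * stats::rnorm(nrow(pep))
  .as_hdx(data.frame(
    protein = protein, start = pep[, 1], end = pep[, 2],
    sequence = strrep("A", pep[, 2] - pep[, 1] + 1L),
    delta_15s = mu + 2 * e1, delta_120s = mu + 2 * e2,
    stringsAsFactors = FALSE))
}

#' End-to-end synthetic pose-recovery experiment
#'
#' Generates a toy complex and a contaminated cross-link table from a
#' scenario, docks the mobile domain onto the receptor from scratch, refines
#' the top-ranked pose against the satisfaction criterion, and reports
#' recovery metrics against the known truth.
#'
#' @param scn A \code{\link{scenario}}.
#' @param n_starts Docking starts (default 512).
#' @param satisfaction_threshold Refinement stopping threshold.
#' @param use_saxs Use a simulated SAXS curve of the true complex the way
#'   the full pipeline would use measured scattering: its Guinier Rg gates
#'   pose ranking (Rg window) and its curve gates refinement (chi-square
#'   non-worsening). Default \code{TRUE}.
#' @param docking_seed Seed for the docking sampler (default
#'   \code{scn$seed + 3}); lets the stochastic search be re-seeded while the
#'   generated ground truth stays fixed.
#' @return List: \code{satisfaction_pct} (percent of all simulated
#'   restraints satisfied by the top refined model),
#'   \code{satisfaction_true_pct} (non-decoy restraints only),
#'   \code{rmsd_to_truth} (mobile-Calpha RMSD, Angstrom),
#'   \code{stop_reason}, \code{result} (the refinement result),
#'   \code{truth} (per-link truth table).
#' @export
pose_recovery_experiment <- function(scn, n_starts = 512,
                                     satisfaction_threshold = 0.90,
                                     use_saxs = TRUE, docking_seed = NULL) {
  if (is.null(docking_seed)) docking_seed <- scn$seed + 3L
  toy <- make_toy_complex(scn)
  csms <- simulate_crosslinks(toy$assembly, n_links = scn$n_links,
                              chemistry = scn$chemistry,
                              decoy_fraction = scn$decoy_fraction,
                              seed = scn$seed + 1L)
  truth <- attr(csms, "truth")
  links <- deduplicate_links(csms)
  built <- build_restraints(links, toy$assembly,
                            chain_map = c(receptor = "A", mobile = "B"))
  saxs_target <- if (use_saxs) {
    simulate_saxs(toy$assembly, noise_fraction = scn$saxs_noise,
                  seed = scn$seed + 2L)
  } else NULL
  rg_target <- if (use_saxs) guinier_fit(saxs_target)$Rg else NULL
  poses <- sample_poses(toy$receptor, toy$mobile, built$restraints,
                        n_starts = n_starts, seed = docking_seed,
                        rg_target = rg_target)
  res <- iterative_refine(poses[[1]], toy$receptor, toy$mobile,
                          built$restraints,
                          satisfaction_threshold = satisfaction_threshold,
                          saxs_target = saxs_target)
  # satisfaction over the simulated links (decoys included), at the
  # chemistry cutoff, in the top-ranked refined model
  rep_all <- evaluate_satisfaction(res$assembly, built$restraints)
  # map truth decoy flags onto the (deduplicated, reordered) restraints;
  # deduplication canonicalizes site order, so key on receptor chain A
  on_a <- built$restraints$chain_a == "A"
  key <- paste(ifelse(on_a, built$restraints$res_a, built$restraints$res_b),
               ifelse(on_a, built$restraints$res_b, built$restraints$res_a))
  tkey <- paste(truth$residue_a, truth$residue_b)
  is_decoy <- truth$is_decoy[match(key, tkey)]
  sat <- rep_all$per_restraint$satisfied
  mob_true <- apply_transform(ca_matrix(toy$mobile), toy$true_transform)
  mob_fit <- apply_transform(ca_matrix(toy$mobile),
                             res$assembly$transforms$mobile)
  list(satisfaction_pct = 100 * mean(sat),
       satisfaction_true_pct = 100 * mean(sat[!is_decoy]),
       rmsd_to_truth = sqrt(mean(rowSums((mob_true - mob_fit)^2))),
       stop_reason = res$stop_reason,
       result = res,
       truth = truth)
}

#' Write all scenario fixtures to a directory
#'
#' Emits \code{receptor.pdb}, \code{mobile.pdb}, \code{truth.json},
#' \code{links.csv}, \code{curve.dat} and \code{hdx.csv} for a scenario.
#'
#' @param scn A \code{\link{scenario}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_complex(scn)
  write_structure(toy$receptor, file.path(dir, "receptor.pdb"))
  write_structure(toy$mobile, file.path(dir, "mobile.pdb"))
  csms <- simulate_crosslinks(toy$assembly, n_links = scn$n_links,
                              chemistry = scn$chemistry,
                              decoy_fraction = scn$decoy_fraction,
                              seed = scn$seed + 1L)
  utils::write.csv(as.data.frame(csms), file.path(dir, "links.csv"),
                   row.names = FALSE)
  curve <- simulate_saxs(toy$assembly, noise_fraction = scn$saxs_noise,
                         seed = scn$seed + 2L)
  write_saxs(curve, file.path(dir, "curve.dat"))
  rec_ca <- ca_matrix(component_structure(toy$assembly, "receptor"))
  mob_ca <- ca_matrix(component_structure(toy$assembly, "mobile"))
  dd <- matrix(cpp_cross_distances(rec_ca, mob_ca), nrow = nrow(rec_ca))
  iface <- which(apply(dd, 1, min) < 8)
  hdx <- simulate_hdx(scn$n_receptor, iface, effect = scn$hdx_effect,
                      seed = scn$seed + 3L)
  utils::write.csv(as.data.frame(hdx), file.path(dir, "hdx.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = unclass(scn),
         true_transform = list(
           rotation = toy$true_transform$rotation,
           translation = toy$true_transform$translation),
         truth = attr(csms, "truth"), interface = iface),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
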