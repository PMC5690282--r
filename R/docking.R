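# Restraint-driven rigid-body docking with iterative refinement to a
# restraint-satisfaction stopping criterion.
#
# The mobile component is docked onto the receptor under cross-link distance
# restraints (flat-bottom harmonic, linearly capped beyond the satisfaction
# cutoff so that decoy links cannot dominate) plus a soft-sphere Calpha
# clash penalty. Refinement iterates local descent, down-weighting the
# single worst-violated restraint between iterations, until the satisfied
# fraction exceeds the threshold (default 0.90) or iterations run out. An
# optional SAXS target curve gates refinement: iterations that worsen the
# Debye-profile chi-square by more than 20% are rejected.

#' Default clash parameters
#'
#' The clash weight is deliberately large relative to restraint energies:
#' interpenetrating poses must never outrank clash-free ones merely by
#' accommodating a few extra (possibly decoy) restraints.
#'
#' @return List with \code{clash_dist} (Angstrom, default 4),
#'   \code{clash_weight} (default 300: any interpenetration is prohibitive),
#'   \code{outlier_slope} (restraint energy slope beyond the satisfaction
#'   cutoff, default 1 per Angstrom), \code{contact_weight} (depth of the
#'   short-range contact attraction per Calpha pair; 0 = pure repulsion,
#'   the published score form) and \code{contact_range} (Angstrom).
#' @export
default_clash_params <- function() {
  list(clash_dist = 4.0, clash_weight = 300.0, outlier_slope = 1.0,
       contact_weight = 0.0, contact_range = 10.0, flat_bottom = TRUE)
}

#' Docking energy parameters
#'
#' Like \code{\link{default_clash_params}} but with harmonic (two-sided)
#' cross-link restraints: quadratic about the chemistry's mean distance on
#' both sides, as in Gaussian distance restraints used for model refinement.
#' One-sided flat-bottom restraints leave a broad pose plateau (any pose
#' keeping every link under its target is restraint-free, so squeeze and
#' pivot motions cost nothing); centring the restraints on the observed mean
#' cross-link distance makes the true pose a strict minimum and is what the
#' docking pipeline uses by default.
#' @return Parameter list as in \code{\link{default_clash_params}} with
#'   \code{flat_bottom = FALSE}.
#' @export
docking_energy_params <- function() {
  p <- default_clash_params()
  p$flat_bottom <- FALSE
  p
}

# Precompute everything the hot scoring loop needs: receptor/mobile Calpha
# matrices and restraint site indices. Restraints with both sites on the
# same body contribute a pose-independent term and are kept separately.
.docking_context <- function(receptor, mobile, restraints,
                             clash_params = default_clash_params()) {
  rec_ca <- ca_matrix(receptor)
  mob_ca <- ca_matrix(mobile)
  n <- nrow(restraints)
  if (n == 0L) stop("zero mappable restraints", call. = FALSE)
  key_a <- .res_key(restraints$chain_a, restraints$res_a)
  key_b <- .res_key(restraints$chain_b, restraints$res_b)
  ra <- match(key_a, rownames(rec_ca)); ma <- match(key_a, rownames(mob_ca))
  rb <- match(key_b, rownames(rec_ca)); mb <- match(key_b, rownames(mob_ca))
  side_a <- ifelse(!is.na(ra), "rec", ifelse(!is.na(ma), "mob", NA))
  side_b <- ifelse(!is.na(rb), "rec", ifelse(!is.na(mb), "mob", NA))
  if (anyNA(side_a) || anyNA(side_b)) {
    stop("restraint site(s) not resolvable to a Calpha in either body",
         call. = FALSE)
  }
  inter <- side_a != side_b
  ri <- ifelse(side_a == "rec", ra, rb)[inter]
  mi <- ifelse(side_a == "mob", ma, mb)[inter]
  list(rec_ca = rec_ca, mob_ca = mob_ca, restraints = restraints,
       inter = which(inter), ri = as.integer(ri - 1L),
       mi = as.integer(mi - 1L),
       intra = which(!inter),
       clash = clash_params)
}

# energy + satisfaction of a transform within a context, using current
# per-restraint weights
.context_energy <- function(ctx, transform, weights) {
  rs <- ctx$restraints
  v <- cpp_pose_energy(ctx$rec_ca, ctx$mob_ca, transform$rotation,
                       transform$translation,
                       ctx$ri, ctx$mi,
                       rs$target[ctx$inter], rs$upper[ctx$inter],
                       weights[ctx$inter],
                       ctx$clash$clash_dist, ctx$clash$clash_weight,
                       ctx$clash$outlier_slope %||% 1.0,
                       ctx$clash$contact_weight %||% 0.0,
                       ctx$clash$contact_range %||% 10.0,
                       as.integer(isTRUE(ctx$clash$flat_bottom %||% TRUE)))
  e_res <- v[1]; n_sat <- v[3]
  # pose-independent intra-body restraints still count toward satisfaction
  if (length(ctx$intra)) {
    for (k in ctx$intra) {
      key_a <- .res_key(rs$chain_a[k], rs$res_a[k])
      key_b <- .res_key(rs$chain_b[k], rs$res_b[k])
      src <- if (key_a %in% rownames(ctx$rec_ca)) ctx$rec_ca else ctx$mob_ca
      d <- sqrt(sum((src[key_a, ] - src[key_b, ])^2))
      e_res <- e_res + restraint_energy(d, rs$target[k], rs$upper[k],
                                        weights[k],
                                        ctx$clash$outlier_slope %||% 1.0,
                                        isTRUE(ctx$clash$flat_bottom %||% TRUE))
      if (d <= rs$upper[k]) n_sat <- n_sat + 1
    }
  }
  list(score_restraint = e_res, score_clash = v[2],
       score_total = e_res + v[2],
       satisfaction = n_sat / nrow(rs))
}

.make_pose <- function(transform, en) {
  structure(list(transform = transform,
                 score_restraint = en$score_restraint,
                 score_clash = en$score_clash,
                 score_total = en$score_total,
                 satisfaction = en$satisfaction), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: total %.3f (restraint %.3f + clash %.3f), %.0f%% satisfied\n",
              x$score_total, x$score_restraint, x$score_clash,
              100 * x$satisfaction))
  invisible(x)
}

#' Score a two-body pose
#'
#' @param assembly Assembly with one mobile component.
#' @param restraints A \code{"restraints"} data frame (sites resolved
#'   against the assembly's chains).
#' @param clash_params See \code{\link{default_clash_params}}.
#' @return A \code{"pose"}: the mobile transform plus score breakdown
#'   (\code{score_total = score_restraint + score_clash}) and satisfied
#'   fraction.
#' @export
score_pose <- function(assembly, restraints,
                       clash_params = default_clash_params()) {
  lab_mob <- names(assembly$roles)[assembly$roles == "mobile"]
  if (length(lab_mob) != 1L) stop("assembly needs exactly one mobile component",
                                  call. = FALSE)
  lab_rec <- setdiff(names(assembly$components), lab_mob)
  rec <- do.call(rbind, lapply(lab_rec, function(l)
    as.data.frame(component_structure(assembly, l))))
  rec <- new_structure(rec, id = "receptor")
  ctx <- .docking_context(rec, assembly$components[[lab_mob]], restraints,
                          clash_params)
  tr <- assembly$transforms[[lab_mob]]
  .make_pose(tr, .context_energy(ctx, tr, restraints$weight))
}

#' Local rigid-body refinement of a pose
#'
#' Derivative-free Nelder-Mead descent over the six rigid-body parameters
#' (axis-angle rotation increment about the mobile centroid, plus
#' translation). Deterministic; the returned score never exceeds the input
#' score.
#'
#' @param pose A \code{"pose"} (or bare \code{"rigid_transform"}).
#' @param receptor,mobile Structures of the two bodies.
#' @param restraints Restraints resolved against the two bodies' chains.
#' @param clash_params See \code{\link{default_clash_params}}.
#' @param max_evals Cap on objective evaluations (default 400).
#' @param weights Optional per-restraint weight override.
#' @return The refined \code{"pose"}.
#' @export
local_refine <- function(pose, receptor, mobile, restraints,
                         clash_params = default_clash_params(),
                         max_evals = 400, weights = NULL) {
  ctx <- .docking_context(receptor, mobile, restraints, clash_params)
  if (is.null(weights)) weights <- restraints$weight
  tr <- if (inherits(pose, "pose")) pose$transform else pose
  .make_pose_refined(ctx, tr, weights, max_evals)
}

# core refinement on a precomputed context (internal; avoids rebuilding the
# context inside sampling/refinement loops)
.make_pose_refined <- function(ctx, tr, weights, max_evals) {
  cm <- colMeans(ctx$mob_ca)
  c0 <- as.numeric(tr$rotation %*% cm) + tr$translation
  rot_scale <- 0.2  # radians per parameter unit; translations in Angstrom
  par2tr <- function(p) {
    Raa <- rotation_from_axis_angle(p[1:3] * rot_scale)
    rigid_transform(Raa %*% tr$rotation,
                    as.numeric(Raa %*% (tr$translation - c0)) + c0 + p[4:6])
  }
  fn <- function(p) .context_energy(ctx, par2tr(p), weights)$score_total
  # restart Nelder-Mead from the incumbent until it stops improving (a
  # single pass often terminates on simplex collapse well short of the
  # local minimum)
  best_p <- rep(0, 6)
  best_v <- fn(best_p)
  remaining <- max_evals
  repeat {
    fit <- stats::optim(best_p, fn, method = "Nelder-Mead",
                        control = list(maxit = remaining, reltol = 1e-10))
    remaining <- remaining - fit$counts[1]
    if (fit$value >= best_v - 1e-8 * (1 + abs(best_v))) break
    best_p <- fit$par
    best_v <- fit$value
    if (remaining < 50) break
  }
  tr_new <- par2tr(best_p)
  en_new <- .context_energy(ctx, tr_new, weights)
  en_old <- .context_energy(ctx, tr, weights)
  if (en_old$score_total <= en_new$score_total) {
    return(.make_pose(tr, en_old))
  }
  .make_pose(tr_new, en_new)
}

#' Sample and locally refine rigid-body docking poses
#'
#' Starting poses combine uniform random rotations (quaternion sampling)
#' with translations placing the mobile restraint-site centroid at the
#' receptor restraint-site centroid plus isotropic Gaussian jitter
#' (sigma = 10 Angstrom). Every start is locally refined; results are
#' deduplicated by mobile-Calpha RMSD (< 2 Angstrom collapses to the
#' better-scoring pose) and ranked by score ascending, ties broken by
#' satisfaction descending then seed order.
#'
#' @param receptor,mobile Structures.
#' @param restraints Restraints resolved against the two bodies' chains;
#'   at least one must link the two bodies.
#' @param n_starts Number of random starts (default 512).
#' @param seed RNG seed (the sampler restores the caller's RNG state).
#' @param clash_params See \code{\link{default_clash_params}}.
#' @param max_evals Local-refinement evaluation cap per start.
#' @param dedup_rmsd RMSD radius for pose deduplication (Angstrom).
#' @param rg_target Optional radius of gyration (Angstrom) of the full
#'   complex, e.g. a Guinier Rg from a SAXS curve; poses whose assembly Rg
#'   deviates from it by more than \code{rg_window} are ranked after all
#'   conforming poses (the quantitative stand-in for selecting docking
#'   solutions inside a scattering envelope).
#' @param rg_window Relative Rg tolerance (default 0.10).
#' @return List of \code{"pose"} objects, best first.
#' @export
sample_poses <- function(receptor, mobile, restraints, n_starts = 512,
                         seed = 2017, clash_params = default_clash_params(),
                         max_evals = 300, dedup_rmsd = 2.0,
                         rg_target = NULL, rg_window = 0.10) {
  ctx <- .docking_context(receptor, mobile, restraints, clash_params)
  if (length(ctx$inter) == 0L) {
    stop("no restraint links the two bodies", call. = FALSE)
  }
  rec_site_centroid <- colMeans(ctx$rec_ca[ctx$ri + 1L, , drop = FALSE])
  mob_site_centroid <- colMeans(ctx$mob_ca[ctx$mi + 1L, , drop = FALSE])
  weights <- restraints$weight

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  poses <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    R <- random_rotation()
    jitter <- stats::rnorm(3, 0, 10)
    t0 <- rec_site_centroid + jitter - as.numeric(R %*% mob_site_centroid)
    tr <- rigid_transform(R, t0)
    poses[[k]] <- .make_pose_refined(ctx, tr, weights, max_evals)
  }

  scores <- vapply(poses, `[[`, 0.0, "score_total")
  sats <- vapply(poses, `[[`, 0.0, "satisfaction")
  out_of_window <- rep(FALSE, length(poses))
  if (!is.null(rg_target)) {
    out_of_window <- vapply(poses, function(p) {
      rg <- radius_of_gyration(rbind(ctx$rec_ca,
                                     apply_transform(ctx$mob_ca, p$transform)))
      abs(rg - rg_target) / rg_target > rg_window
    }, TRUE)
  }
  ord <- order(out_of_window, scores, -sats, seq_along(poses))
  kept <- list()
  kept_coords <- list()
  for (k in ord) {
    m <- apply_transform(ctx$mob_ca, poses[[k]]$transform)
    dup <- FALSE
    for (kc in kept_coords) {
      if (sqrt(mean(rowSums((m - kc)^2))) < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- poses[[k]]
      kept_coords[[length(kept_coords) + 1L]] <- m
    }
  }
  kept
}

#' Iterative refinement against a satisfaction criterion
#'
#' Loop: local refinement, then restraint-satisfaction evaluation; stop as
#' soon as the satisfied fraction exceeds \code{satisfaction_threshold}
#' (stop reason \code{"converged_satisfaction"}). Otherwise the single
#' worst-violated restraint is down-weighted by 0.5 (never removed) and the
#' loop continues, up to \code{max_iterations} (stop reason
#' \code{"max_iterations"}, never an error). If a SAXS target curve is
#' supplied, the Debye-profile chi-square of the current model is computed
#' each iteration and an iteration worsening it by more than 20% is rejected
#' (previous pose restored; the most-violated restraint is halved instead).
#'
#' @param start A \code{"pose"} to refine.
#' @param receptor,mobile Structures.
#' @param restraints Restraints resolved against the two bodies' chains.
#' @param satisfaction_threshold Stopping threshold on the satisfied
#'   fraction (default 0.90; convergence requires strictly greater).
#' @param saxs_target Optional \code{"saxs_curve"} gating refinement.
#' @param max_iterations Iteration cap (default 25).
#' @param clash_params See \code{\link{default_clash_params}}.
#' @param max_evals Local-refinement evaluation cap per iteration.
#' @return List of class \code{"refinement_result"}: \code{assembly} (final
#'   two-body assembly, receptor chain labels preserved), \code{pose},
#'   \code{n_iterations}, \code{satisfaction}, \code{stop_reason},
#'   \code{distances} (per restraint), \code{weights} (final restraint
#'   weights), \code{chi2} (per-iteration, if a SAXS target was given).
#' @export
iterative_refine <- function(start, receptor, mobile, restraints,
                             satisfaction_threshold = 0.90,
                             saxs_target = NULL, max_iterations = 25,
                             clash_params = default_clash_params(),
                             max_evals = 400) {
  ctx <- .docking_context(receptor, mobile, restraints, clash_params)
  weights <- restraints$weight
  pose <- if (inherits(start, "pose")) start else
    .make_pose(start, .context_energy(ctx, start, weights))

  restraint_distances <- function(tr) {
    m <- apply_transform(ctx$mob_ca, tr)
    rs <- ctx$restraints
    d <- numeric(nrow(rs))
    d[ctx$inter] <- sqrt(rowSums(
      (ctx$rec_ca[ctx$ri + 1L, , drop = FALSE] -
         m[ctx$mi + 1L, , drop = FALSE])^2))
    for (k in ctx$intra) {
      key_a <- .res_key(rs$chain_a[k], rs$res_a[k])
      key_b <- .res_key(rs$chain_b[k], rs$res_b[k])
      src <- if (key_a %in% rownames(ctx$rec_ca)) ctx$rec_ca else ctx$mob_ca
      d[k] <- sqrt(sum((src[key_a, ] - src[key_b, ])^2))
    }
    d
  }
  model_chi2 <- function(tr) {
    asm <- new_assembly(list(receptor = receptor, mobile = mobile),
                        transforms = list(receptor = transform_identity(),
                                          mobile = tr),
                        roles = c(receptor = "receptor", mobile = "mobile"))
    chi_square(debye_profile(asm, saxs_target$s), saxs_target)
  }

  halve_worst <- function(w, d) {
    viol <- d - ctx$restraints$upper
    k <- which.max(viol)
    w[k] <- w[k] * 0.5
    w
  }

  chi2_trace <- numeric(0)
  chi2_prev <- if (!is.null(saxs_target)) model_chi2(pose$transform) else NA
  stop_reason <- "max_iterations"
  n_iter <- 0L
  for (it in seq_len(max_iterations)) {
    n_iter <- it
    cand <- .make_pose_refined(ctx, pose$transform, weights, max_evals)
    accept <- TRUE
    if (!is.null(saxs_target)) {
      chi2_new <- model_chi2(cand$transform)
      # SAXS gate: a move that degrades the scattering fit by > 20% is
      # rejected and the current pose kept
      if (chi2_new > 1.2 * chi2_prev) accept <- FALSE else chi2_prev <- chi2_new
      chi2_trace <- c(chi2_trace, chi2_prev)
    }
    if (accept) pose <- cand
    d <- restraint_distances(pose$transform)
    frac <- mean(d <= ctx$restraints$upper)
    if (frac > satisfaction_threshold) {
      stop_reason <- "converged_satisfaction"
      break
    }
    weights <- halve_worst(weights, d)
  }

  d <- restraint_distances(pose$transform)
  frac <- mean(d <= ctx$restraints$upper)
  asm <- new_assembly(list(receptor = receptor, mobile = mobile),
                      transforms = list(receptor = transform_identity(),
                                        mobile = pose$transform),
                      roles = c(receptor = "receptor", mobile = "mobile"))
  out <- list(assembly = asm, pose = pose, n_iterations = n_iter,
              satisfaction = frac, stop_reason = stop_reason,
              distances = d, weights = weights,
              chi2 = if (is.null(saxs_target)) NULL else chi2_trace)
  class(out) <- "refinement_result"
  out
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: %s after %d iteration(s), %.0f%% satisfied\n",
              x$stop_reason, x$n_iterations, 100 * x$satisfaction))
  invisible(x)
}

#' Dock and refine in one call
#'
#' Convenience wrapper: \code{\link{sample_poses}} followed by
#' \code{\link{iterative_refine}} of the top-ranked pose. With
#' \code{compare_flipped = TRUE} the receptor is additionally rotated 180
#' degrees about its centroid x-axis and re-docked, and both results are
#' returned for comparison.
#'
#' @inheritParams sample_poses
#' @inheritParams iterative_refine
#' @param compare_flipped Also dock against the flipped receptor.
#' @return A \code{"refinement_result"}; with \code{compare_flipped}, a list
#'   with elements \code{standard} and \code{flipped}.
#' @export
dock <- function(receptor, mobile, restraints, n_starts = 512, seed = 2017,
                 satisfaction_threshold = 0.90, saxs_target = NULL,
                 max_iterations = 25,
                 clash_params = default_clash_params(),
                 compare_flipped = FALSE) {
  run_one <- function(rec) {
    poses <- sample_poses(rec, mobile, restraints, n_starts = n_starts,
                          seed = seed, clash_params = clash_params)
    iterative_refine(poses[[1]], rec, mobile, restraints,
                     satisfaction_threshold = satisfaction_threshold,
                     saxs_target = saxs_target,
                     max_iterations = max_iterations,
                     clash_params = clash_params)
  }
  res <- run_one(receptor)
  if (!compare_flipped) return(res)
  ctr <- colMeans(ca_matrix(receptor))
  R <- rotation_from_axis_angle(c(pi, 0, 0))
  flip <- rigid_transform(R, ctr - as.numeric(R %*% ctr))
  list(standard = res, flipped = run_one(apply_transform(receptor, flip)))
}
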