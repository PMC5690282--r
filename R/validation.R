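# Orthogonal validation computations: solvent-accessible surface areas and
# buried interfaces, native-MS stoichiometry inference, NSAF stoichiometry
# estimates, and the consolidated model-quality report.

# Bondi-style van der Waals radii (Angstrom), fixed so results are
# reproducible across environments
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, FE = 2.00, ZN = 1.39, MG = 1.73)

# deterministic quasi-uniform sphere point set (Fibonacci spiral); no
# randomness, so SASA is reproducible for fixed n_points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with a deterministic spiral point set. Atom radii
#' come from a built-in Bondi-style table keyed on element; individual
#' elements can be overridden (e.g. \code{radii = c(C = 3.0)} to treat
#' Calpha-only models as inflated pseudo-atoms).
#'
#' @param x A structure or assembly.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960).
#' @param radii Named per-element radius overrides (Angstrom).
#' @return List of class \code{"sasa_result"}: \code{area} (per-atom, A^2),
#'   \code{total}, \code{probe}, \code{n_points}.
#' @export
sasa <- function(x, probe = 1.4, n_points = 960, radii = NULL) {
  st <- if (inherits(x, "assembly")) flatten_assembly(x) else x
  rtab <- .vdw_radii
  if (!is.null(radii)) rtab[names(radii)] <- radii
  el <- toupper(st$element)
  unknown <- setdiff(unique(el), names(rtab))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  r <- as.numeric(rtab[el]) + probe
  xyz <- as.matrix(st[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour search radius: two largest augmented radii
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + rmax)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dd <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dd >= r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  out <- list(area = area, total = sum(area), probe = probe,
              n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A)\n",
              x$total, length(x$area), x$probe))
  invisible(x)
}

#' Buried interface area between two parts of an assembly
#'
#' Computed as (SASA(A) + SASA(B) - SASA(A+B)) / 2 with a 1.4 Angstrom
#' probe by default; symmetric in its arguments by construction.
#'
#' @param assembly An assembly.
#' @param part_a,part_b Disjoint sets of component labels.
#' @param ... Passed to \code{\link{sasa}} (probe, n_points, radii).
#' @return Buried area in A^2.
#' @export
interface_area <- function(assembly, part_a, part_b, ...) {
  if (length(intersect(part_a, part_b))) {
    stop("parts must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(part_a, part_b), names(assembly$components))
  if (length(missing)) stop("unknown component(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  sub_assembly <- function(labs) {
    new_assembly(assembly$components[labs], assembly$transforms[labs],
                 assembly$roles[labs])
  }
  a <- sasa(sub_assembly(part_a), ...)$total
  b <- sasa(sub_assembly(part_b), ...)$total
  ab <- sasa(sub_assembly(c(part_a, part_b)), ...)$total
  (a + b - ab) / 2
}

#' Infer complex stoichiometry from subunit masses
#'
#' Exhaustive search over integer copy-number vectors in
#' [0, max_copies]^k for combinations whose summed mass matches the
#' observed complex mass within tolerance.
#'
#' @param component_masses Named numeric vector of subunit masses (Da).
#' @param complex_mass Observed complex mass (Da).
#' @param tolerance Mass tolerance (Da).
#' @param max_copies Per-component copy-number cap (default 4).
#' @return Data frame of class \code{"stoichiometry_solutions"} with one
#'   column per component plus \code{predicted_mass} and \code{residual}
#'   (Da, signed: predicted - observed), sorted by |residual|; zero rows if
#'   no combination fits.
#' @export
infer_stoichiometry <- function(component_masses, complex_mass, tolerance = 2,
                                max_copies = 4) {
  if (any(component_masses <= 0)) stop("masses must be positive",
                                       call. = FALSE)
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  k <- length(component_masses)
  grid <- do.call(expand.grid, replicate(k, 0:max_copies, simplify = FALSE))
  names(grid) <- names(component_masses)
  pred <- as.matrix(grid) %*% component_masses
  resid <- as.numeric(pred) - complex_mass
  keep <- abs(resid) <= tolerance & rowSums(grid) > 0
  out <- grid[keep, , drop = FALSE]
  out$predicted_mass <- as.numeric(pred)[keep]
  out$residual <- resid[keep]
  out <- out[order(abs(out$residual)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stoichiometry_solutions", "data.frame")
  out
}

#' Normalized spectral abundance factors
#'
#' NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j): spectral counts normalized
#' by protein length, then across the table so values sum to one.
#'
#' @param counts Data frame with columns \code{protein}, \code{spectral_count},
#'   \code{length} (residues), or a named list of \code{c(count, length)}.
#' @return Data frame of class \code{"nsaf_table"} with columns
#'   \code{protein}, \code{spectral_count}, \code{length}, \code{nsaf}.
#' @export
nsaf <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- data.frame(
      protein = names(counts),
      spectral_count = vapply(counts, `[`, 0.0, 1),
      length = vapply(counts, `[`, 0.0, 2),
      stringsAsFactors = FALSE)
  }
  if (any(counts$length <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(counts$spectral_count < 0)) stop("negative spectral count",
                                           call. = FALSE)
  saf <- counts$spectral_count / counts$length
  if (sum(saf) == 0) stop("all spectral counts are zero", call. = FALSE)
  counts$nsaf <- saf / sum(saf)
  rownames(counts) <- NULL
  class(counts) <- c("nsaf_table", "data.frame")
  counts
}

#' Consolidated model-quality report
#'
#' Collects the refinement outcome and any available orthogonal validation
#' metrics into one JSON-serializable document. Absent sections are
#' explicit nulls. Deterministic: regenerating from the same inputs gives
#' byte-identical JSON (no timestamps).
#'
#' @param refinement A \code{"refinement_result"} (required).
#' @param satisfaction Optional \code{"satisfaction_report"}.
#' @param saxs Optional list of SAXS results (e.g. Guinier, Porod, chi2).
#' @param hdx Optional interface-enrichment result.
#' @param interface_areas Optional named numeric vector of buried areas.
#' @param config Optional configuration echo (seeds, cutoffs).
#' @param path Optional output path; when given, JSON is written there.
#' @return The report as a list (invisibly when written to a file).
#' @export
quality_report <- function(refinement, satisfaction = NULL, saxs = NULL,
                           hdx = NULL, interface_areas = NULL,
                           config = NULL, path = NULL) {
  if (!inherits(refinement, "refinement_result")) {
    stop("refinement must be a refinement_result", call. = FALSE)
  }
  report <- list(
    software = list(package = "intmod",
                    version = as.character(utils::packageVersion("intmod"))),
    refinement = list(
      stop_reason = refinement$stop_reason,
      n_iterations = refinement$n_iterations,
      satisfaction = refinement$satisfaction,
      score_total = refinement$pose$score_total,
      score_restraint = refinement$pose$score_restraint,
      score_clash = refinement$pose$score_clash,
      restraint_distances = refinement$distances,
      restraint_weights = refinement$weights,
      chi2_trace = refinement$chi2
    ),
    satisfaction = if (is.null(satisfaction)) NULL else list(
      n_satisfied = satisfaction$n_satisfied,
      n_total = satisfaction$n_total,
      fraction = satisfaction$fraction,
      distances = satisfaction$per_restraint$distance
    ),
    saxs = saxs,
    hdx = hdx,
    interface_areas = as.list(interface_areas),
    config = config
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}
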