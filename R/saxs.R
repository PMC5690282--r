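# Small-angle X-ray scattering: Debye profiles from coordinates, Guinier
# fitting, regularized indirect Fourier transform to P(r), Porod volume and
# molecular mass, and chi-square model-vs-data comparison.
#
# Momentum transfer convention throughout: s = 4*pi*sin(theta)/lambda in
# 1/Angstrom (use convert_q_nm() for data recorded as q in 1/nm).

#' Construct a SAXS curve
#'
#' @param s Momentum transfer grid (1/Angstrom), strictly increasing, >= 0.
#' @param intensity Intensities (arbitrary units).
#' @param sigma Optional per-point uncertainties (> 0).
#' @return Data frame of class \code{"saxs_curve"}.
#' @export
saxs_curve <- function(s, intensity, sigma = NULL) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) != length(intensity)) stop("s and intensity lengths differ")
  if (any(s < 0) || any(diff(s) <= 0)) {
    stop("s must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("non-finite intensity", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be positive and finite", call. = FALSE)
    }
  }
  df <- data.frame(s = s, intensity = intensity)
  if (!is.null(sigma)) df$sigma <- sigma
  class(df) <- c("saxs_curve", "data.frame")
  df
}

#' Read a 3-column SAXS curve file
#'
#' Whitespace-delimited columns s, I, sigma (sigma optional); lines starting
#' with \code{#} are comments. \code{convert_q_nm = TRUE} converts an s grid
#' recorded as q in 1/nm to 1/Angstrom (divide by 10).
#'
#' @param path File path.
#' @param convert_q_nm Convert from 1/nm on input.
#' @return A \code{"saxs_curve"}.
#' @export
read_saxs <- function(path, convert_q_nm = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & trimws(lines) != ""]
  m <- utils::read.table(text = lines)
  s <- m[[1]]
  if (convert_q_nm) s <- s / 10
  saxs_curve(s, m[[2]], if (ncol(m) >= 3) m[[3]] else NULL)
}

#' Write a SAXS curve to a 3-column text file
#' @param curve A \code{"saxs_curve"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_saxs <- function(curve, path) {
  sig <- if (!is.null(curve$sigma)) curve$sigma else rep(NA, nrow(curve))
  writeLines(c("# s intensity sigma",
               sprintf("%.9g %.9g %.9g", curve$s, curve$intensity, sig)),
             path)
  invisible(path)
}

# electron counts per residue (including average side chain; used as dummy
# scatterer weights for one bead per Calpha)
.residue_electrons <- c(
  ALA = 38, ARG = 85, ASN = 60, ASP = 59, CYS = 54, GLN = 68, GLU = 67,
  GLY = 30, HIS = 72, ILE = 62, LEU = 62, LYS = 71, MET = 70, PHE = 78,
  PRO = 52, SER = 46, THR = 54, TRP = 98, TYR = 86, VAL = 54)

#' Per-residue scattering weights for a structure
#'
#' One dummy scatterer per Calpha, weighted by the residue's electron count
#' (unknown residue names fall back to the mean amino-acid value).
#'
#' @param structure A structure or assembly.
#' @return List with \code{coords} (Calpha matrix) and \code{weights}.
#' @export
scattering_beads <- function(structure) {
  st <- if (inherits(structure, "assembly")) flatten_assembly(structure) else
    structure
  ca <- st[st$atom == "CA", , drop = FALSE]
  w <- .residue_electrons[ca$resname]
  w[is.na(w)] <- mean(.residue_electrons)
  list(coords = as.matrix(ca[, c("x", "y", "z")]), weights = as.numeric(w))
}

#' Theoretical scattering profile by the Debye equation
#'
#' I(s) = sum_i sum_j f_i f_j sin(s r_ij)/(s r_ij), with the sinc term taken
#' as 1 at s = 0. Invariant under rigid transforms and point permutations;
#' I(0) equals (sum f)^2.
#'
#' @param coords n x 3 coordinate matrix (or a structure/assembly, in which
#'   case per-residue bead weights are used).
#' @param s_grid Momentum transfer grid (1/Angstrom).
#' @param weights Per-point scattering weights (default 1).
#' @return A \code{"saxs_curve"}.
#' @export
debye_profile <- function(coords, s_grid, weights = NULL) {
  if (inherits(coords, "structure3d") || inherits(coords, "assembly")) {
    bd <- scattering_beads(coords)
    coords <- bd$coords
    if (is.null(weights)) weights <- bd$weights
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) stop("empty coordinate set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  d <- as.matrix(stats::dist(coords))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  rij <- d[ij]
  fij <- weights[ij[, 1]] * weights[ij[, 2]]
  self <- sum(weights^2)
  I <- vapply(s_grid, function(s) {
    if (s == 0) return(self + 2 * sum(fij))
    x <- s * rij
    self + 2 * sum(fij * sin(x) / x)
  }, 0.0)
  saxs_curve(s_grid, I)
}

#' Guinier fit of the low-angle region
#'
#' Linear fit of ln I versus s^2 over the longest low-s window satisfying
#' s * Rg <= \code{sRg_limit}, iterated to self-consistency (the window is
#' recomputed from the fitted Rg until stable, at most 20 iterations).
#'
#' @param curve A \code{"saxs_curve"}.
#' @param sRg_limit Guinier validity limit (default 1.3).
#' @param min_points Minimum number of points in the fit window.
#' @return List of class \code{"guinier_result"}: \code{Rg}, \code{I0},
#'   \code{s_min}, \code{s_max}, \code{sRg_max}, \code{n_points},
#'   \code{residual} (RMS of ln-I residuals).
#' @export
guinier_fit <- function(curve, sRg_limit = 1.3, min_points = 10) {
  s <- curve$s; I <- curve$intensity
  pos <- s > 0
  s <- s[pos]; I <- I[pos]
  if (length(s) < min_points) stop("too few points for Guinier fit",
                                   call. = FALSE)
  fit_window <- function(n_use) {
    si <- s[seq_len(n_use)]; Ii <- I[seq_len(n_use)]
    if (any(Ii <= 0)) stop("non-positive intensities in Guinier window",
                           call. = FALSE)
    s2 <- si^2
    co <- stats::coef(stats::lm(log(Ii) ~ s2))
    if (co[2] >= 0) return(NULL)  # no decay: not a Guinier regime
    list(Rg = sqrt(-3 * unname(co[2])), I0 = exp(unname(co[1])))
  }
  n_use <- min(length(s), max(min_points, 20L))
  fit <- fit_window(n_use)
  if (is.null(fit)) stop("no convergent Guinier window", call. = FALSE)
  for (it in seq_len(20L)) {
    n_new <- max(min_points, sum(s * fit$Rg <= sRg_limit))
    n_new <- min(n_new, length(s))
    if (n_new == n_use) break
    n_use <- n_new
    fit2 <- fit_window(n_use)
    if (is.null(fit2)) break
    fit <- fit2
  }
  si <- s[seq_len(n_use)]; Ii <- I[seq_len(n_use)]
  pred <- log(fit$I0) - si^2 * fit$Rg^2 / 3
  out <- list(Rg = fit$Rg, I0 = fit$I0, s_min = si[1], s_max = si[n_use],
              sRg_max = si[n_use] * fit$Rg, n_points = n_use,
              residual = sqrt(mean((log(Ii) - pred)^2)))
  class(out) <- "guinier_result"
  out
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f A, I(0) = %.4g (%d pts, sRg_max %.2f)\n",
              x$Rg, x$I0, x$n_points, x$sRg_max))
  invisible(x)
}

#' Indirect Fourier transform to the pair-distance distribution P(r)
#'
#' Solves for p(r) on [0, Dmax] minimizing
#' ||(I_model - I)/sigma||^2 + alpha ||p''||^2 subject to p >= 0 and
#' p(0) = p(Dmax) = 0, where I_model(s) = 4 pi int p(r) sinc(s r) dr.
#' When \code{alpha = NULL} the regularization weight is chosen by an
#' L-curve scan over a 13-point log grid (1e-4 .. 1e2), taking the corner of
#' maximum curvature.
#'
#' @param curve A \code{"saxs_curve"}.
#' @param Dmax Maximum particle dimension (Angstrom).
#' @param n_r Number of r-grid intervals (default 80).
#' @param alpha Regularization weight, or \code{NULL} for automatic choice.
#' @return List of class \code{"pr_curve"}: \code{r}, \code{p}, \code{Dmax},
#'   \code{Rg}, \code{I0}, \code{alpha}, \code{residual} (mean squared
#'   weighted data misfit).
#' @export
pr_transform <- function(curve, Dmax, n_r = 80, alpha = NULL) {
  if (Dmax <= 0) stop("Dmax must be positive", call. = FALSE)
  s <- curve$s; I <- curve$intensity
  sig <- if (!is.null(curve$sigma)) curve$sigma else rep(1, length(s))
  r <- seq(0, Dmax, length.out = n_r + 1L)
  dr <- r[2] - r[1]
  inner <- 2:n_r                       # p fixed to 0 at both endpoints
  ri <- r[inner]
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  A <- 4 * pi * dr * outer(s, ri, function(ss, rr) sinc(ss * rr))
  Aw <- A / sig
  Iw <- I / sig
  # second-difference operator on the inner grid, with the zero boundary
  # values folded in so smoothness is enforced up to the endpoints
  m <- length(inner)
  D <- matrix(0, m, m)
  for (k in seq_len(m)) {
    D[k, k] <- -2
    if (k > 1) D[k, k - 1] <- 1
    if (k < m) D[k, k + 1] <- 1
  }
  D <- D / dr^2
  AtA <- crossprod(Aw); Atb <- crossprod(Aw, Iw); DtD <- crossprod(D)

  solve_alpha <- function(a) {
    H <- AtA + a * DtD
    obj <- function(p) {
      resid <- Aw %*% p - Iw
      sum(resid^2) + a * sum((D %*% p)^2)
    }
    grad <- function(p) as.numeric(2 * (H %*% p - Atb))
    p0 <- rep(max(mean(I), 1e-6) / (4 * pi * Dmax), m)
    fit <- tryCatch(
      stats::optim(p0, obj, grad, method = "L-BFGS-B", lower = 0,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) stop("ill-conditioned P(r) system at alpha = ", a,
                               "; try alpha in [1e-4, 1e2]", call. = FALSE))
    p <- fit$par
    list(p = p, misfit = sum((Aw %*% p - Iw)^2),
         rough = sum((D %*% p)^2))
  }

  if (is.null(alpha)) {
    grid <- 10^seq(-4, 2, length.out = 13)
    sols <- lapply(grid, solve_alpha)
    lx <- log10(vapply(sols, `[[`, 0.0, "misfit") + 1e-300)
    ly <- log10(vapply(sols, `[[`, 0.0, "rough") + 1e-300)
    # discrete curvature of the L-curve; endpoints excluded
    curv <- rep(-Inf, length(grid))
    for (k in 2:(length(grid) - 1L)) {
      x1 <- lx[k] - lx[k - 1]; y1 <- ly[k] - ly[k - 1]
      x2 <- lx[k + 1] - lx[k]; y2 <- ly[k + 1] - ly[k]
      num <- x1 * y2 - y1 * x2
      den <- (x1^2 + y1^2)^0.75 * (x2^2 + y2^2)^0.75
      curv[k] <- if (den > 0) num / den else -Inf
    }
    k_best <- which.max(curv)
    alpha <- grid[k_best]
    sol <- sols[[k_best]]
  } else {
    sol <- solve_alpha(alpha)
  }
  p_full <- c(0, sol$p, 0)
  ip <- sum(p_full) * dr
  if (ip <= 0) stop("P(r) integrates to zero; data inconsistent with Dmax",
                    call. = FALSE)
  Rg <- sqrt(sum(r^2 * p_full) * dr / (2 * ip))
  out <- list(r = r, p = p_full, Dmax = Dmax, Rg = Rg, I0 = 4 * pi * ip,
              alpha = alpha, residual = sol$misfit / length(s))
  class(out) <- "pr_curve"
  out
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("P(r): Dmax = %.1f A, Rg = %.2f A, I(0) = %.4g (alpha %.3g)\n",
              x$Dmax, x$Rg, x$I0, x$alpha))
  invisible(x)
}

#' Porod volume and molecular mass
#'
#' Given a curve, the Porod volume is V = 2 pi^2 I(0) / Q with the Porod
#' invariant Q = int s^2 (I(s) - B) ds over the measured range; the constant
#' background B is estimated from the high-s tail by a linear fit of
#' I s^4 = K + B s^4. I(0) is taken from a Guinier fit. Given a volume
#' directly, only the mass conversion is applied:
#' mass (kDa) = volume (A^3) / conversion.
#'
#' @param curve_or_volume A \code{"saxs_curve"} or a numeric volume in A^3.
#' @param conversion Volume-to-mass factor, A^3 per kDa (default 1.7e3).
#' @param tail_fraction Fraction of the s range (highest s) used for the
#'   background fit (default 0.2).
#' @return List of class \code{"porod_result"}: \code{porod_volume},
#'   \code{molecular_mass} (kDa), \code{conversion}, and for curve input
#'   \code{Q} and \code{background}.
#' @export
porod_mass <- function(curve_or_volume, conversion = 1.7e3,
                       tail_fraction = 0.2) {
  if (is.numeric(curve_or_volume)) {
    vol <- curve_or_volume
    out <- list(porod_volume = vol, molecular_mass = vol / conversion,
                conversion = conversion, Q = NA_real_,
                background = NA_real_)
    class(out) <- "porod_result"
    return(out)
  }
  curve <- curve_or_volume
  s <- curve$s; I <- curve$intensity
  tail <- s >= stats::quantile(s, 1 - tail_fraction)
  ytail <- I[tail] * s[tail]^4
  xtail <- s[tail]^4
  co <- stats::coef(stats::lm(ytail ~ xtail))
  B <- max(unname(co[2]), 0)  # constant background; never subtract below zero
  integrand <- s^2 * (I - B)
  Q <- sum(diff(s) * (integrand[-1] + integrand[-length(s)]) / 2)
  if (Q <= 0) stop("negative Porod invariant after background subtraction",
                   call. = FALSE)
  I0 <- guinier_fit(curve)$I0
  vol <- 2 * pi^2 * I0 / Q
  out <- list(porod_volume = vol, molecular_mass = vol / conversion,
              conversion = conversion, Q = Q, background = B)
  class(out) <- "porod_result"
  out
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("Porod: V = %.0f A^3 -> %.2f kDa (factor %.3g A^3/kDa)\n",
              x$porod_volume, x$molecular_mass, x$conversion))
  invisible(x)
}

#' Reduced chi-square between a model and an experimental curve
#'
#' chi^2 = 1/(N-1) sum ((c I_model - I_exp)/sigma)^2 with the scale factor c
#' chosen in closed form to minimize chi^2. The model is linearly
#' interpolated onto the experimental grid. A missing sigma column falls
#' back to unit weights with a warning.
#'
#' @param model_curve,experimental \code{"saxs_curve"} objects.
#' @return Non-negative chi-square value (0 iff proportional).
#' @export
chi_square <- function(model_curve, experimental) {
  Im <- stats::approx(model_curve$s, model_curve$intensity,
                      xout = experimental$s, rule = 2)$y
  Ie <- experimental$intensity
  if (is.null(experimental$sigma)) {
    warning("experimental curve has no sigma; using unit weights")
    sig <- rep(1, length(Ie))
  } else {
    sig <- experimental$sigma
  }
  w <- 1 / sig^2
  cc <- sum(w * Im * Ie) / sum(w * Im^2)
  sum(w * (cc * Im - Ie)^2) / (length(Ie) - 1)
}
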