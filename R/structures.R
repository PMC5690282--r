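# Structure I/O and rigid-body geometry: the coordinate substrate for
# restraint evaluation, docking and scattering calculations.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 fixed columns) into a structure
#' object. Author chain identifiers, author residue numbers and insertion
#' codes are preserved verbatim; they are the single residue coordinate
#' system used throughout the package.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only \code{"pdb"} is supported.
#' @return An object of class \code{"structure3d"}: a data frame with one row
#'   per atom and columns \code{chain}, \code{resno}, \code{inscode},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{occ}, \code{b}. The structure id is carried in
#'   \code{attr(x, "id")}.
#' @export
read_structure <- function(path, format = "pdb") {
  if (!identical(format, "pdb")) {
    stop("unknown format: ", format, call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("unreadable file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  fx <- function(a, b) trimws(substr(lines, a, b))
  atom    <- fx(13, 16)
  resname <- fx(18, 20)
  chain   <- substr(lines, 22, 22)
  resno   <- suppressWarnings(as.integer(fx(23, 26)))
  inscode <- trimws(substr(lines, 27, 27))
  x <- as.numeric(fx(31, 38))
  y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  b   <- suppressWarnings(as.numeric(fx(61, 66)))
  element <- fx(77, 78)
  # fall back to first letter of the atom name when the element field is blank
  blank <- element == ""
  element[blank] <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", atom[blank]))
  element[blank] <- substr(element[blank], 1, 1)
  element <- toupper(element)
  if (anyNA(resno)) stop("unparseable residue number in ", path, call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(z) || any(!is.finite(c(x, y, z)))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  occ[is.na(occ)] <- 1
  b[is.na(b)] <- 0
  st <- data.frame(
    chain = chain, resno = resno, inscode = inscode, resname = resname,
    atom = atom, element = element, x = x, y = y, z = z, occ = occ, b = b,
    stringsAsFactors = FALSE
  )
  new_structure(st, id = sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a structure object from an atom table
#'
#' @param atoms Data frame with at least \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}; \code{inscode}, \code{occ} and \code{b} are filled with
#'   defaults when absent.
#' @param id Structure label.
#' @return A \code{"structure3d"} object.
#' @export
new_structure <- function(atoms, id = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("structure has zero atoms", call. = FALSE)
  if (is.null(atoms$inscode)) atoms$inscode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  need <- c("chain", "resno", "inscode", "resname", "atom", "element",
            "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  atoms <- atoms[, need]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  class(atoms) <- c("structure3d", "data.frame")
  attr(atoms, "id") <- id
  atoms
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d atoms, %d chains (%s)\n",
              attr(x, "id"), nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written with three decimals; re-reading the file yields an
#' equivalent structure (same chains, residue numbering, coordinates to 1e-3).
#'
#' @param structure A \code{"structure3d"} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(structure, path) {
  if (!inherits(structure, "structure3d")) structure <- new_structure(structure)
  if (nrow(structure) == 0L) stop("empty structure", call. = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("unwritable path: ", path, call. = FALSE))
  on.exit(close(con))
  nm <- structure$atom
  # PDB atom-name alignment: names shorter than 4 chars start in column 14
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(structure)) %% 100000L, nm4, structure$resname,
    structure$chain, structure$resno,
    ifelse(structure$inscode == "", " ", structure$inscode),
    structure$x, structure$y, structure$z, structure$occ, structure$b,
    structure$element)
  writeLines(c(lines, "END"), con)
  invisible(path)
}

# residue key used for all lookups: chain|resno|inscode
.res_key <- function(chain, resno, inscode = "") {
  paste(chain, resno, inscode, sep = "|")
}

#' Look up a Cα atom
#'
#' @param structure A structure.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param inscode Insertion code ("" for none).
#' @return Numeric length-3 coordinate vector.
#' @export
ca_coord <- function(structure, chain, resno, inscode = "") {
  i <- which(structure$chain == chain & structure$resno == resno &
             structure$inscode == inscode & structure$atom == "CA")
  if (length(i) == 0L) {
    stop(sprintf("no CA atom for residue %s:%s%s", chain, resno, inscode),
         call. = FALSE)
  }
  if (length(i) > 1L) {
    stop(sprintf("ambiguous CA for residue %s:%s%s", chain, resno, inscode),
         call. = FALSE)
  }
  as.numeric(structure[i, c("x", "y", "z")])
}

#' Cα coordinate matrix of a structure
#'
#' @param structure A structure.
#' @return n x 3 matrix of Cα coordinates, with rownames giving residue keys.
#' @export
ca_matrix <- function(structure) {
  ca <- structure[structure$atom == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- .res_key(ca$chain, ca$resno, ca$inscode)
  m
}

#' Cα–Cα distance between two residues
#'
#' Distances are measured in the current (transformed) coordinates; for an
#' assembly, component transforms are applied first.
#'
#' @param x A structure or assembly.
#' @param site_a,site_b Sites as \code{c(chain, resno)} (residue number may be
#'   given as a string or integer).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(x, site_a, site_b) {
  st <- if (inherits(x, "assembly")) flatten_assembly(x) else x
  a <- ca_coord(st, as.character(site_a[1]), as.integer(site_a[2]))
  b <- ca_coord(st, as.character(site_b[1]), as.integer(site_b[2]))
  sqrt(sum((a - b)^2))
}

## ---- rigid transforms -------------------------------------------------

#' Create a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation in Angstrom.
#' @return A \code{"rigid_transform"} object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must be length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity transform
#' @return The identity \code{"rigid_transform"}.
#' @export
transform_identity <- function() rigid_transform()

#' Compose two rigid transforms (apply \code{b} first, then \code{a})
#' @param a,b Rigid transforms.
#' @return Their composition as a \code{"rigid_transform"}.
#' @export
transform_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tr A rigid transform.
#' @return The inverse transform.
#' @export
transform_inverse <- function(tr) {
  rigid_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Apply a rigid transform to coordinates
#'
#' @param x An n x 3 coordinate matrix or a structure.
#' @param tr A rigid transform.
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, tr) {
  if (inherits(x, "structure3d")) {
    m <- as.matrix(x[, c("x", "y", "z")])
    m <- m %*% t(tr$rotation)
    x$x <- m[, 1] + tr$translation[1]
    x$y <- m[, 2] + tr$translation[2]
    x$z <- m[, 3] + tr$translation[3]
    return(x)
  }
  m <- as.matrix(x)
  sweep(m %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Rotation matrix from an axis-angle vector
#'
#' The rotation angle is the Euclidean norm of \code{w} (radians); \code{w}
#' of norm 0 gives the identity.
#'
#' @param w Length-3 axis-angle vector.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniform random rotation matrix
#'
#' Uniform over SO(3) via quaternion sampling (Shoemake). Uses the current
#' RNG stream.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Kabsch superposition of two point sets
#'
#' Finds the rigid transform minimizing the RMSD between \code{mobile} (after
#' transformation) and \code{reference}.
#'
#' @param mobile,reference n x 3 matrices of paired points, n >= 3.
#' @return List with \code{transform} (a \code{"rigid_transform"}) and
#'   \code{rmsd} (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("point sets must be equal-size n x 3 matrices", call. = FALSE)
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  sv <- svd(crossprod(A, B))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) point set", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t)
  diff <- apply_transform(mobile, tr) - reference
  list(transform = tr, rmsd = sqrt(sum(diff^2) / n))
}

#' Radius of gyration of a point set
#'
#' @param coords n x 3 coordinate matrix.
#' @param weights Optional per-point masses (default uniform).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty point set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  w <- weights / sum(weights)
  ctr <- colSums(coords * w)
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  sqrt(sum(w * d2))
}

## ---- assemblies -------------------------------------------------------

#' Build an assembly of rigid components
#'
#' An assembly is an ordered list of components, each a structure carried
#' with a rigid transform mapping its stored coordinates into the common
#' assembly frame. Exactly one component may be tagged \code{"mobile"} in a
#' two-body docking problem; the rest are \code{"receptor"}.
#'
#' @param components Named list of structures.
#' @param transforms Optional named list of rigid transforms (default
#'   identity).
#' @param roles Optional named character vector of roles
#'   (\code{"receptor"}/\code{"mobile"}).
#' @return An \code{"assembly"} object.
#' @export
new_assembly <- function(components, transforms = NULL, roles = NULL) {
  labels <- names(components)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == "")) {
    stop("components must be uniquely named", call. = FALSE)
  }
  if (is.null(transforms)) {
    transforms <- stats::setNames(
      replicate(length(labels), transform_identity(), simplify = FALSE), labels)
  }
  if (is.null(roles)) {
    roles <- stats::setNames(rep("receptor", length(labels)), labels)
  }
  if (sum(roles == "mobile") > 1L) {
    stop("at most one component may be tagged mobile", call. = FALSE)
  }
  structure(list(components = components, transforms = transforms,
                 roles = roles), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("assembly: %d components (%s)\n", length(x$components),
              paste(names(x$components), x$roles, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Component structure in assembly-frame coordinates
#' @param assembly An assembly.
#' @param label Component label.
#' @return The component's structure with its transform applied.
#' @export
component_structure <- function(assembly, label) {
  apply_transform(assembly$components[[label]], assembly$transforms[[label]])
}

#' Flatten an assembly to a single structure
#'
#' Component transforms are applied; chain labels are deduplicated
#' deterministically: components keep their labels in order, and a chain
#' label already used by an earlier component is remapped to the first unused
#' letter (A–Z, then a–z, 0–9).
#'
#' @param assembly An assembly.
#' @return A single \code{"structure3d"}.
#' @export
flatten_assembly <- function(assembly) {
  pool <- c(LETTERS, letters, as.character(0:9))
  used <- character(0)
  out <- vector("list", length(assembly$components))
  for (i in seq_along(assembly$components)) {
    st <- component_structure(assembly, names(assembly$components)[i])
    for (ch in unique(st$chain)) {
      if (ch %in% used) {
        new <- setdiff(pool, used)[1]
        if (is.na(new)) stop("chain label pool exhausted", call. = FALSE)
        st$chain[st$chain == ch] <- new
        used <- c(used, new)
      } else {
        used <- c(used, ch)
      }
    }
    out[[i]] <- as.data.frame(st)
  }
  new_structure(do.call(rbind, out), id = "assembly")
}

#' Set the mobile component's transform
#' @param assembly An assembly.
#' @param transform New rigid transform for the mobile component.
#' @return The updated assembly.
#' @export
set_mobile_transform <- function(assembly, transform) {
  lab <- names(assembly$roles)[assembly$roles == "mobile"]
  if (length(lab) != 1L) stop("assembly has no unique mobile component",
                              call. = FALSE)
  assembly$transforms[[lab]] <- transform
  assembly
}
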