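# Cross-linking mass spectrometry: spectrum-match tables, unique-link
# deduplication, chemistry-aware distance restraints and their evaluation.

# default chemistry parameters: BS3 targets the lysine-lysine Calpha-Calpha
# distance distribution (mean 11.4 A) with a community-standard 30 A
# satisfaction cutoff; photo (diazirine) cross-links are short-range.
#' Default cross-link chemistry parameters
#'
#' @return Named list per chemistry with \code{target} and \code{upper_bound}
#'   (Angstrom, Calpha–Calpha).
#' @export
default_chemistry_params <- function() {
  list(
    BS3   = list(target = 11.4, upper_bound = 30.0),
    photo = list(target = 5.0,  upper_bound = 15.0)
  )
}

# normalize unicode minus / dashes and whitespace in numeric tokens
.num <- function(x) {
  x <- gsub("−", "-", x)
  x <- gsub("[–—]", "-", x)
  suppressWarnings(as.numeric(trimws(x)))
}

.parse_residue_token <- function(tok) {
  tok <- trimws(tok)
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1]]
  if (length(m) != 3L) stop("malformed residue token: '", tok, "'",
                            call. = FALSE)
  list(type = toupper(m[2]), resno = as.integer(m[3]))
}

#' Parse a cross-link spectrum-match table
#'
#' Two dialects are supported. \code{"csv"} expects one CSM per row with
#' columns \code{protein_a,residue_a,protein_b,residue_b,score,chemistry}
#' (residues as tokens like \code{"K97"}). \code{"paper_table"} reads the
#' printed three-block layout in which each block is headed by a
#' \code{PROTA-PROTB} line followed by rows
#' \code{residue_a residue_b n_matches highest_score}; each row is expanded
#' into \code{n_matches} CSMs all carrying the row's highest score, so that
#' deduplication recovers both the match count and the per-pair maximum.
#' Unicode minus signs and stray whitespace are tolerated.
#'
#' @param path_or_text File path, or a character vector of table lines.
#' @param dialect \code{"paper_table"} or \code{"csv"}.
#' @param chemistry Chemistry assigned to parsed CSMs when the table does not
#'   carry one (default \code{"BS3"}).
#' @return Data frame of class \code{"csm_table"} with columns
#'   \code{protein_a}, \code{restype_a}, \code{residue_a}, \code{protein_b},
#'   \code{restype_b}, \code{residue_b}, \code{score}, \code{chemistry}.
#' @export
parse_csm_table <- function(path_or_text, dialect = c("paper_table", "csv"),
                            chemistry = "BS3") {
  dialect <- match.arg(dialect)
  lines <- if (length(path_or_text) == 1L && file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  empty <- data.frame(protein_a = character(), restype_a = character(),
                      residue_a = integer(), protein_b = character(),
                      restype_b = character(), residue_b = integer(),
                      score = numeric(), chemistry = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(.as_csm(empty))

  if (dialect == "csv") {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(.as_csm(empty))
    ra <- lapply(as.character(df$residue_a), .parse_residue_token)
    rb <- lapply(as.character(df$residue_b), .parse_residue_token)
    sc <- .num(as.character(df$score))
    if (any(is.na(sc)) || any(sc < 0)) stop("negative or unparseable score",
                                            call. = FALSE)
    chem <- if (!is.null(df$chemistry)) as.character(df$chemistry) else
      rep(chemistry, nrow(df))
    out <- data.frame(
      protein_a = as.character(df$protein_a),
      restype_a = vapply(ra, `[[`, "", "type"),
      residue_a = vapply(ra, `[[`, 0L, "resno"),
      protein_b = as.character(df$protein_b),
      restype_b = vapply(rb, `[[`, "", "type"),
      residue_b = vapply(rb, `[[`, 0L, "resno"),
      score = sc, chemistry = chem, stringsAsFactors = FALSE)
    return(.as_csm(out))
  }

  # paper_table dialect
  prot_a <- prot_b <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (grepl("^\\(", ln)) next                 # "(n unique links)" summary
    if (grepl("^\\*", ln)) next                 # column header line
    toks <- strsplit(ln, "[\t ]+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) == 1L && grepl("^[A-Za-z0-9/]+-[A-Za-z0-9/]+$", toks)) {
      pp <- strsplit(toks, "-", fixed = TRUE)[[1]]
      prot_a <- pp[1]; prot_b <- pp[2]
      next
    }
    if (length(toks) < 4L) next
    if (is.na(prot_a)) stop("data row before any protein-pair header",
                            call. = FALSE)
    ra <- .parse_residue_token(toks[1])
    rb <- .parse_residue_token(toks[2])
    nm <- as.integer(.num(toks[3]))
    sc <- .num(toks[4])
    if (is.na(sc) || sc < 0) stop("negative or unparseable score in row: ", ln,
                                  call. = FALSE)
    if (is.na(nm) || nm < 1L) stop("bad match count in row: ", ln,
                                   call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_a = prot_a, restype_a = ra$type, residue_a = ra$resno,
      protein_b = prot_b, restype_b = rb$type, residue_b = rb$resno,
      score = sc, chemistry = chemistry, n = nm, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.as_csm(empty))
  df <- do.call(rbind, rows)
  df <- df[rep(seq_len(nrow(df)), df$n), ]     # expand to one row per CSM
  df$n <- NULL
  rownames(df) <- NULL
  .as_csm(df)
}

.as_csm <- function(df) {
  class(df) <- c("csm_table", "data.frame")
  df
}

# canonical unordered pair key for a CSM row
.link_key <- function(df) {
  a <- paste(df$protein_a, sprintf("%06d", df$residue_a), df$restype_a)
  b <- paste(df$protein_b, sprintf("%06d", df$residue_b), df$restype_b)
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  list(key = paste(key_a, key_b, sep = " :: "), swap = swap)
}

#' Collapse spectrum matches to unique residue-pair links
#'
#' Pairs are unordered: swapping the two sites of a CSM yields the same link.
#' Output is sorted by highest score descending, ties broken lexicographically
#' by (protein_a, residue_a, residue_b).
#'
#' @param csms A \code{"csm_table"} data frame.
#' @return Data frame of class \code{"unique_links"} with columns
#'   \code{protein_a}, \code{restype_a}, \code{residue_a}, \code{protein_b},
#'   \code{restype_b}, \code{residue_b}, \code{n_matches},
#'   \code{highest_score}, \code{chemistry}.
#' @export
deduplicate_links <- function(csms) {
  if (nrow(csms) == 0L) {
    out <- data.frame(protein_a = character(), restype_a = character(),
                      residue_a = integer(), protein_b = character(),
                      restype_b = character(), residue_b = integer(),
                      n_matches = integer(), highest_score = numeric(),
                      chemistry = character(), stringsAsFactors = FALSE)
    class(out) <- c("unique_links", "data.frame")
    return(out)
  }
  lk <- .link_key(csms)
  df <- as.data.frame(csms)
  # canonicalize site order
  for (col in c("protein", "restype", "residue")) {
    a <- df[[paste0(col, "_a")]]; b <- df[[paste0(col, "_b")]]
    df[[paste0(col, "_a")]] <- ifelse(lk$swap, b, a)
    df[[paste0(col, "_b")]] <- ifelse(lk$swap, a, b)
  }
  sp <- split(df, lk$key)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(g[1, c("protein_a", "restype_a", "residue_a",
                      "protein_b", "restype_b", "residue_b")],
               n_matches = nrow(g), highest_score = max(g$score),
               chemistry = g$chemistry[1], stringsAsFactors = FALSE)
  }))
  ord <- order(-out$highest_score, out$protein_a, out$residue_a, out$residue_b)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("unique_links", "data.frame")
  out
}

#' Build distance restraints from unique links
#'
#' Each link's protein labels are mapped to assembly chains through
#' \code{chain_map}; per-chain residue-number offsets (\code{offsets}, added
#' to table numbering to obtain structure numbering) accommodate constructs
#' whose deposited coordinates use a different numbering than the full-length
#' sequence. Links whose residues have no Calpha in the mapped chain are
#' returned separately, never silently dropped.
#'
#' @param links A \code{"unique_links"} data frame.
#' @param assembly Target assembly.
#' @param chain_map Named character vector, protein label -> chain id.
#' @param offsets Named numeric vector per protein label (default 0).
#' @param chemistry_params Per-chemistry \code{target}/\code{upper_bound}
#'   list; see \code{\link{default_chemistry_params}}.
#' @param score_weighting If \code{TRUE}, restraint weights are proportional
#'   to the link's highest score (normalized to mean 1); default uniform 1.
#' @return List with \code{restraints} (data frame of class
#'   \code{"restraints"}: \code{chain_a}, \code{res_a}, \code{chain_b},
#'   \code{res_b}, \code{target}, \code{lower}, \code{upper}, \code{weight},
#'   \code{chemistry}) and \code{unmappable} (the subset of \code{links} that
#'   could not be resolved).
#' @export
build_restraints <- function(links, assembly, chain_map, offsets = NULL,
                             chemistry_params = default_chemistry_params(),
                             score_weighting = FALSE) {
  unknown <- setdiff(unique(c(links$protein_a, links$protein_b)),
                     names(chain_map))
  if (length(unknown)) stop("unknown protein label(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(offsets)) offsets <- stats::setNames(rep(0, length(chain_map)),
                                                   names(chain_map))
  flat <- flatten_assembly(assembly)
  ca_keys <- .res_key(flat$chain[flat$atom == "CA"],
                      flat$resno[flat$atom == "CA"])
  ok <- logical(nrow(links))
  rows <- vector("list", nrow(links))
  for (i in seq_len(nrow(links))) {
    cha <- chain_map[[links$protein_a[i]]]
    chb <- chain_map[[links$protein_b[i]]]
    ra <- links$residue_a[i] + (offsets[links$protein_a[i]] %||% 0)
    rb <- links$residue_b[i] + (offsets[links$protein_b[i]] %||% 0)
    ok[i] <- .res_key(cha, ra) %in% ca_keys && .res_key(chb, rb) %in% ca_keys
    if (!ok[i]) next
    chem <- links$chemistry[i]
    cp <- chemistry_params[[chem]]
    if (is.null(cp)) stop("no chemistry parameters for '", chem, "'",
                          call. = FALSE)
    rows[[i]] <- data.frame(
      chain_a = cha, res_a = ra, chain_b = chb, res_b = rb,
      target = cp$target, lower = 0, upper = cp$upper_bound,
      weight = 1, chemistry = chem, stringsAsFactors = FALSE)
  }
  restraints <- if (any(ok)) do.call(rbind, rows[ok]) else
    data.frame(chain_a = character(), res_a = numeric(), chain_b = character(),
               res_b = numeric(), target = numeric(), lower = numeric(),
               upper = numeric(), weight = numeric(), chemistry = character(),
               stringsAsFactors = FALSE)
  if (score_weighting && nrow(restraints) > 0L) {
    sc <- links$highest_score[ok]
    restraints$weight <- sc / mean(sc)
  }
  rownames(restraints) <- NULL
  class(restraints) <- c("restraints", "data.frame")
  list(restraints = restraints,
       unmappable = links[!ok, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Evaluate restraint satisfaction on a model
#'
#' A restraint is satisfied when its Calpha–Calpha distance in the current
#' model does not exceed its upper bound.
#'
#' @param assembly An assembly (or a single flattened structure).
#' @param restraints A \code{"restraints"} data frame.
#' @return List of class \code{"satisfaction_report"}: \code{per_restraint}
#'   (data frame with \code{distance} and \code{satisfied}),
#'   \code{n_satisfied}, \code{n_total}, \code{fraction}. Serializable with
#'   \code{jsonlite::toJSON}.
#' @export
evaluate_satisfaction <- function(assembly, restraints) {
  if (nrow(restraints) == 0L) {
    stop("empty restraint list: satisfaction fraction undefined",
         call. = FALSE)
  }
  st <- if (inherits(assembly, "assembly")) flatten_assembly(assembly) else
    assembly
  d <- vapply(seq_len(nrow(restraints)), function(i) {
    ca_distance(st, c(restraints$chain_a[i], restraints$res_a[i]),
                c(restraints$chain_b[i], restraints$res_b[i]))
  }, 0.0)
  sat <- d <= restraints$upper
  per <- data.frame(as.data.frame(restraints), distance = d, satisfied = sat,
                    stringsAsFactors = FALSE)
  out <- list(per_restraint = per, n_satisfied = sum(sat),
              n_total = length(sat), fraction = mean(sat))
  class(out) <- "satisfaction_report"
  out
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat(sprintf("restraint satisfaction: %d/%d (%.1f%%)\n",
              x$n_satisfied, x$n_total, 100 * x$fraction))
  invisible(x)
}

#' Flat-bottom restraint energy
#'
#' Zero up to the target distance, quadratic between target and upper bound,
#' then capped to near-constant growth (a gentle linear slope,
#' \code{outlier_slope} per Angstrom) beyond the upper bound, so that a
#' handful of decoy links cannot out-pull the consistent majority.
#'
#' @param d Distances (Angstrom).
#' @param target,upper Restraint parameters.
#' @param weight Restraint weight.
#' @param outlier_slope Linear slope beyond the upper bound (default 1).
#' @param flat_bottom If \code{FALSE}, distances below the target are also
#'   penalized quadratically (harmonic restraint centred on the target).
#' @return Energies, same length as \code{d}.
#' @export
restraint_energy <- function(d, target, upper, weight = 1,
                             outlier_slope = 1.0, flat_bottom = TRUE) {
  target <- rep_len(target, length(d))
  upper <- rep_len(upper, length(d))
  weight <- rep_len(weight, length(d))
  e <- numeric(length(d))
  mid <- d > target & d <= upper
  e[mid] <- (d[mid] - target[mid])^2
  if (!flat_bottom) {
    lo <- d <= target
    e[lo] <- (target[lo] - d[lo])^2
  }
  beyond <- d > upper
  wmax <- (upper - target)^2
  e[beyond] <- wmax[beyond] + outlier_slope * (d[beyond] - upper[beyond])
  e * weight
}
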