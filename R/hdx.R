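# Hydrogen-deuterium exchange: deuteration-change tables, significance
# filtering, residue-level protection maps, and a permutation test for
# enrichment of protection at a modeled interface.

#' Parse an HDX deuteration-change table
#'
#' Two dialects: \code{"csv"} with columns
#' \code{protein,start,end,sequence,delta_15s,delta_120s}, and
#' \code{"paper_table"}, the printed block layout in which a line holding a
#' single protein label starts a block, column-header lines start with
#' \code{*}, and data rows are
#' \code{start-end  SEQUENCE  delta_15s  delta_120s} with either timepoint
#' possibly absent. Unicode minus signs, en-dash ranges and trailing
#' footnote markers (\code{*}) on the range are tolerated. Missing cells
#' stay \code{NA}, never 0.
#'
#' @param path_or_text File path or character vector of lines.
#' @param dialect \code{"paper_table"} or \code{"csv"}.
#' @return Data frame of class \code{"hdx_peptides"} with columns
#'   \code{protein}, \code{start}, \code{end}, \code{sequence},
#'   \code{delta_15s}, \code{delta_120s}. Negative values indicate
#'   protection (reduced deuteration on complex formation).
#' @export
parse_hdx_table <- function(path_or_text, dialect = c("paper_table", "csv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(path_or_text) == 1L && file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  empty <- data.frame(protein = character(), start = integer(),
                      end = integer(), sequence = character(),
                      delta_15s = numeric(), delta_120s = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(.as_hdx(empty))

  if (dialect == "csv") {
    df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(.as_hdx(empty))
    out <- data.frame(protein = as.character(df$protein),
                      start = as.integer(df$start), end = as.integer(df$end),
                      sequence = as.character(df$sequence),
                      delta_15s = .num(as.character(df$delta_15s)),
                      delta_120s = .num(as.character(df$delta_120s)),
                      stringsAsFactors = FALSE)
    return(.validate_hdx(out))
  }

  protein <- NA_character_
  rows <- list()
  for (ln in lines) {
    t0 <- trimws(ln)
    if (startsWith(t0, "*")) next               # column header / footnote
    toks <- strsplit(t0, "\t")[[1]]
    toks <- trimws(toks)
    if (length(toks) == 1L &&
        !grepl("^[0-9]+[–—−-][0-9]+", toks)) {
      protein <- toks
      next
    }
    rng <- toks[1]
    rng <- sub("\\*+$", "", rng)                # footnote marker on range
    rng <- gsub("[–—−]", "-", rng)
    m <- regmatches(rng, regexec("^([0-9]+)-([0-9]+)$", rng))[[1]]
    if (length(m) != 3L) {
      if (grepl("[0-9]", rng)) stop("malformed range token: '", toks[1], "'",
                                    call. = FALSE)
      next
    }
    if (is.na(protein)) stop("data row before any protein header",
                             call. = FALSE)
    d15 <- if (length(toks) >= 3L && nzchar(toks[3])) .num(toks[3]) else NA_real_
    d120 <- if (length(toks) >= 4L && nzchar(toks[4])) .num(toks[4]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      protein = protein, start = as.integer(m[2]), end = as.integer(m[3]),
      sequence = if (length(toks) >= 2L) toks[2] else "",
      delta_15s = d15, delta_120s = d120, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.as_hdx(empty))
  .validate_hdx(do.call(rbind, rows))
}

.as_hdx <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("hdx_peptides", "data.frame")
  df
}

.validate_hdx <- function(df) {
  if (any(df$end < df$start)) stop("peptide with end < start", call. = FALSE)
  bad <- nzchar(df$sequence) & nchar(df$sequence) != (df$end - df$start + 1L)
  if (any(bad)) {
    warning("peptide sequence length disagrees with residue range for ",
            sum(bad), " row(s)")
  }
  .as_hdx(df)
}

# largest-magnitude timepoint represents each peptide
.hdx_repr <- function(peptides) {
  d15 <- peptides$delta_15s; d120 <- peptides$delta_120s
  a15 <- ifelse(is.na(d15), -Inf, abs(d15))
  a120 <- ifelse(is.na(d120), -Inf, abs(d120))
  ifelse(a15 >= a120, d15, d120)
}

#' Split peptides into significantly protected / deprotected sets
#'
#' A peptide is significant when any timepoint has |delta| >= threshold;
#' the sign of its largest-magnitude timepoint decides which list it joins
#' (negative = protected), so no peptide appears in both.
#'
#' @param peptides An \code{"hdx_peptides"} data frame.
#' @param threshold Significance threshold in percentage points (default 7).
#' @return List with \code{protected} and \code{deprotected} subsets.
#' @export
filter_significant <- function(peptides, threshold = 7.0) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  mx <- pmax(abs(peptides$delta_15s), abs(peptides$delta_120s), na.rm = TRUE)
  mx[is.na(peptides$delta_15s) & is.na(peptides$delta_120s)] <- NA
  sig <- !is.na(mx) & mx >= threshold
  repr <- .hdx_repr(peptides)
  list(protected = .as_hdx(peptides[sig & repr < 0, , drop = FALSE]),
       deprotected = .as_hdx(peptides[sig & repr > 0, , drop = FALSE]))
}

#' Project peptide-level deuteration changes onto residues
#'
#' Each residue's score is the mean, over all peptides spanning it, of the
#' peptide's largest-magnitude timepoint. Residues covered by no peptide are
#' reported with \code{NA} score and coverage 0 (explicit no-data, not 0.0).
#'
#' @param peptides Peptides from a single protein.
#' @return List of class \code{"protection_map"}: \code{protein},
#'   \code{residue}, \code{score}, \code{coverage} (parallel vectors over
#'   the covered residue range).
#' @export
residue_protection_map <- function(peptides) {
  if (nrow(peptides) == 0L) stop("no peptides", call. = FALSE)
  if (length(unique(peptides$protein)) != 1L) {
    stop("peptides from mixed proteins; map one protein at a time",
         call. = FALSE)
  }
  repr <- .hdx_repr(peptides)
  lo <- min(peptides$start); hi <- max(peptides$end)
  res <- lo:hi
  total <- numeric(length(res)); cov <- integer(length(res))
  for (i in seq_len(nrow(peptides))) {
    if (is.na(repr[i])) next
    idx <- (peptides$start[i]:peptides$end[i]) - lo + 1L
    total[idx] <- total[idx] + repr[i]
    cov[idx] <- cov[idx] + 1L
  }
  score <- ifelse(cov > 0, total / pmax(cov, 1L), NA_real_)
  out <- list(protein = peptides$protein[1], residue = res, score = score,
              coverage = cov)
  class(out) <- "protection_map"
  out
}

#' @export
print.protection_map <- function(x, ...) {
  cat(sprintf("protection map '%s': residues %d-%d, %d covered, min score %.2f\n",
              x$protein, min(x$residue), max(x$residue), sum(x$coverage > 0),
              min(x$score, na.rm = TRUE)))
  invisible(x)
}

#' Permutation test for protection enrichment at an interface
#'
#' Statistic: mean protection score over interface residues minus mean over
#' covered non-interface residues (more negative = stronger protection at
#' the interface). One-sided by default (enrichment of protection, i.e.
#' observed statistic in the lower tail);
#' p = (1 + #{permuted <= observed}) / (n_permutations + 1).
#'
#' Two exchangeability models are available. The default permutes residue
#' scores among covered residues. Residue scores projected from overlapping
#' peptides are spatially correlated, which makes residue-level permutation
#' anti-conservative on peptide-level noise; passing the peptide table via
#' \code{peptides} switches to a block permutation that shuffles
#' peptide-level values and re-projects the map for every draw, which is
#' calibrated under a peptide-exchangeable null.
#'
#' @param map A \code{"protection_map"}.
#' @param interface_residues Residue numbers forming the interface.
#' @param n_permutations Number of permutations (default 1e4).
#' @param seed RNG seed (local to this test).
#' @param two_sided Use |statistic| for the tail instead.
#' @param peptides Optional \code{"hdx_peptides"} table the map was built
#'   from; enables peptide-level (block) permutation.
#' @return List: \code{statistic}, \code{p_value}, \code{n_interface},
#'   \code{n_background}.
#' @export
interface_enrichment_test <- function(map, interface_residues,
                                      n_permutations = 1e4, seed = 1,
                                      two_sided = FALSE, peptides = NULL) {
  covered <- map$residue[map$coverage > 0]
  scores <- map$score[map$coverage > 0]
  if (length(interface_residues) == 0L) stop("empty interface set",
                                             call. = FALSE)
  if (!all(interface_residues %in% covered)) {
    stop("interface contains residues without HDX coverage", call. = FALSE)
  }
  is_int <- covered %in% interface_residues
  stat <- function(sc) {
    if (all(is_int)) return(0)
    mean(sc[is_int]) - mean(sc[!is_int])
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (is.null(peptides)) {
    obs <- stat(scores)
    perm <- vapply(seq_len(n_permutations),
                   function(k) stat(sample(scores)), 0.0)
  } else {
    repr <- .hdx_repr(peptides)
    project <- function(vals) {
      p2 <- as.data.frame(peptides)
      p2$delta_15s <- vals
      p2$delta_120s <- NA_real_
      m <- residue_protection_map(.as_hdx(p2))
      m$score[m$coverage > 0][match(covered,
                                    m$residue[m$coverage > 0])]
    }
    obs <- stat(project(repr))
    perm <- vapply(seq_len(n_permutations),
                   function(k) stat(project(sample(repr))), 0.0)
  }
  p <- if (two_sided) {
    (1 + sum(abs(perm) >= abs(obs))) / (n_permutations + 1)
  } else {
    (1 + sum(perm <= obs)) / (n_permutations + 1)
  }
  list(statistic = obs, p_value = p, n_interface = sum(is_int),
       n_background = sum(!is_int))
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
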