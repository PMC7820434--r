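# Monoisotopic masses (Da) of the most abundant isotope of each supported
# element (CODATA/AME). 12C defines the dalton, so C is exact.
MONOISOTOPIC_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.99491461956,
  Na = 22.9897692809,
  Cl = 34.96885268,
  S  = 31.97207100,
  P  = 30.97376163
)

#' Supported electrospray adducts
#'
#' The five singly charged quasi-molecular species handled by the annotation
#' functions. `mass_delta` is the mass (Da) added to the neutral monoisotopic
#' mass to obtain the ion m/z; the values are electron-corrected (a protonated
#' cation is lighter than M + H by one electron mass, a deprotonated anion is
#' heavier than M - H by one).
#'
#' @return A tibble with columns `adduct`, `polarity` and `mass_delta`.
#' @examples
#' supported_adducts()
#' @export
supported_adducts <- function() {
  tibble::tibble(
    adduct     = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+Cl]-", "[M+COOH]-"),
    polarity   = c("positive", "positive", "negative", "negative", "negative"),
    mass_delta = c(1.00727646, 22.98922142, -1.00727646, 34.96940126, 44.99820285)
  )
}

#' Parse a molecular formula string
#'
#' Parses Hill-notation element/count groups (e.g. `"C9H16O4"`) into a named
#' integer vector of element counts. An omitted count means one atom.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts (an `ElementalComposition`).
#' @examples
#' parse_formula("C9H16O4")
#' parse_formula("C")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  groups <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  sym <- gsub("[0-9]", "", groups)
  cnt <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", groups)))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  validate_composition(out)
}

validate_composition <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("composition must be a named vector of element counts", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0 || sum(counts) < 1) {
    stop("composition must contain at least one atom", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Format a composition in Hill notation
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; a count
#' of one is omitted. Inverse of [parse_formula()].
#'
#' @param counts Named integer vector of element counts.
#' @return A formula string.
#' @examples
#' format_formula(c(C = 9, H = 16, O = 4))
#' @export
format_formula <- function(counts) {
  counts <- validate_composition(counts)
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1, "", counts[ord]), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' @param counts Named integer vector of element counts, or a formula string.
#' @return Mass in Da: the sum over elements of count times the mass of the
#'   most abundant isotope.
#' @examples
#' monoisotopic_mass("C9H16O4")
#' monoisotopic_mass(c(H = 2, O = 1))
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  counts <- validate_composition(counts)
  sum(counts * MONOISOTOPIC_MASS[names(counts)])
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' All supported adducts are singly charged, so the m/z is the neutral mass
#' plus the adduct's electron-corrected mass delta.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (non-negative).
#' @param adduct Adduct name, one of `supported_adducts()$adduct`.
#' @return m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass("C5H5N5"), "[M+H]+")
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  tab <- supported_adducts()
  i <- match(adduct, tab$adduct)
  if (anyNA(i)) {
    stop("unsupported adduct: ", paste(adduct[is.na(i)], collapse = ", "), call. = FALSE)
  }
  if (any(neutral_mass < 0)) stop("neutral_mass must be non-negative", call. = FALSE)
  neutral_mass + tab$mass_delta[i]
}

#' Signed parts-per-million mass error
#'
#' @param observed_mz Observed m/z (Da).
#' @param theoretical_mz Theoretical m/z (Da), strictly positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(187.0980, adduct_mz(monoisotopic_mass("C9H16O4"), "[M-H]-"))
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical_mz must be positive", call. = FALSE)
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Rings-plus-double-bond equivalents
#'
#' Valence-based plausibility score for a neutral formula:
#' `C + 1 + (N + P)/2 - (H + Cl + Na)/2`. Oxygen and sulfur are divalent and
#' contribute nothing; sodium and chlorine are monovalent and count like
#' hydrogen; phosphorus is treated as trivalent like nitrogen.
#'
#' @param counts Named integer vector of element counts, or a formula string.
#' @return A half-integer (possibly negative for implausible formulas).
#' @examples
#' rdbe("C6H6") # benzene: 4
#' @export
rdbe <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  counts <- validate_composition(counts)
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  g("C") + 1 + (g("N") + g("P")) / 2 - (g("H") + g("Cl") + g("Na")) / 2
}

#' Default element-count bounds for formula fitting
#'
#' Wide enough to cover small-molecule phytochemistry below ~700 Da while
#' keeping the exhaustive search tractable.
#'
#' @return Named list of `c(min, max)` integer pairs per element.
#' @export
default_bounds <- function() {
  list(
    C = c(0L, 50L), H = c(0L, 100L), N = c(0L, 10L), O = c(0L, 20L),
    S = c(0L, 3L), P = c(0L, 3L), Na = c(0L, 1L), Cl = c(0L, 1L)
  )
}

# Exhaustive enumeration of compositions whose total monoisotopic mass lies
# in [lo, hi]. Depth-first over the low-count elements (heaviest first, with
# branch-and-bound on the attainable remaining mass), a vectorized sweep
# over the widest-range heavy element (carbon under the default bounds), and
# a closed-form solve for the lightest element: the search window is always
# far narrower than one hydrogen mass, so at most one hydrogen count fits a
# given partial composition. Returns a matrix (columns = elements).
enumerate_compositions <- function(lo, hi, bounds) {
  els <- names(bounds)
  mass_all <- MONOISOTOPIC_MASS[els]
  light <- els[which.min(mass_all)]
  rest <- setdiff(els, light)
  vec <- if (length(rest) > 0) {
    widths <- vapply(bounds[rest], function(b) b[2] - b[1], numeric(1))
    rest[which.max(widths)]
  } else {
    character(0)
  }
  deep <- setdiff(rest, vec)
  deep <- deep[order(mass_all[deep], decreasing = TRUE)]
  ord <- c(deep, vec, light)
  mass <- unname(mass_all[ord])
  bmin <- vapply(bounds[ord], function(b) as.integer(b[1]), integer(1))
  bmax <- vapply(bounds[ord], function(b) as.integer(b[2]), integer(1))
  k <- length(ord)
  tail_max <- rev(cumsum(rev(bmax * mass)))

  m_l <- mass[k]
  acc_mat <- NULL # rows: counts of ord[1..k], grown in blocks
  found <- list()

  solve_leaf <- function(counts_deep, acc) {
    # vectorized over the wide element (if any), closed-form for the light one
    if (k >= 2) {
      i_vec <- k - 1L
      v_lo <- max(bmin[i_vec], 0L)
      v_hi <- min(bmax[i_vec], floor((hi - acc) / mass[i_vec] + 1e-9))
      if (v_hi < v_lo) return()
      v <- v_lo:v_hi
      rem_lo <- lo - acc - v * mass[i_vec]
      rem_hi <- hi - acc - v * mass[i_vec]
      h_lo <- pmax(bmin[k], ceiling(rem_lo / m_l - 1e-9))
      h_hi <- pmin(bmax[k], floor(rem_hi / m_l + 1e-9))
      ok <- which(h_lo <= h_hi)
      for (j in ok) {
        for (hcnt in h_lo[j]:h_hi[j]) {
          cnt <- c(counts_deep, v[j], hcnt)
          if (sum(cnt) >= 1L) found[[length(found) + 1L]] <<- cnt
        }
      }
    } else {
      h_lo <- max(bmin[1], ceiling(lo / m_l - 1e-9), 1L)
      h_hi <- min(bmax[1], floor(hi / m_l + 1e-9))
      if (h_hi >= h_lo) for (hcnt in h_lo:h_hi) found[[length(found) + 1L]] <<- hcnt
    }
  }

  n_deep <- length(deep)
  recurse <- function(i, counts_deep, acc) {
    if (i > n_deep) {
      solve_leaf(counts_deep, acc)
      return(invisible())
    }
    for (cc in bmin[i]:bmax[i]) {
      acc_i <- acc + cc * mass[i]
      if (acc_i > hi) break
      if (acc_i + tail_max[i + 1L] < lo) next
      counts_deep[i] <- cc
      recurse(i + 1L, counts_deep, acc_i)
    }
    invisible()
  }
  recurse(1L, integer(n_deep), 0)
  if (length(found) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = k, dimnames = list(NULL, ord)))
  }
  m <- do.call(rbind, found)
  colnames(m) <- ord
  storage.mode(m) <- "integer"
  m
}

# vectorized helpers over a composition count matrix
matrix_mass <- function(m) {
  as.numeric(m %*% MONOISOTOPIC_MASS[colnames(m)])
}

matrix_rdbe <- function(m) {
  g <- function(el) if (el %in% colnames(m)) m[, el] else 0L
  g("C") + 1 + (g("N") + g("P")) / 2 - (g("H") + g("Cl") + g("Na")) / 2
}

matrix_formula <- function(m) {
  els <- colnames(m)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  m <- m[, ord, drop = FALSE]
  apply(m, 1, function(cnt) {
    nz <- cnt > 0
    paste0(ord[nz], ifelse(cnt[nz] == 1, "", cnt[nz]), collapse = "")
  })
}

n_heteroatoms <- function(counts) {
  sum(counts[setdiff(names(counts), c("C", "H"))])
}

#' Enumerate candidate formulas for one peak
#'
#' Exhaustively enumerates every elemental composition within `bounds` whose
#' adduct m/z falls within `tolerance_ppm` of the observed m/z, for every
#' adduct matching the peak polarity. Candidates with negative
#' rings-plus-double-bond equivalents are discarded. The search is complete:
#' the true formula is always returned when it lies inside the bounds and
#' tolerance.
#'
#' @param observed_mz Observed m/z (Da).
#' @param polarity `"positive"` or `"negative"`.
#' @param adducts Character vector of adduct names to consider; defaults to
#'   all supported adducts of the peak polarity. Supplying an adduct of the
#'   wrong polarity is an error.
#' @param bounds Per-element `c(min, max)` bounds, as [default_bounds()].
#' @param tolerance_ppm Search window in ppm (default 5, a typical
#'   quadrupole time-of-flight accuracy specification).
#' @return A tibble with columns `rank`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, `rdbe`, sorted by absolute ppm error
#'   (ties: fewer heteroatoms, then formula string). Zero rows when nothing
#'   matches.
#' @examples
#' fit_formulas(187.0980, "negative")
#' @export
fit_formulas <- function(observed_mz, polarity = c("negative", "positive"),
                         adducts = NULL, bounds = default_bounds(),
                         tolerance_ppm = 5) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1, observed_mz > 0,
            tolerance_ppm > 0)
  tab <- supported_adducts()
  if (is.null(adducts)) {
    adducts <- tab$adduct[tab$polarity == polarity]
  } else {
    i <- match(adducts, tab$adduct)
    if (anyNA(i)) stop("unsupported adduct: ", paste(adducts[is.na(i)], collapse = ", "),
                       call. = FALSE)
    bad <- tab$polarity[i] != polarity
    if (any(bad)) {
      stop("adduct(s) ", paste(adducts[bad], collapse = ", "),
           " do not match polarity '", polarity, "'", call. = FALSE)
    }
  }
  rows <- list()
  for (a in adducts) {
    delta <- tab$mass_delta[match(a, tab$adduct)]
    # |obs - (m + delta)| / (m + delta) <= tol  <=>  m + delta in
    # [obs / (1 + tol), obs / (1 - tol)]
    t <- tolerance_ppm * 1e-6
    lo <- observed_mz / (1 + t) - delta
    hi <- observed_mz / (1 - t) - delta
    if (hi <= 0) next
    lo <- max(lo, 0)
    m <- enumerate_compositions(lo, hi, bounds)
    if (nrow(m) == 0) next
    r <- matrix_rdbe(m)
    theo <- matrix_mass(m) + delta
    ppm <- ppm_error(observed_mz, theo)
    keep <- r >= 0 & abs(ppm) <= tolerance_ppm + 1e-12
    if (!any(keep)) next
    m <- m[keep, , drop = FALSE]
    het_cols <- setdiff(colnames(m), c("C", "H"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      formula = matrix_formula(m), adduct = a,
      theoretical_mz = theo[keep], ppm_error = ppm[keep], rdbe = r[keep],
      .hetero = if (length(het_cols) > 0) {
        as.integer(rowSums(m[, het_cols, drop = FALSE]))
      } else {
        0L
      }
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(rank = integer(), formula = character(),
                          adduct = character(), theoretical_mz = numeric(),
                          ppm_error = numeric(), rdbe = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, abs(.data$ppm_error), .data$.hetero, .data$formula)
  out$.hetero <- NULL
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Fit formulas for a whole peak table
#'
#' Applies [fit_formulas()] to each row of a peak table.
#'
#' @param peaks A data frame with columns `peak_id`, `observed_mz`,
#'   `polarity` (and optionally `rt_min`, `known_formula`).
#' @inheritParams fit_formulas
#' @return A tibble of candidates with a leading `peak_id` column.
#' @export
fit_peaks <- function(peaks, bounds = default_bounds(), tolerance_ppm = 5) {
  peaks <- validate_peak_table(peaks)
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    res <- fit_formulas(peaks$observed_mz[i], peaks$polarity[i],
                        bounds = bounds, tolerance_ppm = tolerance_ppm)
    if (nrow(res) == 0) return(res)
    dplyr::bind_cols(tibble::tibble(peak_id = peaks$peak_id[i]), res)
  })
}

#' Annotate peaks that carry a known formula
#'
#' For each peak with a non-missing `known_formula`, picks the supported
#' adduct of the peak's polarity (or either polarity when `polarity` is
#' missing) minimizing the absolute ppm error, and reports the theoretical
#' m/z and the signed error. This is how printed compound tables are
#' recomputed when the originating adduct is not stated explicitly.
#'
#' @param peaks A data frame with columns `peak_id`, `observed_mz`,
#'   `known_formula`, and optionally `polarity` and `rt_min`.
#' @return A tibble with `peak_id`, `formula`, `adduct`, `theoretical_mz`,
#'   `ppm_error` and `ppm_error_1dp` (rounded to one decimal, the convention
#'   used in compound identification tables).
#' @export
annotate_peaks <- function(peaks) {
  peaks <- validate_peak_table(peaks, require_polarity = FALSE)
  if (!"known_formula" %in% names(peaks)) {
    stop("peak table has no 'known_formula' column", call. = FALSE)
  }
  tab <- supported_adducts()
  peaks <- peaks[!is.na(peaks$known_formula) & nzchar(peaks$known_formula), ]
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    mass <- monoisotopic_mass(peaks$known_formula[i])
    cand <- tab
    if ("polarity" %in% names(peaks) && !is.na(peaks$polarity[i])) {
      cand <- cand[cand$polarity == peaks$polarity[i], ]
    }
    theo <- mass + cand$mass_delta
    err <- ppm_error(peaks$observed_mz[i], theo)
    j <- which.min(abs(err))
    tibble::tibble(
      peak_id = peaks$peak_id[i], formula = peaks$known_formula[i],
      adduct = cand$adduct[j], polarity = cand$polarity[j],
      theoretical_mz = theo[j], ppm_error = err[j],
      ppm_error_1dp = round(err[j], 1)
    )
  })
}

validate_peak_table <- function(peaks, require_polarity = TRUE) {
  peaks <- tibble::as_tibble(peaks)
  need <- c("peak_id", "observed_mz", if (require_polarity) "polarity")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(peaks$observed_mz) | peaks$observed_mz <= 0)) {
    stop("observed_mz must be positive and finite", call. = FALSE)
  }
  if ("rt_min" %in% names(peaks) && any(peaks$rt_min < 0, na.rm = TRUE)) {
    stop("rt_min must be non-negative", call. = FALSE)
  }
  if ("polarity" %in% names(peaks)) {
    ok <- is.na(peaks$polarity) | peaks$polarity %in% c("positive", "negative")
    if (!all(ok)) stop("polarity must be 'positive' or 'negative'", call. = FALSE)
  }
  peaks
}

#' Read a peak table from CSV/TSV
#'
#' Expects columns `peak_id`, `rt_min`, `observed_mz`, `polarity` and
#' optionally `known_formula` (blank allowed). The delimiter is chosen from
#' the file extension.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_peak_table <- function(path) {
  peaks <- read_delim_auto(path)
  validate_peak_table(peaks, require_polarity = FALSE)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}
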