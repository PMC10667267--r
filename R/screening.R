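#' Desirability of a descriptor value
#'
#' Evaluates the normalised asymmetric double sigmoid (ADS) used by the
#' quantitative estimate of drug-likeness (QED). The raw curve is
#' \deqn{raw(x) = a + \frac{b}{1 + e^{-(x - c + d/2)/e}}
#'   \left(1 - \frac{1}{1 + e^{-(x - c - d/2)/f}}\right)}
#' and the desirability is `raw(x) / dmax`, where `dmax` is the curve's
#' maximum, so the result lies in (0, 1] and peaks in the drug-like range.
#'
#' @param x Descriptor value(s); vectorised.
#' @param params Named numeric vector with elements `a, b, c, d, e, f` and
#'   optionally `dmax`; alternatively one of the descriptor names
#'   `"MW", "ALOGP", "HBA", "HBD", "TPSA", "ROTB", "AROM", "ALERTS"` to use the
#'   published coefficients.
#' @return Desirability in (0, 1], same length as `x`.
#' @examples
#' desirability(300, "MW")
#' @export
desirability <- function(x, params) {
  p <- resolve_ads_params(params)
  ads_raw(x, p) / p[["dmax"]]
}

resolve_ads_params <- function(params) {
  if (is.character(params) && length(params) == 1L) {
    if (!params %in% QED_DESCRIPTORS) {
      abort(sprintf("Unknown descriptor '%s'; one of: %s.", params,
                    paste(QED_DESCRIPTORS, collapse = ", ")))
    }
    return(QED_ADS_PARAMS[[params]])
  }
  need <- c("a", "b", "c", "d", "e", "f")
  if (!is.numeric(params) || !all(need %in% names(params))) {
    abort("`params` must name coefficients a, b, c, d, e, f.")
  }
  if (params[["e"]] == 0 || params[["f"]] == 0) {
    abort("Degenerate sigmoid: coefficients `e` and `f` must be non-zero.")
  }
  if (!"dmax" %in% names(params)) {
    # numeric maximisation over a wide bracket around c
    centre <- params[["c"]]
    span <- max(abs(params[["d"]]), abs(params[["e"]]), abs(params[["f"]]), 1) * 50
    opt <- optimize(function(z) ads_raw(z, params),
                    lower = centre - span, upper = centre + span,
                    maximum = TRUE, tol = 1e-10)
    params <- c(params, dmax = opt$objective)
  }
  params
}

ads_raw <- function(x, p) {
  p[["a"]] + p[["b"]] /
    (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The weighted geometric mean of the eight descriptor desirabilities:
#' \deqn{QED = \exp\left(\sum_i w_i \ln d_i / \sum_i w_i\right)}
#' The `"weighted"` mode uses the published mean-weight scheme (the common
#' reference-implementation default), `"unweighted"` sets all weights to 1
#' (plain geometric mean), `"max"` uses the published max-weight scheme.
#'
#' @param mw,alogp,hba,hbd,tpsa,rotb,arom,alerts Descriptor values
#'   (vectorised): molecular weight (Da), Crippen logP, H-bond acceptor and
#'   donor counts, topological polar surface area (A^2), rotatable-bond count,
#'   aromatic-ring count, structural-alert count.
#' @param mode Weighting scheme: `"weighted"` (default), `"unweighted"` or
#'   `"max"`; alternatively supply `weights` directly.
#' @param weights Optional named non-negative weights for
#'   `MW, ALOGP, HBA, HBD, TPSA, ROTB, AROM, ALERTS`; overrides `mode`. At
#'   least one weight must be positive. The score is invariant to rescaling
#'   all weights by a positive constant.
#' @return QED score(s) in (0, 1].
#' @examples
#' qed_score(300, 2.5, 4, 1, 70, 4, 2, 0)
#' @export
qed_score <- function(mw, alogp, hba, hbd, tpsa, rotb, arom, alerts,
                      mode = c("weighted", "unweighted", "max"),
                      weights = NULL) {
  if (is.null(weights)) {
    mode <- match.arg(mode)
    weights <- QED_WEIGHTS[[mode]]
  } else {
    if (is.null(names(weights)) || !all(QED_DESCRIPTORS %in% names(weights))) {
      abort("`weights` must name all eight descriptors.")
    }
    weights <- weights[QED_DESCRIPTORS]
    if (any(weights < 0) || sum(weights) <= 0) {
      abort("Weights must be non-negative with at least one positive.")
    }
  }
  d <- cbind(
    MW     = desirability(mw, "MW"),
    ALOGP  = desirability(alogp, "ALOGP"),
    HBA    = desirability(hba, "HBA"),
    HBD    = desirability(hbd, "HBD"),
    TPSA   = desirability(tpsa, "TPSA"),
    ROTB   = desirability(rotb, "ROTB"),
    AROM   = desirability(arom, "AROM"),
    ALERTS = desirability(alerts, "ALERTS")
  )
  if (any(d <= 0)) abort("Desirability fell outside (0, 1]; check descriptors.")
  exp(as.vector(log(d) %*% weights) / sum(weights))
}

#' Veber oral-bioavailability rule
#'
#' `TRUE` iff rotatable bonds <= 10 and topological polar surface area
#' <= 140 A^2 (both bounds inclusive).
#'
#' @param rotb Rotatable-bond count(s).
#' @param tpsa Topological polar surface area(s), A^2.
#' @return Logical vector.
#' @examples
#' veber_pass(rotb = 10, tpsa = 140) # TRUE: boundary included
#' @export
veber_pass <- function(rotb, tpsa) {
  if (missing(rotb) || is.null(rotb)) abort("Missing descriptor: rotb.")
  if (missing(tpsa) || is.null(tpsa)) abort("Missing descriptor: tpsa.")
  if (anyNA(rotb)) abort("Missing values in descriptor: rotb.")
  if (anyNA(tpsa)) abort("Missing values in descriptor: tpsa.")
  rotb <= 10 & tpsa <= 140
}

DESCRIPTOR_COLS <- c("MW", "ALOGP", "HBA", "HBD", "TPSA", "ROTB", "AROM", "ALERTS")

# map case-insensitive column names onto the canonical descriptor headers
canonical_descriptors <- function(data) {
  lookup <- setNames(names(data), toupper(names(data)))
  missing <- setdiff(DESCRIPTOR_COLS, names(lookup))
  if (length(missing)) {
    abort(sprintf("Compound table lacks descriptor column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  lookup[DESCRIPTOR_COLS]
}

#' Screen compounds for drug-likeness and oral bioavailability
#'
#' Computes the QED score and the Veber verdict for every compound and flags
#' the expected active compounds (EAC): `is_eac = qed >= qed_cutoff & ob_pass`.
#' Both cutoffs are inclusive; the default QED cutoff is 0.3.
#'
#' @param data Data frame with columns `MW, ALOGP, HBA, HBD, TPSA, ROTB, AROM,
#'   ALERTS` (case-insensitive); other columns (e.g. `compound_id`, `name`,
#'   `formula`) pass through untouched.
#' @param qed_cutoff Inclusive lower QED bound for selection; default 0.3.
#' @param qed_mode Weighting scheme passed to [qed_score()].
#' @return A tibble of class `np_screen`: the input plus `qed`, `ob_pass`,
#'   `is_eac` columns, input order preserved.
#' @examples
#' tbl <- tibble::tibble(compound_id = "c1", MW = 320, ALOGP = 2.1, HBA = 5,
#'   HBD = 2, TPSA = 80, ROTB = 3, AROM = 2, ALERTS = 0)
#' screen_compounds(tbl)
#' @export
screen_compounds <- function(data, qed_cutoff = 0.3,
                             qed_mode = c("weighted", "unweighted", "max")) {
  qed_mode <- match.arg(qed_mode)
  data <- as_tibble(data)
  cols <- canonical_descriptors(data)
  d <- data[unname(cols)]
  names(d) <- DESCRIPTOR_COLS
  if (nrow(d)) {
    if (any(d$MW <= 0)) abort("MW must be positive.")
    if (any(d$TPSA < 0)) abort("TPSA must be non-negative.")
    counts <- c("HBA", "HBD", "ROTB", "AROM", "ALERTS")
    if (any(unlist(d[counts]) < 0)) {
      abort("Count descriptors must be non-negative.")
    }
  }
  out <- dplyr::mutate(
    data,
    qed = if (nrow(d)) qed_score(d$MW, d$ALOGP, d$HBA, d$HBD, d$TPSA,
                                 d$ROTB, d$AROM, d$ALERTS, mode = qed_mode)
          else double(0),
    ob_pass = if (nrow(d)) veber_pass(d$ROTB, d$TPSA) else logical(0)
  )
  out <- select_eac(out, qed_cutoff = qed_cutoff)
  attr(out, "qed_mode") <- qed_mode
  attr(out, "qed_cutoff") <- qed_cutoff
  class(out) <- c("np_screen", class(out))
  out
}

#' Flag expected active compounds at a QED cutoff
#'
#' Recomputes `is_eac = qed >= qed_cutoff & ob_pass` on an already-scored
#' table. Idempotent; preserves row order; raising the cutoff never adds
#' compounds.
#'
#' @param data Data frame with `qed` and `ob_pass` columns.
#' @param qed_cutoff Inclusive lower QED bound; default 0.3.
#' @return `data` with the `is_eac` logical column (re)computed.
#' @export
select_eac <- function(data, qed_cutoff = 0.3) {
  if (!is.numeric(qed_cutoff) || length(qed_cutoff) != 1L ||
      is.na(qed_cutoff) || qed_cutoff < 0 || qed_cutoff > 1) {
    abort("`qed_cutoff` must be a single value in [0, 1].")
  }
  data <- as_tibble(data)
  for (col in c("qed", "ob_pass")) {
    if (!col %in% names(data)) {
      abort(sprintf("Column '%s' missing; run screen_compounds() first.", col))
    }
  }
  dplyr::mutate(data, is_eac = .data$qed >= qed_cutoff & .data$ob_pass)
}

#' Read a compound descriptor table
#'
#' @param path CSV or TSV file (delimiter inferred from extension, `.csv` vs
#'   anything else) with header columns `compound_id, name, MW, ALOGP, HBA,
#'   HBD, TPSA, ROTB, AROM, ALERTS` and optionally `SMILES`, `formula`.
#' @return A tibble.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) abort(sprintf("Compound table not found: '%s'.", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  reader(path, show_col_types = FALSE, progress = FALSE)
}

#' @export
glance.np_screen <- function(x, ...) {
  tibble(
    n_compounds = nrow(x),
    n_ob_pass = sum(x$ob_pass),
    n_eac = sum(x$is_eac),
    qed_mode = attr(x, "qed_mode") %||% NA_character_,
    qed_cutoff = attr(x, "qed_cutoff") %||% NA_real_
  )
}

#' @export
tidy.np_screen <- function(x, ...) {
  as_tibble(unclass(x))
}
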