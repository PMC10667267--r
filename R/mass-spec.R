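# Monoisotopic masses (Da) of the most abundant isotope, IUPAC/CODATA values.
# Hard-coded so results cannot drift with external library versions.
MONOISOTOPIC_MASS <- c(
  C  = 12.000000000,
  H  = 1.007825032,
  N  = 14.003074005,
  O  = 15.994914620,
  S  = 31.972070690,
  P  = 30.973761510,
  F  = 18.998403163,
  Cl = 34.968852682,
  Br = 78.918337600,
  I  = 126.904473000
)

# electron rest mass, Da
ELECTRON_MASS <- 0.000548579909

#' Parse an elemental formula
#'
#' Parses a Hill-style molecular formula string (element symbol optionally
#' followed by a count, e.g. `"C24H20O7"`) into a named integer vector of atom
#' counts. Only elements with an entry in the internal monoisotopic mass table
#' (C, H, N, O, S, P, F, Cl, Br, I) are accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector of class `elemental_formula`; names are
#'   element symbols, values are strictly positive atom counts. Repeated
#'   element blocks (e.g. `"CH3CH3"`) are summed.
#' @examples
#' parse_formula("C24H20O7")
#' parse_formula("H2O")
#' @seealso [monoisotopic_mass()], [adduct_mz()], [format_formula()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single formula string.")
  }
  text <- trimws(text)
  if (!nzchar(text)) abort("Empty formula string.")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regmatches(
      substr(text, pos, n),
      regexpr("^([A-Z][a-z]?)([0-9]*)", substr(text, pos, n))
    )
    if (length(m) == 0L || !nzchar(m)) {
      abort(sprintf(
        "Malformed formula '%s': unexpected character '%s' at position %d.",
        text, substr(text, pos, pos), pos
      ))
    }
    sym <- sub("[0-9]*$", "", m)
    if (!sym %in% names(MONOISOTOPIC_MASS)) {
      abort(sprintf(
        "Unknown element symbol '%s' at position %d of '%s'.", sym, pos, text
      ))
    }
    digits <- substr(m, nchar(sym) + 1L, nchar(m))
    k <- if (nzchar(digits)) as.integer(digits) else 1L
    if (k <= 0L) {
      abort(sprintf("Zero count for element '%s' in '%s'.", sym, text))
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m)
  }
  new_elemental_formula(counts)
}

new_elemental_formula <- function(counts) {
  counts <- counts[counts > 0L]
  # Hill order: C first, then H, then remaining elements alphabetically
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  structure(as.integer(counts[ord]), names = ord, class = "elemental_formula")
}

#' Serialize an elemental formula to Hill notation
#'
#' @param f An `elemental_formula` (or named integer vector of counts).
#' @return A single string; `parse_formula(format_formula(f))` is the identity.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.elemental_formula <- function(x, ...) format_formula(x)

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    bad <- setdiff(names(f), names(MONOISOTOPIC_MASS))
    if (length(bad)) {
      abort(sprintf("No monoisotopic mass for element(s): %s.",
                    paste(bad, collapse = ", ")))
    }
    if (any(f < 0)) abort("Element counts must be non-negative.")
    return(new_elemental_formula(f))
  }
  abort("`f` must be a formula string or a named count vector.")
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic atomic masses times atom counts, in Da.
#'
#' @param f Formula string, `elemental_formula`, or named count vector.
#' @return Mass in Da (double).
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}

#' Adduct specifications
#'
#' An adduct specification records the net atom delta applied to the neutral
#' molecule M and the ion charge. `adduct_spec()` constructs one;
#' `default_adducts()` returns the built-in negative-mode registry used in
#' HR-ESI-MS assignment: the deprotonated ion `[M-H]-`, the formate adduct
#' `[M+HCOO]-`, and the composite formate-adduct-minus-water
#' `[M+HCOO]-[H2O]` (net delta +C +O -H, both steps applied jointly to a
#' single reported ion).
#'
#' @param name Text label, e.g. `"[M-H]-"`.
#' @param delta Named integer vector of net atoms added (positive) or removed
#'   (negative) relative to M. May be empty.
#' @param charge Signed integer ion charge; must be non-zero.
#' @return An object of class `adduct_spec`.
#' @examples
#' adduct_spec("[M-H]-", c(H = -1), -1L)
#' names(default_adducts())
#' @export
adduct_spec <- function(name, delta = integer(0), charge = -1L) {
  if (!is.character(name) || length(name) != 1L) abort("`name` must be a string.")
  if (length(delta) && (is.null(names(delta)) || any(!nzchar(names(delta))))) {
    abort("`delta` must be a named vector.")
  }
  bad <- setdiff(names(delta), names(MONOISOTOPIC_MASS))
  if (length(bad)) {
    abort(sprintf("No monoisotopic mass for element(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) abort("`charge` must be a non-zero integer.")
  delta <- delta[delta != 0]
  delta <- setNames(as.integer(delta), names(delta))
  structure(list(name = name, delta = delta, charge = charge),
            class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  d <- if (length(x$delta)) {
    paste(sprintf("%+d %s", unname(x$delta), names(x$delta)), collapse = ", ")
  } else "none"
  cat(sprintf("<adduct_spec> %s (delta: %s; charge %+d)\n", x$name, d, x$charge))
  invisible(x)
}

#' @rdname adduct_spec
#' @export
default_adducts <- function() {
  list(
    "[M-H]-"       = adduct_spec("[M-H]-", c(H = -1L), -1L),
    "[M+HCOO]-"    = adduct_spec("[M+HCOO]-", c(C = 1L, H = 1L, O = 2L), -1L),
    "[M+HCOO]-[H2O]" = adduct_spec("[M+HCOO]-[H2O]",
                                   c(C = 1L, H = -1L, O = 1L), -1L)
  )
}

#' Load an adduct registry from a JSON file
#'
#' The JSON maps adduct name to an object with fields `delta` (element to
#' signed integer) and `charge`. Entries extend/override the built-in registry.
#'
#' @param path Path to a JSON file.
#' @return Named list of `adduct_spec`.
#' @examples
#' reg <- read_adducts(system.file("extdata", "example_adducts.json",
#'                                 package = "netpharm"))
#' names(reg)
#' @export
read_adducts <- function(path) {
  raw <- jsonlite::read_json(path)
  extra <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    adduct_spec(nm, unlist(entry$delta), entry$charge)
  })
  names(extra) <- names(raw)
  utils::modifyList(default_adducts(), extra)
}

resolve_adduct <- function(adduct) {
  if (inherits(adduct, "adduct_spec")) return(adduct)
  if (is.character(adduct) && length(adduct) == 1L) {
    reg <- default_adducts()
    if (!adduct %in% names(reg)) {
      abort(sprintf("Unknown adduct '%s'; known: %s.", adduct,
                    paste(names(reg), collapse = ", ")))
    }
    return(reg[[adduct]])
  }
  abort("`adduct` must be an adduct_spec or a registered adduct name.")
}

#' Theoretical adduct m/z
#'
#' Applies an adduct's net atom delta to a molecular formula and returns the
#' theoretical monoisotopic m/z, i.e. the ion's monoisotopic mass divided by
#' |charge|. By convention (matching standard "calcd" reporting) the electron
#' mass is neglected; set `electron_mass = TRUE` for the electron-corrected
#' value (a shift of about 0.00055 Da per unit charge: electrons are added for
#' anions, removed for cations).
#'
#' @param f Formula string, `elemental_formula`, or named count vector.
#' @param adduct An `adduct_spec` or the name of a registered adduct
#'   (see [default_adducts()]).
#' @param electron_mass Include the electron-mass correction? Default `FALSE`.
#' @return m/z in Da per unit charge (double, full precision). Round to
#'   4 decimals for the conventional "calcd" presentation.
#' @examples
#' round(adduct_mz("C24H20O7", "[M+HCOO]-[H2O]"), 4) # 447.1080
#' round(adduct_mz("C25H26O7", "[M-H]-"), 4)         # 437.1600
#' @export
adduct_mz <- function(f, adduct, electron_mass = FALSE) {
  f <- as_formula(f)
  a <- resolve_adduct(adduct)
  counts <- setNames(as.integer(f), names(f))
  for (el in names(a$delta)) {
    cur <- if (el %in% names(counts)) counts[[el]] else 0L
    counts[el] <- cur + a$delta[[el]]
  }
  if (any(counts < 0L)) {
    bad <- names(counts)[counts < 0L]
    abort(sprintf(
      "Adduct '%s' removes more %s atoms than present in %s.",
      a$name, paste(bad, collapse = ", "), format_formula(f)
    ))
  }
  ion_mass <- monoisotopic_mass(counts[counts > 0L])
  if (isTRUE(electron_mass)) {
    ion_mass <- ion_mass - a$charge * ELECTRON_MASS
  }
  ion_mass / abs(a$charge)
}

#' Tabulate theoretical m/z for a compound table
#'
#' Data-frame-first wrapper: takes a table with a formula column and an adduct
#' name per row (or one adduct for all rows) and appends the theoretical
#' monoisotopic m/z plus its conventional 4-decimal presentation.
#'
#' @param data A data frame.
#' @param formula_col Name of the column holding formula strings.
#' @param adduct One adduct name/spec for all rows, or the name of a column in
#'   `data` holding per-row adduct names.
#' @param electron_mass Passed to [adduct_mz()].
#' @return `data` as a tibble with `mz` and `mz_calcd` (4 dp) columns added.
#' @export
mz_table <- function(data, formula_col = "formula", adduct = "[M-H]-",
                     electron_mass = FALSE) {
  data <- as_tibble(data)
  if (!formula_col %in% names(data)) {
    abort(sprintf("Column '%s' not found.", formula_col))
  }
  adducts <- if (is.character(adduct) && length(adduct) == 1L &&
                 adduct %in% names(data)) {
    data[[adduct]]
  } else {
    rep(list(adduct), nrow(data))
  }
  mz <- purrr::map2_dbl(data[[formula_col]], adducts, function(fm, ad) {
    adduct_mz(fm, ad, electron_mass)
  })
  dplyr::mutate(data, mz = mz, mz_calcd = round(mz, 4))
}
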