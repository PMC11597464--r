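#' Monoisotopic atomic masses
#'
#' Returns the table of monoisotopic atomic masses (in Da) used throughout the
#' package, together with the mass of the proton as the `"proton"` attribute.
#' Values are CODATA/AME full-precision monoisotopic masses; carbon-12 is exact
#' by definition. The table covers every element appearing in the bundled
#' betalain catalog (C, H, N, O, S) plus a few common ones.
#'
#' @return Named numeric vector of monoisotopic masses in Da, with attribute
#'   `proton` (mass of H+ in Da, i.e. the hydrogen atom minus one electron).
#' @examples
#' atomic_masses()[["O"]]
#' attr(atomic_masses(), "proton")
#' @export
atomic_masses <- function() {
  m <- c(
    C  = 12.0,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    Na = 22.9897692809,
    K  = 38.96370668,
    Cl = 34.96885268
  )
  attr(m, "proton") <- 1.007276466
  m
}

#' Mass of the proton in Da
#' @return Numeric scalar, 1.007276466 Da.
#' @export
proton_mass <- function() attr(atomic_masses(), "proton")

new_composition <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts)) counts <- counts[order(names(counts))]
  storage.mode(counts) <- "double"
  structure(counts, class = "elem_comp")
}

#' Construct an elemental composition
#'
#' An elemental composition is a named count vector (element symbol -> number
#' of atoms). Counts must be non-negative integers; zero counts are dropped.
#' The empty composition is valid and has monoisotopic mass 0.
#'
#' @param ... Element counts, e.g. `composition(C = 6, H = 10, O = 5)`.
#'   Alternatively a single named vector.
#' @return An object of class `elem_comp`.
#' @examples
#' composition(C = 6, H = 10, O = 5)
#' @export
composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (is.null(counts)) counts <- numeric(0)
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("composition counts must be named by element symbol")
  if (any(counts < 0)) stop("element counts must be non-negative")
  if (any(counts != round(counts))) stop("element counts must be integers")
  if (anyDuplicated(names(counts))) counts <- tapply(counts, names(counts), sum)
  new_composition(counts)
}

#' @export
format.elem_comp <- function(x, ...) {
  if (!length(x)) return("")
  # Hill order: C, H, then alphabetical
  sym <- names(x)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  paste0(sym[ord], ifelse(x[ord] == 1, "", format(x[ord], scientific = FALSE, trim = TRUE)),
         collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<composition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a molecular formula
#'
#' Accepts both the compact dialect (`"C24H26N2O13"`) and the
#' underscore-subscript dialect used in the source tables
#' (`"C_24_H_26_N_2_O_13_"`). An omitted count means 1 (`"C_9_H_9_NO_5_"`).
#' Whitespace is ignored. Unknown element symbols, malformed counts and the
#' empty string are errors.
#'
#' @param text Formula string.
#' @param masses Atomic mass table; element symbols are validated against it.
#' @return An `elem_comp` (element -> count).
#' @examples
#' parse_formula("C_24_H_26_N_2_O_13_")
#' parse_formula("C9H9NO5")
#' @export
parse_formula <- function(text, masses = atomic_masses()) {
  if (length(text) != 1L || !is.character(text))
    stop("formula must be a single character string")
  s <- gsub("[[:space:]_]", "", text)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(s) || !length(toks))
    stop("malformed formula: ", sQuote(text))
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  # two-letter symbol not in table may really be two one-letter elements (e.g. "NO")
  fix <- which(!(sym %in% names(masses)) & nchar(sym) == 2L & !nzchar(cnt))
  for (i in rev(fix)) {
    first <- substr(sym[i], 1, 1); second <- substr(sym[i], 2, 2)
    second <- toupper(second)
    if (first %in% names(masses) && second %in% names(masses)) {
      sym <- append(sym[-i], c(first, second), after = i - 1L)
      cnt <- append(cnt[-i], c("", ""), after = i - 1L)
    }
  }
  unknown <- setdiff(unique(sym), names(masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  n <- ifelse(nzchar(cnt), suppressWarnings(as.numeric(cnt)), 1)
  if (anyNA(n)) stop("malformed count in formula ", sQuote(text))
  composition(stats::setNames(n, sym))
}

as_composition <- function(x, masses = atomic_masses()) {
  if (inherits(x, "elem_comp")) return(x)
  if (is.character(x)) return(parse_formula(x, masses))
  if (is.numeric(x) && !is.null(names(x))) return(composition(x))
  stop("cannot interpret object of class ", class(x)[1L], " as a composition")
}

#' Composition arithmetic
#'
#' Element-wise addition and subtraction of elemental compositions.
#' Subtraction that would drive any count negative is an error (there is no
#' such molecule), e.g. removing CO2 from a composition without carbon.
#'
#' @param a,b Compositions (or formula strings, which are parsed).
#' @return An `elem_comp`.
#' @examples
#' compose_add("C24H26N2O13", "C6H8O6")     # betanin + glucuronosyl residue
#' compose_subtract("C24H26N2O13", "CO2")   # one decarboxylation
#' @export
compose_add <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  sym <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(sym)), sym); av[names(a)] <- a
  bv <- stats::setNames(rep(0, length(sym)), sym); bv[names(b)] <- b
  new_composition(av + bv)
}

#' @rdname compose_add
#' @export
compose_subtract <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  sym <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(sym)), sym); av[names(a)] <- a
  bv <- stats::setNames(rep(0, length(sym)), sym); bv[names(b)] <- b
  d <- av - bv
  if (any(d < 0))
    stop("composition subtraction would give negative count for: ",
         paste(sym[d < 0], collapse = ", "))
  new_composition(d)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times monoisotopic atomic mass. The empty
#' composition has mass 0.
#'
#' @param comp Composition or formula string.
#' @param masses Atomic mass table.
#' @return Neutral monoisotopic mass in Da (unrounded).
#' @examples
#' monoisotopic_mass("C6H10O5")  # glucosyl residue, 162.0528
#' @export
monoisotopic_mass <- function(comp, masses = atomic_masses()) {
  comp <- as_composition(comp, masses)
  if (!length(comp)) return(0)
  missing <- setdiff(names(comp), names(masses))
  if (length(missing))
    stop("no monoisotopic mass for element(s): ", paste(missing, collapse = ", "))
  sum(unclass(comp) * masses[names(comp)])
}

#' Protonated-ion m/z ([M+H]+)
#'
#' Monoisotopic mass of the neutral molecule plus the proton mass. All ions in
#' this package are treated as singly charged positive, matching
#' positive-mode electrospray acquisition. Internal computation never rounds;
#' use `round_half_away(x, 4)` to reproduce the 4-decimal printing convention
#' of the catalog.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Th (unrounded).
#' @examples
#' round_half_away(protonated_mz("C24H26N2O13"), 4)  # betanin, 551.1508
#' @export
protonated_mz <- function(comp, masses = atomic_masses()) {
  monoisotopic_mass(comp, masses) + attr(masses, "proton")
}

#' Signed ppm mass accuracy
#'
#' `(observed - theoretical) / theoretical * 1e6`. The sign is preserved
#' (instrument calibration bias shows up as a consistent sign).
#'
#' @param observed,theoretical m/z values in Th; `theoretical` must be > 0.
#' @return Signed mass accuracy in ppm (unrounded).
#' @examples
#' ppm_error(551.1483, 551.1508)  # -4.54 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Round half away from zero
#'
#' Presentation rounding used for all reported m/z (4 decimals) and ppm
#' (2 decimals) values: ties round away from zero, unlike base R's
#' round-half-even. Computation is never performed on rounded values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(2.345, 2)   # 2.35
#' round_half_away(-2.345, 2)  # -2.35
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
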