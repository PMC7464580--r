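#' @importFrom stats rnorm runif setNames
#' @importFrom utils head modifyList read.table write.table
NULL

# Pinned monoisotopic atomic masses (Da). Printed ppm values in the
# acylpolyamine literature only reproduce with electron-mass-corrected
# cation masses computed from a table at this precision.
.ATOMIC_MASS <- c(
  H = 1.00782503,
  C = 12.0,
  N = 14.00307401,
  O = 15.99491462,
  F = 18.99840322,
  S = 31.97207117
)

#' Physical constants used in ion m/z arithmetic
#'
#' Monoisotopic masses of the supported elements (H, C, N, O, F, S), the
#' electron mass and the proton mass, all in daltons.
#'
#' @return Named list with elements `atomic`, `electron`, `proton`.
#' @export
#' @examples
#' mass_constants()$proton
mass_constants <- function() {
  list(atomic = .ATOMIC_MASS, electron = 0.00054858, proton = 1.00727646)
}

.ELECTRON_MASS <- 0.00054858
.PROTON_MASS <- 1.00727646

#' Construct a molecular formula
#'
#' A `chem_formula` is a bag of element counts plus a net charge in
#' elementary charges. It is the unit of all mass arithmetic in the package.
#' Zero counts are normalized away; elements are restricted to the pinned
#' atomic-mass table (H, C, N, O, F, S).
#'
#' @param counts named integer vector of element counts (may be empty).
#' @param charge integer net charge (elementary charges), default 0.
#' @return An object of class `chem_formula`.
#' @export
#' @examples
#' chem_formula(c(C = 2, H = 7, N = 1))
chem_formula <- function(counts = integer(), charge = 0L) {
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("element counts must be named")
    bad <- setdiff(names(counts), names(.ATOMIC_MASS))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0))
      stop("negative count for element(s): ",
           paste(names(counts)[counts < 0], collapse = ", "))
    counts <- counts[counts > 0]
    agg <- tapply(as.integer(counts), names(counts), sum)
    els <- c(intersect(c("C", "H"), names(agg)),
             sort(setdiff(names(agg), c("C", "H"))))
    counts <- setNames(as.integer(agg[els]), els)
  } else {
    counts <- setNames(integer(), character())
  }
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "chem_formula")
}

#' Parse a Hill-notation formula string
#'
#' Accepts strings such as `"C27H49N6O3+"` or `"H2O"`: a sequence of element
#' symbols with optional multiplicities, followed by an optional trailing
#' charge sign (`+` or `-`). Multiply charged species use the unambiguous
#' bracketed form `"[C27H50N6O3]2+"` (a bare trailing digit would be
#' indistinguishable from an element count). Zero multiplicities are
#' normalized away.
#'
#' @param text formula string.
#' @return A [chem_formula].
#' @export
#' @examples
#' parse_formula("C27H49N6O3+")
#' parse_formula("[C27H50N6O3]2+")
#' parse_formula("C0H2O")  # same as H2O
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  if (!nzchar(s)) return(chem_formula())
  charge <- 0L
  if (startsWith(s, "[")) {
    m <- regmatches(s, regexpr("^\\[([^]]*)\\]([0-9]*)([+-])$", s))
    if (!length(m))
      stop(sprintf("malformed bracketed ion formula '%s'", text))
    mult <- sub("[+-]$", "", sub("^\\[[^]]*\\]", "", s))
    mag <- if (nzchar(mult)) as.integer(mult) else 1L
    charge <- if (endsWith(s, "+")) mag else -mag
    s <- sub("^\\[", "", sub("\\][0-9]*[+-]$", "", s))
  } else {
    chm <- regmatches(s, regexpr("([+-])$", s))
    if (length(chm)) {
      charge <- if (chm == "+") 1L else -1L
      s <- substr(s, 1L, nchar(s) - 1L)
    }
  }
  counts <- integer()
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    frag <- substr(s, pos, n)
    m <- regmatches(frag, regexpr("^([A-Z][a-z]?)([0-9]*)", frag))
    if (!length(m) || !nzchar(m))
      stop(sprintf("malformed formula token at position %d in '%s'", pos, text))
    sym <- sub("[0-9]*$", "", m)
    if (!sym %in% names(.ATOMIC_MASS))
      stop(sprintf("unknown element symbol '%s' at position %d in '%s'",
                   sym, pos, text))
    mult <- sub("^[A-Za-z]+", "", m)
    cnt <- if (nzchar(mult)) as.integer(mult) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m)
  }
  chem_formula(counts, charge)
}

#' Serialize a formula in Hill notation
#'
#' Carbon first, hydrogen second, remaining elements alphabetical. Singly
#' charged species get a trailing `+`/`-`; multiply charged species are
#' bracketed (`[C27H50N6O3]2+`) to keep the charge multiplicity distinct
#' from element counts.
#'
#' @param f a [chem_formula].
#' @return A single string.
#' @export
#' @examples
#' format_formula(parse_formula("O3N6C27H49+"))
format_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  cnt <- f$counts
  body <- paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
  ch <- f$charge
  if (ch == 0L) return(body)
  sign <- if (ch > 0L) "+" else "-"
  if (abs(ch) == 1L) paste0(body, sign)
  else paste0("[", body, "]", abs(ch), sign)
}

#' @export
format.chem_formula <- function(x, ...) format_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x),
      sprintf("  (%.5f Da)", monoisotopic_mass(x)), "\n", sep = "")
  invisible(x)
}

#' Add or subtract formulas
#'
#' Elementwise sum (`sign = +1`) or difference (`sign = -1`) of two
#' formulas; charges add or subtract accordingly. Subtraction that would
#' drive any element negative is an error naming the offending element.
#'
#' @param a,b [chem_formula] objects.
#' @param sign `+1` or `-1`.
#' @return A [chem_formula].
#' @export
#' @examples
#' formula_combine(parse_formula("C27H49N6O3"), parse_formula("C24H40N5O3"), -1)
formula_combine <- function(a, b, sign = 1L) {
  stopifnot(inherits(a, "chem_formula"), inherits(b, "chem_formula"),
            sign %in% c(1L, -1L))
  els <- union(names(a$counts), names(b$counts))
  av <- setNames(integer(length(els)), els)
  av[names(a$counts)] <- a$counts
  bv <- setNames(integer(length(els)), els)
  bv[names(b$counts)] <- b$counts
  res <- av + sign * bv
  if (any(res < 0L))
    stop("formula subtraction underflow for element(s): ",
         paste(els[res < 0L], collapse = ", "))
  chem_formula(res, a$charge + sign * b$charge)
}

#' @export
`+.chem_formula` <- function(e1, e2) formula_combine(e1, e2, 1L)

#' @export
`-.chem_formula` <- function(e1, e2) formula_combine(e1, e2, -1L)

#' @export
`==.chem_formula` <- function(e1, e2) {
  identical(e1$counts, e2$counts) && e1$charge == e2$charge
}

#' Monoisotopic mass of a formula
#'
#' Neutral-atom sum over the pinned atomic-mass table; no electron
#' correction is applied here (see [ion_mz()] for ions).
#'
#' @param f a [chem_formula].
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("C2H7N"))  # 45.05785
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  if (!length(f$counts)) return(0.0)
  sum(.ATOMIC_MASS[names(f$counts)] * f$counts)
}

#' m/z of an ion with electron-mass correction
#'
#' Computes `(sum of atomic masses + protons_added * m(H) - charge * m_e) /
#' charge`. `atoms` lists every atom in the ion except the added ionizing
#' protons; the net electron deficit equals `charge`.
#'
#' @param atoms [chem_formula] of the ion's atoms (excluding added protons).
#' @param protons_added number of ionizing protons (>= 0).
#' @param charge ion charge (>= 1).
#' @return m/z in Th.
#' @export
#' @examples
#' # [M+H]+ of IndAc4333 (C23H40N6O):
#' ion_mz(parse_formula("C23H40N6O"), protons_added = 1, charge = 1)
ion_mz <- function(atoms, protons_added = 0L, charge = 1L) {
  stopifnot(inherits(atoms, "chem_formula"))
  if (charge < 1L) stop("charge must be >= 1")
  if (protons_added < 0L) stop("protons_added must be >= 0")
  (monoisotopic_mass(atoms) + protons_added * .ATOMIC_MASS[["H"]] -
     charge * .ELECTRON_MASS) / charge
}

#' Relative mass error in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`. Report to two decimals
#' for comparison with published values.
#'
#' @param measured measured m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return Signed ppm error (full precision; round for display).
#' @export
#' @examples
#' ppm_error(146.06041, 146.06004)
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (measured - theoretical) / theoretical * 1e6
}
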