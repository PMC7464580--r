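# Building-block registry: heads, backbone units, N-substituents, tails,
# and amino-acid linkers, each with its formula contribution, number of
# exchangeable (labile N-H/O-H) protons, intrinsic charge, and optional
# diagnostic ions.

.BLOCK_KINDS <- c("head", "unit", "substituent", "tail", "linker")

#' Create an empty building-block registry
#'
#' @return An object of class `block_registry` (environment-backed, so
#'   registration mutates in place).
#' @seealso [default_block_registry()] for the seeded registry.
#' @export
block_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$blocks <- list()
  structure(env, class = "block_registry")
}

#' Register a building block
#'
#' @param registry a [block_registry()].
#' @param kind one of `"head"`, `"unit"`, `"substituent"`, `"tail"`,
#'   `"linker"`.
#' @param abbrev token used in generic names (e.g. `"4-OH-IndAc"`,
#'   `"NMe3"`). Opaque: no chemistry is parsed inside an abbreviation.
#' @param formula [chem_formula] or Hill string of the block's atom
#'   contribution to the assembled molecule.
#' @param exchangeable_h number of labile protons the block contributes.
#' @param intrinsic_charge fixed charge carried by the block (e.g. +1 for a
#'   quaternary NMe3 tail).
#' @param diagnostic_ions named list of extra diagnostic ion formulas
#'   (cations), e.g. tail-internal t-ions.
#' @param style name-formatting style for tails: `"bracketed"` (printed as
#'   `(NMe3)`), `"bare"` (printed as `Arg`), or `"default"` (omitted, the
#'   implicit terminal NH2).
#' @param provisional flag for values not derivable from primary data.
#' @return The registry, invisibly.
#' @export
register_block <- function(registry, kind, abbrev, formula,
                           exchangeable_h = 0L, intrinsic_charge = 0L,
                           diagnostic_ions = list(), style = "bare",
                           provisional = FALSE) {
  stopifnot(inherits(registry, "block_registry"))
  kind <- match.arg(kind, .BLOCK_KINDS)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "chem_formula"))
  if (exchangeable_h < 0L) stop("exchangeable_h must be >= 0")
  nH <- if ("H" %in% names(formula$counts)) formula$counts[["H"]] else 0L
  if (kind != "substituent" && exchangeable_h > nH)
    stop("exchangeable_h cannot exceed the H count of the block")
  key <- paste(kind, abbrev, sep = "\r")
  if (!is.null(registry$blocks[[key]]))
    stop(sprintf("duplicate %s abbreviation '%s'", kind, abbrev))
  diagnostic_ions <- lapply(diagnostic_ions, function(f)
    if (is.character(f)) parse_formula(f) else f)
  registry$blocks[[key]] <- structure(
    list(kind = kind, abbrev = abbrev, atoms = formula,
         exchangeable_h = as.integer(exchangeable_h),
         intrinsic_charge = as.integer(intrinsic_charge),
         diagnostic_ions = diagnostic_ions, style = style,
         provisional = isTRUE(provisional)),
    class = "building_block")
  invisible(registry)
}

#' Look up a building block
#'
#' @param registry a [block_registry()].
#' @param abbrev block token.
#' @param kind block kind; if `NULL`, all kinds are searched.
#' @return A `building_block`, or an error if not found.
#' @export
lookup_block <- function(registry, abbrev, kind = NULL) {
  stopifnot(inherits(registry, "block_registry"))
  kinds <- if (is.null(kind)) .BLOCK_KINDS else match.arg(kind, .BLOCK_KINDS)
  for (k in kinds) {
    b <- registry$blocks[[paste(k, abbrev, sep = "\r")]]
    if (!is.null(b)) return(b)
  }
  stop(sprintf("no registered block '%s'%s", abbrev,
               if (is.null(kind)) "" else paste0(" of kind '", kind, "'")))
}

#' List registered blocks of one kind
#'
#' @param registry a [block_registry()].
#' @param kind block kind.
#' @return List of `building_block` objects.
#' @export
list_blocks <- function(registry, kind) {
  kind <- match.arg(kind, .BLOCK_KINDS)
  keys <- names(registry$blocks)
  registry$blocks[startsWith(keys, paste0(kind, "\r"))]
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf("<%s> %s  %s  exchH=%d  charge=%+d%s\n", x$kind, x$abbrev,
              format_formula(x$atoms), x$exchangeable_h, x$intrinsic_charge,
              if (x$provisional) "  [provisional]" else ""))
  invisible(x)
}

# Atom contribution of a backbone unit: chain of `n` methylenes preceded by
# its nitrogen, i.e. NH(CH2)n = CnH(2n+1)N; an N-OH substituent adds O
# (replacing the N-H by N-OH is a net +O), an N-Me adds CH2.
unit_atoms <- function(chain, nsub = "H") {
  if (chain < 1L || chain > 9L) stop("chain length must be 1-9 methylenes")
  f <- chem_formula(c(C = chain, H = 2L * chain + 1L, N = 1L))
  switch(nsub,
         H = f,
         OH = f + chem_formula(c(O = 1L)),
         Me = f + chem_formula(c(C = 1L, H = 2L)),
         stop(sprintf("unknown N-substituent '%s'", nsub)))
}

# Exchangeable protons carried by a backbone nitrogen: N-H and N-OH each
# carry one labile proton, N-Me none.
unit_exchangeable_h <- function(nsub) {
  switch(nsub, H = 1L, OH = 1L, Me = 0L,
         stop(sprintf("unknown N-substituent '%s'", nsub)))
}

#' Seeded default building-block registry
#'
#' Heads: IndAc (indolylacetyl), 4-OH-IndAc, 4-OH-Bz, 2,4-(OH)2-PhAc.
#' Tails: the default terminal NH2, NMe2, NMe3 (fixed cation), Arg, Gu.
#' Linker: Asn. Substituents: OH, Me. Backbone units 1-9.
#'
#' Exchangeable-proton counts for the Arg and Gu tails and the Asn linker
#' are provisional conventions (not derivable from the reference data used
#' to validate the mass arithmetic) and are flagged as such.
#'
#' @return A seeded [block_registry()], user-extensible via
#'   [register_block()].
#' @export
#' @examples
#' reg <- default_block_registry()
#' lookup_block(reg, "4-OH-IndAc", "head")
default_block_registry <- function() {
  reg <- block_registry()
  # acyl heads (formula = acyl group as attached, R-CO-)
  register_block(reg, "head", "IndAc", "C10H8NO", exchangeable_h = 1L)
  register_block(reg, "head", "4-OH-IndAc", "C10H8NO2", exchangeable_h = 2L)
  register_block(reg, "head", "4-OH-Bz", "C7H5O2", exchangeable_h = 1L)
  register_block(reg, "head", "2,4-(OH)2-PhAc", "C8H7O3", exchangeable_h = 2L)
  # backbone units 1..9 (chain only; the N-substituent is resolved at
  # assembly time)
  for (n in 1:9)
    register_block(reg, "unit", as.character(n),
                   chem_formula(c(C = n, H = 2L * n + 1L, N = 1L)),
                   exchangeable_h = 1L)
  # N-substituents
  register_block(reg, "substituent", "OH", chem_formula(c(O = 1L)),
                 exchangeable_h = 1L)
  register_block(reg, "substituent", "Me", chem_formula(c(C = 1L, H = 2L)),
                 exchangeable_h = 0L)
  # tails
  register_block(reg, "tail", "NH2", chem_formula(c(H = 2L, N = 1L)),
                 exchangeable_h = 2L, style = "default")
  register_block(reg, "tail", "NMe2", "C2H6N", exchangeable_h = 0L,
                 style = "bracketed")
  register_block(reg, "tail", "NMe3", "C3H9N", exchangeable_h = 0L,
                 intrinsic_charge = 1L, style = "bracketed")
  # Arg: terminal NH amide-bonded to the arginine carboxyl;
  # Gu: terminal NH carrying a guanidino group. Exchangeable-H counts
  # provisional.
  register_block(reg, "tail", "Arg", "C6H14N5O", exchangeable_h = 7L,
                 provisional = TRUE)
  register_block(reg, "tail", "Gu", "CH4N3", exchangeable_h = 4L,
                 provisional = TRUE)
  # amino-acid linker (asparagine residue -NH-CH(CH2CONH2)-CO-);
  # exchangeable H = amide NH + side-chain NH2, provisional
  register_block(reg, "linker", "Asn", "C4H6N2O2", exchangeable_h = 3L,
                 provisional = TRUE)
  reg
}

#' Diagnostic head fragment ions (a0 and a')
#'
#' The a0 ion is the head acylium cation (the head's atoms carrying the
#' positive charge); a' is a0 minus CO. Both are even-electron singly
#' charged cations whose m/z carries the one-electron deficit correction.
#'
#' @param head a `building_block` of kind `"head"`.
#' @return Data frame with columns `label`, `formula`, `mz`.
#' @export
#' @examples
#' reg <- default_block_registry()
#' head_diagnostic_ions(lookup_block(reg, "4-OH-IndAc", "head"))
head_diagnostic_ions <- function(head) {
  stopifnot(inherits(head, "building_block"))
  if (head$kind != "head")
    stop("head_diagnostic_ions() requires a block of kind 'head'")
  a0 <- chem_formula(head$atoms$counts, charge = 1L)
  co <- chem_formula(c(C = 1L, O = 1L))
  aprime <- tryCatch(formula_combine(a0, co, -1L), error = function(e)
    stop("head too small to lose CO for the a' ion: ", conditionMessage(e)))
  data.frame(
    label = c("a0", "a'"),
    formula = c(format_formula(a0), format_formula(aprime)),
    mz = c(ion_mz(a0, 0L, 1L), ion_mz(aprime, 0L, 1L)),
    stringsAsFactors = FALSE
  )
}

#' Write block definitions to JSON
#'
#' @param registry a [block_registry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(registry, path) {
  stopifnot(inherits(registry, "block_registry"))
  recs <- lapply(unname(registry$blocks), function(b) {
    list(kind = b$kind, abbrev = b$abbrev,
         formula = format_formula(b$atoms),
         exchangeable_h = b$exchangeable_h,
         intrinsic_charge = b$intrinsic_charge,
         diagnostic_ions = lapply(b$diagnostic_ions, format_formula),
         style = b$style, provisional = b$provisional)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read block definitions from JSON
#'
#' @param path JSON file written by [write_blocks()] (schema: `kind`,
#'   `abbrev`, `formula`, `exchangeable_h`, `intrinsic_charge`,
#'   `diagnostic_ions`, `style`, `provisional`).
#' @return A [block_registry()].
#' @export
read_blocks <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- block_registry()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    ok <- tryCatch({
      register_block(reg, r$kind, r$abbrev, r$formula,
                     exchangeable_h = r$exchangeable_h %||% 0L,
                     intrinsic_charge = r$intrinsic_charge %||% 0L,
                     diagnostic_ions = r$diagnostic_ions %||% list(),
                     style = r$style %||% "bare",
                     provisional = r$provisional %||% FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("invalid block record %d: %s", i, conditionMessage(ok)))
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
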