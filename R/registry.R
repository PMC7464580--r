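# Local compound registry: records with generic/trivial names, species,
# formula, precursor m/z list, retention time under the standardized
# chromatographic method, structure-reliability level (S-1..S-5) and
# data-comparability level (C-1..C-4), and an optional reference spectrum.

.S_LEVELS <- paste0("S-", 1:5)
.C_LEVELS <- paste0("C-", 1:4)

#' Create a compound record
#'
#' @param generic_name generic (or, for non-polyamines, conventional) name.
#' @param trivial_names character vector of trivial-name aliases.
#' @param species character vector of source species.
#' @param family taxonomic family.
#' @param formula [chem_formula], Hill string, or `NULL` (permitted only at
#'   reliability level S-5, unknown structure).
#' @param monoisotopic_mass neutral/cation monoisotopic mass in Da
#'   (computed from `formula` when available).
#' @param cas optional CAS number.
#' @param n_exchangeable optional exchangeable-proton count.
#' @param rt_min optional retention time (minutes) under the standardized
#'   method.
#' @param s_level structure-reliability level, `"S-1"` (synthesis-confirmed)
#'   to `"S-5"` (unknown structure).
#' @param c_level data-comparability level, `"C-1"` (standardized MS/MS
#'   available) to `"C-4"` (no spectra or predictions). `"C-1"` requires a
#'   reference spectrum.
#' @param references character vector of citation strings.
#' @param reference_spectrum optional [new_spectrum()].
#' @param precursor_mzs numeric vector of precursor ion m/z values
#'   (singly/doubly charged species).
#' @return Object of class `compound_record`.
#' @export
compound_record <- function(generic_name, trivial_names = character(),
                            species = character(), family = "",
                            formula = NULL, monoisotopic_mass = NA_real_,
                            cas = NA_character_, n_exchangeable = NA_integer_,
                            rt_min = NA_real_, s_level, c_level,
                            references = character(),
                            reference_spectrum = NULL,
                            precursor_mzs = numeric()) {
  if (!s_level %in% .S_LEVELS)
    stop(sprintf("invalid structure-reliability level '%s' (expected %s)",
                 s_level, paste(.S_LEVELS, collapse = "/")))
  if (!c_level %in% .C_LEVELS)
    stop(sprintf("invalid comparability level '%s' (expected %s)",
                 c_level, paste(.C_LEVELS, collapse = "/")))
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(formula) && s_level != "S-5")
    stop("a formula is required for records below reliability level S-5")
  if (c_level == "C-1" && is.null(reference_spectrum))
    stop("comparability level C-1 requires a reference spectrum")
  if (!is.null(reference_spectrum))
    stopifnot(inherits(reference_spectrum, "spectrum"))
  if (!is.null(formula) && is.na(monoisotopic_mass))
    monoisotopic_mass <- monoisotopic_mass(formula)
  structure(list(
    generic_name = generic_name, trivial_names = trivial_names,
    species = species, family = family, formula = formula,
    monoisotopic_mass = monoisotopic_mass, cas = cas,
    n_exchangeable = n_exchangeable, rt_min = rt_min, s_level = s_level,
    c_level = c_level, references = references,
    reference_spectrum = reference_spectrum,
    precursor_mzs = as.numeric(precursor_mzs)
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound> %s  [%s/%s]%s\n", x$generic_name, x$s_level,
              x$c_level,
              if (is.null(x$formula)) "" else
                paste0("  ", format_formula(x$formula))))
  invisible(x)
}

#' Build a compound registry from records
#'
#' @param records list of [compound_record()] objects; duplicate generic
#'   names are rejected.
#' @return Object of class `compound_registry`.
#' @export
compound_registry <- function(records = list()) {
  names_ <- vapply(records, `[[`, "", "generic_name")
  dup <- names_[duplicated(names_)]
  if (length(dup))
    stop("duplicate generic name(s) in registry: ",
         paste(unique(dup), collapse = ", "))
  structure(list(records = records), class = "compound_registry")
}

#' @export
print.compound_registry <- function(x, ...) {
  cat(sprintf("<compound registry> %d records\n", length(x$records)))
  invisible(x)
}

#' @export
length.compound_registry <- function(x) length(x$records)

#' Load a compound registry from JSON
#'
#' One object per record; schema as written by [write_compound_registry()].
#' Validation failures name the offending record index.
#'
#' @param path JSON file path.
#' @return A [compound_registry()].
#' @export
load_compound_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    spec <- NULL
    if (!is.null(r$reference_spectrum)) {
      rs <- r$reference_spectrum
      spec <- new_spectrum(unlist(rs$mz), unlist(rs$intensity),
                           precursor_mz = rs$precursor_mz %||% NA_real_,
                           precursor_charge = rs$precursor_charge %||% NA_integer_,
                           title = rs$title %||% "")
    }
    tryCatch(
      compound_record(
        generic_name = r$generic_name,
        trivial_names = unlist(r$trivial_names) %||% character(),
        species = unlist(r$species) %||% character(),
        family = r$family %||% "",
        formula = if (is.character(r$formula)) r$formula else NULL,
        cas = r$cas %||% NA_character_,
        n_exchangeable = r$n_exchangeable %||% NA_integer_,
        rt_min = r$rt_min %||% NA_real_,
        s_level = r$s_level, c_level = r$c_level,
        references = unlist(r$references) %||% character(),
        reference_spectrum = spec,
        precursor_mzs = unlist(r$precursor_mzs) %||% numeric()),
      error = function(e)
        stop(sprintf("invalid compound record %d: %s", i,
                     conditionMessage(e)), call. = FALSE))
  })
  compound_registry(records)
}

#' Write a compound registry to JSON
#'
#' @param registry a [compound_registry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_compound_registry <- function(registry, path) {
  stopifnot(inherits(registry, "compound_registry"))
  recs <- lapply(registry$records, function(r) {
    out <- list(generic_name = r$generic_name,
                trivial_names = r$trivial_names, species = r$species,
                family = r$family,
                formula = if (is.null(r$formula)) NULL else
                  format_formula(r$formula),
                monoisotopic_mass = r$monoisotopic_mass, cas = r$cas,
                n_exchangeable = r$n_exchangeable, rt_min = r$rt_min,
                s_level = r$s_level, c_level = r$c_level,
                references = r$references, precursor_mzs = r$precursor_mzs)
    if (!is.null(r$reference_spectrum)) {
      sp <- r$reference_spectrum
      out$reference_spectrum <- list(
        mz = round(sp$peaks$mz, 5), intensity = round(sp$peaks$intensity, 4),
        precursor_mz = sp$precursor_mz,
        precursor_charge = sp$precursor_charge, title = sp$title)
    }
    out
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Search the registry by exact molecular formula
#'
#' Element counts and net charge must match exactly: a fixed cation record
#' (e.g. a quaternary-ammonium toxin stored as its cation formula) is not
#' returned for the corresponding neutral formula, mirroring how such
#' compounds are indexed under the formula of the non-protonated structure.
#'
#' @param registry a [compound_registry()].
#' @param formula [chem_formula] or Hill string.
#' @return List of matching [compound_record()]s.
#' @export
search_by_formula <- function(registry, formula) {
  stopifnot(inherits(registry, "compound_registry"))
  if (is.character(formula)) formula <- parse_formula(formula)
  Filter(function(r) !is.null(r$formula) &&
           identical(r$formula$counts, formula$counts) &&
           r$formula$charge == formula$charge,
         registry$records)
}

#' Search the registry by floored precursor m/z
#'
#' Returns records for which any stored precursor ion m/z, rounded down to
#' the nearest whole number, equals `mz_floor`.
#'
#' @param registry a [compound_registry()].
#' @param mz_floor integer floor of the observed precursor m/z (>= 1).
#' @return List of matching [compound_record()]s.
#' @export
search_by_precursor <- function(registry, mz_floor) {
  stopifnot(inherits(registry, "compound_registry"))
  if (mz_floor < 1) stop("mz_floor must be >= 1")
  Filter(function(r) length(r$precursor_mzs) &&
           any(floor(r$precursor_mzs) == mz_floor),
         registry$records)
}

#' Filter candidates by retention time
#'
#' Keeps candidates whose standardized retention time lies within
#' `rel_tol` (default 2%) of the observed value; the half-window is
#' `rel_tol * observed_rt` (reported rounded to two decimals, e.g.
#' 8.89 +/- 0.18 min). Records lacking a standardized retention time pass
#' through flagged as not comparable.
#'
#' @param candidates list of [compound_record()]s.
#' @param observed_rt observed retention time in minutes (> 0).
#' @param rel_tol relative tolerance (fraction of the observed value).
#' @return List of surviving records, with attributes `window` (rounded
#'   half-window) and `status` (named character vector `"kept"`,
#'   `"excluded"` or `"not comparable"` per input candidate).
#' @export
rt_filter <- function(candidates, observed_rt, rel_tol = 0.02) {
  if (observed_rt <= 0) stop("observed_rt must be > 0")
  half <- rel_tol * observed_rt
  status <- vapply(candidates, function(r) {
    if (is.na(r$rt_min)) "not comparable"
    else if (abs(r$rt_min - observed_rt) <= half) "kept"
    else "excluded"
  }, "")
  names(status) <- vapply(candidates, `[[`, "", "generic_name")
  kept <- candidates[status != "excluded"]
  attr(kept, "window") <- round(half, 2)
  attr(kept, "status") <- status
  kept
}

#' Export search results as CSV
#'
#' @param records list of [compound_record()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_csv <- function(records, path) {
  tab <- do.call(rbind, lapply(records, function(r) data.frame(
    generic_name = r$generic_name,
    trivial_names = paste(r$trivial_names, collapse = "; "),
    formula = if (is.null(r$formula)) "" else format_formula(r$formula),
    monoisotopic_mass = round(r$monoisotopic_mass, 5),
    rt_min = r$rt_min, s_level = r$s_level, c_level = r$c_level,
    stringsAsFactors = FALSE)))
  if (is.null(tab))
    tab <- data.frame(generic_name = character(), trivial_names = character(),
                      formula = character(), monoisotopic_mass = numeric(),
                      rt_min = numeric(), s_level = character(),
                      c_level = character())
  write.table(tab, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}
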