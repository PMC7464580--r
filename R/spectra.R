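# Centroided peak-list handling: MGF/TSV reading and writing, annotation
# of observed peaks with predicted ions at ppm tolerance, and spectral
# similarity for library matching.

#' Construct a spectrum
#'
#' @param mz,intensity numeric vectors of equal length; peaks are stored
#'   sorted ascending by m/z.
#' @param precursor_mz precursor m/z (optional).
#' @param precursor_charge precursor charge (optional).
#' @param rt_min retention time in minutes (optional).
#' @param title title string.
#' @return Object of class `spectrum` with a `peaks` data frame.
#' @export
new_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                         precursor_charge = NA_integer_, rt_min = NA_real_,
                         title = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && (any(!is.finite(mz)) || any(!is.finite(intensity))))
    stop("peak m/z and intensities must be finite")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  ord <- order(mz)
  structure(list(
    peaks = data.frame(mz = as.numeric(mz[ord]),
                       intensity = as.numeric(intensity[ord])),
    precursor_mz = precursor_mz,
    precursor_charge = as.integer(precursor_charge),
    rt_min = rt_min, title = title
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> '%s': %d peaks", x$title, nrow(x$peaks)))
  if (!is.na(x$precursor_mz))
    cat(sprintf(", precursor %.5f (%s+)", x$precursor_mz,
                ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  if (!is.na(x$rt_min)) cat(sprintf(", Rt %.2f min", x$rt_min))
  cat("\n")
  invisible(x)
}

#' Read centroided peak lists
#'
#' Supports Mascot Generic Format (`BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, `CHARGE`, `RTINSECONDS` and `TITLE` headers) and two-column
#' TSV (m/z, intensity; optional header line). Malformed MGF blocks raise
#' errors naming the offending line; an empty file yields an empty list.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"tsv"`.
#' @return List of [new_spectrum()] objects.
#' @export
read_peaklist <- function(path, format = c("auto", "mgf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "txt", "tab")) "tsv" else "mgf"
  }
  if (format == "tsv") return(list(.read_tsv_peaks(path)))
  .read_mgf(path)
}

.read_tsv_peaks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(new_spectrum(numeric(), numeric(), title = basename(path)))
  first <- strsplit(trimws(lines[[1L]]), "[\t ]+")[[1L]]
  skip <- if (suppressWarnings(any(is.na(as.numeric(first))))) 1L else 0L
  body <- lines[(1L + skip):length(lines)]
  if (!length(body))
    return(new_spectrum(numeric(), numeric(), title = basename(path)))
  vals <- lapply(seq_along(body), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(body[[i]]), "[\t ]+")[[1L]]))
    if (length(f) < 2L || any(is.na(f[1:2])))
      stop(sprintf("malformed TSV peak at line %d of %s", i + skip, path))
    f[1:2]
  })
  m <- do.call(rbind, vals)
  new_spectrum(m[, 1L], m[, 2L], title = basename(path))
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    if (line != "BEGIN IONS")
      stop(sprintf("unexpected content outside BEGIN/END IONS at line %d: '%s'",
                   i, line))
    begin_line <- i
    i <- i + 1L
    meta <- list(precursor_mz = NA_real_, charge = NA_integer_,
                 rt_min = NA_real_, title = "")
    mzv <- numeric(); intv <- numeric()
    closed <- FALSE
    while (i <= n) {
      l <- trimws(lines[[i]])
      if (l == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (!nzchar(l)) { i <- i + 1L; next }
      if (grepl("=", l, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", l))
        val <- sub("^[^=]*=", "", l)
        if (key == "PEPMASS") {
          meta$precursor_mz <- suppressWarnings(
            as.numeric(strsplit(trimws(val), "[\t ]+")[[1L]][1L]))
          if (is.na(meta$precursor_mz))
            stop(sprintf("malformed PEPMASS at line %d", i))
        } else if (key == "CHARGE") {
          meta$charge <- suppressWarnings(as.integer(gsub("[+-]", "", val)))
        } else if (key == "RTINSECONDS") {
          meta$rt_min <- suppressWarnings(as.numeric(val)) / 60
        } else if (key == "TITLE") {
          meta$title <- val
        }
      } else {
        f <- suppressWarnings(as.numeric(strsplit(l, "[\t ]+")[[1L]]))
        if (length(f) < 1L || any(is.na(f[seq_len(min(2L, length(f)))])))
          stop(sprintf("malformed peak line %d: '%s'", i, l))
        mzv <- c(mzv, f[1L])
        intv <- c(intv, if (length(f) >= 2L) f[2L] else 1.0)
      }
      i <- i + 1L
    }
    if (!closed)
      stop(sprintf("BEGIN IONS at line %d has no matching END IONS", begin_line))
    spectra[[length(spectra) + 1L]] <- new_spectrum(
      mzv, intv, precursor_mz = meta$precursor_mz,
      precursor_charge = meta$charge, rt_min = meta$rt_min,
      title = meta$title)
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra a `spectrum` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz))
      writeLines(sprintf("PEPMASS=%.5f", sp$precursor_mz), con)
    if (!is.na(sp$precursor_charge))
      writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (!is.na(sp$rt_min))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$rt_min * 60), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.5f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Annotate a spectrum with predicted ions
#'
#' Each peak is linked to the predicted ion with the smallest absolute ppm
#' error within tolerance (one annotation per peak; ties broken toward the
#' lower-m/z prediction). Predictions not linked to any peak are reported
#' as unmatched. Annotation depends on m/z only, never on intensity.
#'
#' @param spectrum a [new_spectrum()].
#' @param predicted data frame of predicted ions with columns `ion_type`,
#'   `index`, `formula`, `mz` (as from [fragment_ions()]), optionally with
#'   precursor rows.
#' @param tol_ppm match tolerance in ppm (> 0), default 5.
#' @return Object of class `annotated_spectrum` with elements `spectrum`,
#'   `annotations` (peak, ion, ppm error) and `unmatched_predicted`.
#' @export
annotate_spectrum <- function(spectrum, predicted, tol_ppm = 5) {
  stopifnot(inherits(spectrum, "spectrum"), tol_ppm > 0)
  pred <- as.data.frame(predicted)
  stopifnot(all(c("ion_type", "formula", "mz") %in% names(pred)))
  if (!"index" %in% names(pred)) pred$index <- NA_integer_
  pred <- pred[order(pred$mz), , drop = FALSE]
  ann <- list()
  used <- logical(nrow(pred))
  pk <- spectrum$peaks
  for (i in seq_len(nrow(pk))) {
    if (!nrow(pred)) break
    errs <- ppm_error(pk$mz[i], pred$mz)
    ok <- which(abs(errs) <= tol_ppm)
    if (!length(ok)) next
    best <- ok[order(abs(errs[ok]), pred$mz[ok])][1L]
    used[best] <- TRUE
    ann[[length(ann) + 1L]] <- data.frame(
      peak = i, mz = pk$mz[i], intensity = pk$intensity[i],
      ion_type = pred$ion_type[best], index = pred$index[best],
      formula = pred$formula[best], theoretical_mz = pred$mz[best],
      ppm = errs[best], stringsAsFactors = FALSE)
  }
  structure(list(
    spectrum = spectrum,
    annotations = if (length(ann)) do.call(rbind, ann) else
      data.frame(peak = integer(), mz = numeric(), intensity = numeric(),
                 ion_type = character(), index = integer(),
                 formula = character(), theoretical_mz = numeric(),
                 ppm = numeric(), stringsAsFactors = FALSE),
    unmatched_predicted = pred[!used, , drop = FALSE],
    tol_ppm = tol_ppm
  ), class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat(sprintf("<annotated spectrum> %d/%d peaks annotated (tol %.1f ppm), %d predictions unmatched\n",
              nrow(x$annotations), nrow(x$spectrum$peaks), x$tol_ppm,
              nrow(x$unmatched_predicted)))
  a <- x$annotations
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %10.5f  %-3s%-3s %-16s %+6.2f ppm\n", a$mz[i],
                a$ion_type[i], ifelse(is.na(a$index[i]), "", a$index[i]),
                a$formula[i], a$ppm[i]))
  invisible(x)
}

#' Write annotations as TSV
#'
#' @param annotated an `annotated_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotated, path) {
  stopifnot(inherits(annotated, "annotated_spectrum"))
  a <- annotated$annotations
  a$ppm <- round(a$ppm, 2)
  a$mz <- round(a$mz, 5)
  a$theoretical_mz <- round(a$theoretical_mz, 5)
  write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spectral similarity
#'
#' Cosine score over square-root-transformed intensities of peak pairs
#' matched within a ppm tolerance (square-root weighting de-emphasizes
#' base peaks, as in standard library-search practice). Also reports the
#' fraction of reference (`b`) peaks matched.
#'
#' @param a,b non-empty [new_spectrum()] objects (`b` is the reference).
#' @param tol_ppm match tolerance in ppm.
#' @return List with `score` in \[0, 1\] and `matched_fraction` (share of
#'   `b`'s peaks matched).
#' @export
spectrum_similarity <- function(a, b, tol_ppm = 5) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!nrow(a$peaks) || !nrow(b$peaks))
    stop("spectral similarity requires non-empty spectra")
  wa <- sqrt(a$peaks$intensity)
  wb <- sqrt(b$peaks$intensity)
  # greedy unique matching by ascending |ppm|
  pairs <- list()
  for (i in seq_len(nrow(a$peaks))) {
    errs <- abs(ppm_error(a$peaks$mz[i], b$peaks$mz))
    ok <- which(errs <= tol_ppm)
    for (j in ok)
      pairs[[length(pairs) + 1L]] <- c(i, j, errs[j])
  }
  dot <- 0.0
  matched_b <- logical(nrow(b$peaks))
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3L]), , drop = FALSE]
    used_a <- logical(nrow(a$peaks))
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1L]; j <- pm[r, 2L]
      if (used_a[i] || matched_b[j]) next
      used_a[i] <- TRUE
      matched_b[j] <- TRUE
      dot <- dot + wa[i] * wb[j]
    }
  }
  list(score = dot / (sqrt(sum(wa^2)) * sqrt(sum(wb^2))),
       matched_fraction = mean(matched_b))
}
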