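# Rule-based prediction engine: molecular formula, precursor ion species,
# MS/MS fragment ion series, and exchangeable-proton (HDX) accounting for
# an assembled polyamine structure.
#
# The a-type series (head-retaining even-electron cations formed by
# intramolecular nucleophilic substitution at protonated amino groups) and
# the a0/a' head diagnostics are the validated core. The b-, c-, z- and
# t-type rules are configurable reconstructions (see `fragment_rules()`):
# the ion types are standard for this compound class but their exact
# offsets are conventions of this package, flagged provisional.

.TFA_NEUTRAL <- "C2HF3O2"  # trifluoroacetic acid, 113.99286 Da

#' Molecular formula of a polyamine structure
#'
#' Head + optional linker + backbone-unit contributions (CnH(2n+1)N per
#' unit, +O for N-OH, +CH2 for N-Me) + tail. The net charge equals the
#' tail's intrinsic charge (e.g. +1 for a quaternary NMe3 tail).
#'
#' @param s a [polyamine_structure()].
#' @return A [chem_formula].
#' @export
#' @examples
#' molecular_formula(parse_generic_name("IndAc4333"))  # C23H40N6O
molecular_formula <- function(s) {
  stopifnot(inherits(s, "polyamine_structure"))
  f <- s$head$atoms
  if (!is.null(s$linker)) f <- f + s$linker$atoms
  for (u in s$units) f <- f + unit_atoms(u$chain, u$nsub)
  f <- f + s$tail$atoms
  chem_formula(f$counts, s$intrinsic_charge)
}

#' Precursor ion species and m/z
#'
#' For neutral structures: `[M+H]+`, `[M+2H]2+` and the TFA adduct
#' `[M+H+TFA]+` (TFA = trifluoroacetic acid from the mobile phase). For
#' fixed singly charged cations: `M+`, `[M+H]2+` and the TFA adduct
#' `[(M+H)+CF3CO2]+` (the cation associated with neutral TFA).
#'
#' @param s a [polyamine_structure()].
#' @return Data frame with columns `label`, `protons_added`, `charge`,
#'   `formula`, `mz`.
#' @export
#' @examples
#' precursor_ion_set(parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+"))
precursor_ion_set <- function(s) {
  M <- molecular_formula(s)
  tfa <- parse_formula(.TFA_NEUTRAL)
  if (s$intrinsic_charge == 0L) {
    labels <- c("[M+H]+", "[M+2H]2+", "[M+H+TFA]+")
    protons <- c(1L, 2L, 1L)
    charges <- c(1L, 2L, 1L)
    atoms <- list(M, M, M + tfa)
  } else if (s$intrinsic_charge == 1L) {
    labels <- c("M+", "[M+H]2+", "[(M+H)+CF3CO2]+")
    protons <- c(0L, 1L, 0L)
    charges <- c(1L, 2L, 1L)
    atoms <- list(M, M, M + tfa)
  } else {
    stop("structures with intrinsic charge > 1 are not supported")
  }
  data.frame(
    label = labels, protons_added = protons, charge = charges,
    formula = vapply(seq_along(atoms), function(i) {
      withH <- if (protons[[i]] > 0L)
        atoms[[i]] + chem_formula(c(H = protons[[i]])) else atoms[[i]]
      format_formula(chem_formula(withH$counts, charges[[i]]))
    }, ""),
    mz = vapply(seq_along(atoms), function(i)
      ion_mz(atoms[[i]], protons[[i]], charges[[i]]), 0.0),
    stringsAsFactors = FALSE
  )
}

#' Fragment-rule configuration
#'
#' Toggles for the individual fragment ion types emitted by
#' [fragment_ions()]. The a-series and a0/a' head diagnostics are the
#' validated core; b, c, y, z and t rules are package conventions and can
#' be switched off individually.
#'
#' @param a,a_head,y,b,c,z,t logical toggles (`a_head` covers a0 and a').
#' @return Named logical list.
#' @export
fragment_rules <- function(a = TRUE, a_head = TRUE, y = TRUE, b = TRUE,
                           c = TRUE, z = TRUE, t = TRUE) {
  list(a = a, a_head = a_head, y = y, b = b, c = c, z = z, t = t)
}

# group atoms of an N-substituent as removed/added in b/c/z arithmetic
.nsub_group <- function(nsub) {
  switch(nsub,
         H = chem_formula(c(H = 1L)),
         OH = chem_formula(c(O = 1L, H = 1L)),
         Me = chem_formula(c(C = 1L, H = 3L)))
}

#' Rule-based MS/MS fragment ions
#'
#' Emits singly charged even-electron fragment cations for a polyamine
#' structure:
#' * `a_k` — head (+ linker) plus backbone units 1..k, as a cation
#'   (m/z = mass − electron mass); `a0` (head acylium) and `a'` (a0 − CO)
#'   head diagnostics.
#' * `y_j` — the tail-side complement retaining j backbone units plus the
#'   tail, as a protonated amine (neutral structures only).
#' * `c_k = a_k + N(s)H2` and `b_k = c_k − H2`, where s is the substituent
#'   on the next nitrogen (provisional conventions).
#' * `z_j = y_j − N(s)H2 − H` (provisional convention).
#' * `t` — tail/linker diagnostic ions from the block's diagnostic table.
#'
#' The fragment `index` counts backbone units on the retained side.
#'
#' @param s a [polyamine_structure()].
#' @param rules a [fragment_rules()] configuration.
#' @return Data frame with columns `ion_type`, `index`, `formula`, `mz`,
#'   `charge`, sorted by m/z.
#' @export
#' @examples
#' fr <- fragment_ions(parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+"))
#' subset(fr, ion_type == "a")
fragment_ions <- function(s, rules = fragment_rules()) {
  stopifnot(inherits(s, "polyamine_structure"))
  n <- length(s$units)
  M <- molecular_formula(s)
  out <- list()
  add <- function(type, index, atoms, mz) {
    out[[length(out) + 1L]] <<- data.frame(
      ion_type = type, index = index,
      formula = format_formula(chem_formula(atoms$counts, 1L)),
      mz = mz, charge = 1L, stringsAsFactors = FALSE)
  }

  if (isTRUE(rules$a_head)) {
    dg <- head_diagnostic_ions(s$head)
    out[[length(out) + 1L]] <- data.frame(
      ion_type = dg$label, index = 0L, formula = dg$formula, mz = dg$mz,
      charge = 1L, stringsAsFactors = FALSE)
  }

  # cumulative head-side substructures (head + linker + units 1..k)
  aside <- vector("list", n)
  acc <- s$head$atoms
  if (!is.null(s$linker)) acc <- acc + s$linker$atoms
  for (k in seq_len(n)) {
    acc <- acc + unit_atoms(s$units[[k]]$chain, s$units[[k]]$nsub)
    aside[[k]] <- acc
  }

  if (isTRUE(rules$a))
    for (k in seq_len(n)) add("a", k, aside[[k]], ion_mz(aside[[k]], 0L, 1L))

  if (isTRUE(rules$c) || isTRUE(rules$b)) {
    for (k in seq_len(n - 1L)) {
      nh2s <- chem_formula(c(N = 1L, H = 2L)) +
        .nsub_group(s$units[[k + 1L]]$nsub)
      catoms <- aside[[k]] + nh2s
      if (isTRUE(rules$c)) add("c", k, catoms, ion_mz(catoms, 0L, 1L))
      if (isTRUE(rules$b)) {
        batoms <- tryCatch(catoms - chem_formula(c(H = 2L)),
                           error = function(e) NULL)
        if (!is.null(batoms)) add("b", k, batoms, ion_mz(batoms, 0L, 1L))
      }
    }
  }

  # tail-side fragments only exist for neutral structures (a fixed cationic
  # tail keeps the charge on the head side ion and leaves as a neutral)
  if (s$intrinsic_charge == 0L && (isTRUE(rules$y) || isTRUE(rules$z))) {
    H1 <- chem_formula(c(H = 1L))
    for (j in seq_len(n)) {
      cut <- n - j  # complement of a_cut
      headside <- if (cut == 0L) {
        hh <- s$head$atoms
        if (!is.null(s$linker)) hh <- hh + s$linker$atoms
        hh
      } else aside[[cut]]
      yatoms <- (M - headside) + H1
      if (isTRUE(rules$y)) add("y", j, yatoms, ion_mz(yatoms, 1L, 1L))
      if (isTRUE(rules$z)) {
        rem <- chem_formula(c(N = 1L, H = 2L)) +
          .nsub_group(s$units[[cut + 1L]]$nsub) + H1
        zatoms <- tryCatch(yatoms - rem, error = function(e) NULL)
        if (!is.null(zatoms))
          add("z", j, zatoms, ion_mz(zatoms, 1L, 1L))
      }
    }
  }

  if (isTRUE(rules$t)) {
    emit_diag <- function(block, type) {
      for (lbl in names(block$diagnostic_ions)) {
        f <- block$diagnostic_ions[[lbl]]
        add(type, NA_integer_, f, ion_mz(f, 0L, 1L))
      }
    }
    emit_diag(s$tail, "t_z")
    if (!is.null(s$linker)) emit_diag(s$linker, "t_a")
  }

  if (!length(out))
    return(data.frame(ion_type = character(), index = integer(),
                      formula = character(), mz = numeric(),
                      charge = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$mz), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Number of exchangeable protons (HDX)
#'
#' Labile N-H/O-H protons: head contribution + one per backbone N-H or
#' N-OH (none for N-Me) + tail contribution + linker contribution. In a
#' deuterated mobile phase each exchangeable proton shifts the observed
#' mass by one unit.
#'
#' @param s a [polyamine_structure()].
#' @return Integer count.
#' @export
#' @examples
#' exchangeable_protons(parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+"))  # 6
exchangeable_protons <- function(s) {
  stopifnot(inherits(s, "polyamine_structure"))
  s$head$exchangeable_h +
    sum(vapply(s$units, function(u) unit_exchangeable_h(u$nsub), 0L)) +
    s$tail$exchangeable_h +
    (if (!is.null(s$linker)) s$linker$exchangeable_h else 0L)
}

#' Observed HDX mass shift of an ionized species
#'
#' In deuterated solvent the ionizing protons are deuterons too, so the
#' observed full-scan mass shift equals the number of exchangeable protons
#' plus the number of protons added on ionization (0 for `M+`, 1 for
#' `[M+H]+` and `[M+H]2+`, 2 for `[M+2H]2+`).
#'
#' @param s a [polyamine_structure()].
#' @param species a species label from [precursor_ion_set()] (e.g.
#'   `"[M+H]+"`) or a row of that data frame.
#' @return Integer mass shift in units.
#' @export
#' @examples
#' hdx_observed_shift(parse_generic_name("4-OH-IndAc3(OH)335(NMe2)"), "[M+H]+")
hdx_observed_shift <- function(s, species) {
  pset <- precursor_ion_set(s)
  if (is.character(species)) {
    row <- pset[pset$label == species, , drop = FALSE]
    if (!nrow(row))
      stop(sprintf("species '%s' is not valid for this structure (expected %s)",
                   species, paste(pset$label, collapse = ", ")))
  } else {
    row <- as.data.frame(species)
  }
  exchangeable_protons(s) + row$protons_added[[1L]]
}

# enumerate terminal-amine tail isomers: the terminal N carries the chain
# plus either two substituents from {H, Me, Et, Pr} (neutral amine) or
# three alkyls (quaternary ammonium, fixed charge +1)
.amine_substituents <- list(
  H = list(atoms = chem_formula(c(H = 1L)), label = "H", exch = 1L),
  Me = list(atoms = chem_formula(c(C = 1L, H = 3L)), label = "Me", exch = 0L),
  Et = list(atoms = chem_formula(c(C = 2L, H = 5L)), label = "Et", exch = 0L),
  Pr = list(atoms = chem_formula(c(C = 3L, H = 7L)), label = "Pr", exch = 0L)
)

.enumerate_amine_tails <- function() {
  subs <- names(.amine_substituents)
  out <- list()
  label_of <- function(combo) {
    nH <- sum(combo == "H")
    alk <- combo[combo != "H"]
    tab <- table(factor(alk, levels = c("Me", "Et", "Pr")))
    paste0("N",
           if (nH > 0) paste0("H", if (nH > 1) nH else "") else "",
           paste0(vapply(names(tab)[tab > 0], function(a)
             paste0(a, if (tab[[a]] > 1) tab[[a]] else ""), ""),
             collapse = ""))
  }
  # neutral amines: N + 2 substituents
  grid2 <- expand.grid(a = subs, b = subs, stringsAsFactors = FALSE)
  seen <- character()
  for (i in seq_len(nrow(grid2))) {
    combo <- sort(c(grid2$a[i], grid2$b[i]))
    key <- paste(combo, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    atoms <- chem_formula(c(N = 1L))
    for (x in combo) atoms <- atoms + .amine_substituents[[x]]$atoms
    out[[length(out) + 1L]] <- list(
      label = label_of(combo), atoms = atoms, charge = 0L,
      exch = sum(vapply(combo, function(x) .amine_substituents[[x]]$exch, 0L)))
  }
  # quaternary ammonium: N + 3 alkyls, fixed +1
  alks <- setdiff(subs, "H")
  grid3 <- expand.grid(a = alks, b = alks, c = alks, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid3))) {
    combo <- sort(c(grid3$a[i], grid3$b[i], grid3$c[i]))
    key <- paste(c("q", combo), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    atoms <- chem_formula(c(N = 1L))
    for (x in combo) atoms <- atoms + .amine_substituents[[x]]$atoms
    out[[length(out) + 1L]] <- list(
      label = label_of(combo), atoms = atoms, charge = 1L, exch = 0L)
  }
  out
}

#' Infer the tail moiety from an observed neutral loss
#'
#' The accurate-mass difference between the precursor ion and the largest
#' a-type fragment is the neutral loss of the departed tail amine.
#' Enumerates terminal-amine isomers (H/methyl/ethyl/propyl substituents on
#' the terminal nitrogen, including quaternary ammonium tails) whose atoms
#' match the loss — for a protonated neutral precursor the leaving amine
#' carries one transferred H (loss = tail + H); for a fixed cationic tail
#' the loss equals the tail atoms — and ranks candidates by consistency
#' with an observed HDX mass shift when one is supplied.
#'
#' @param loss [chem_formula] (or Hill string) of the observed neutral loss.
#' @param partial a [polyamine_structure()] giving the established
#'   head+backbone partial structure (its tail is ignored); used for the
#'   HDX consistency check.
#' @param observed_hdx_shift optional observed HDX mass shift (units).
#' @return Data frame of candidate tails with columns `tail`, `formula`,
#'   `intrinsic_charge`, `exchangeable_h`, `predicted_shift`,
#'   `hdx_consistent`, ranked consistent-first.
#' @export
#' @examples
#' p <- parse_generic_name("4-OH-IndAc3(OH)335")
#' infer_tail_from_neutral_loss("C2H7N", p, observed_hdx_shift = 7)
infer_tail_from_neutral_loss <- function(loss, partial,
                                         observed_hdx_shift = NULL) {
  if (is.character(loss)) loss <- parse_formula(loss)
  stopifnot(inherits(loss, "chem_formula"),
            inherits(partial, "polyamine_structure"))
  H1 <- chem_formula(c(H = 1L))
  cands <- Filter(function(tl) {
    expect <- if (tl$charge == 0L) tl$atoms + H1 else tl$atoms
    identical(expect$counts, loss$counts)
  }, .enumerate_amine_tails())
  if (!length(cands))
    stop(sprintf("no terminal-amine isomer matches the neutral loss %s",
                 format_formula(loss)))
  # exchangeable protons of the partial structure without its tail
  partial_exch <- exchangeable_protons(partial) - partial$tail$exchangeable_h
  res <- do.call(rbind, lapply(cands, function(tl) {
    ionizing <- if (tl$charge == 0L) 1L else 0L  # [M+H]+ vs M+
    shift <- partial_exch + tl$exch + ionizing
    data.frame(tail = tl$label, formula = format_formula(tl$atoms),
               intrinsic_charge = tl$charge, exchangeable_h = tl$exch,
               predicted_shift = shift,
               hdx_consistent = if (is.null(observed_hdx_shift)) NA
                                else shift == observed_hdx_shift,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(observed_hdx_shift))
    res <- res[order(!res$hdx_consistent, res$tail), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full prediction report for a structure
#'
#' Collects everything the fragment-ion calculator reports for one
#' structure: generic name, molecular formula, monoisotopic mass, number
#' of exchangeable protons, precursor species, and the rule-based fragment
#' ion table.
#'
#' @param s a [polyamine_structure()] or a generic name string.
#' @param registry [block_registry()] used when `s` is a name.
#' @param rules a [fragment_rules()] configuration.
#' @return Object of class `prediction_report`.
#' @export
#' @examples
#' predict_ions("IndAc4333")
predict_ions <- function(s, registry = default_block_registry(),
                         rules = fragment_rules()) {
  if (is.character(s)) s <- parse_generic_name(s, registry)
  stopifnot(inherits(s, "polyamine_structure"))
  f <- molecular_formula(s)
  structure(list(
    generic_name = format_generic_name(s),
    structure = s,
    molecular_formula = format_formula(f),
    monoisotopic_mass = monoisotopic_mass(f),
    exchangeable_h = exchangeable_protons(s),
    precursor_ions = precursor_ion_set(s),
    fragments = fragment_ions(s, rules)
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Prediction report for", x$generic_name, "\n")
  cat("  formula:          ", x$molecular_formula, "\n")
  cat(sprintf("  monoisotopic mass: %.5f Da\n", x$monoisotopic_mass))
  cat("  exchangeable H:   ", x$exchangeable_h, "\n")
  cat("  precursor ions:\n")
  p <- x$precursor_ions
  for (i in seq_len(nrow(p)))
    cat(sprintf("    %-18s %-18s %10.5f\n", p$label[i], p$formula[i], p$mz[i]))
  cat("  fragments:\n")
  fr <- x$fragments
  for (i in seq_len(nrow(fr)))
    cat(sprintf("    %-3s %-3s %-16s %10.5f\n", fr$ion_type[i],
                ifelse(is.na(fr$index[i]), "", fr$index[i]),
                fr$formula[i], fr$mz[i]))
  invisible(x)
}

#' Write a prediction report as a flat TSV table
#'
#' One row per ion (precursors then fragments) with columns `ion_type`,
#' `index`, `formula`, `mz`.
#'
#' @param report a `prediction_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  pre <- data.frame(ion_type = report$precursor_ions$label, index = NA_integer_,
                    formula = report$precursor_ions$formula,
                    mz = report$precursor_ions$mz, stringsAsFactors = FALSE)
  fr <- report$fragments[, c("ion_type", "index", "formula", "mz")]
  tab <- rbind(pre, fr)
  tab$mz <- round(tab$mz, 5)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
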