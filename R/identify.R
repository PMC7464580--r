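# Stepwise identification workflow over a fragment spectrum, a precursor,
# an optional retention time and HDX shift, and a local compound registry.
# The flow follows the decision chart used for venom-toxin annotation:
# registry search (Q1), retention-time plausibility (Q2), reference-
# spectrum comparison (Q3), polyamine triage (Q4/Q8), predicted-fragment
# support (Q5), backbone-fingerprint comparison (Q6), HDX consistency
# (Q7), head detection (Q9) and stepwise structure assembly (Q10).

#' Identification workflow configuration
#'
#' @param tol_ppm fragment/diagnostic match tolerance (ppm).
#' @param rt_rel_tol relative retention-time tolerance (fraction of the
#'   observed value).
#' @param similarity_threshold minimum cosine score for a reference-
#'   spectrum match.
#' @param min_matched_fraction minimum fraction of reference peaks matched.
#' @param precursor_guard_ppm accurate-mass guard: registry candidates
#'   whose stored precursor deviates more than this from the observed
#'   value are excluded even on a floor match.
#' @param assembly_tol_ppm precursor-mass acceptance for assembled
#'   candidate structures.
#' @param min_a_support minimum number of matched a-family ions for a
#'   candidate to count as supported by prediction.
#' @param max_units assembly search bound on backbone length.
#' @param rules a [fragment_rules()] configuration.
#' @param seed optional integer seed recorded in outputs.
#' @return Named list of settings.
#' @export
identify_config <- function(tol_ppm = 5, rt_rel_tol = 0.02,
                            similarity_threshold = 0.80,
                            min_matched_fraction = 0.5,
                            precursor_guard_ppm = 10,
                            assembly_tol_ppm = 5, min_a_support = 2,
                            max_units = 10, rules = fragment_rules(),
                            seed = NULL) {
  stopifnot(tol_ppm > 0, rt_rel_tol > 0, assembly_tol_ppm > 0)
  list(tol_ppm = tol_ppm, rt_rel_tol = rt_rel_tol,
       similarity_threshold = similarity_threshold,
       min_matched_fraction = min_matched_fraction,
       precursor_guard_ppm = precursor_guard_ppm,
       assembly_tol_ppm = assembly_tol_ppm, min_a_support = min_a_support,
       max_units = max_units, rules = rules, seed = seed)
}

# nearest-peak ppm lookup on a sorted m/z vector
.nearest_ppm <- function(peaks_mz, mz) {
  if (!length(peaks_mz)) return(Inf)
  i <- findInterval(mz, peaks_mz)
  cand <- peaks_mz[pmax(1L, pmin(length(peaks_mz), c(i, i + 1L)))]
  min(abs((cand - mz) / mz * 1e6))
}

.rdbe <- function(f) {
  cnt <- function(e) if (e %in% names(f$counts)) f$counts[[e]] else 0L
  cnt("C") - cnt("H") / 2 + cnt("N") / 2 + 1
}

# precursor species label for a structure observed at a given charge
.species_for_charge <- function(s, charge) {
  if (s$intrinsic_charge == 1L) {
    if (charge == 1L) "M+" else "[M+H]2+"
  } else {
    if (charge == 1L) "[M+H]+" else "[M+2H]2+"
  }
}

#' Detect the acyl head moiety from diagnostic fragment ions
#'
#' Scores every registered head by its characteristic low-mass fragment
#' ions: the a0 acylium, the a' (a0 − CO) ion, and the a1 ions formed with
#' each possible first backbone unit. Heads are ranked by the number of
#' matched diagnostics, then by mean absolute ppm error.
#'
#' @param spectrum a [new_spectrum()].
#' @param registry a [block_registry()].
#' @param tol_ppm match tolerance (ppm).
#' @return Data frame `head`, `n_matched`, `mean_abs_ppm`, `a1_chain`
#'   (chain length of the best-matching a1, NA if none), ranked; zero rows
#'   if no head matches.
#' @export
#' @examples
#' sp <- synth_spectrum("4-OH-IndAc3(OH)335(NMe2)")
#' detect_head(sp)
detect_head <- function(spectrum, registry = default_block_registry(),
                        tol_ppm = 5) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (!nrow(spectrum$peaks)) return(.empty_head_df())
  pmz <- spectrum$peaks$mz
  rows <- lapply(list_blocks(registry, "head"), function(h) {
    dg <- head_diagnostic_ions(h)
    errs <- vapply(dg$mz, function(m) .nearest_ppm(pmz, m), 0.0)
    hits <- errs[errs <= tol_ppm]
    a1_chain <- NA_integer_
    a1_err <- Inf
    for (n in 1:9) {
      a1 <- ion_mz(h$atoms + unit_atoms(n, "H"), 0L, 1L)
      e <- .nearest_ppm(pmz, a1)
      if (e <= tol_ppm && e < a1_err) { a1_err <- e; a1_chain <- n }
    }
    if (is.finite(a1_err)) hits <- c(hits, a1_err)
    data.frame(head = h$abbrev, n_matched = length(hits),
               mean_abs_ppm = if (length(hits)) mean(hits) else NA_real_,
               a1_chain = a1_chain, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$n_matched > 0L, , drop = FALSE]
  if (!nrow(df)) return(.empty_head_df())
  df <- df[order(-df$n_matched, df$mean_abs_ppm), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_head_df <- function()
  data.frame(head = character(), n_matched = integer(),
             mean_abs_ppm = numeric(), a1_chain = integer(),
             stringsAsFactors = FALSE)

# Bounded, peak-guided assembly search: starting from a detected head
# (optionally via a linker), extend the a-type series unit by unit, each
# extension requiring a supporting peak, and close with any registered
# tail whose assembled precursor matches the observed one at tolerance.
assemble_structures <- function(spectrum, precursor_mz, precursor_charge,
                                head, registry, cfg = identify_config()) {
  stopifnot(inherits(head, "building_block"), head$kind == "head")
  pmz <- spectrum$peaks$mz
  tails <- list_blocks(registry, "tail")
  max_mass <- precursor_mz * precursor_charge + 2
  results <- list()

  try_tails <- function(atoms, units, linker) {
    for (tl in tails) {
      total <- atoms + tl$atoms
      z <- precursor_charge
      theo <- if (tl$intrinsic_charge == 0L) ion_mz(total, z, z)
              else if (tl$intrinsic_charge == 1L)
                ion_mz(total, z - 1L, z)
              else next
      if (abs(ppm_error(precursor_mz, theo)) <= cfg$assembly_tol_ppm)
        results[[length(results) + 1L]] <<-
          polyamine_structure(head, units, tl, linker)
    }
  }

  recurse <- function(atoms, units, linker) {
    if (length(units) >= 1L) try_tails(atoms, units, linker)
    if (length(units) >= cfg$max_units) return()
    subs <- if (length(units) == 0L) "H" else c("H", "OH", "Me")
    for (chain in 1:9) {
      for (sub in subs) {
        ua <- unit_atoms(chain, sub)
        natoms <- atoms + ua
        if (monoisotopic_mass(natoms) > max_mass) next
        if (.nearest_ppm(pmz, ion_mz(natoms, 0L, 1L)) > cfg$tol_ppm) next
        recurse(natoms, c(units, list(list(chain = chain, nsub = sub))),
                linker)
      }
    }
  }

  recurse(head$atoms, list(), NULL)
  for (lk in list_blocks(registry, "linker"))
    recurse(head$atoms + lk$atoms, list(), lk)
  results
}

# evaluate predicted-fragment support of one candidate structure
.eval_candidate <- function(s, spectrum, cfg) {
  pred_fr <- fragment_ions(s, cfg$rules)
  pre <- precursor_ion_set(s)
  pred <- rbind(pred_fr[, c("ion_type", "index", "formula", "mz")],
                data.frame(ion_type = pre$label, index = NA_integer_,
                           formula = pre$formula, mz = pre$mz,
                           stringsAsFactors = FALSE))
  ann <- annotate_spectrum(spectrum, pred, cfg$tol_ppm)
  a_fam <- ann$annotations$ion_type %in% c("a", "a0", "a'")
  list(annotated = ann,
       a_count = sum(a_fam),
       total = nrow(ann$annotations),
       mean_abs_ppm = if (nrow(ann$annotations))
         mean(abs(ann$annotations$ppm)) else NA_real_)
}

# backbone signature: the sequence of backbone-unit formulas (head, tail
# and linker excluded), so that compounds sharing the polyamine backbone
# are recognized independently of head or tail differences
.backbone_signature <- function(s) {
  paste(vapply(s$units, function(u)
    format_formula(unit_atoms(u$chain, u$nsub)), ""), collapse = "-")
}

#' Identify or elucidate a compound from its fragment spectrum
#'
#' Runs the full decision flow: registry search by formula and floored
#' precursor m/z with an accurate-mass guard (Q1), retention-time filter
#' (Q2), reference-spectrum comparison (Q3), polyamine triage (Q4/Q8),
#' predicted-fragment support and candidate ranking (Q5), comparison with
#' backbone-sharing registry entries (Q6), HDX consistency (Q7), and — for
#' unknowns — head detection (Q9) followed by bounded stepwise assembly of
#' candidate structures (Q10). Every executed step is appended to the
#' decision trace.
#'
#' @param spectrum a [new_spectrum()] (MS/MS peak list).
#' @param precursor_mz observed precursor m/z (> 0).
#' @param precursor_charge observed precursor charge (1 or 2).
#' @param rt observed retention time in minutes under the standardized
#'   method, or `NULL` to skip the Rt filter.
#' @param hdx_shift observed HDX mass shift (units), or `NULL`.
#' @param formula observed-precursor chemical formula ([chem_formula] or
#'   Hill string) if one was derived from accurate mass, or `NULL`.
#' @param registry a [compound_registry()].
#' @param blocks a [block_registry()].
#' @param config an [identify_config()].
#' @return Object of class `identification_report` with fields `verdict`
#'   (`identified_by_reference`, `supported_by_prediction`,
#'   `proposed_new_structure` or `unresolved`), `best_candidate`,
#'   `structure`, `decision_trace`, `candidates`, `matched_ions`,
#'   `hdx_check`, `ties` and `warnings`.
#' @export
identify_compound <- function(spectrum, precursor_mz, precursor_charge = 1L,
                              rt = NULL, hdx_shift = NULL, formula = NULL,
                              registry, blocks = default_block_registry(),
                              config = identify_config()) {
  stopifnot(inherits(spectrum, "spectrum"), precursor_mz > 0,
            inherits(registry, "compound_registry"))
  if (is.character(formula)) formula <- parse_formula(formula)
  cfg <- config
  trace <- list()
  addq <- function(q, answer, evidence = "") {
    if (q %in% names(trace)) {
      trace[[q]]$evidence <<- paste(trace[[q]]$evidence, evidence, sep = " | ")
    } else {
      trace[[q]] <<- list(question = q, answer = answer, evidence = evidence)
    }
  }
  warnings_ <- character()

  # ---- Q1: registry search (formula and floored precursor) + mass guard
  cands <- list()
  if (!is.null(formula)) cands <- search_by_formula(registry, formula)
  for (r in search_by_precursor(registry, floor(precursor_mz))) {
    if (!r$generic_name %in% vapply(cands, `[[`, "", "generic_name"))
      cands <- c(cands, list(r))
  }
  guard_ppm <- vapply(cands, function(r) {
    if (!length(r$precursor_mzs)) return(Inf)
    min(abs(ppm_error(precursor_mz, r$precursor_mzs)))
  }, 0.0)
  excluded <- cands[guard_ppm > cfg$precursor_guard_ppm]
  kept <- cands[guard_ppm <= cfg$precursor_guard_ppm]
  ev1 <- sprintf("%d raw hit(s)", length(cands))
  if (length(excluded))
    ev1 <- paste0(ev1, "; excluded by accurate mass: ",
                  paste(sprintf("%s (%.0f ppm)",
                                vapply(excluded, `[[`, "", "generic_name"),
                                guard_ppm[guard_ppm > cfg$precursor_guard_ppm]),
                        collapse = ", "))
  addq("Q1", sprintf("%d candidate(s)", length(kept)), ev1)

  ranked <- NULL
  verdict <- "unresolved"
  best_struct <- NULL
  best_name <- NA_character_
  matched_ions <- NULL
  ties <- character()
  hdx_check <- NULL

  finish <- function() {
    tr <- do.call(rbind, lapply(trace, function(t) data.frame(
      question = t$question, answer = t$answer, evidence = t$evidence,
      stringsAsFactors = FALSE)))
    rownames(tr) <- NULL
    structure(list(verdict = verdict, best_candidate = best_name,
                   structure = best_struct, decision_trace = tr,
                   candidates = ranked, matched_ions = matched_ions,
                   hdx_check = hdx_check, ties = ties,
                   warnings = warnings_, config = cfg),
              class = "identification_report")
  }

  # validation shared by registry candidates (Q5-Q7) and assembled
  # candidates after Q10
  validate_structures <- function(structs) {
    evals <- lapply(structs, function(s) {
      e <- .eval_candidate(s, spectrum, cfg)
      e$structure <- s
      e$name <- format_generic_name(s)
      e
    })
    ord <- order(-vapply(evals, `[[`, 0L, "a_count"),
                 -vapply(evals, `[[`, 0L, "total"),
                 vapply(evals, `[[`, 0.0, "mean_abs_ppm"))
    evals <- evals[ord]
    addq("Q5", sprintf("%d candidate(s) with a-type support",
                       sum(vapply(evals, `[[`, 0L, "a_count") >=
                             cfg$min_a_support)),
         paste(vapply(evals, function(e)
           sprintf("%s: %d a-ions, %d matched, %.2f ppm", e$name,
                   e$a_count, e$total, e$mean_abs_ppm), ""),
           collapse = "; "))
    evals <- Filter(function(e) e$a_count >= cfg$min_a_support, evals)
    if (!length(evals)) return(list())

    # Q6: backbone-sharing fingerprint comparison for the front-runner
    top <- evals[[1L]]
    sig <- .backbone_signature(top$structure)
    siblings <- Filter(function(r) {
      if (r$generic_name == top$name) return(FALSE)
      rs <- tryCatch(parse_generic_name(r$generic_name, blocks),
                     error = function(e) NULL)
      !is.null(rs) && identical(.backbone_signature(rs), sig)
    }, registry$records)
    if (!length(siblings)) {
      addq("Q6", "not comparable",
           "no registry entry shares the polyamine backbone")
    } else {
      withspec <- Filter(function(r) !is.null(r$reference_spectrum), siblings)
      if (length(withspec)) {
        sim <- spectrum_similarity(spectrum,
                                   withspec[[1L]]$reference_spectrum,
                                   cfg$tol_ppm)
        addq("Q6", sprintf("fingerprint score %.2f vs %s", sim$score,
                           withspec[[1L]]$generic_name), "")
      } else {
        addq("Q6", "not comparable",
             sprintf("backbone-sharing entr%s %s lack(s) a reference spectrum",
                     if (length(siblings) > 1) "ies" else "y",
                     paste(vapply(siblings, `[[`, "", "generic_name"),
                           collapse = ", ")))
      }
    }

    # Q7: HDX consistency
    if (!is.null(hdx_shift)) {
      pred_shifts <- vapply(evals, function(e)
        hdx_observed_shift(e$structure,
                           .species_for_charge(e$structure,
                                               precursor_charge)), 0L)
      addq("Q7", sprintf("observed shift %d", hdx_shift),
           paste(sprintf("%s: expected %d",
                         vapply(evals, `[[`, "", "name"), pred_shifts),
                 collapse = "; "))
      consistent <- pred_shifts == hdx_shift
      if (any(consistent)) evals <- evals[consistent]
      else return(list())
    } else {
      addq("Q7", "skipped (no HDX shift supplied)", "")
    }
    evals
  }

  set_best <- function(evals) {
    top <- evals[[1L]]
    best_struct <<- top$structure
    best_name <<- top$name
    matched_ions <<- top$annotated$annotations
    ranked <<- do.call(rbind, lapply(evals, function(e) data.frame(
      candidate = e$name, a_ions = e$a_count, matched = e$total,
      mean_abs_ppm = round(e$mean_abs_ppm, 2), stringsAsFactors = FALSE)))
    if (length(evals) > 1L) {
      key <- function(e) c(e$a_count, e$total)
      ties <<- vapply(Filter(function(e)
        identical(key(e), key(top)), evals[-1L]), `[[`, "", "name")
    }
    if (!is.null(hdx_shift)) {
      hdx_check <<- list(
        expected = hdx_observed_shift(top$structure,
                                      .species_for_charge(top$structure,
                                                          precursor_charge)),
        observed = as.integer(hdx_shift))
    }
  }

  if (length(kept)) {
    # ---- Q2: retention-time plausibility
    if (!is.null(rt)) {
      filt <- rt_filter(kept, rt, cfg$rt_rel_tol)
      st <- attr(filt, "status")
      addq("Q2", sprintf("%d candidate(s) within %.2f +/- %.2f min",
                         sum(st == "kept"), rt, attr(filt, "window")),
           paste(sprintf("%s: %s", names(st), st), collapse = "; "))
      kept <- filt
    } else {
      addq("Q2", "skipped (no observed Rt)", "")
    }

    if (length(kept)) {
      # ---- Q3: reference-spectrum comparison
      withref <- Filter(function(r) !is.null(r$reference_spectrum), kept)
      if (length(withref)) {
        sims <- lapply(withref, function(r)
          spectrum_similarity(spectrum, r$reference_spectrum, cfg$tol_ppm))
        scores <- vapply(sims, `[[`, 0.0, "score")
        fracs <- vapply(sims, `[[`, 0.0, "matched_fraction")
        besti <- which.max(scores)
        ev <- paste(sprintf("%s: score %.2f, %.0f%% ref peaks",
                            vapply(withref, `[[`, "", "generic_name"),
                            scores, 100 * fracs), collapse = "; ")
        if (scores[besti] >= cfg$similarity_threshold &&
            fracs[besti] >= cfg$min_matched_fraction) {
          addq("Q3", "reference spectrum matched", ev)
          verdict <- "identified_by_reference"
          rec <- withref[[besti]]
          best_name <- rec$generic_name
          best_struct <- tryCatch(parse_generic_name(rec$generic_name, blocks),
                                  error = function(e) NULL)
          if (!is.null(best_struct)) {
            e <- .eval_candidate(best_struct, spectrum, cfg)
            matched_ions <- e$annotated$annotations
            if (!is.null(hdx_shift))
              hdx_check <- list(
                expected = hdx_observed_shift(
                  best_struct, .species_for_charge(best_struct,
                                                   precursor_charge)),
                observed = as.integer(hdx_shift))
          }
          return(finish())
        }
        addq("Q3", "reference spectrum did not match", ev)
        keepn <- vapply(withref, `[[`, "", "generic_name")[
          scores >= cfg$similarity_threshold]
        kept <- Filter(function(r)
          is.null(r$reference_spectrum) || r$generic_name %in% keepn, kept)
      } else {
        addq("Q3", "no reference spectrum available", "")
      }

      # ---- Q4: polyamine triage of remaining candidates
      structs <- list()
      for (r in kept) {
        s <- tryCatch(parse_generic_name(r$generic_name, blocks),
                      error = function(e) NULL)
        if (!is.null(s)) structs <- c(structs, list(s))
      }
      addq("Q4", if (length(structs))
        sprintf("%d polyamine candidate(s) to scrutinize", length(structs))
        else "no polyamine candidate; consult general metabolome databases",
        "")

      if (length(structs)) {
        evals <- validate_structures(structs)
        if (length(evals)) {
          set_best(evals)
          verdict <- "supported_by_prediction"
          return(finish())
        }
      }
    }
  } else if (!is.null(rt) && rt > 2) {
    warnings_ <- c(warnings_,
                   "no registry hit; if the precursor is a free polyamine, Rt > 2 min suggests in-source CID of an acylpolyamine")
  }

  # ---- unknown-compound path: Q8 -> Q9 -> Q10 -> Q5/Q6/Q7
  if (!is.null(formula)) {
    nN <- if ("N" %in% names(formula$counts)) formula$counts[["N"]] else 0L
    rd <- .rdbe(formula)
    plausible <- nN >= 3L && rd >= 3 && rd <= 15
    addq("Q8", if (plausible) "plausible polyamine derivative"
         else "formula inconsistent with a polyamine derivative",
         sprintf("N = %d, RDBE = %.1f", nN, rd))
    if (!plausible) return(finish())
  } else {
    addq("Q8", "no formula supplied; assuming a polyamine derivative", "")
  }

  heads <- detect_head(spectrum, blocks, cfg$tol_ppm)
  if (!nrow(heads)) {
    addq("Q9", "no head moiety identified", "")
    return(finish())
  }
  addq("Q9", sprintf("head %s (%d diagnostic ion(s), %.2f ppm)",
                     heads$head[1L], heads$n_matched[1L],
                     heads$mean_abs_ppm[1L]),
       if (!is.na(heads$a1_chain[1L]))
         sprintf("a1 consistent with a %d-methylene first unit",
                 heads$a1_chain[1L]) else "")

  assembled <- list()
  for (i in seq_len(min(2L, nrow(heads)))) {
    hb <- lookup_block(blocks, heads$head[i], "head")
    assembled <- assemble_structures(spectrum, precursor_mz,
                                     precursor_charge, hb, blocks, cfg)
    if (length(assembled)) break
  }
  addq("Q10", sprintf("%d assembled candidate(s) match the precursor mass",
                      length(assembled)), "")
  if (!length(assembled)) return(finish())

  evals <- validate_structures(assembled)
  if (!length(evals)) return(finish())
  set_best(evals)
  verdict <- "proposed_new_structure"
  finish()
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Identification report\n")
  cat("  verdict:       ", x$verdict, "\n")
  cat("  best candidate:", x$best_candidate, "\n")
  if (length(x$ties))
    cat("  tied candidates:", paste(x$ties, collapse = ", "), "\n")
  if (!is.null(x$hdx_check))
    cat(sprintf("  HDX: expected %d, observed %d\n", x$hdx_check$expected,
                x$hdx_check$observed))
  cat("  decision trace:\n")
  tr <- x$decision_trace
  for (i in seq_len(nrow(tr)))
    cat(sprintf("    %-3s %s%s\n", tr$question[i], tr$answer[i],
                ifelse(nzchar(tr$evidence[i]),
                       paste0("  [", tr$evidence[i], "]"), "")))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize an identification report as JSON
#'
#' @param report an `identification_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "identification_report"))
  out <- list(verdict = report$verdict,
              best_candidate = report$best_candidate,
              ties = report$ties,
              hdx_check = report$hdx_check,
              decision_trace = report$decision_trace,
              candidates = report$candidates,
              matched_ions = report$matched_ions,
              warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
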