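# Synthetic spectra and offline fixture generation. The generator emits
# the spectrum the fragmentation rules predict for a structure: the
# a-type series plus the a0/a' head diagnostics and the surviving
# precursor ion, with optional seeded m/z jitter (Gaussian, in ppm) and
# uniform decoy peaks. Intensities descend toward high m/z, mimicking the
# dominant low-mass head ions of measured acylpolyamine spectra; they are
# a fixed convention, since the rules predict no intensities.

#' Synthesize the predicted spectrum of a structure
#'
#' @param x a [polyamine_structure()] or generic name string.
#' @param registry a [block_registry()].
#' @param jitter_ppm Gaussian m/z jitter standard deviation in ppm
#'   (0 = noiseless).
#' @param decoy_fraction number of uniform decoy peaks as a fraction of
#'   the true peak count.
#' @param seed optional integer seed (jitter and decoys are deterministic
#'   per seed).
#' @param ion_types fragment types included as true peaks; `NULL` (default)
#'   emits every predicted fragment type.
#' @param include_precursor include the surviving precursor ion peak.
#' @return A [new_spectrum()] with precursor metadata set.
#' @export
#' @examples
#' sp <- synth_spectrum("IndAc4333")
#' sp
synth_spectrum <- function(x, registry = default_block_registry(),
                           jitter_ppm = 0, decoy_fraction = 0, seed = NULL,
                           ion_types = NULL, include_precursor = TRUE) {
  if (is.character(x)) x <- parse_generic_name(x, registry)
  rep_ <- predict_ions(x, registry)
  frags <- rep_$fragments
  if (!is.null(ion_types))
    frags <- frags[frags$ion_type %in% ion_types, , drop = FALSE]
  mzs <- frags$mz
  pre <- rep_$precursor_ions
  pre1 <- pre[pre$charge == 1L, , drop = FALSE][1L, ]
  if (include_precursor) mzs <- c(mzs, pre1$mz)
  mzs <- sort(unique(mzs))
  n <- length(mzs)
  # descending intensity toward high m/z
  intens <- seq(1000, 200, length.out = n)
  if (!is.null(seed)) set.seed(seed)
  if (jitter_ppm > 0)
    mzs <- mzs * (1 + rnorm(n, 0, jitter_ppm) * 1e-6)
  n_decoy <- round(decoy_fraction * n)
  if (n_decoy > 0) {
    dmz <- runif(n_decoy, 100, max(mzs) + 50)
    dint <- runif(n_decoy, 20, 150)
    mzs <- c(mzs, dmz)
    intens <- c(intens, dint)
  }
  new_spectrum(mzs, intens, precursor_mz = pre1$mz, precursor_charge = 1L,
               title = rep_$generic_name)
}

#' Draw a random polyamine structure from the registered blocks
#'
#' Uniform head and tail, 2-6 backbone units with chain lengths 1-9;
#' units after the first carry an N-OH or N-Me substituent with
#' probability `p_sub` each. Used to generate test assemblies and
#' synthetic identification cases.
#'
#' @param registry a [block_registry()].
#' @param n_units backbone length; drawn uniformly from 2-6 if `NULL`.
#' @param p_sub per-nitrogen substitution probability.
#' @param tails tail abbreviations to draw from.
#' @return A [polyamine_structure()].
#' @export
random_structure <- function(registry = default_block_registry(),
                             n_units = NULL, p_sub = 0.25,
                             tails = c("NH2", "NMe2", "NMe3", "Arg", "Gu")) {
  heads <- vapply(list_blocks(registry, "head"), `[[`, "", "abbrev")
  head <- lookup_block(registry, sample(heads, 1L), "head")
  if (is.null(n_units)) n_units <- sample(2:6, 1L)
  units <- vector("list", n_units)
  for (k in seq_len(n_units)) {
    sub <- "H"
    if (k > 1L && runif(1) < p_sub) sub <- sample(c("OH", "Me"), 1L)
    units[[k]] <- list(chain = sample(1:9, 1L), nsub = sub)
  }
  tail <- lookup_block(registry, sample(tails, 1L), "tail")
  polyamine_structure(head, units, tail)
}

# sanitize a generic name into a file-system-safe slug
.name_slug <- function(name) gsub("[^A-Za-z0-9._-]+", "_", name)

#' Build the packaged fixture compound registry
#'
#' Constructs, in code, a small registry of acylpolyamine records with
#' known masses, retention times, reliability (S) and comparability (C)
#' levels, including one record with an embedded reference spectrum
#' (synthesized noiselessly from its own predicted ions) and two
#' non-polyamine placeholder records without predictions. All polyamine
#' formulas, masses and precursor m/z values are computed from the
#' building blocks at call time.
#'
#' @param registry a [block_registry()].
#' @return A [compound_registry()] with 11 records.
#' @export
build_fixture_registry <- function(registry = default_block_registry()) {
  sp_ref <- function(name)
    synth_spectrum(name, registry, jitter_ppm = 0, decoy_fraction = 0)
  poly <- function(name, rt = NA_real_, s = "S-1", cl = "C-3",
                   trivial = character(), refspec = NULL) {
    st <- parse_generic_name(name, registry)
    pre <- precursor_ion_set(st)
    compound_record(
      generic_name = format_generic_name(st),
      trivial_names = trivial,
      species = "Agelenopsis aperta", family = "Agelenidae",
      formula = molecular_formula(st),
      n_exchangeable = exchangeable_protons(st),
      rt_min = rt, s_level = s, c_level = cl,
      reference_spectrum = refspec,
      precursor_mzs = pre$mz[pre$charge %in% c(1L, 2L) &
                               !grepl("TFA|CF3", pre$label)])
  }
  records <- list(
    poly("IndAc3334", rt = 7.59),
    poly("IndAc3343", rt = 7.64),
    poly("IndAc3433", rt = 7.82),
    poly("IndAc4333", rt = 9.00, cl = "C-1", refspec = sp_ref("IndAc4333")),
    poly("4-OH-IndAc3(OH)335(NMe3)+"),
    poly("IndAc3(OH)335(NMe3)+"),
    poly("4-OH-IndAc3(OH)334Gu", s = "S-3"),
    poly("4-OH-Bz3(OH)334", cl = "C-2"),
    poly("2,4-(OH)2-PhAcAsn533Arg",
         trivial = c("AR 636", "Arg 636", "argiopine", "argiotoxin 636",
                     "ArgTX 636", "ATX", "AVTX 636")),
    # non-polyamine / unknown-structure placeholders (synthetic stand-ins:
    # only level and precursor behavior matter for the workflow)
    compound_record("VdTX1", species = "Vitalius dubius",
                    family = "Theraphosidae", s_level = "S-5",
                    c_level = "C-4", rt_min = 22.2,
                    precursor_mzs = 729.406),
    compound_record("HF-7", species = "Hololena curta",
                    family = "Agelenidae", s_level = "S-5", c_level = "C-4",
                    precursor_mzs = 594.0)
  )
  compound_registry(records)
}

#' Generate offline test fixtures
#'
#' Writes the fixture compound registry (JSON) and synthetic MGF spectra
#' to a directory: a noiseless spectrum at the predicted m/z values for
#' every polyamine record, plus a seeded noisy variant (Gaussian ppm
#' jitter and uniform decoy peaks). Output is byte-deterministic per seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param jitter_ppm jitter sigma for the noisy variants (ppm).
#' @param decoy_fraction decoy-peak fraction for the noisy variants.
#' @param registry a [block_registry()].
#' @return Invisible character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L, jitter_ppm = 2,
                          decoy_fraction = 0.1,
                          registry = default_block_registry()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create fixture directory: ", dir)
  creg <- build_fixture_registry(registry)
  paths <- character()
  reg_path <- file.path(dir, "registry.json")
  write_compound_registry(creg, reg_path)
  paths <- c(paths, reg_path)
  set.seed(seed)
  for (r in creg$records) {
    st <- tryCatch(parse_generic_name(r$generic_name, registry),
                   error = function(e) NULL)
    if (is.null(st)) next
    clean <- synth_spectrum(st, registry)
    noisy <- synth_spectrum(st, registry, jitter_ppm = jitter_ppm,
                            decoy_fraction = decoy_fraction,
                            seed = sample.int(1e6, 1L))
    p1 <- file.path(dir, paste0(.name_slug(r$generic_name), ".mgf"))
    p2 <- file.path(dir, paste0(.name_slug(r$generic_name), "_noisy.mgf"))
    write_mgf(clean, p1)
    write_mgf(noisy, p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
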