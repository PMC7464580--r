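# Generic acylpolyamine nomenclature.
#
# A name is: head abbreviation, optional amino-acid linker, a digit per
# backbone chain (number of methylene units between two nitrogens), a
# bracketed token after digit k naming the substituent on the nitrogen
# between chain k and chain k+1, and an optional tail token (bracketed or
# bare) with a trailing "+" for fixed cations. Example:
# 4-OH-IndAc3(OH)335(NMe3)+ or 2,4-(OH)2-PhAcAsn533Arg.

#' Construct a polyamine structure
#'
#' @param head `building_block` of kind head.
#' @param units list of `list(chain =, nsub =)` entries, one per backbone
#'   unit, in head-to-tail order. `chain` is the methylene count (1-9),
#'   `nsub` the substituent on the unit's own nitrogen (`"H"`, `"OH"` or
#'   `"Me"`). The first nitrogen (head-amide nitrogen) is always
#'   unsubstituted.
#' @param tail `building_block` of kind tail.
#' @param linker optional `building_block` of kind linker.
#' @return Object of class `polyamine_structure`.
#' @export
polyamine_structure <- function(head, units, tail, linker = NULL) {
  stopifnot(inherits(head, "building_block"), head$kind == "head",
            inherits(tail, "building_block"), tail$kind == "tail")
  if (!is.null(linker))
    stopifnot(inherits(linker, "building_block"), linker$kind == "linker")
  if (length(units) < 1L || length(units) > 10L)
    stop("a polyamine backbone has 1 to 10 units; got ", length(units))
  units <- lapply(units, function(u) {
    if (is.numeric(u)) u <- list(chain = u, nsub = "H")
    stopifnot(is.list(u))
    u$chain <- as.integer(u$chain)
    u$nsub <- u$nsub %||% "H"
    if (u$chain < 1L || u$chain > 9L)
      stop("chain lengths are limited to 1-9 methylenes; got ", u$chain)
    if (!u$nsub %in% c("H", "OH", "Me"))
      stop(sprintf("unknown N-substituent '%s'", u$nsub))
    u[c("chain", "nsub")]
  })
  if (units[[1L]]$nsub != "H")
    stop("the head-amide nitrogen cannot carry a substituent")
  structure(list(head = head, linker = linker, units = units, tail = tail,
                 intrinsic_charge = tail$intrinsic_charge),
            class = "polyamine_structure")
}

# Normalize typographic variants: markdown sub/superscript underscores and
# carets ("(OH)_2_", "^+^"), Unicode minus/dashes, stray whitespace.
normalize_generic_name <- function(name) {
  s <- gsub("−|–|—", "-", name)
  s <- gsub("\\s", "", s)
  s <- gsub("_([0-9]+)_", "\\1", s)
  gsub("\\^", "", s)
}

#' Parse a generic acylpolyamine name
#'
#' Longest-match head prefix, optional linker token, chain digits with
#' bracketed N-substituents, optional tail token (bracketed or bare),
#' optional trailing `+` for fixed cations. Typographic variants
#' (`(OH)_2_`, Unicode minus) are normalized before matching. An absent
#' tail means the default terminal NH2.
#'
#' @param name generic name string.
#' @param registry a [block_registry()]; defaults to the seeded registry.
#' @return A [polyamine_structure()].
#' @export
#' @examples
#' s <- parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+")
#' format_generic_name(s)
parse_generic_name <- function(name, registry = default_block_registry()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  s <- normalize_generic_name(name)

  match_longest <- function(text, kind) {
    abbrevs <- vapply(list_blocks(registry, kind), `[[`, "", "abbrev")
    hits <- abbrevs[startsWith(text, abbrevs)]
    if (!length(hits)) return(NULL)
    hits[which.max(nchar(hits))]
  }

  head_ab <- match_longest(s, "head")
  if (is.null(head_ab))
    stop(sprintf("no registered head matches the start of '%s'", name))
  head <- lookup_block(registry, head_ab, "head")
  rest <- substring(s, nchar(head_ab) + 1L)

  linker <- NULL
  link_ab <- match_longest(rest, "linker")
  if (!is.null(link_ab)) {
    linker <- lookup_block(registry, link_ab, "linker")
    rest <- substring(rest, nchar(link_ab) + 1L)
  }

  if (startsWith(rest, "("))
    stop("a bracketed token cannot precede the first chain digit ",
         "(the head-amide nitrogen is unsubstituted): '", rest, "'")
  if (!grepl("^[1-9]", rest))
    stop(sprintf("expected a chain digit after the head%s in '%s'; ",
                 if (is.null(linker)) "" else "/linker", name),
         sprintf("unconsumed suffix: '%s'", rest))

  chains <- integer()
  nsubs <- character()   # substituent on each unit's own nitrogen
  tail_tok <- NULL
  explicit_plus <- FALSE

  take_bracket <- function(text) {
    close <- regexpr("\\)", text)
    if (close < 0L)
      stop(sprintf("unclosed bracket in '%s'; unconsumed suffix: '%s'",
                   name, text))
    list(tok = substr(text, 2L, close - 1L),
         rest = substring(text, close + 1L))
  }

  while (nzchar(rest)) {
    ch <- substr(rest, 1L, 1L)
    if (grepl("^[1-9]$", ch)) {
      chains <- c(chains, as.integer(ch))
      if (length(nsubs) < length(chains)) nsubs <- c(nsubs, "H")
      rest <- substring(rest, 2L)
      if (startsWith(rest, "(")) {
        br <- take_bracket(rest)
        after <- br$rest
        if (grepl("^[1-9]", after)) {
          # substituent on the nitrogen between this chain and the next
          sub <- tryCatch(lookup_block(registry, br$tok, "substituent"),
                          error = function(e) NULL)
          if (is.null(sub))
            stop(sprintf("unknown N-substituent token '(%s)' in '%s'",
                         br$tok, name))
          nsubs[length(nsubs) + 1L] <- br$tok  # belongs to the NEXT unit
          rest <- after
        } else {
          # terminal bracket: must name a tail
          tl <- tryCatch(lookup_block(registry, br$tok, "tail"),
                         error = function(e) NULL)
          if (is.null(tl)) {
            if (!is.null(tryCatch(lookup_block(registry, br$tok, "substituent"),
                                  error = function(e) NULL)))
              stop(sprintf(
                "substituent '(%s)' cannot bind the terminal nitrogen in '%s'",
                br$tok, name))
            stop(sprintf("unknown tail token '(%s)' in '%s'", br$tok, name))
          }
          tail_tok <- br$tok
          rest <- after
          break
        }
      }
      next
    }
    break
  }
  # nsubs may carry one pending entry for a unit that never came
  if (length(nsubs) > length(chains))
    stop(sprintf("substituent '(%s)' is not followed by a chain digit in '%s'",
                 nsubs[length(nsubs)], name))

  if (is.null(tail_tok) && nzchar(rest) && !startsWith(rest, "+")) {
    cand <- sub("\\+$", "", rest)
    tl <- tryCatch(lookup_block(registry, cand, "tail"), error = function(e) NULL)
    if (is.null(tl))
      stop(sprintf("cannot parse '%s'; unconsumed suffix: '%s'", name, rest))
    tail_tok <- cand
    rest <- substring(rest, nchar(cand) + 1L)
  }
  if (startsWith(rest, "+")) {
    explicit_plus <- TRUE
    rest <- substring(rest, 2L)
  }
  if (nzchar(rest))
    stop(sprintf("cannot parse '%s'; unconsumed suffix: '%s'", name, rest))
  if (!length(chains))
    stop(sprintf("no backbone units found in '%s'", name))
  if (length(chains) > 10L)
    stop("a polyamine backbone has at most 10 units; got ", length(chains))

  tail <- lookup_block(registry, tail_tok %||% "NH2", "tail")
  if (explicit_plus && tail$intrinsic_charge == 0L)
    stop(sprintf("trailing '+' on a neutral structure in '%s'", name))

  units <- Map(function(c, s) list(chain = c, nsub = s), chains, nsubs)
  polyamine_structure(head, units, tail, linker)
}

#' Format a polyamine structure as its canonical generic name
#'
#' Inverse of [parse_generic_name()]: `format_generic_name(parse_generic_name(x))`
#' returns `x` for canonical inputs. The default terminal NH2 tail is
#' omitted; amine tails print bracketed, amino-acid/guanidino tails bare;
#' fixed cations carry a trailing `+`.
#'
#' @param s a [polyamine_structure()].
#' @return Canonical generic name string.
#' @export
format_generic_name <- function(s) {
  stopifnot(inherits(s, "polyamine_structure"))
  n <- length(s$units)
  parts <- character()
  for (k in seq_len(n)) {
    parts <- c(parts, as.character(s$units[[k]]$chain))
    if (k < n && s$units[[k + 1L]]$nsub != "H")
      parts <- c(parts, paste0("(", s$units[[k + 1L]]$nsub, ")"))
  }
  tail_str <- switch(s$tail$style,
                     default = "",
                     bracketed = paste0("(", s$tail$abbrev, ")"),
                     s$tail$abbrev)
  plus <- if (s$intrinsic_charge > 0L) "+" else ""
  paste0(s$head$abbrev,
         if (!is.null(s$linker)) s$linker$abbrev else "",
         paste(parts, collapse = ""), tail_str, plus)
}

#' @export
print.polyamine_structure <- function(x, ...) {
  cat("<polyamine> ", format_generic_name(x), "\n", sep = "")
  f <- molecular_formula(x)
  cat("  formula: ", format_formula(f),
      sprintf("  mass: %.5f Da  exch H: %d\n", monoisotopic_mass(f),
              exchangeable_protons(x)), sep = "")
  invisible(x)
}
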