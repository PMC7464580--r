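# Independent brute-force oracles used to cross-check the incremental
# formula arithmetic. These deliberately avoid the package's chem_formula
# algebra: counts are accumulated as plain named integer vectors and
# masses summed from a local copy of the monoisotopic table.

.oracle_mass_table <- c(H = 1.00782503, C = 12.0, N = 14.00307401,
                        O = 15.99491462, F = 18.99840322, S = 31.97207117)

# element counts from a Hill string (charge marks ignored)
oracle_counts <- function(hill) {
  hill <- gsub("[0-9]*[+-]$", "", hill)
  toks <- regmatches(hill, gregexpr("[A-Z][a-z]?[0-9]*", hill))[[1]]
  v <- integer()
  for (t in toks) {
    sym <- gsub("[0-9]", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    v[sym] <- (if (sym %in% names(v)) v[[sym]] else 0L) + n
  }
  v
}

oracle_add <- function(a, b) {
  for (sym in names(b)) a[sym] <- (if (sym %in% names(a)) a[[sym]] else 0L) + b[[sym]]
  a[a > 0L]
}

# atom recount of a whole structure from first principles: head/tail/linker
# from their serialized formulas, each backbone unit by direct arithmetic
oracle_structure_counts <- function(s) {
  v <- oracle_counts(format_formula(s$head$atoms))
  if (!is.null(s$linker))
    v <- oracle_add(v, oracle_counts(format_formula(s$linker$atoms)))
  for (u in s$units) {
    uc <- c(C = u$chain + (u$nsub == "Me"),
            H = 2L * u$chain + 1L + 2L * (u$nsub == "Me"),
            N = 1L)
    if (u$nsub == "OH") uc["O"] <- 1L
    v <- oracle_add(v, uc)
  }
  oracle_add(v, oracle_counts(format_formula(s$tail$atoms)))
}

oracle_mass <- function(counts) {
  sum(.oracle_mass_table[names(counts)] * counts)
}

# sorted canonical string for count comparison
oracle_key <- function(counts) {
  counts <- counts[counts > 0L]
  paste(sort(paste0(names(counts), counts)), collapse = " ")
}

formula_key <- function(f) oracle_key(f$counts)

expect_same_counts <- function(f, counts) {
  expect_identical(formula_key(f), oracle_key(counts))
}
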