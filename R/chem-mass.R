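# Elemental composition arithmetic for delta-mass annotation.
#
# Compositions are signed element -> count maps written in the Unimod
# dialect, e.g. "C(-1)O(2)" for loss of one carbon and gain of two oxygens.
# A bare element symbol means count +1; concatenation means summation.

#' Monoisotopic atomic mass table
#'
#' Monoisotopic masses (Da) of the most abundant isotope for the elements
#' that occur in protein modification compositions. Carbon is exactly 12 by
#' definition of the unified atomic mass scale; the remaining values are the
#' standard IUPAC/AME monoisotopic masses to at least six decimal places.
#'
#' @return Named numeric vector mapping element symbol to monoisotopic mass
#'   in Da.
#' @examples
#' atomic_masses()[["O"]]
#' @export
atomic_masses <- function() {
  c(
    H  = 1.0078250319,
    C  = 12.0,
    N  = 14.0030740052,
    O  = 15.9949146221,
    S  = 31.97207069,
    P  = 30.97376151,
    Se = 79.9165218,
    Na = 22.98976928,
    K  = 38.9637069,
    Ca = 39.9625912,
    Mg = 23.9850423,
    Fe = 55.9349421,
    Zn = 63.9291466,
    Cu = 62.9296011,
    Cl = 34.96885271,
    Br = 78.9183376,
    I  = 126.904473
  )
}

new_composition <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts)) {
    # canonical Hill-like order: C, H, then the rest alphabetically
    els <- names(counts)
    ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
    counts <- counts[ord]
  }
  structure(as.integer(counts), names = names(counts),
            class = "elemental_composition")
}

#' Parse a Unimod-style elemental composition string
#'
#' The dialect: an element symbol (capital letter plus optional lower-case
#' letters, longest match wins) optionally followed by a signed integer count
#' in parentheses; a missing parenthetical means count 1; concatenated terms
#' are summed, so `"OO"` equals `"O(2)"`.
#'
#' @param text Single composition string, e.g. `"H(11)C(6)NO(3)S(2)"`.
#' @return An `elemental_composition`: a named integer vector of signed
#'   counts with zero-count elements removed, in canonical order.
#' @seealso [format_composition()], [monoisotopic_mass()]
#' @examples
#' parse_composition("C(-1)O(2)")
#' @export
parse_composition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("composition must be a single character string", call. = FALSE)
  }
  if (!nzchar(trimws(text))) {
    stop("empty composition string at position 1", call. = FALSE)
  }
  text <- gsub("[[:space:]]", "", text)
  known <- names(atomic_masses())
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]*)", rest))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed composition '%s': expected element symbol at position %d",
                   text, pos), call. = FALSE)
    }
    sym <- m[2]
    # longest-match against the known table (e.g. "Na" before "N")
    while (nchar(sym) > 1L && !(sym %in% known)) {
      sym <- substr(sym, 1L, nchar(sym) - 1L)
    }
    if (!(sym %in% known)) {
      stop(sprintf("unknown element '%s' at position %d in '%s'",
                   m[2], pos, text), call. = FALSE)
    }
    pos <- pos + nchar(sym)
    cnt <- 1L
    if (pos <= n && substr(text, pos, pos) == "(") {
      close <- regexpr(")", substr(text, pos, n), fixed = TRUE)
      inner <- if (close > 0) substr(text, pos + 1L, pos + close - 2L) else ""
      if (close < 0 || !grepl("^[+-]?[0-9]+$", inner)) {
        stop(sprintf("malformed parenthetical count at position %d in '%s'",
                     pos, text), call. = FALSE)
      }
      cnt <- as.integer(inner)
      pos <- pos + close
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
  }
  new_composition(counts)
}

#' Format an elemental composition in the canonical dialect
#'
#' Inverse of [parse_composition()] on canonical strings: counts of one are
#' written as the bare symbol, all other counts (including negative) in
#' parentheses. The empty composition formats as `""`.
#'
#' @param comp An `elemental_composition` or named integer vector.
#' @return Single character string.
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0L) return("")
  paste0(vapply(seq_along(comp), function(i) {
    el <- names(comp)[i]; k <- comp[[i]]
    if (k == 1L) el else sprintf("%s(%d)", el, k)
  }, character(1)), collapse = "")
}

as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_composition(x))
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), names(atomic_masses()))
    if (length(bad)) {
      stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    return(new_composition(round(x)))
  }
  stop("cannot interpret object as an elemental composition", call. = FALSE)
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition> ", format_composition(x),
      sprintf("  (%.6f Da)\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}

#' Merge (sum) two compositions
#'
#' @param a,b Compositions (objects or strings).
#' @return The element-wise sum as an `elemental_composition`.
#' @export
composition_merge <- function(a, b) {
  a <- as_composition(a); b <- as_composition(b)
  els <- union(names(a), names(b))
  counts <- vapply(els, function(e) {
    (if (e %in% names(a)) a[[e]] else 0L) + (if (e %in% names(b)) b[[e]] else 0L)
  }, integer(1))
  names(counts) <- els
  new_composition(counts)
}

#' Negate a composition
#'
#' @param comp Composition (object or string).
#' @return Composition with all counts negated.
#' @export
composition_negate <- function(comp) {
  comp <- as_composition(comp)
  new_composition(structure(-unclass(comp), names = names(comp)))
}

#' Monoisotopic mass of a composition
#'
#' Sum of signed count times monoisotopic element mass; additive over
#' [composition_merge()]. The empty composition has mass 0.
#'
#' @param comp Composition (object or string).
#' @param masses Atomic mass table; defaults to [atomic_masses()].
#' @return Signed mass in Da.
#' @examples
#' monoisotopic_mass("O(2)")          # 31.98983
#' monoisotopic_mass("C(-1)O")        #  3.99491
#' @export
monoisotopic_mass <- function(comp, masses = atomic_masses()) {
  comp <- as_composition(comp)
  if (length(comp) == 0L) return(0)
  bad <- setdiff(names(comp), names(masses))
  if (length(bad)) {
    stop("no monoisotopic mass for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(unclass(comp) * masses[names(comp)])
}

#' Annotation error of an observed delta mass against a composition
#'
#' The signed difference between an observed (cluster-centre) delta mass and
#' the monoisotopic mass predicted by the annotated composition; the "Error
#' (Da)" of an annotation report.
#'
#' @param observed_delta Observed delta mass in Da.
#' @param comp Composition (object or string) of the annotation.
#' @inheritParams monoisotopic_mass
#' @return `observed_delta - monoisotopic_mass(comp)`, vectorised over
#'   `observed_delta`.
#' @export
annotation_error <- function(observed_delta, comp, masses = atomic_masses()) {
  observed_delta - monoisotopic_mass(comp, masses)
}
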