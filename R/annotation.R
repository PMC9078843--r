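# Annotation of called delta-mass peaks.
#
# Stage 1: match each peak centre against the curated database of
# previously reported variants (nearest entry, |error| strictly below the
# tolerance). Stage 2: for unmatched peaks, enumerate all centre-minus-base
# residuals against the curated database and match every residual against
# the larger Unimod-like catalogue, yielding cascade (base then secondary)
# candidates ranked by combined error. Classification is carried as data on
# the database entries, not hard-coded chemistry: a peak inherits the class
# of its matched (or base) entry, and peaks with no plausible candidate are
# "Unknown".

#' Match a delta-mass centre against a modification database
#'
#' Returns the database entry minimizing the absolute annotation error,
#' provided that minimum is strictly below `tol`. Ties on |error| are
#' broken by the plausibility flag (plausible first), then by name order.
#'
#' @param center Peak centre in Da.
#' @param db Modification database (see [read_modification_db()]).
#' @param tol Match tolerance in Da, strict inequality (default 0.010, i.e.
#'   10 mDa).
#' @return One-row `data.frame` (the entry plus an `error` column), or
#'   `NULL` if no entry lies within the tolerance.
#' @export
match_known <- function(center, db, tol = 0.010) {
  if (nrow(db) == 0L) stop("modification database is empty", call. = FALSE)
  err <- center - db$delta
  ord <- order(abs(err), !db$plausible, db$name)
  best <- ord[1]
  if (abs(err[best]) >= tol) return(NULL)
  out <- db[best, , drop = FALSE]
  out$error <- err[best]
  rownames(out) <- NULL
  out
}

#' Enumerate centre-minus-base residuals
#'
#' Forms the full cross product of unknown peak centres with the base
#' (curated) database: one record per (centre, base entry) carrying the
#' residual mass `center - base.delta` still to be explained by a
#' secondary reaction. The cardinality is always
#' `length(unknown_centers) * nrow(preknown)`.
#'
#' @param unknown_centers Numeric vector of unmatched peak centres (Da).
#' @param preknown Base modification database.
#' @return `data.frame` with columns `center`, `base_name`,
#'   `base_composition`, `base_delta`, `base_class`, `base_plausible`,
#'   `base_steps`, `residual`.
#' @export
enumerate_residuals <- function(unknown_centers, preknown) {
  if (length(unknown_centers) == 0L || nrow(preknown) == 0L) {
    return(data.frame(center = numeric(0), base_name = character(0),
                      base_composition = character(0),
                      base_delta = numeric(0), base_class = character(0),
                      base_plausible = logical(0), base_steps = integer(0),
                      residual = numeric(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(base = seq_len(nrow(preknown)),
                      center = unknown_centers, KEEP.OUT.ATTRS = FALSE)
  data.frame(center = grid$center,
             base_name = preknown$name[grid$base],
             base_composition = preknown$composition[grid$base],
             base_delta = preknown$delta[grid$base],
             base_class = preknown$class[grid$base],
             base_plausible = preknown$plausible[grid$base],
             base_steps = preknown$steps[grid$base],
             residual = grid$center - preknown$delta[grid$base],
             stringsAsFactors = FALSE)
}

#' Match residuals against a secondary-modification catalogue
#'
#' For every residual, every catalogue entry within `tol` (strict) of the
#' residual is paired with the base, giving a cascade candidate with
#' combined composition `base + secondary` and combined error
#' `center - (base.delta + secondary.delta)`. Candidates are pooled per
#' centre and sorted by absolute combined error, then plausibility (both
#' members plausible first), then fewest implied reaction steps.
#'
#' @param residuals Output of [enumerate_residuals()].
#' @param unimod Secondary catalogue (see [read_modification_db()]).
#' @param tol Match tolerance in Da, strict (default 0.010).
#' @return `data.frame` of candidates with columns `center`, `base_name`,
#'   `secondary_name`, `combined_composition`, `combined_delta`,
#'   `combined_error`, `plausible`, `steps`, `annotation` (a readable
#'   "base then secondary" label), sorted per centre by the ranking above.
#' @export
match_cascades <- function(residuals, unimod, tol = 0.010) {
  empty <- data.frame(center = numeric(0), base_name = character(0),
                      secondary_name = character(0),
                      combined_composition = character(0),
                      combined_delta = numeric(0),
                      combined_error = numeric(0), plausible = logical(0),
                      steps = integer(0), annotation = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(residuals) == 0L || nrow(unimod) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(residuals)), function(i) {
    hit <- which(abs(residuals$residual[i] - unimod$delta) < tol)
    if (length(hit) == 0L) return(NULL)
    comp <- vapply(hit, function(j) {
      format_composition(composition_merge(residuals$base_composition[i],
                                           unimod$composition[j]))
    }, character(1))
    data.frame(center = residuals$center[i],
               base_name = residuals$base_name[i],
               secondary_name = unimod$name[hit],
               combined_composition = comp,
               combined_delta = residuals$base_delta[i] + unimod$delta[hit],
               combined_error = residuals$center[i] -
                 (residuals$base_delta[i] + unimod$delta[hit]),
               plausible = residuals$base_plausible[i] & unimod$plausible[hit],
               steps = residuals$base_steps[i] + unimod$steps[hit],
               annotation = paste(residuals$base_name[i], "then",
                                  unimod$name[hit]),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$center, abs(out$combined_error), !out$plausible,
                   out$steps, out$annotation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a final class to annotated peaks
#'
#' A peak inherits the class label of its matched entry (single match) or
#' of its base entry (cascade match), provided the selected candidate is
#' flagged plausible; peaks with no match, or only implausible candidates,
#' are classed "Unknown". Every peak gets exactly one class.
#'
#' @param results Annotation `data.frame` with columns `matched_class` and
#'   `matched_plausible` (`NA` when unmatched).
#' @return `results` with the `final_class` column (re)assigned.
#' @export
classify_peaks <- function(results) {
  if (nrow(results) == 0L) {
    results$final_class <- character(0)
    return(results)
  }
  cls <- results$matched_class
  ok <- !is.na(cls) & !is.na(results$matched_plausible) &
    results$matched_plausible
  results$final_class <- ifelse(ok, cls, "Unknown")
  results
}

#' Annotate called variant peaks
#'
#' Runs the two annotation stages over a cluster table: single matching
#' against the curated base database, then cascade matching of the
#' unmatched peaks against the secondary catalogue. The top-ranked
#' plausible candidate is auto-selected, but the full ranked candidate
#' list for each peak is attached as attribute `"candidates"` for review.
#'
#' @param clusters Cluster `data.frame` from [call_variant_peaks()] (needs
#'   `center`; `cluster_id` and `n_psms` are carried through if present).
#' @param preknown Curated base database (default: the packaged
#'   [trp_preknown_db()]).
#' @param unimod Secondary catalogue (default: the packaged
#'   [trp_unimod_db()]).
#' @param tol Match tolerance in Da, strict (default 0.010).
#' @return `data.frame` with one row per peak: `cluster_id`, `center`,
#'   `n_psms`, `match_type` (`single`, `cascade` or `none`),
#'   `matched_class`, `matched_plausible`, `final_class`, `final_name`,
#'   `formula`, `monoisotopic_mass`, `error`.
#' @export
annotate_peaks <- function(clusters, preknown = trp_preknown_db(),
                           unimod = trp_unimod_db(), tol = 0.010) {
  n <- nrow(clusters)
  cluster_id <- if ("cluster_id" %in% names(clusters)) clusters$cluster_id
                else sprintf("C%03d", seq_len(n))
  n_psms <- if ("n_psms" %in% names(clusters)) clusters$n_psms
            else rep(NA_integer_, n)
  out <- data.frame(cluster_id = cluster_id, center = clusters$center,
                    n_psms = n_psms, match_type = rep("none", n),
                    matched_class = rep(NA_character_, n),
                    matched_plausible = rep(NA, n),
                    final_name = rep("Unknown", n),
                    formula = rep(NA_character_, n),
                    monoisotopic_mass = rep(NA_real_, n),
                    error = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  candidates <- stats::setNames(vector("list", n), cluster_id)
  for (i in seq_len(n)) {
    hit <- match_known(clusters$center[i], preknown, tol = tol)
    if (!is.null(hit)) {
      out$match_type[i] <- "single"
      out$matched_class[i] <- hit$class
      out$matched_plausible[i] <- hit$plausible
      out$final_name[i] <- hit$name
      out$formula[i] <- hit$composition
      out$monoisotopic_mass[i] <- hit$delta
      out$error[i] <- hit$error
      next
    }
    res <- enumerate_residuals(clusters$center[i], preknown)
    cand <- match_cascades(res, unimod, tol = tol)
    candidates[[i]] <- cand
    pl <- which(cand$plausible)
    if (nrow(cand) > 0L && length(pl) > 0L) {
      top <- pl[1]  # candidates are already ranked
      base_class <- preknown$class[match(cand$base_name[top], preknown$name)]
      out$match_type[i] <- "cascade"
      out$matched_class[i] <- base_class
      out$matched_plausible[i] <- TRUE
      out$final_name[i] <- cand$annotation[top]
      out$formula[i] <- cand$combined_composition[top]
      out$monoisotopic_mass[i] <- cand$combined_delta[top]
      out$error[i] <- cand$combined_error[top]
    } else if (nrow(cand) > 0L) {
      out$match_type[i] <- "cascade"
      out$matched_class[i] <- NA_character_
      out$matched_plausible[i] <- FALSE
    }
  }
  out <- classify_peaks(out)
  out <- out[c("cluster_id", "center", "n_psms", "match_type",
               "matched_class", "matched_plausible", "final_class",
               "final_name", "formula", "monoisotopic_mass", "error")]
  attr(out, "candidates") <- candidates
  out
}

#' Summarize peak classes by total frequency
#'
#' Aggregates per-class total frequency (sum of supporting spectra) and the
#' percentage of the grand total, rounded to two decimals. Classes
#' partition the total exactly.
#'
#' @param classes Character vector of class labels (one per peak), or an
#'   annotation `data.frame` with `final_class` and `n_psms`.
#' @param frequencies Numeric vector of per-peak frequencies; ignored when
#'   `classes` is a `data.frame`.
#' @return `data.frame` with columns `class`, `frequency`, `percentage`,
#'   with the grand total as attribute `"total"`; empty input gives an
#'   empty summary with total 0.
#' @export
summarize_classes <- function(classes, frequencies = NULL) {
  if (is.data.frame(classes)) {
    frequencies <- classes$n_psms
    classes <- classes$final_class
  }
  if (length(classes) == 0L) {
    out <- data.frame(class = character(0), frequency = numeric(0),
                      percentage = numeric(0), stringsAsFactors = FALSE)
    attr(out, "total") <- 0
    return(out)
  }
  stopifnot(length(classes) == length(frequencies))
  agg <- tapply(frequencies, classes, sum)
  total <- sum(frequencies)
  lev <- c(intersect(MOD_CLASSES, names(agg)),
           setdiff(names(agg), MOD_CLASSES))
  out <- data.frame(class = lev, frequency = as.numeric(agg[lev]),
                    percentage = round(100 * as.numeric(agg[lev]) / total, 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
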