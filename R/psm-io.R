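# Tabular I/O: PSM tables, modification databases, cluster tables,
# clinical tables. All files are UTF-8 TSV with "." decimal point.

PSM_COLUMNS <- c("spectrum_id", "peptide", "protein", "site", "residue",
                 "delta_mass", "score", "delta_mod_score", "fdr_2d",
                 "sample_id", "group")

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MOD_CLASSES <- c("Reactive species", "AA substitution", "Chemical derivative",
                 "Artefact", "Unknown")

validate_psm_table <- function(psms, file = NULL) {
  where <- function(i) {
    if (is.null(file)) sprintf("row %d", i) else sprintf("%s line %d", file, i + 1L)
  }
  missing_cols <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing_cols)) {
    stop("PSM table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("site", "delta_mass", "score", "delta_mod_score", "fdr_2d")
  for (col in num_cols) {
    bad <- which(!is.finite(psms[[col]]))
    if (length(bad)) {
      stop(sprintf("unparseable or missing %s at %s", col, where(bad[1])),
           call. = FALSE)
    }
  }
  bad <- which(psms$site < 1 | psms$site != round(psms$site))
  if (length(bad)) {
    stop(sprintf("site must be a 1-based integer position at %s", where(bad[1])),
         call. = FALSE)
  }
  bad <- which(!(psms$residue %in% AA_CODES))
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at %s", psms$residue[bad[1]],
                 where(bad[1])), call. = FALSE)
  }
  bad <- which(psms$fdr_2d < 0 | psms$fdr_2d > 1)
  if (length(bad)) {
    stop(sprintf("fdr_2d out of [0, 1] at %s", where(bad[1])), call. = FALSE)
  }
  invisible(psms)
}

#' Read a PSM table
#'
#' Reads the tab-separated peptide-spectrum-match dialect consumed by the
#' pipeline (one row per localized PSM). Required columns: `spectrum_id`,
#' `peptide`, `protein`, `site` (1-based position in the full protein
#' sequence, initiator Met included), `residue` (one-letter code),
#' `delta_mass` (Da), `score`, `delta_mod_score`, `fdr_2d`, `sample_id`,
#' `group`. Real search-engine exports with different headers can be adapted
#' with `col_map`.
#'
#' Every row is validated against the record invariants (positive integer
#' site, standard residue code, `fdr_2d` in \[0, 1\]); the first violation is
#' reported with its line number and no rows are silently dropped.
#'
#' @param path Path to a TSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(delta_mass = "Delta Mass")`.
#' @return A `data.frame` with the canonical columns.
#' @export
read_psm_table <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }
  missing_cols <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[PSM_COLUMNS]
  validate_psm_table(df, file = path)
  df
}

#' Write a PSM table
#'
#' @param psms PSM `data.frame` (see [read_psm_table()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  validate_psm_table(psms)
  utils::write.table(psms[PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a modification database
#'
#' A modification database is a TSV with columns `name`, `composition`
#' (Unimod-style signed composition string, see [parse_composition()]),
#' `class` (one of "Reactive species", "AA substitution",
#' "Chemical derivative", "Artefact", "Unknown"), `plausible`
#' (logical flag used for tie-breaking and final classification) and
#' optionally `source` (`preknown` or `unimod`) and `steps` (implied number
#' of reaction steps, default 1; precomposed multi-step combination entries
#' carry larger values). The monoisotopic `delta` is computed from the
#' composition and attached.
#'
#' Duplicate names are legal and retained: names are labels, masses are the
#' keys.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `name`, `composition` (string),
#'   `delta`, `class`, `plausible`, `source`, `steps`.
#' @export
read_modification_db <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  need <- c("name", "composition", "class", "plausible")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$source)) df$source <- "preknown"
  if (is.null(df$steps)) df$steps <- 1L
  df$plausible <- as.logical(df$plausible)
  df$delta <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(monoisotopic_mass(parse_composition(df$composition[i])),
             error = function(e) {
               stop(sprintf("%s: entry '%s': %s", path, df$name[i],
                            conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1))
  df[c("name", "composition", "delta", "class", "plausible", "source", "steps")]
}

#' Packaged synthetic modification databases
#'
#' `trp_preknown_db()` returns the packaged 62-entry database of previously
#' reported tryptophan variants (oxidation cascade products, amino-acid
#' substitutions, adducts and preparation artefacts). `trp_unimod_db()`
#' returns the packaged larger Unimod-like table of general protein
#' modifications used as the secondary-reaction catalogue in cascade
#' annotation.
#'
#' Both files are reconstructions assembled from standard public
#' modification chemistry; they are synthetic fixtures, not a copy of any
#' proprietary table, and ship under `inst/extdata/` with `_synthetic` in
#' the filename.
#'
#' @return A modification database `data.frame` (see
#'   [read_modification_db()]).
#' @export
trp_preknown_db <- function() {
  read_modification_db(system.file("extdata", "preknown_trp_db_synthetic.tsv",
                                   package = "trpscan", mustWork = TRUE))
}

#' @rdname trp_preknown_db
#' @export
trp_unimod_db <- function() {
  read_modification_db(system.file("extdata", "unimod_subset_synthetic.tsv",
                                   package = "trpscan", mustWork = TRUE))
}

#' Read or write a clinical survival table
#'
#' TSV with columns `patient_id`, `time` (follow-up duration, > 0), `event`
#' (1 = event observed, 0 = censored) and `marker` (continuous level of the
#' candidate prognostic marker).
#'
#' @param path Path to a TSV file.
#' @return `read_survival_table`: a validated `data.frame`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event", "marker")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: time must be > 0", path, bad[1] + 1L),
         call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop(sprintf("%s: event must be 0 or 1", path), call. = FALSE)
  }
  df[need]
}

#' @rdname read_survival_table
#' @param records Survival `data.frame` to write.
#' @export
write_survival_table <- function(records, path) {
  utils::write.table(records[c("patient_id", "time", "event", "marker")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a variant-peak cluster table
#'
#' @param clusters Cluster `data.frame` from [call_variant_peaks()].
#' @param path Output path.
#' @export
write_cluster_table <- function(clusters, path) {
  cols <- c("cluster_id", "center", "sd", "weight", "window", "n_psms",
            "r_squared")
  utils::write.table(clusters[intersect(cols, names(clusters))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an annotation report
#'
#' Writes the annotation results both as a TSV and, if `json` is given, as a
#' JSON report whose records mirror the columns of a variant summary table:
#' classification, delta mass, frequency, annotation, chemical formula,
#' predicted monoisotopic mass and error.
#'
#' @param results Annotation `data.frame` from [annotate_peaks()].
#' @param path Output TSV path.
#' @param json Optional output JSON path.
#' @export
write_annotation_report <- function(results, path, json = NULL) {
  cols <- c("cluster_id", "center", "n_psms", "final_class", "final_name",
            "formula", "monoisotopic_mass", "error")
  tab <- results[intersect(cols, names(results))]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(json)) {
    recs <- lapply(seq_len(nrow(tab)), function(i) {
      list(classification = tab$final_class[i],
           delta_mass = tab$center[i],
           frequency = tab$n_psms[i],
           annotation = tab$final_name[i],
           chemical_formula = tab$formula[i],
           monoisotopic_mass = tab$monoisotopic_mass[i],
           error = tab$error[i])
    })
    jsonlite::write_json(recs, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}
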