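# Site-level aggregation and cohort statistics: paired tumour/NAT
# differential modification levels, Spearman correlation of modification
# profiles, and optimal-cutpoint log-rank survival.

#' Attach cluster assignments to PSMs
#'
#' Joins the spectrum-to-cluster map produced by [call_variant_peaks()]
#' onto the PSM table; PSMs not assigned to any surviving cluster are
#' dropped.
#'
#' @param psms PSM `data.frame`.
#' @param clusters Cluster table from [call_variant_peaks()].
#' @return `psms` subset with `cluster_id` and `cluster_center` columns.
#' @export
assign_clusters <- function(psms, clusters) {
  asg <- attr(clusters, "assignments")
  if (is.null(asg)) stop("clusters carry no assignment attribute", call. = FALSE)
  idx <- match(psms$spectrum_id, asg$spectrum_id)
  keep <- !is.na(idx)
  out <- psms[keep, , drop = FALSE]
  out$cluster_id <- asg$cluster_id[idx[keep]]
  out$cluster_center <- clusters$center[match(out$cluster_id,
                                              clusters$cluster_id)]
  out
}

#' Aggregate cluster-assigned PSMs into a site frequency table
#'
#' One row per unique (protein, site, cluster); one column per sample; each
#' cell is the spectral count of that variant at that site in that sample.
#' The grand total over all cells equals the number of assigned PSMs.
#'
#' Normalized modification levels divide the modified count by the total
#' spectral count of the protein in that sample (taken from `totals_from`,
#' which should be the full filtered PSM table so unrelated variants of the
#' protein contribute to the denominator), with a pseudocount:
#' `level = (count + 0.5) / (total + 0.5)`.
#'
#' @param assigned PSM `data.frame` with `cluster_id` / `cluster_center`
#'   columns (see [assign_clusters()]).
#' @param totals_from PSM `data.frame` used for per-protein per-sample
#'   total counts; defaults to `assigned`.
#' @param samples Character vector fixing the sample set and column order;
#'   default: all samples seen in `totals_from`.
#' @return A `site_frequency_table`: list with `row_info` (`data.frame`
#'   protein, site, center, cluster_id), `counts` and `levels` matrices
#'   (rows x samples), `samples`, and `groups` (per-sample group label if a
#'   `group` column is present).
#' @export
aggregate_sites <- function(assigned, totals_from = assigned,
                            samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(totals_from$sample_id))
  if (nrow(assigned) == 0L) {
    out <- list(row_info = data.frame(protein = character(0),
                                      site = integer(0), center = numeric(0),
                                      cluster_id = character(0)),
                counts = matrix(0, 0, length(samples),
                                dimnames = list(NULL, samples)),
                levels = matrix(numeric(0), 0, length(samples),
                                dimnames = list(NULL, samples)),
                samples = samples, groups = NULL)
    class(out) <- "site_frequency_table"
    return(out)
  }
  key <- paste(assigned$protein, assigned$site, assigned$cluster_id,
               sep = "\r")
  ukey <- unique(key)
  row_info <- assigned[match(ukey, key),
                       c("protein", "site", "cluster_center", "cluster_id")]
  names(row_info)[3] <- "center"
  rownames(row_info) <- NULL
  counts <- table(factor(key, levels = ukey),
                  factor(assigned$sample_id, levels = samples))
  counts <- matrix(as.numeric(counts), nrow = length(ukey),
                   dimnames = list(NULL, samples))
  totals <- table(factor(totals_from$protein,
                         levels = unique(row_info$protein)),
                  factor(totals_from$sample_id, levels = samples))
  totals <- matrix(as.numeric(totals),
                   nrow = length(unique(row_info$protein)),
                   dimnames = list(unique(row_info$protein), samples))
  lv <- (counts + 0.5) / (totals[row_info$protein, , drop = FALSE] + 0.5)
  groups <- NULL
  if ("group" %in% names(totals_from)) {
    groups <- totals_from$group[match(samples, totals_from$sample_id)]
    names(groups) <- samples
  }
  out <- list(row_info = row_info, counts = counts, levels = lv,
              samples = samples, groups = groups)
  class(out) <- "site_frequency_table"
  out
}

#' @export
print.site_frequency_table <- function(x, ...) {
  cat(sprintf("<site_frequency_table> %d rows x %d samples, %d spectra\n",
              nrow(x$counts), length(x$samples), sum(x$counts)))
  invisible(x)
}

infer_pairs <- function(samples) {
  tum <- grep("_T$", samples, value = TRUE)
  nat <- grep("_N$", samples, value = TRUE)
  prefixes <- union(sub("_T$", "", tum), sub("_N$", "", nat))
  miss_t <- prefixes[!(paste0(prefixes, "_T") %in% samples)]
  miss_n <- prefixes[!(paste0(prefixes, "_N") %in% samples)]
  if (length(miss_t) || length(miss_n)) {
    stop("unpaired sample(s): ",
         paste(c(paste0(miss_t, "_T"), paste0(miss_n, "_N")), collapse = ", "),
         call. = FALSE)
  }
  if (length(prefixes) == 0L) {
    stop("cannot infer tumour/NAT pairing from sample names; pass tumor= and nat=",
         call. = FALSE)
  }
  list(tumor = paste0(sort(prefixes), "_T"), nat = paste0(sort(prefixes), "_N"))
}

#' Paired tumour-vs-NAT differential modification levels
#'
#' Per (protein, site, cluster) row: log2 fold change of the mean
#' normalized level in tumour versus paired NAT samples, a paired
#' two-sided Wilcoxon signed-rank p-value, and a Benjamini-Hochberg
#' adjusted q-value across the tested rows. Rows with all-zero counts, or
#' cohorts with fewer than two pairs, are flagged `tested = FALSE` and get
#' no p-value; identical tumour and NAT level vectors give p = 1.
#'
#' @param sft A `site_frequency_table`.
#' @param tumor,nat Equal-length vectors of sample ids defining the pairs
#'   (element i of `tumor` is paired with element i of `nat`); by default
#'   inferred from the `P<k>_T` / `P<k>_N` naming convention. A sample
#'   named in the pairing but absent from the table is an error naming it.
#' @return `data.frame`: `protein`, `site`, `center`, `cluster_id`,
#'   `log2fc`, `p`, `q`, `tested`.
#' @export
differential_modification <- function(sft, tumor = NULL, nat = NULL) {
  stopifnot(inherits(sft, "site_frequency_table"))
  if (is.null(tumor) || is.null(nat)) {
    pr <- infer_pairs(sft$samples)
    tumor <- pr$tumor; nat <- pr$nat
  }
  if (length(tumor) != length(nat)) {
    stop("tumor and nat pairings differ in length", call. = FALSE)
  }
  missing_s <- setdiff(c(tumor, nat), sft$samples)
  if (length(missing_s)) {
    stop("unpaired sample(s): ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  n_rows <- nrow(sft$counts)
  out <- cbind(sft$row_info,
               data.frame(log2fc = rep(NA_real_, n_rows),
                          p = rep(NA_real_, n_rows),
                          q = rep(NA_real_, n_rows),
                          tested = rep(FALSE, n_rows)))
  for (i in seq_len(n_rows)) {
    lt <- sft$levels[i, tumor]
    ln <- sft$levels[i, nat]
    out$log2fc[i] <- log2(mean(lt) / mean(ln))
    if (sum(sft$counts[i, c(tumor, nat)]) == 0) next    # all-zero: flagged
    if (length(tumor) < 2L) next                        # degenerate n
    d <- lt - ln
    out$tested[i] <- TRUE
    # exact signed-rank p when n < 50 and no ties/zeros (stats default);
    # silently falls back to the normal approximation otherwise
    out$p[i] <- if (all(d == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(lt, ln, paired = TRUE)$p.value)
    }
  }
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Spearman correlation matrix of modification profiles
#'
#' Correlates the per-sample profiles of selected rows of a site frequency
#' table (normalized levels by default) using Spearman's rank correlation
#' with midranks for ties, and a two-sided p-value per pair. Constant rows
#' have undefined correlation and are reported as `NA`, not 0.
#'
#' @param sft A `site_frequency_table`, or a numeric matrix with one row
#'   per profile and one column per sample.
#' @param rows Optional row subset (indices into the table).
#' @param use `"levels"` (default) or `"counts"` profiles when `sft` is a
#'   `site_frequency_table`.
#' @return List with matrices `rho` and `p` (symmetric, unit diagonal,
#'   entries in \[-1, 1\]) and `n`, the number of samples.
#' @export
correlation_matrix <- function(sft, rows = NULL, use = c("levels", "counts")) {
  use <- match.arg(use)
  mat <- if (inherits(sft, "site_frequency_table")) sft[[use]] else sft
  if (!is.null(rows)) mat <- mat[rows, , drop = FALSE]
  if (ncol(mat) < 3L) stop("need at least 3 samples", call. = FALSE)
  m <- nrow(mat)
  rho <- matrix(NA_real_, m, m)
  p <- matrix(NA_real_, m, m)
  diag(rho) <- 1
  diag(p) <- 0
  constant <- apply(mat, 1L, function(v) length(unique(v)) == 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i || constant[i] || constant[j]) next
      ct <- suppressWarnings(
        stats::cor.test(mat[i, ], mat[j, ], method = "spearman",
                        exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(rho)[constant] <- NA_real_
  diag(p)[constant] <- NA_real_
  rn <- if (inherits(sft, "site_frequency_table")) {
    info <- if (is.null(rows)) sft$row_info else sft$row_info[rows, ]
    paste0(info$protein, ":", info$site, "@", round(info$center, 4))
  } else rownames(mat)
  dimnames(rho) <- dimnames(p) <- list(rn, rn)
  list(rho = rho, p = p, n = ncol(mat))
}

# Two-group log-rank z statistics for every cutpoint at once, vectorised
# over cutpoints: group 1 is marker > cutpoint.
logrank_scan_z <- function(time, event, marker, cutpoints) {
  ut <- sort(unique(time[event == 1]))
  R <- outer(ut, time, "<=")                          # at risk at each event time
  D <- outer(ut, time, "==") & rep(event == 1, each = length(ut))
  storage.mode(R) <- "double"; storage.mode(D) <- "double"
  d <- rowSums(D)
  nrisk <- rowSums(R)
  G <- outer(marker, cutpoints, ">")
  storage.mode(G) <- "double"
  n1 <- R %*% G
  d1 <- D %*% G
  O1 <- colSums(d1)
  E1 <- colSums(d * n1 / nrisk)
  frac <- n1 / nrisk
  vt <- d * frac * (1 - frac) *
    ifelse(nrisk > 1, (nrisk - d) / (nrisk - 1), 0)
  V <- colSums(vt)
  ifelse(V > 0, (O1 - E1) / sqrt(V), 0)
}

#' Optimal-cutpoint log-rank survival analysis
#'
#' Scans every admissible cutpoint of a continuous marker (the distinct
#' marker values whose quantile lies in `quantile_range`, excluding the
#' maximum so both groups are non-empty), computes the standardized
#' two-group log-rank statistic at each, and returns the cutpoint
#' maximizing |z|. The naive log-rank p at the selected cutpoint is
#' reported as `p` (this is the quantity conventionally quoted after
#' cut-off optimisation), together with a permutation-adjusted p
#' (`n_perm` label permutations of the marker, comparing maxima of |z|)
#' that accounts for the selection-induced type-I inflation.
#'
#' @param records Survival `data.frame` with columns `time`, `event`,
#'   `marker` (see [read_survival_table()]).
#' @param quantile_range Marker quantile interval scanned (default
#'   \[0.10, 0.90\]).
#' @param n_perm Number of marker permutations for the adjusted p; 0
#'   disables the correction (adjusted p is `NA`).
#' @param seed Seed for the permutations.
#' @return List: `cutpoint`, `statistic` (|z| at the optimum), `chisq`,
#'   `p` (naive), `p_adjusted`, `n_high`, `n_low`, and `scan`
#'   (`data.frame` of cutpoint and z over the whole scan).
#' @export
optimal_cutpoint_survival <- function(records, quantile_range = c(0.10, 0.90),
                                      n_perm = 200, seed = 1L) {
  time <- records$time; event <- records$event; marker <- records$marker
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and > 0", call. = FALSE)
  }
  if (sum(event) == 0) stop("all observations are censored", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (length(unique(marker)) < 2L) stop("marker is constant", call. = FALSE)
  qs <- stats::quantile(marker, quantile_range, names = FALSE)
  cand <- sort(unique(marker))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(marker)]
  if (length(cand) == 0L) {
    cand <- sort(unique(marker))
    cand <- cand[-length(cand)]
  }
  z <- logrank_scan_z(time, event, marker, cand)
  best <- which.max(abs(z))
  chisq <- z[best]^2
  obs_max <- abs(z[best])
  p_adj <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zp <- logrank_scan_z(time, event, sample(marker), cand)
      if (max(abs(zp)) >= obs_max) exceed <- exceed + 1L
    }
    p_adj <- (1 + exceed) / (n_perm + 1)
  }
  list(cutpoint = cand[best],
       statistic = obs_max,
       chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       p_adjusted = p_adj,
       n_high = sum(marker > cand[best]),
       n_low = sum(marker <= cand[best]),
       scan = data.frame(cutpoint = cand, z = z))
}
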