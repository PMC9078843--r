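# Confidence filtering and delta-mass peak calling.
#
# The delta-mass axis is cut into 1-Da half-open windows; within each
# window a one-dimensional Gaussian mixture is fitted by EM for k = 1..k_max
# components and the k minimizing BIC is kept. Windows whose fitted density
# does not reproduce the empirical histogram (low R-squared) are rejected,
# as are broad background components and components with too few supporting
# spectra. Surviving components are the called variant peaks.

#' Confidence filter criteria for PSMs
#'
#' Defaults follow the conventional high-confidence open-search filter:
#' search score >= 300, localization (delta modification) score >= 10,
#' two-dimensional FDR <= 0.01, delta mass inside \[-150, 500\] Da, target
#' residue tryptophan, exact-zero deltas (unmodified matches) excluded.
#' All threshold comparisons are inclusive.
#'
#' @param min_score Minimum search score.
#' @param min_delta_mod_score Minimum localization score.
#' @param max_fdr_2d Maximum two-dimensional FDR.
#' @param delta_range Closed interval of admissible delta masses (Da).
#' @param target_residue One-letter residue code the variant must localize
#'   to; `NULL` disables the residue filter.
#' @param exclude_zero Drop records with delta mass exactly 0.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(min_score = 300, min_delta_mod_score = 10,
                            max_fdr_2d = 0.01,
                            delta_range = DEFAULT_DELTA_RANGE,
                            target_residue = "W", exclude_zero = TRUE) {
  if (delta_range[1] >= delta_range[2]) {
    stop("delta_range lower bound must be below the upper bound", call. = FALSE)
  }
  structure(list(min_score = min_score,
                 min_delta_mod_score = min_delta_mod_score,
                 max_fdr_2d = max_fdr_2d, delta_range = delta_range,
                 target_residue = target_residue, exclude_zero = exclude_zero),
            class = "filter_criteria")
}

#' Filter PSMs by confidence, residue and delta range
#'
#' Retains a record iff score, localization score and FDR pass their
#' (inclusive) thresholds, the residue equals the target, the delta mass
#' lies in the closed delta range, and (if `exclude_zero`) the delta is not
#' exactly zero. Row order is preserved; an empty result is legal.
#'
#' @param psms PSM `data.frame`.
#' @param criteria A [filter_criteria()].
#' @return The retained subset of `psms`.
#' @export
filter_psms <- function(psms, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- psms$score >= criteria$min_score &
    psms$delta_mod_score >= criteria$min_delta_mod_score &
    psms$fdr_2d <= criteria$max_fdr_2d &
    psms$delta_mass >= criteria$delta_range[1] &
    psms$delta_mass <= criteria$delta_range[2]
  if (!is.null(criteria$target_residue)) {
    keep <- keep & psms$residue == criteria$target_residue
  }
  if (isTRUE(criteria$exclude_zero)) {
    keep <- keep & psms$delta_mass != 0
  }
  psms[keep, , drop = FALSE]
}

#' Partition delta masses into integer-Da windows
#'
#' Windows are half-open intervals `[k * width, (k + 1) * width)` anchored
#' at integer multiples of `width`; every delta falls in exactly one
#' window.
#'
#' @param x Numeric vector of delta masses, or a PSM `data.frame` (its
#'   `delta_mass` column is used).
#' @param width Window width in Da (default 1).
#' @return Named list mapping the window's lower bound (as a name) to the
#'   vector of deltas in it; empty input gives an empty list.
#' @export
window_deltas <- function(x, width = 1) {
  if (is.data.frame(x)) x <- x$delta_mass
  if (length(x) == 0L) return(structure(list(), names = character(0)))
  idx <- floor(x / width)
  split(x, factor(idx * width, levels = sort(unique(idx)) * width))
}

# log-density matrix n x k for a Gaussian mixture; returns list with
# responsibilities and total log-likelihood
gmm_estep <- function(x, w, mu, sigma) {
  n <- length(x)
  k <- length(w)
  logd <- matrix(0, n, k)
  for (j in seq_len(k)) {
    logd[, j] <- stats::dnorm(x, mu[j], sigma[j], log = TRUE) + log(w[j])
  }
  m <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
  lse <- m + log(rowSums(exp(logd - m)))
  list(resp = exp(logd - lse), loglik = sum(lse))
}

gmm_em_once <- function(x, k, mu0, max_iter = 100, rel_tol = 1e-8,
                        sd_floor = 1e-4) {
  n <- length(x)
  if (k == 1L) {           # closed form, no EM needed
    mu <- mean(x)
    sigma <- max(sqrt(mean((x - mu)^2)), sd_floor)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(list(w = 1, mu = mu, sigma = sigma, loglik = ll,
                resp = matrix(1, n, 1)))
  }
  w <- rep(1 / k, k)
  mu <- mu0
  sigma <- rep(max(stats::sd(x) / k, sd_floor), k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    e <- gmm_estep(x, w, mu, sigma)
    r <- e$resp
    nk <- pmax(colSums(r), 1e-12)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(pmax(colSums(r * (outer(x, mu, "-")^2)) / nk, sd_floor^2))
    if (is.finite(e$loglik) &&
        e$loglik - ll_old < rel_tol * (abs(e$loglik) + 1)) break
    ll_old <- e$loglik
  }
  e <- gmm_estep(x, w, mu, sigma)
  list(w = w, mu = mu, sigma = sigma, loglik = e$loglik, resp = e$resp)
}

fit_gmm_k <- function(x, k, restarts = 10) {
  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE,
                        type = 7)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- if (r == 1L) qs else sort(sample(x, k, replace = length(x) < k))
    mu0 <- mu0 + stats::rnorm(k, 0, if (r == 1L) 0 else 1e-3)
    fit <- tryCatch(gmm_em_once(x, k, mu0), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  best
}

mixture_cdf <- function(xs, w, mu, sigma) {
  rowSums(vapply(seq_along(w), function(j) {
    w[j] * stats::pnorm(xs, mu[j], sigma[j])
  }, numeric(length(xs))))
}

# Coefficient of determination of the fitted mixture against the empirical
# histogram over the whole 1-Da window (bin width in Da). Expected counts
# use exact bin probabilities (mixture CDF differences): with 2-mDa bins
# comparable to the peak width, the midpoint-density approximation misfits
# systematically. Evaluating over the full window rather than occupied
# bins only keeps the statistic defined under a sparse uniform background
# (where all occupied counts are 1) and stable for narrow peaks.
fit_r_squared <- function(x, w, mu, sigma, bin_width = 0.002) {
  lo <- floor(min(x))
  hi <- max(ceiling(max(x)), lo + 1)
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  cdf <- mixture_cdf(breaks, w, mu, sigma)
  expected <- length(x) * diff(cdf)
  ss_res <- sum((counts - expected)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  if (ss_tot <= 0) return(1)
  max(0, min(1, 1 - ss_res / ss_tot))
}

#' Fit a Gaussian mixture to the deltas of one window
#'
#' Fits mixtures with 1 to `k_max` components by EM (quantile-spaced
#' initial means, `restarts` random restarts, best likelihood kept),
#' selects the component count minimizing BIC (ties go to the smaller k),
#' hard-assigns each delta to its maximum-responsibility component, and
#' returns one candidate cluster per component. Components supported by
#' fewer than `min_support` deltas, or broader than `max_sd` (background
#' rather than an instrument-resolution peak), are discarded.
#'
#' @param deltas Numeric vector of delta masses, all in one window.
#' @param k_max Maximum number of mixture components per window.
#' @param min_support Minimum spectra per surviving cluster.
#' @param max_sd Maximum cluster standard deviation in Da; components wider
#'   than this model diffuse background and are dropped.
#' @param merge_tol Surviving components closer than this (Da) are merged:
#'   they are one physical peak that EM overfitted.
#' @param restarts EM restarts per k.
#' @param bin_width Histogram bin width (Da) for the R-squared
#'   goodness-of-fit.
#' @return `data.frame` with columns `center`, `sd`, `weight`, `window`,
#'   `n_psms`, `r_squared` and a list column `members` of member indices
#'   into `deltas`; zero rows when nothing survives (never an error).
#' @export
fit_window <- function(deltas, k_max = 4, min_support = 10, max_sd = 0.02,
                       merge_tol = 0.01, restarts = 10, bin_width = 0.002) {
  empty <- data.frame(center = numeric(0), sd = numeric(0),
                      weight = numeric(0), window = numeric(0),
                      n_psms = integer(0), r_squared = numeric(0))
  empty$members <- list()
  n <- length(deltas)
  if (n < max(min_support, 1L)) return(empty)
  win <- floor(min(deltas))
  if (n == 1L || length(unique(deltas)) == 1L) {
    out <- data.frame(center = deltas[1], sd = 1e-4, weight = 1,
                      window = win, n_psms = n, r_squared = 1)
    out$members <- list(seq_len(n))
    if (n < min_support) return(empty)
    return(out)
  }
  kmax_eff <- max(1L, min(k_max, length(unique(deltas)), floor(n / 2)))
  fits <- vector("list", kmax_eff)
  bic <- rep(Inf, kmax_eff)
  for (k in seq_len(kmax_eff)) {
    fit <- fit_gmm_k(deltas, k, restarts = restarts)
    if (is.null(fit)) next
    fits[[k]] <- fit
    bic[k] <- -2 * fit$loglik + (3 * k - 1) * log(n)
  }
  if (all(!is.finite(bic))) return(empty)
  k_best <- which.min(bic)  # which.min takes the first (smallest k) on ties
  fit <- fits[[k_best]]
  r2 <- fit_r_squared(deltas, fit$w, fit$mu, fit$sigma, bin_width = bin_width)
  assign <- max.col(fit$resp, ties.method = "first")
  rows <- lapply(seq_len(k_best), function(j) {
    members <- which(assign == j)
    if (length(members) < min_support) return(NULL)
    if (fit$sigma[j] > max_sd) return(NULL)
    out <- data.frame(center = fit$mu[j], sd = fit$sigma[j],
                      weight = fit$w[j], window = win,
                      n_psms = length(members), r_squared = r2)
    out$members <- list(members)
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$center), , drop = FALSE]
  # chain-merge components closer than merge_tol: EM sometimes overfits
  # one physical peak into nearly coincident narrow components
  i <- 1L
  while (i < nrow(out)) {
    if (out$center[i + 1L] - out$center[i] < merge_tol) {
      members <- c(out$members[[i]], out$members[[i + 1L]])
      xs <- deltas[members]
      out$center[i] <- mean(xs)
      out$sd[i] <- max(stats::sd(xs), 1e-6, na.rm = TRUE)
      out$weight[i] <- out$weight[i] + out$weight[i + 1L]
      out$n_psms[i] <- length(members)
      out$members[[i]] <- members
      out <- out[-(i + 1L), , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }
  rownames(out) <- NULL
  out
}

#' Call variant peaks from filtered PSMs
#'
#' Partitions the delta masses into 1-Da windows, fits each window
#' independently with [fit_window()], discards windows whose histogram
#' R-squared falls below `r2_threshold`, merges successive clusters whose
#' centres are closer than `merge_tol` (a real peak sitting on a window
#' boundary is otherwise split in two, and EM occasionally overfits one
#' peak into nearly coincident components), recomputes centre and spread
#' from the pooled member deltas, and returns the clusters sorted by
#' centre. Member spectra are those hard-assigned to the component by
#' maximum posterior responsibility.
#'
#' @param psms Filtered PSM `data.frame` (see [filter_psms()]).
#' @param r2_threshold Minimum histogram R-squared for a window's clusters
#'   to be kept (default 0.9).
#' @param k_max,min_support,max_sd,restarts,bin_width Passed to
#'   [fit_window()].
#' @param merge_tol Maximum centre distance (Da) for merging
#'   adjacent-window clusters.
#' @param seed Integer seed for the EM restarts; a fixed seed makes the
#'   cluster table reproducible.
#' @param verbose Log each discarded cluster and the reason.
#' @return `data.frame` with columns `cluster_id`, `center`, `sd`,
#'   `weight`, `window`, `n_psms`, `r_squared` and list column `members`
#'   (spectrum ids). The spectrum-to-cluster map is attached as attribute
#'   `"assignments"` (`data.frame` with `spectrum_id`, `cluster_id`).
#' @export
call_variant_peaks <- function(psms, r2_threshold = 0.9, k_max = 4,
                               min_support = 10, max_sd = 0.02,
                               merge_tol = 0.01, restarts = 10,
                               bin_width = 0.002, seed = 1L,
                               verbose = FALSE) {
  set.seed(seed)
  deltas <- psms$delta_mass
  ids <- psms$spectrum_id
  empty <- data.frame(cluster_id = character(0), center = numeric(0),
                      sd = numeric(0), weight = numeric(0),
                      window = numeric(0), n_psms = integer(0),
                      r_squared = numeric(0))
  empty$members <- list()
  attr(empty, "assignments") <- data.frame(spectrum_id = character(0),
                                           cluster_id = character(0))
  if (length(deltas) == 0L) return(empty)
  win_idx <- split(seq_along(deltas), floor(deltas))
  clusters <- list()
  for (w in names(win_idx)) {
    idx <- win_idx[[w]]
    fit <- fit_window(deltas[idx], k_max = k_max, min_support = min_support,
                      max_sd = max_sd, merge_tol = merge_tol,
                      restarts = restarts, bin_width = bin_width)
    if (nrow(fit) == 0L) next
    if (fit$r_squared[1] < r2_threshold) {
      if (verbose) {
        message(sprintf("window %s: %d cluster(s) discarded (R^2 %.3f < %.3f)",
                        w, nrow(fit), fit$r_squared[1], r2_threshold))
      }
      next
    }
    for (j in seq_len(nrow(fit))) {
      clusters[[length(clusters) + 1L]] <- list(
        member_idx = idx[fit$members[[j]]],
        window = fit$window[j], weight = fit$weight[j],
        r_squared = fit$r_squared[j])
    }
  }
  if (length(clusters) == 0L) return(empty)
  centers <- vapply(clusters, function(cl) mean(deltas[cl$member_idx]),
                    numeric(1))
  ord <- order(centers)
  clusters <- clusters[ord]
  centers <- centers[ord]
  # merge successive clusters closer than merge_tol: reunifies peaks split
  # by a window boundary and chains EM components overfitted onto one peak
  merged <- list(clusters[[1]])
  for (i in seq_along(clusters)[-1]) {
    prev <- merged[[length(merged)]]
    prev_center <- mean(deltas[prev$member_idx])
    if (centers[i] - prev_center < merge_tol) {
      prev$member_idx <- c(prev$member_idx, clusters[[i]]$member_idx)
      prev$weight <- prev$weight + clusters[[i]]$weight
      prev$r_squared <- max(prev$r_squared, clusters[[i]]$r_squared)
      merged[[length(merged)]] <- prev
    } else {
      merged[[length(merged) + 1L]] <- clusters[[i]]
    }
  }
  out <- do.call(rbind, lapply(seq_along(merged), function(i) {
    cl <- merged[[i]]
    xs <- deltas[cl$member_idx]
    s <- stats::sd(xs)
    if (!is.finite(s)) s <- 1e-6
    row <- data.frame(cluster_id = sprintf("C%03d", i), center = mean(xs),
                      sd = max(s, 1e-6),
                      weight = cl$weight, window = cl$window,
                      n_psms = length(xs), r_squared = cl$r_squared)
    row$members <- list(ids[cl$member_idx])
    row
  }))
  out <- out[order(out$center), , drop = FALSE]
  out$cluster_id <- sprintf("C%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  assignments <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    data.frame(spectrum_id = out$members[[i]], cluster_id = out$cluster_id[i],
               stringsAsFactors = FALSE)
  }))
  attr(out, "assignments") <- assignments
  out
}
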