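# Synthetic PSM tables, cohorts and clinical tables.
#
# The generator emulates the statistical structure the downstream pipeline
# assumes: delta-mass peaks as Gaussians around a true modification mass,
# a uniform background of spurious open-search deltas, confidence columns
# with a controllable pass fraction, paired tumour/NAT samples with
# planted per-site enrichment, and exponential survival with a marker-
# scaled hazard. It does not simulate spectra, retention times or protein
# abundance biology.

DEFAULT_DELTA_RANGE <- c(-150, 500)

#' Specify a planted delta-mass peak
#'
#' @param true_delta True modification delta mass in Da; must lie inside
#'   `delta_range`.
#' @param n_psms Number of PSMs drawn for this peak (>= 0).
#' @param mass_sd Standard deviation of the instrument mass error in Da
#'   (> 0). Orbitrap-class open-search deltas scatter with an sd of a few
#'   mDa; default 0.002.
#' @param residue One-letter code of the modified residue (default `"W"`).
#' @param site_pool `data.frame` with columns `protein`, `site`: the sites
#'   this peak's PSMs are attributed to (uniformly, unless enriched via the
#'   cohort's `effect_map`). Default: one synthetic site per peak.
#' @param delta_range Admissible delta-mass interval.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(true_delta, n_psms, mass_sd = 0.002, residue = "W",
                      site_pool = NULL, delta_range = DEFAULT_DELTA_RANGE) {
  if (!is.numeric(true_delta) || length(true_delta) != 1L ||
      true_delta < delta_range[1] || true_delta > delta_range[2]) {
    stop("invalid peak spec: true_delta must be a single value inside the delta range",
         call. = FALSE)
  }
  if (!is.numeric(n_psms) || n_psms < 0 || n_psms != round(n_psms)) {
    stop("invalid peak spec: n_psms must be a non-negative integer", call. = FALSE)
  }
  if (!is.numeric(mass_sd) || mass_sd <= 0) {
    stop("invalid peak spec: mass_sd must be > 0", call. = FALSE)
  }
  if (!(residue %in% AA_CODES)) {
    stop("invalid peak spec: residue must be a standard one-letter code",
         call. = FALSE)
  }
  if (!is.null(site_pool) &&
      (!is.data.frame(site_pool) ||
       !all(c("protein", "site") %in% names(site_pool)) ||
       nrow(site_pool) == 0L)) {
    stop("invalid peak spec: site_pool needs columns protein, site and >= 1 row",
         call. = FALSE)
  }
  structure(list(true_delta = true_delta, n_psms = as.integer(n_psms),
                 mass_sd = mass_sd, residue = residue, site_pool = site_pool,
                 delta_range = delta_range),
            class = "peak_spec")
}

#' Specify a paired tumour/NAT cohort
#'
#' @param n_pairs Number of tumour/NAT sample pairs (>= 1). Samples are
#'   labelled `P<k>_T` and `P<k>_N`.
#' @param effect_map Optional `data.frame` with columns `protein`, `site`,
#'   `true_delta`, `effect`: multiplicative tumour enrichment of PSM counts
#'   for that site within that peak (effect 1 = no enrichment).
#' @param noise_fraction Fraction of all PSMs drawn uniformly over the
#'   delta range rather than from a planted peak, in \[0, 1\].
#' @param confident_fraction Fraction of records passing all three
#'   confidence thresholds (score, localization score, FDR); the rest fail
#'   exactly one, chosen at random. Default 0.9.
#' @param mislocalization_rate Fraction of planted records whose residue is
#'   corrupted to a random other amino acid. Default 0.
#' @param seed Integer seed governing all draws.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_pairs, effect_map = NULL, noise_fraction = 0,
                        confident_fraction = 0.9, mislocalization_rate = 0,
                        seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 1 || n_pairs != round(n_pairs)) {
    stop("invalid cohort spec: n_pairs must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction > 1) {
    stop("invalid cohort spec: noise_fraction must be in [0, 1]", call. = FALSE)
  }
  if (confident_fraction < 0 || confident_fraction > 1) {
    stop("invalid cohort spec: confident_fraction must be in [0, 1]",
         call. = FALSE)
  }
  if (mislocalization_rate < 0 || mislocalization_rate > 1) {
    stop("invalid cohort spec: mislocalization_rate must be in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(effect_map) &&
      (!is.data.frame(effect_map) ||
       !all(c("protein", "site", "true_delta", "effect") %in% names(effect_map)))) {
    stop("invalid cohort spec: effect_map needs columns protein, site, true_delta, effect",
         call. = FALSE)
  }
  structure(list(n_pairs = as.integer(n_pairs), effect_map = effect_map,
                 noise_fraction = noise_fraction,
                 confident_fraction = confident_fraction,
                 mislocalization_rate = mislocalization_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_samples <- function(cohort) {
  k <- seq_len(cohort$n_pairs)
  data.frame(sample_id = as.vector(rbind(sprintf("P%02d_T", k),
                                         sprintf("P%02d_N", k))),
             group = rep(c("tumor", "NAT"), cohort$n_pairs),
             pair = rep(k, each = 2L),
             stringsAsFactors = FALSE)
}

random_peptide <- function(n, residue) {
  left <- vapply(seq_len(n), function(i) {
    paste(sample(AA_CODES, 5L, replace = TRUE), collapse = "")
  }, character(1))
  right <- vapply(seq_len(n), function(i) {
    paste(sample(AA_CODES, 4L, replace = TRUE), collapse = "")
  }, character(1))
  paste0(left, residue, right, "K")
}

draw_confidence <- function(n, confident_fraction) {
  conf <- stats::runif(n) < confident_fraction
  fail_which <- sample.int(3L, n, replace = TRUE)   # criterion failed when !conf
  score <- 300 + stats::rlnorm(n, meanlog = log(150), sdlog = 0.6)
  dms <- 10 + stats::rlnorm(n, meanlog = log(15), sdlog = 0.7)
  fdr <- stats::runif(n, 0, 0.01)
  score[!conf & fail_which == 1L] <- stats::runif(sum(!conf & fail_which == 1L), 0, 299.9)
  dms[!conf & fail_which == 2L] <- stats::runif(sum(!conf & fail_which == 2L), 0, 9.9)
  fdr[!conf & fail_which == 3L] <- stats::runif(sum(!conf & fail_which == 3L), 0.0101, 0.2)
  list(score = score, delta_mod_score = dms, fdr_2d = fdr)
}

#' Generate a synthetic PSM table
#'
#' Draws `n_psms` delta masses per planted peak from
#' `Normal(true_delta, mass_sd)` and `n_noise` spurious deltas uniformly
#' over the delta range, attaches sites, confidence columns and paired
#' tumour/NAT sample labels, and returns a table in the canonical PSM
#' schema (see [read_psm_table()]) plus a `truth_peak` column (index of the
#' generating peak, `NA` for noise).
#'
#' Site attribution is uniform over the peak's `site_pool`; the cohort's
#' `effect_map` multiplies the sampling weight of tumour samples for the
#' named (protein, site, peak), which makes the expected tumour/NAT count
#' ratio at that site equal to `effect`.
#'
#' The same (specs, seed) always yields a byte-identical table.
#'
#' @param peaks List of [peak_spec()] objects (may be empty when
#'   `n_noise > 0`).
#' @param cohort A [cohort_spec()].
#' @param n_noise Number of uniform background records. Default: chosen so
#'   that noise makes up `cohort$noise_fraction` of all records; must be
#'   given explicitly when there are no peaks.
#' @param noise_residue Residue assigned to noise records (default `"W"`,
#'   so the background survives the residue filter and stresses the
#'   clustering stage).
#' @return PSM `data.frame` with canonical columns plus `truth_peak`.
#' @export
generate_psm_table <- function(peaks, cohort, n_noise = NULL,
                               noise_residue = "W") {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (length(peaks) == 0L && is.null(n_noise) && cohort$noise_fraction < 1) {
    stop("peaks must be non-empty unless noise_fraction is 1 (or n_noise given)",
         call. = FALSE)
  }
  for (p in peaks) stopifnot(inherits(p, "peak_spec"))
  n_planted <- sum(vapply(peaks, `[[`, integer(1), "n_psms"))
  if (is.null(n_noise)) {
    n_noise <- if (cohort$noise_fraction >= 1) {
      stop("n_noise must be given explicitly when noise_fraction = 1",
           call. = FALSE)
    } else {
      as.integer(round(n_planted * cohort$noise_fraction /
                         (1 - cohort$noise_fraction)))
    }
  }
  set.seed(cohort$seed)
  samples <- cohort_samples(cohort)
  range_ <- if (length(peaks)) peaks[[1]]$delta_range else DEFAULT_DELTA_RANGE

  blocks <- list()
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    if (p$n_psms == 0L) next
    pool <- p$site_pool
    if (is.null(pool)) {
      pool <- data.frame(protein = sprintf("PROT%02d", i), site = 100L + i,
                         stringsAsFactors = FALSE)
    }
    site_idx <- sample.int(nrow(pool), p$n_psms, replace = TRUE)
    delta <- stats::rnorm(p$n_psms, p$true_delta, p$mass_sd)
    delta <- pmin(pmax(delta, range_[1]), range_[2])
    # per-record sample draw, tumour weight scaled by any planted effect
    eff <- rep(1, p$n_psms)
    em <- cohort$effect_map
    if (!is.null(em)) {
      for (j in seq_len(nrow(em))) {
        hit <- pool$protein[site_idx] == em$protein[j] &
          pool$site[site_idx] == em$site[j] &
          abs(p$true_delta - em$true_delta[j]) < 1e-6
        eff[hit] <- em$effect[j]
      }
    }
    w_tumor <- ifelse(samples$group == "tumor", 1, 0)
    sample_idx <- vapply(eff, function(e) {
      w <- ifelse(w_tumor == 1, e, 1)
      sample.int(nrow(samples), 1L, prob = w)
    }, integer(1))
    residue <- rep(p$residue, p$n_psms)
    if (cohort$mislocalization_rate > 0) {
      flip <- stats::runif(p$n_psms) < cohort$mislocalization_rate
      residue[flip] <- vapply(which(flip), function(k) {
        sample(setdiff(AA_CODES, p$residue), 1L)
      }, character(1))
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      peptide = random_peptide(p$n_psms, p$residue),
      protein = pool$protein[site_idx],
      site = as.integer(pool$site[site_idx]),
      residue = residue,
      delta_mass = delta,
      sample_id = samples$sample_id[sample_idx],
      group = samples$group[sample_idx],
      truth_peak = i,
      stringsAsFactors = FALSE)
  }
  if (n_noise > 0L) {
    sample_idx <- sample.int(nrow(samples), n_noise, replace = TRUE)
    blocks[[length(blocks) + 1L]] <- data.frame(
      peptide = random_peptide(n_noise, noise_residue),
      protein = sprintf("PN%02d", sample.int(20L, n_noise, replace = TRUE)),
      site = sample.int(500L, n_noise, replace = TRUE),
      residue = rep(noise_residue, n_noise),
      delta_mass = stats::runif(n_noise, range_[1], range_[2]),
      sample_id = samples$sample_id[sample_idx],
      group = samples$group[sample_idx],
      truth_peak = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0L) {
    out <- data.frame(spectrum_id = character(0), peptide = character(0),
                      protein = character(0), site = integer(0),
                      residue = character(0), delta_mass = numeric(0),
                      score = numeric(0), delta_mod_score = numeric(0),
                      fdr_2d = numeric(0), sample_id = character(0),
                      group = character(0), truth_peak = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, blocks)
  conf <- draw_confidence(nrow(out), cohort$confident_fraction)
  out$score <- conf$score
  out$delta_mod_score <- conf$delta_mod_score
  out$fdr_2d <- conf$fdr_2d
  out$spectrum_id <- sprintf("S%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c(PSM_COLUMNS, "truth_peak")]
}

#' Generate a synthetic survival table
#'
#' Event times are exponential with per-patient hazard
#' `baseline_hazard * marker_effect^marker`, where `marker` is a standard
#' normal level, so `marker_effect` is the hazard ratio per unit of marker.
#' Censoring times are independent exponentials.
#'
#' @param n_patients Number of patients (>= 2).
#' @param marker_effect Hazard ratio per unit marker (> 0); 1 means the
#'   marker is independent of survival.
#' @param seed Integer seed.
#' @param baseline_hazard Event hazard at marker 0 (per unit time).
#' @param censor_hazard Hazard of independent censoring.
#' @return `data.frame` with columns `patient_id`, `time`, `event`,
#'   `marker`.
#' @export
generate_survival_table <- function(n_patients, marker_effect, seed = 1L,
                                    baseline_hazard = 0.05,
                                    censor_hazard = 0.02) {
  if (!is.numeric(n_patients) || n_patients < 2) {
    stop("n_patients must be >= 2", call. = FALSE)
  }
  if (!is.numeric(marker_effect) || marker_effect <= 0) {
    stop("marker_effect (hazard ratio) must be > 0", call. = FALSE)
  }
  set.seed(seed)
  n <- as.integer(n_patients)
  marker <- stats::rnorm(n)
  hazard <- baseline_hazard * marker_effect^marker
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::rexp(n, rate = censor_hazard)
  data.frame(patient_id = sprintf("PT%04d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             marker = marker,
             stringsAsFactors = FALSE)
}
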