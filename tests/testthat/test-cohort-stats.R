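make_sft <- function(counts, samples, groups = NULL,
                     proteins = paste0("P", seq_len(nrow(counts))),
                     sites = seq_len(nrow(counts)) * 10L) {
  long <- NULL
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]
    if (k > 0) {
      long <- rbind(long, data.frame(
        protein = proteins[i], site = sites[i], residue = "W",
        cluster_id = paste0("C", i), cluster_center = i + 0.5,
        sample_id = samples[j],
        group = if (is.null(groups)) "tumor" else groups[j],
        stringsAsFactors = FALSE)[rep(1, k), ])
    }
  }
  long$spectrum_id <- sprintf("S%05d", seq_len(nrow(long)))
  aggregate_sites(long, samples = samples)
}

test_that("aggregation counts cells exactly and conserves totals", {
  psms <- data.frame(protein = "P1", site = 5L,
                     cluster_id = "C1", cluster_center = 15.99,
                     sample_id = c("A", "A", "B"),
                     spectrum_id = c("s1", "s2", "s3"),
                     stringsAsFactors = FALSE)
  sft <- aggregate_sites(psms)
  expect_identical(nrow(sft$counts), 1L)
  expect_equal(unname(sft$counts[1, ]), c(2, 1))

  empty <- aggregate_sites(psms[0, ])
  expect_identical(nrow(empty$counts), 0L)

  # conservation against planted ground truth, through the real pipeline
  peaks <- list(peak_spec(15.9949, 250,
                          site_pool = data.frame(protein = c("P1", "P2"),
                                                 site = c(7L, 9L))),
                peak_spec(3.9953, 200))
  psms2 <- filter_psms(generate_psm_table(peaks, cohort_spec(3, seed = 8),
                                          n_noise = 0))
  cl <- call_variant_peaks(psms2, seed = 4)
  asg <- assign_clusters(psms2, cl)
  sft2 <- aggregate_sites(asg, totals_from = psms2)
  expect_equal(sum(sft2$counts), nrow(asg))
  expect_equal(sum(sft2$counts), sum(cl$n_psms))
  # row sums match the per-site planted allocation
  by_site <- tapply(rep(1, nrow(asg)), paste(asg$protein, asg$site), sum)
  expect_equal(sort(unname(rowSums(sft2$counts))), sort(as.numeric(by_site)))
})

test_that("differential testing handles null, degenerate and planted cases", {
  samples <- c("P01_T", "P01_N", "P02_T", "P02_N", "P03_T", "P03_N")
  groups <- rep(c("tumor", "NAT"), 3)
  cnt <- rbind(c(4, 4, 6, 6, 5, 5),
               c(8, 2, 9, 3, 7, 2))
  sft <- make_sft(cnt, samples, groups, proteins = c("P1", "P1"),
                  sites = c(10L, 20L))
  res <- differential_modification(sft)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$tested))
  expect_true(res$log2fc[2] > 0)

  # identical tumour and NAT vectors: log2FC 0, p = 1
  same <- make_sft(rbind(c(3, 3, 5, 5, 7, 7)), samples, groups)
  r1 <- differential_modification(same)
  expect_equal(r1$log2fc, 0)
  expect_equal(r1$p, 1)

  # single pair: flagged untested
  single <- make_sft(rbind(c(3, 5)), c("P01_T", "P01_N"),
                     c("tumor", "NAT"))
  expect_false(differential_modification(single)$tested)

  # unpaired sample: error naming it
  expect_error(differential_modification(sft, tumor = c("P01_T", "P09_T"),
                                         nat = c("P01_N", "P02_N")),
               "P09_T")

  # label swap negates every log2 fold change
  swapped <- differential_modification(sft,
                                       tumor = paste0("P0", 1:3, "_N"),
                                       nat = paste0("P0", 1:3, "_T"))
  expect_equal(swapped$log2fc, -res$log2fc)
  # BH q-values are non-decreasing in p-value rank
  ord <- order(res$p)
  expect_true(!is.unsorted(res$q[ord]))
})

test_that("planted tumour enrichment is detected (power, scaled down)", {
  hits <- vapply(1:10, function(s) {
    pool <- data.frame(protein = "PROT_E", site = c(11L, 12L, 13L, 14L))
    peaks <- list(peak_spec(15.9949, 1600, site_pool = pool))
    em <- data.frame(protein = "PROT_E", site = 11L, true_delta = 15.9949,
                     effect = 4)
    co <- cohort_spec(20, effect_map = em, seed = 1000 + s)
    psms <- filter_psms(generate_psm_table(peaks, co, n_noise = 0))
    psms$cluster_id <- "C1"
    psms$cluster_center <- 15.9949
    sft <- aggregate_sites(psms, totals_from = psms)
    res <- differential_modification(sft)
    res$q[res$site == 11L] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("correlation matrices respect rank invariances and ties", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1, 0.3)
  mat <- rbind(a = x, b = exp(x), c = -x, d = rep(2, 6))
  cm <- correlation_matrix(mat)
  expect_equal(cm$rho["a", "b"], 1)               # monotone transform
  expect_equal(cm$rho["a", "c"], -1)              # negation
  expect_true(is.na(cm$rho["a", "d"]))            # constant row: missing
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(abs(cm$rho) <= 1, na.rm = TRUE))

  set.seed(19)
  ind <- rbind(rnorm(1000), rnorm(1000))
  ci <- correlation_matrix(ind)
  expect_lt(abs(ci$rho[1, 2]), 0.1)
  expect_gt(ci$p[1, 2], 0.01)

  expect_error(correlation_matrix(mat[, 1:2]), "3 samples")
})

test_that("optimal cutpoint equals the exhaustive survdiff oracle", {
  skip_if_not_installed("survival")
  oracle <- function(df, qr = c(0.10, 0.90)) {
    qs <- stats::quantile(df$marker, qr, names = FALSE)
    cand <- sort(unique(df$marker))
    cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(df$marker)]
    stats <- vapply(cand, function(cc) {
      g <- factor(df$marker > cc, levels = c(FALSE, TRUE))
      survival::survdiff(survival::Surv(time, event) ~ g, data = df)$chisq
    }, numeric(1))
    list(cutpoint = cand[which.max(stats)], chisq = max(stats))
  }
  for (s in 1:5) {
    df <- generate_survival_table(40, 2.0, seed = 100 + s)
    got <- optimal_cutpoint_survival(df, n_perm = 0)
    want <- oracle(df)
    expect_equal(got$cutpoint, want$cutpoint)
    expect_equal(got$chisq, want$chisq, tolerance = 1e-8)
    expect_equal(got$p,
                 stats::pchisq(want$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("identical survival curves give a zero log-rank statistic", {
  base <- data.frame(time = c(2, 4, 6, 8, 10, 12), event = c(1, 1, 0, 1, 1, 0))
  df <- rbind(cbind(base, marker = 0), cbind(base, marker = 1))
  df$patient_id <- sprintf("PT%02d", seq_len(nrow(df)))
  res <- optimal_cutpoint_survival(df, quantile_range = c(0, 1), n_perm = 0)
  expect_equal(res$statistic, 0)
})

test_that("degenerate survival inputs are rejected", {
  df <- generate_survival_table(30, 1.5, seed = 2)
  allcens <- df; allcens$event <- 0
  expect_error(optimal_cutpoint_survival(allcens), "censored")
  const <- df; const$marker <- 1
  expect_error(optimal_cutpoint_survival(const), "constant")
})

test_that("permutation-adjusted p is calibrated under the null (scaled)", {
  # marker independent of survival; 60 replicates of B = 99 permutations
  # (scaled down from the 200 x B design for runtime)
  rej <- vapply(1:60, function(s) {
    df <- generate_survival_table(80, 1.0, seed = 5000 + s)
    res <- optimal_cutpoint_survival(df, n_perm = 99, seed = s)
    res$p_adjusted <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.10)
  # and the naive p is anti-conservative by construction: it can only be
  # smaller than the permutation-adjusted p on the same data
  df <- generate_survival_table(80, 1.0, seed = 77)
  res <- optimal_cutpoint_survival(df, n_perm = 199, seed = 3)
  expect_lte(res$p, res$p_adjusted)
})
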