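test_that("filter applies inclusive thresholds, residue, range and zero rule", {
  border <- make_psms(1, delta_mass = 15.99, score = 300,
                      delta_mod_score = 10, fdr_2d = 0.01)
  expect_identical(nrow(filter_psms(border)), 1L)      # thresholds inclusive

  cases <- list(
    list(score = 299.9),                # just below score
    list(delta_mod_score = 9.99),
    list(fdr_2d = 0.0101),
    list(residue = "K"),                # wrong residue
    list(delta_mass = 500.1),           # out of range
    list(delta_mass = 0)                # exact zero excluded
  )
  for (ch in cases) {
    p <- border
    p[[names(ch)]] <- ch[[1]]
    expect_identical(nrow(filter_psms(p)), 0L)
  }
  p0 <- border
  p0$delta_mass <- 0
  keep0 <- filter_criteria(exclude_zero = FALSE)
  expect_identical(nrow(filter_psms(p0, keep0)), 1L)
})

test_that("tightening any single criterion never grows the output", {
  set.seed(31)
  psms <- make_psms(400,
                    delta_mass = runif(400, -150, 500),
                    residue = sample(c("W", "K", "C"), 400, replace = TRUE),
                    score = runif(400, 0, 600),
                    delta_mod_score = runif(400, 0, 40),
                    fdr_2d = runif(400, 0, 0.05))
  base <- filter_criteria()
  n0 <- nrow(filter_psms(psms, base))
  tighter <- list(filter_criteria(min_score = 400),
                  filter_criteria(min_delta_mod_score = 20),
                  filter_criteria(max_fdr_2d = 0.005),
                  filter_criteria(delta_range = c(-50, 200)))
  for (cr in tighter) expect_lte(nrow(filter_psms(psms, cr)), n0)
  # output is a subset, order preserved
  out <- filter_psms(psms, base)
  expect_identical(out$spectrum_id,
                   psms$spectrum_id[psms$spectrum_id %in% out$spectrum_id])
})

test_that("windows partition deltas on half-open integer bins", {
  w <- window_deltas(c(15.2, 15.9, 16.1))
  expect_identical(names(w), c("15", "16"))
  expect_equal(w[["15"]], c(15.2, 15.9))
  expect_equal(w[["16"]], 16.1)
  expect_identical(length(window_deltas(numeric(0))), 0L)
  expect_identical(names(window_deltas(16.0)), "16")   # boundary goes right
  expect_identical(names(window_deltas(-72.9961)), "-73")

  set.seed(7)
  x <- runif(500, -150, 500)
  ws <- window_deltas(x)
  expect_identical(sum(lengths(ws)), 500L)             # exact partition
  expect_equal(sort(unlist(ws, use.names = FALSE)), sort(x))
})

test_that("fit_window recovers a planted peak against the mean oracle", {
  set.seed(41)
  planted <- rnorm(500, 15.9949, 0.002)
  noise <- runif(50, 15, 16)
  fit <- fit_window(c(planted, noise))
  expect_identical(nrow(fit), 1L)                      # one surviving cluster
  expect_lt(abs(fit$center - 15.9949), 0.005)
  # oracle: sample mean of the planted draws
  expect_lt(abs(fit$center - mean(planted)), 0.001)
  expect_gt(fit$r_squared, 0.9)
  expect_identical(fit_window(numeric(0)), fit_window(numeric(0)))
  expect_identical(nrow(fit_window(numeric(0))), 0L)
  expect_identical(nrow(fit_window(rnorm(5, 0.5, 0.01))), 0L)  # < min_support
})

test_that("BIC selects the planted component count (ground-truth oracle)", {
  # independent oracle: BIC of the ground-truth hard partition, computed
  # from closed-form Gaussian ML fits, must beat the 1-component BIC on
  # the same data when k_true = 2
  set.seed(43)
  comp1 <- rnorm(300, 3.9953, 0.003)
  comp2 <- rnorm(300, 3.60, 0.003)
  x <- c(comp1, comp2)
  loglik_partition <- function(groups) {
    sum(vapply(groups, function(g) {
      mu <- mean(g); s <- sqrt(mean((g - mu)^2))
      sum(dnorm(g, mu, s, log = TRUE)) + length(g) * log(length(g) / length(x))
    }, numeric(1)))
  }
  bic_k1 <- -2 * loglik_partition(list(x)) + 2 * log(length(x))
  bic_k2 <- -2 * loglik_partition(list(comp1, comp2)) + 5 * log(length(x))
  expect_lt(bic_k2, bic_k1)                            # truth is separable

  fit <- fit_window(x)
  expect_identical(nrow(fit), 2L)                      # BIC agrees with truth
  expect_lt(abs(sort(fit$center)[1] - 3.60), 0.005)
  expect_lt(abs(sort(fit$center)[2] - 3.9953), 0.005)
})

test_that("peak calling assigns every member exactly once and sorts centres", {
  peaks <- list(peak_spec(15.9949, 300), peak_spec(3.9953, 300),
                peak_spec(-72.9961, 300))
  psms <- filter_psms(generate_psm_table(peaks, cohort_spec(2, seed = 17),
                                         n_noise = 60))
  cl <- call_variant_peaks(psms, seed = 2)
  expect_identical(nrow(cl), 3L)
  expect_true(!is.unsorted(cl$center))
  truth <- sort(c(15.9949, 3.9953, -72.9961))
  expect_true(all(abs(cl$center - truth) < 0.005))

  asg <- attr(cl, "assignments")
  expect_identical(anyDuplicated(asg$spectrum_id), 0L) # one cluster per PSM
  expect_identical(sum(cl$n_psms), nrow(asg))
  expect_true(all(asg$spectrum_id %in% psms$spectrum_id))

  # determinism under a fixed seed
  cl2 <- call_variant_peaks(psms, seed = 2)
  expect_identical(cl[setdiff(names(cl), "members")],
                   cl2[setdiff(names(cl2), "members")])
})

test_that("pure uniform noise yields no called peaks", {
  # dense in-window background: the hard case for the goodness-of-fit and
  # background-width screens (20 seeded replicates, scaled down from 100)
  n_called <- vapply(1:20, function(s) {
    set.seed(s)
    psms <- make_psms(300, delta_mass = runif(300, 15, 16))
    psms$spectrum_id <- sprintf("N%04d", 1:300)
    nrow(call_variant_peaks(psms, seed = s))
  }, numeric(1))
  expect_gte(mean(n_called == 0), 0.95)
})

test_that("a peak on a window boundary is reunified by the merge step", {
  # documented behaviour: the truncated halves may fit imperfectly (one
  # side can fail the goodness-of-fit screen), but what is called is at
  # most 2 peaks, all within the merge tolerance of the true centre
  set.seed(47)
  x <- rnorm(600, 16.0005, 0.002)
  psms <- make_psms(600, delta_mass = x)
  psms$spectrum_id <- sprintf("S%04d", 1:600)
  cl <- call_variant_peaks(psms, seed = 3)
  expect_gte(nrow(cl), 1L)
  expect_lte(nrow(cl), 2L)
  expect_true(all(abs(cl$center - 16.0005) < 0.005))
})
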