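simple_series <- function() {
  expand.grid(subject = c("s1", "s2"), taxon = c("A", "B"),
              time = 1:5, stringsAsFactors = FALSE) |>
    transform(abundance = 0)
}

test_that("colonization times use an inclusive threshold", {
  se <- simple_series()
  se$abundance[se$subject == "s1" & se$taxon == "A" & se$time == 3] <- 10
  se$abundance[se$subject == "s1" & se$taxon == "A" & se$time == 4] <- 50
  se$abundance[se$subject == "s2" & se$taxon == "A" & se$time == 2] <- 9.99
  ev <- suppressWarnings(extract_colonization_times(se, 10))
  e1 <- ev[ev$subject == "s1" & ev$taxon == "A", ]
  expect_true(e1$detected)
  expect_equal(e1$time, 3)                      # boundary inclusive
  e2 <- ev[ev$subject == "s2" & ev$taxon == "A", ]
  expect_false(e2$detected)                     # never reaches threshold
  expect_true(is.na(e2$time))
  expect_warning(extract_colonization_times(se, 10), "no taxon")
  expect_error(extract_colonization_times(se[0, ], 10), "empty")
})

test_that("noise-free data from the regression equation is recovered
           exactly", {
  # forward-simulate the discrete model itself: 3 taxa, 1 antibiotic
  set.seed(42)
  M <- 3
  r_true <- c(0.4, 0.2, -0.1)
  a_true <- matrix(c(-1e-3, 2e-4, 0,
                     0, -1e-3, -3e-4,
                     5e-4, 0, -1e-3), 3, 3, byrow = TRUE)
  e_true <- c(-0.5, 0, -0.2)
  days <- 0:30
  rows <- list()
  for (subj in 1:4) {
    X <- matrix(0, length(days), M)
    X[1, ] <- runif(M, 50, 150)
    E <- as.numeric(days >= 5 & days < 8)
    for (l in seq_len(length(days) - 1)) {
      rate <- r_true + as.numeric(a_true %*% X[l, ]) + e_true * E[l]
      X[l + 1, ] <- X[l, ] * exp(rate)  # dt = 1
    }
    rows[[subj]] <- data.frame(
      subject = paste0("s", subj),
      taxon = rep(c("A", "B", "C"), each = length(days)),
      time = rep(days, M), abundance = as.numeric(X),
      abx = rep(E, M))
  }
  se <- do.call(rbind, rows)
  net <- fit_interaction_network(se, abx_cols = "abx", penalty = "ols")
  ord <- c("A", "B", "C")
  expect_equal(unname(net$alpha[ord, ord]), unname(a_true),
               tolerance = 1e-6)
  expect_equal(unname(net$r[ord]), r_true, tolerance = 1e-6)
  expect_equal(unname(net$epsilon[ord, "abx"]), e_true, tolerance = 1e-6)

  # an antibiotic that is never given is unidentifiable and exactly zero
  se$abx2 <- 0
  net2 <- fit_interaction_network(se, abx_cols = c("abx", "abx2"),
                                  penalty = "ols")
  expect_equal(unname(net2$epsilon[, "abx2"]), rep(0, 3))
  expect_true("abx2" %in% net2$unidentifiable)
})

test_that("normalization and the 0.1 threshold classify interactions", {
  set.seed(1)
  ch <- simulate_cohort(cohort_spec(n_subjects = 4, seed = 5))
  net <- fit_interaction_network(ch$series, seed = 5)
  off <- row(net$alpha) != col(net$alpha)
  expect_equal(max(net$normalized[off]), 1)
  expect_true(all(net$class[off][net$normalized[off] >= 0.1] == "strong"))
  expect_true(all(net$class[off][net$normalized[off] < 0.1] == "weak"))
  expect_identical(net$provenance$normalization, "max-abs off-diagonal")
})

test_that("predictability scores count with-or-after proportions", {
  ev <- data.frame(subject = c("s1", "s1"), taxon = c("F", "P"),
                   time = c(5, 2), detected = TRUE)
  sc <- predictability_scores(ev)
  expect_equal(sc$score[sc$focal == "F" & sc$partner == "P"], 1)
  expect_equal(sc$score[sc$focal == "P" & sc$partner == "F"], 0)

  # ties count for the focal ("with or after")
  ev$time <- c(3, 3)
  sc <- predictability_scores(ev)
  expect_equal(sc$score, c(1, 1))

  # undetected partner counts as focal-first; undetected focal drops the
  # subject from the denominator
  ev2 <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                    taxon = rep(c("F", "P"), 2),
                    time = c(5, 2, 4, NA),
                    detected = c(TRUE, TRUE, TRUE, FALSE))
  sc2 <- predictability_scores(ev2)
  expect_equal(sc2$score[sc2$focal == "F" & sc2$partner == "P"], 0.5)
  expect_equal(sc2$n_subjects[sc2$focal == "F"], 2L)
  expect_equal(sc2$n_subjects[sc2$focal == "P"], 1L)
})

test_that("score symmetry holds on synthetic cohorts", {
  ch <- simulate_cohort(cohort_spec(n_subjects = 6, seed = 9))
  ev <- extract_colonization_times(ch$series, 10)
  sc <- predictability_scores(ev)
  key <- paste(sc$focal, sc$partner)
  rev_score <- sc$score[match(paste(sc$partner, sc$focal), key)]
  both <- !is.na(rev_score)
  # focal-first in one direction implies with-or-after in the other;
  # ties are counted in both, so the sums are >= 1
  expect_true(all(sc$score[both] + rev_score[both] >= 1 - 1e-12))
})

test_that("the sign-flip permutation test behaves", {
  flat <- rep(0.5, 10)
  t0 <- test_mean_predictability(flat, n_perm = 500, seed = 2)
  expect_equal(t0$p_value, 1, tolerance = 0.01)

  hi <- rep(1, 4)
  t1 <- test_mean_predictability(hi, n_perm = 10000, seed = 2)
  # only the all-positive flip pattern reaches the observed mean of 1
  expect_lt(t1$p_value, 0.12)
  expect_gt(t1$p_value, 1 / 10001)
  expect_equal(t1$observed_mean, 1)

  # invariant to ordering, reproducible under the seed
  sc <- c(0.9, 0.7, 1, 0.6, 0.8)
  a <- test_mean_predictability(sc, n_perm = 2000, seed = 31)
  b <- test_mean_predictability(rev(sc), n_perm = 2000, seed = 31)
  expect_identical(a$p_value, b$p_value)
  expect_error(test_mean_predictability(0.7), "2 scores")
  expect_warning(test_mean_predictability(c(1, 1), n_perm = 50, seed = 1),
                 "coarse")
})

test_that("helpfulness regression recovers exact and null relations", {
  taxa <- c("A", "B", "C", "D")
  alpha <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  alpha[2:4, 1] <- 0.3    # A helps everyone
  alpha[c(1, 3, 4), 2] <- 0.1
  alpha[c(1, 2, 4), 3] <- -0.1
  helpful <- vapply(1:4, function(i) mean(alpha[-i, i]), 0)
  net <- structure(list(taxa = taxa, alpha = alpha,
                        class = matrix("weak", 4, 4)),
                   class = "interaction_network")
  ev <- data.frame(subject = "s1", taxon = taxa,
                   time = 10 - 2 * helpful, detected = TRUE)
  fit <- helpfulness_regression(net, ev)
  expect_equal(fit$slope, -2, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)

  # permuting helpfulness against times destroys the fit
  set.seed(8)
  ev_perm <- ev; ev_perm$time <- sample(ev$time)
  fit_p <- helpfulness_regression(net, ev_perm)
  expect_lt(fit_p$r_squared, 0.9)

  net0 <- net; net0$alpha[] <- 0.2; diag(net0$alpha) <- 0
  expect_error(helpfulness_regression(net0, ev), "zero variance")
})

test_that("the multimembership mixed model recovers a known slope", {
  set.seed(123)
  genera <- paste0("g", 1:8)
  pairs <- expand.grid(focal = genera, partner = genera,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$focal != pairs$partner, ]
  pairs$normalized <- runif(nrow(pairs), -1, 1)
  pairs$score <- 0.5 + 0.8 * pairs$normalized + rnorm(nrow(pairs), 0, 0.05)
  fit <- mixed_model_predictability(pairs, iterations = 4000, seed = 3)
  expect_gt(fit$ci[1], 0.8 - 0.15)
  expect_lt(fit$ci[2], 0.8 + 0.15)
  expect_true(fit$ci[1] <= fit$beta && fit$beta <= fit$ci[2])

  pairs$normalized <- 0.3
  expect_error(mixed_model_predictability(pairs), "unidentifiable")
})
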