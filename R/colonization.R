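#' Extract colonization times from longitudinal abundance data
#'
#' A taxon's colonization time in a subject is the first sampling time at
#' which its abundance reaches the detection threshold (boundary
#' inclusive). Taxa that never reach the threshold are returned with
#' `detected = FALSE`.
#'
#' @param series long-format data.frame with columns `subject`, `taxon`,
#'   `time`, `abundance` (additional columns are ignored here).
#' @param detection_threshold abundance at or above which a taxon counts
#'   as present.
#' @return data.frame with columns `subject`, `taxon`, `time` (NA when
#'   undetected), `detected`.
#' @export
extract_colonization_times <- function(series, detection_threshold = 10) {
  need <- c("subject", "taxon", "time", "abundance")
  if (!all(need %in% names(series)))
    stop("series must have columns subject, taxon, time, abundance",
         call. = FALSE)
  if (nrow(series) == 0L) stop("series is empty", call. = FALSE)
  out <- do.call(rbind, lapply(split(
    series, list(series$subject, series$taxon), drop = TRUE),
    function(d) {
      d <- d[order(d$time), ]
      hit <- which(d$abundance >= detection_threshold)
      data.frame(subject = d$subject[1], taxon = d$taxon[1],
                 time = if (length(hit)) d$time[hit[1]] else NA_real_,
                 detected = length(hit) > 0)
    }))
  rownames(out) <- NULL
  silent_subjects <- tapply(out$detected, out$subject, function(z) !any(z))
  if (any(silent_subjects))
    warning(sprintf("no taxon ever detected in subject(s): %s",
                    paste(names(silent_subjects)[silent_subjects],
                          collapse = ", ")))
  out
}

# Build per-window regression rows for one subject: response is the
# discrete log-derivative of each taxon, predictors are windowed
# geometric-mean abundances of all taxa plus antibiotic covariates.
windowed_design <- function(d, taxa, abx_cols, window) {
  d <- d[order(d$time), ]
  times <- sort(unique(d$time))
  n_block <- max(1L, floor(length(times) / window))
  if (n_block < 2L) return(NULL)
  block_of <- rep(seq_len(n_block), each = window,
                  length.out = length(times))
  wide <- sapply(taxa, function(tx) {
    v <- setNames(rep(0, length(times)), times)
    dd <- d[d$taxon == tx, ]
    v[as.character(dd$time)] <- dd$abundance
    v
  })
  # geometric mean per block (0 if the taxon is absent anywhere in it)
  gm <- function(x) if (any(x <= 0)) 0 else exp(mean(log(x)))
  Xb <- apply(wide, 2, function(col) tapply(col, block_of, gm))
  Xb <- matrix(Xb, nrow = n_block, dimnames = list(NULL, taxa))
  tmid <- tapply(times, block_of, mean)
  Eb <- NULL
  if (length(abx_cols) > 0) {
    e_wide <- sapply(abx_cols, function(cc) {
      v <- setNames(rep(0, length(times)), times)
      agg <- tapply(d[[cc]], d$time, max)
      v[names(agg)] <- agg
      v
    })
    Eb <- apply(e_wide, 2, function(col) tapply(col, block_of, mean))
    Eb <- matrix(Eb, nrow = n_block, dimnames = list(NULL, abx_cols))
  }
  list(X = Xb, E = Eb, tmid = as.numeric(tmid), n_block = n_block)
}

#' Fit a sparse interaction network from longitudinal data
#'
#' Gradient-matching regression of the discrete gLV equation: for each
#' taxon i the response is `Delta ln X_i(t_l) / Delta t_l` across
#' consecutive windows and the design holds the windowed geometric-mean
#' abundances of every taxon (including i itself, whose coefficient
#' absorbs self-regulation) plus antibiotic exposure covariates. The
#' default fit is lasso-based stability selection followed by an ordinary
#' least-squares refit on the stable support; plain `"lasso"`
#' (cross-validated) and `"ols"` (exact recovery on noise-free data) are
#' also available.
#'
#' @param series long-format data.frame: `subject`, `taxon`, `time`,
#'   `abundance`, plus zero or more antibiotic columns.
#' @param abx_cols character vector naming antibiotic covariate columns
#'   (default: every column beyond the four standard ones).
#' @param window number of consecutive samples aggregated into one
#'   regression window (default 1: consecutive-sample differences).
#' @param penalty `"stability"`, `"lasso"`, or `"ols"`.
#' @param n_subsamples,select_frac,select_threshold stability-selection
#'   controls: number of half-sized subsamples, their fraction of rows,
#'   and the selection frequency required to keep a coefficient.
#' @param stability_lambda which cross-validated penalty the subsample
#'   counting uses: `"min"` (default; keeps attenuated strong links) or
#'   `"1se"` (sparser, fewer false positives).
#' @param seed RNG seed for the subsampling / cross-validation.
#' @return object of class `interaction_network`: `taxa`, `r`, `alpha`
#'   (M x M, diagonal = self term), `epsilon`, `normalized` (off-diagonal
#'   magnitudes divided by their maximum), `class` ("weak"/"strong" at
#'   the 0.1 normalized threshold), `unidentifiable`, `provenance`.
#' @export
fit_interaction_network <- function(series, abx_cols = NULL, window = 1,
                                    penalty = c("stability", "lasso", "ols"),
                                    n_subsamples = 30, select_frac = 0.5,
                                    select_threshold = 0.6,
                                    stability_lambda = c("min", "1se"),
                                    seed = 1) {
  penalty <- match.arg(penalty)
  stability_lambda <- match.arg(stability_lambda)
  if (is.null(abx_cols))
    abx_cols <- setdiff(names(series),
                        c("subject", "taxon", "time", "abundance"))
  taxa <- sort(unique(series$taxon))
  M <- length(taxa)
  designs <- lapply(split(series, series$subject), windowed_design,
                    taxa = taxa, abx_cols = abx_cols, window = window)
  designs <- designs[!vapply(designs, is.null, logical(1))]
  if (length(designs) == 0L)
    stop("no subject has at least two windows", call. = FALSE)

  alpha <- matrix(0, M, M, dimnames = list(taxa, taxa))
  eps <- matrix(0, M, max(1, length(abx_cols)),
                dimnames = list(taxa, if (length(abx_cols)) abx_cols else
                  "none"))
  r_vec <- setNames(rep(NA_real_, M), taxa)
  unident <- character(0)
  excluded <- character(0)

  for (i in seq_len(M)) {
    rows_y <- numeric(0); rows_X <- NULL
    for (dz in designs) {
      xi <- dz$X[, i]
      for (l in seq_len(dz$n_block - 1)) {
        if (xi[l] <= 0 || xi[l + 1] <= 0) next
        dt <- dz$tmid[l + 1] - dz$tmid[l]
        y <- (log(xi[l + 1]) - log(xi[l])) / dt
        pred <- dz$X[l, ]
        if (!is.null(dz$E)) pred <- c(pred, dz$E[l, ])
        rows_y <- c(rows_y, y)
        rows_X <- rbind(rows_X, pred)
      }
    }
    if (length(rows_y) < 3) {
      excluded <- c(excluded, taxa[i])
      next
    }
    keep <- apply(rows_X, 2, function(col) var(col) > 0)
    if (any(!keep))
      unident <- unique(c(unident, colnames(rows_X)[!keep]))
    coefs <- setNames(rep(0, ncol(rows_X)), colnames(rows_X))
    Xk <- rows_X[, keep, drop = FALSE]
    fit_coef <- fit_sparse_row(rows_y, Xk, penalty, n_subsamples,
                               select_frac, select_threshold,
                               derive_seed(seed, i), stability_lambda)
    coefs[colnames(Xk)] <- fit_coef$beta
    r_vec[i] <- fit_coef$intercept
    alpha[i, ] <- coefs[taxa]
    if (length(abx_cols))
      eps[i, ] <- coefs[abx_cols]
  }
  if (length(excluded))
    warning(sprintf("taxa with no usable positive-abundance windows: %s",
                    paste(excluded, collapse = ", ")))

  off <- abs(alpha); diag(off) <- 0
  max_off <- max(off)
  normalized <- if (max_off > 0) off / max_off else off
  cls <- matrix("weak", M, M, dimnames = dimnames(alpha))
  cls[normalized >= 0.1] <- "strong"
  diag(cls) <- "self"
  structure(list(taxa = taxa, r = r_vec, alpha = alpha, epsilon = eps,
                 normalized = normalized, class = cls,
                 unidentifiable = unident, excluded = excluded,
                 provenance = list(penalty = penalty, window = window,
                                   seed = seed,
                                   normalization = "max-abs off-diagonal",
                                   strong_threshold = 0.1)),
            class = "interaction_network")
}

fit_sparse_row <- function(y, X, penalty, n_subsamples, select_frac,
                           select_threshold, seed,
                           stability_lambda = "min") {
  p <- ncol(X)
  ols <- function(yy, XX) {
    fit <- lm(yy ~ XX)
    b <- coef(fit)
    b[is.na(b)] <- 0
    list(intercept = b[1], beta = setNames(b[-1], colnames(XX)))
  }
  if (penalty == "ols" || p < 2 || length(y) <= p + 1) return(ols(y, X))
  set.seed(seed)
  if (penalty == "lasso") {
    cv <- glmnet::cv.glmnet(X, y, nfolds = min(10, max(3, length(y) %/% 5)))
    b <- as.numeric(coef(cv, s = "lambda.min"))
    return(list(intercept = b[1], beta = setNames(b[-1], colnames(X))))
  }
  # stability selection: cross-validate the penalty once on the full
  # data, then count how often each coefficient is selected across
  # subsamples at that penalty; OLS refit on the stable support
  n <- length(y)
  cv <- glmnet::cv.glmnet(X, y, nfolds = min(10, max(3, n %/% 5)))
  lam <- if (identical(stability_lambda, "1se")) cv$lambda.1se else
    cv$lambda.min
  sel <- matrix(0, n_subsamples, p)
  for (b in seq_len(n_subsamples)) {
    idx <- sample(n, min(n, max(p + 2, ceiling(select_frac * n))),
                  replace = FALSE)
    fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx])
    bb <- as.numeric(coef(fit, s = lam, exact = FALSE))[-1]
    sel[b, ] <- bb != 0
  }
  freq <- colMeans(sel)
  support <- which(freq >= select_threshold)
  if (length(support) == 0L) {
    fit0 <- lm(y ~ 1)
    return(list(intercept = coef(fit0)[1],
                beta = setNames(rep(0, p), colnames(X))))
  }
  refit <- ols(y, X[, support, drop = FALSE])
  beta <- setNames(rep(0, p), colnames(X))
  beta[support] <- refit$beta
  list(intercept = refit$intercept, beta = beta)
}

#' Pairwise colonization-order predictability scores
#'
#' For each ordered (focal, partner) pair, the proportion of subjects in
#' which the focal taxon first colonizes *with or after* the partner.
#' Subjects enter a pair's denominator when the focal is detected; a
#' partner that is never detected in such a subject counts as
#' focal-first (non-qualifying). Ties (same sampling time) qualify.
#'
#' @param events output of [extract_colonization_times()].
#' @return data.frame of class `pair_predictability`: `focal`, `partner`,
#'   `score`, `n_subjects`.
#' @export
predictability_scores <- function(events) {
  taxa <- sort(unique(events$taxon))
  res <- list()
  dropped <- 0L
  for (focal in taxa) for (partner in taxa) {
    if (focal == partner) next
    ef <- events[events$taxon == focal & events$detected, ]
    if (nrow(ef) == 0L) { dropped <- dropped + 1L; next }
    ep <- events[events$taxon == partner, ]
    ptime <- setNames(ep$time, ep$subject)
    pdet <- setNames(ep$detected, ep$subject)
    qual <- vapply(seq_len(nrow(ef)), function(k) {
      subj <- as.character(ef$subject[k])
      isTRUE(pdet[subj]) && ptime[subj] <= ef$time[k]
    }, logical(1))
    res[[paste(focal, partner)]] <- data.frame(
      focal = focal, partner = partner, score = mean(qual),
      n_subjects = nrow(ef))
  }
  if (dropped > 0L)
    warning(sprintf("%d ordered pairs had no qualifying subject", dropped))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("pair_predictability", class(out))
  out
}

#' Attach the focal-receives interaction to predictability scores
#'
#' @param scores output of [predictability_scores()].
#' @param network an `interaction_network`.
#' @return `scores` with columns `alpha` (raw effect of partner on
#'   focal), `normalized` (signed normalized magnitude) and
#'   `class` added.
#' @export
link_scores_to_network <- function(scores, network) {
  keep <- scores$focal %in% network$taxa & scores$partner %in% network$taxa
  scores <- scores[keep, , drop = FALSE]
  idx <- cbind(match(scores$focal, network$taxa),
               match(scores$partner, network$taxa))
  scores$alpha <- network$alpha[idx]
  scores$normalized <- sign(network$alpha[idx]) * network$normalized[idx]
  scores$class <- network$class[idx]
  scores
}

#' One-sample permutation test of mean predictability
#'
#' Tests whether the mean score exceeds `null_value` by randomly
#' reflecting each score about 0.5 (`score -> 1 - score`), the standard
#' sign-flip construction for a one-sample test of symmetry.
#' `p = (1 + #{perm mean >= observed}) / (1 + n_perm)`.
#'
#' @param scores numeric vector of scores, or a `pair_predictability`
#'   data.frame (its `score` column is used).
#' @param null_value the null mean (0.5).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `observed_mean`, `p_value`, `n_perm`, `n_scores`.
#' @export
test_mean_predictability <- function(scores, null_value = 0.5,
                                     n_perm = 10000, seed = 1) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) < 2) stop("need at least 2 scores", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  obs <- mean(scores)
  centered <- scores - null_value
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * length(scores), replace = TRUE),
                  nrow = n_perm)
  perm_means <- null_value + as.numeric(flips %*% centered) / length(scores)
  p <- (1 + sum(perm_means >= obs)) / (1 + n_perm)
  list(observed_mean = obs, p_value = p, n_perm = n_perm,
       n_scores = length(scores))
}

#' Helpfulness against colonization time
#'
#' A taxon's helpfulness is its mean outgoing interaction (mean of
#' `alpha[j, i]` over partners j): how much it benefits the rest of the
#' community on average. Ordinary least squares of mean colonization time
#' on helpfulness tests whether helpful taxa colonize earlier (negative
#' slope).
#'
#' @param network an `interaction_network`.
#' @param events output of [extract_colonization_times()].
#' @return list of class `model_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`, `data`.
#' @export
helpfulness_regression <- function(network, events) {
  M <- length(network$taxa)
  helpful <- vapply(seq_len(M), function(i)
    mean(network$alpha[-i, i]), 0)
  mean_time <- vapply(network$taxa, function(tx) {
    e <- events[events$taxon == tx & events$detected, ]
    if (nrow(e) == 0) NA_real_ else mean(e$time)
  }, 0)
  ok <- !is.na(mean_time)
  if (sum(ok) < 3)
    stop("need >= 3 taxa with colonization times and interactions",
         call. = FALSE)
  if (var(helpful[ok]) == 0)
    stop("helpfulness has zero variance; slope unidentifiable",
         call. = FALSE)
  fit <- lm(mean_time[ok] ~ helpful[ok])
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = sum(ok),
                 data = data.frame(taxon = network$taxa[ok],
                                   helpfulness = helpful[ok],
                                   mean_time = mean_time[ok])),
            class = "model_fit")
}

#' Multimembership Bayesian mixed model of predictability
#'
#' Fits `score_fp = b0 + b1 * strength_fp + u_f + u_p + e_fp` by Gibbs
#' sampling, where a single genus-level random effect `u` enters through
#' both the focal and the partner role of each pair (multimembership).
#' Priors: diffuse normal on the fixed effects, inverse-gamma
#' (0.001, 0.001) on both variance components.
#'
#' @param scores a linked score table from [link_scores_to_network()];
#'   must carry columns `score`, `focal`, `partner` and the predictor.
#' @param predictor column used as interaction strength
#'   (default `"normalized"`, the signed normalized magnitude).
#' @param iterations MCMC iterations (default 10000).
#' @param burnin discarded initial iterations (default `iterations / 5`).
#' @param seed RNG seed.
#' @param ess_warn warn when the slope's effective sample size falls
#'   below this.
#' @return list of class `model_fit`: `beta` (posterior mean slope),
#'   `ci` (95% credible interval), `intercept`, `re_variance`,
#'   `resid_variance`, `ess`, `iterations`, `draws` (slope chain).
#' @export
mixed_model_predictability <- function(scores, predictor = "normalized",
                                       iterations = 10000, burnin = NULL,
                                       seed = 1, ess_warn = 200) {
  y <- scores$score
  x <- scores[[predictor]]
  if (is.null(x)) stop("predictor column not found", call. = FALSE)
  if (var(x) == 0)
    stop("interaction strength identical for all pairs; slope unidentifiable",
         call. = FALSE)
  if (is.null(burnin)) burnin <- iterations %/% 5
  genera <- sort(unique(c(scores$focal, scores$partner)))
  G <- length(genera)
  n <- length(y)
  Z <- matrix(0, n, G, dimnames = list(NULL, genera))
  Z[cbind(seq_len(n), match(scores$focal, genera))] <- 1
  Z[cbind(seq_len(n), match(scores$partner, genera))] <-
    Z[cbind(seq_len(n), match(scores$partner, genera))] + 1
  X <- cbind(1, x)

  set.seed(seed)
  b <- c(mean(y), 0)
  u <- rep(0, G)
  s2e <- var(y)
  s2u <- s2e / 2
  a0 <- 0.001; b0 <- 0.001  # inverse-gamma shape/rate
  keep <- iterations - burnin
  chain_b <- matrix(NA_real_, keep, 2)
  chain_v <- matrix(NA_real_, keep, 2)
  XtX <- crossprod(X)
  prior_prec_b <- diag(1e-8, 2)

  for (it in seq_len(iterations)) {
    # fixed effects | rest
    resid_u <- y - as.numeric(Z %*% u)
    Vb <- solve(XtX / s2e + prior_prec_b)
    mb <- Vb %*% (crossprod(X, resid_u) / s2e)
    b <- as.numeric(mb + t(chol(Vb)) %*% rnorm(2))
    # random effects | rest (joint multivariate normal)
    resid_b <- y - as.numeric(X %*% b)
    Vu <- solve(crossprod(Z) / s2e + diag(1 / s2u, G))
    mu <- Vu %*% (crossprod(Z, resid_b) / s2e)
    u <- as.numeric(mu + t(chol(Vu)) %*% rnorm(G))
    # variances | rest
    e <- y - as.numeric(X %*% b) - as.numeric(Z %*% u)
    s2e <- 1 / rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    s2u <- 1 / rgamma(1, a0 + G / 2, b0 + sum(u^2) / 2)
    if (it > burnin) {
      chain_b[it - burnin, ] <- b
      chain_v[it - burnin, ] <- c(s2u, s2e)
    }
  }
  slope <- chain_b[, 2]
  ess <- ess_estimate(slope)
  if (ess < ess_warn)
    warning(sprintf("effective sample size of slope is %.0f (< %d)",
                    ess, ess_warn))
  structure(list(beta = mean(slope),
                 ci = unname(quantile(slope, c(0.025, 0.975))),
                 intercept = mean(chain_b[, 1]),
                 re_variance = mean(chain_v[, 1]),
                 resid_variance = mean(chain_v[, 2]),
                 ess = ess, iterations = iterations, burnin = burnin,
                 draws = slope),
            class = "model_fit")
}

# Initial-positive-sequence effective sample size.
ess_estimate <- function(x) {
  n <- length(x)
  ac <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] <= 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' @export
print.model_fit <- function(x, ...) {
  if (!is.null(x$beta)) {
    cat(sprintf("model_fit: beta = %.3f, 95%% CI [%.3f, %.3f], ESS %.0f\n",
                x$beta, x$ci[1], x$ci[2], x$ess))
  } else {
    cat(sprintf("model_fit: slope = %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
                x$slope, x$r_squared, x$p_value, x$n))
  }
  invisible(x)
}
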