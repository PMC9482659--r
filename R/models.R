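#' Available SDM algorithms
#'
#' Five algorithm families sharing one fit/predict contract, chosen to keep
#' the ensemble heterogeneous at desk scale:
#' * `"sre"` — surface range envelope: the (2.5, 97.5) percentile box of the
#'   presence climate per layer; 1 inside the box, 0 outside.
#' * `"glm"` — ridge-penalized logistic regression with linear + quadratic
#'   features (a GLM/GAM-style smooth additive response).
#' * `"cta"` — a classification/regression tree with a depth cap.
#' * `"rf"` — a probability random forest (bagged trees with feature
#'   subsampling).
#' * `"maxlike"` — an exponential-family density-ratio model: Gaussian
#'   densities with regularized covariance fitted to presence and background
#'   climates; the log density ratio (a linear + quadratic form) is mapped
#'   through the logistic function.
#'
#' @return character vector of algorithm ids.
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom rpart rpart rpart.control
#' @export
sdm_algorithms <- function() c("sre", "glm", "cta", "rf", "maxlike")

# training design matrix + response from a training_set
training_frame <- function(train, stack, kept_layers) {
  cells <- c(train$presence_cells, train$absence_cells)
  X <- env_at(stack, cells, kept_layers)
  y <- rep(c(1L, 0L), c(length(train$presence_cells),
                        length(train$absence_cells)))
  w <- rep(c(train$w_presence, train$w_absence),
           c(length(train$presence_cells), length(train$absence_cells)))
  list(X = X, y = y, w = w)
}

#' Fit one SDM algorithm
#'
#' Fits `algorithm_id` on the training set's presence/pseudo-absence cells
#' using the kept predictor layers. Predictors are standardized with
#' training means/sds, frozen into the fit and re-applied at prediction time
#' (so projections onto future stacks use the calibration scaling). All fits
#' are deterministic given `seed`.
#'
#' @param train a `training_set`.
#' @param stack the calibration [climate_stack()].
#' @param kept_layers predictor layer names.
#' @param algorithm_id one of [sdm_algorithms()].
#' @param seed integer seed (used by the stochastic learners).
#' @return an `sdm_fit`; predict with [predict_sdm()].
#' @export
fit_algorithm <- function(train, stack, kept_layers, algorithm_id,
                          seed = 1L) {
  stopifnot(inherits(train, "training_set"))
  algorithm_id <- match.arg(algorithm_id, sdm_algorithms())
  if (length(train$presence_cells) < 2L || length(train$absence_cells) < 2L)
    stop("degenerate training set: need >= 2 presences and >= 2 absences")
  tf <- training_frame(train, stack, kept_layers)
  center <- colMeans(tf$X)
  scale <- apply(tf$X, 2, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(tf$X, 2, center, "-"), 2, scale, "/")
  model <- switch(
    algorithm_id,
    sre = fit_sre(Z, tf$y),
    glm = fit_glmnet(Z, tf$y, tf$w, seed),
    cta = fit_cta(Z, tf$y, tf$w, seed),
    rf = fit_rf(Z, tf$y, tf$w, seed),
    maxlike = fit_maxlike(Z, tf$y, tf$w))
  structure(
    list(algorithm_id = algorithm_id, kept_layers = kept_layers,
         center = center, scale = scale, model = model, seed = seed),
    class = "sdm_fit")
}

fit_sre <- function(Z, y, q = c(0.025, 0.975)) {
  P <- Z[y == 1L, , drop = FALSE]
  list(type = "sre",
       lo = apply(P, 2, stats::quantile, probs = q[1], names = FALSE),
       hi = apply(P, 2, stats::quantile, probs = q[2], names = FALSE))
}

quad_features <- function(Z) cbind(Z, Z^2)

fit_glmnet <- function(Z, y, w, seed) {
  X <- quad_features(Z)
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        weights = w, alpha = 0, lambda = 0.01,
                        standardize = FALSE)
  list(type = "glm", fit = fit)
}

fit_cta <- function(Z, y, w, seed) {
  df <- data.frame(y = y, Z)
  fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = 8, cp = 0.001, minsplit = 10, xval = 0))
  list(type = "cta", fit = fit)
}

fit_rf <- function(Z, y, w, seed) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), Z)
  fit <- ranger::ranger(y ~ ., data = df, probability = TRUE,
                        num.trees = 100,
                        mtry = max(1L, floor(sqrt(ncol(Z)))),
                        case.weights = w, seed = as.integer(seed),
                        num.threads = 1)
  list(type = "rf", fit = fit)
}

# Gaussian density ratio: weighted mean/cov of presence vs background
# climates with ridge-regularized covariance; score = log density ratio
# mapped through plogis. exp(quadratic form) = exponential-family model with
# linear + quadratic features.
fit_maxlike <- function(Z, y, w, shrink = 0.1) {
  mom <- function(rows) {
    M <- Z[rows, , drop = FALSE]
    mu <- colMeans(M)
    S <- stats::cov(M)
    S <- (1 - shrink) * S + shrink * diag(mean(diag(S)), ncol(Z))
    list(mu = mu, S = S)
  }
  list(type = "maxlike", pres = mom(y == 1L), bg = mom(y == 0L))
}

log_dmvnorm <- function(Z, mu, S) {
  ch <- chol(S)
  d <- sweep(Z, 2, mu, "-")
  q <- rowSums((d %*% chol2inv(ch)) * d)
  -0.5 * q - sum(log(diag(ch))) - 0.5 * ncol(Z) * log(2 * pi)
}

#' Predict suitability from a fitted SDM
#'
#' @param fit an `sdm_fit`.
#' @param stack a [climate_stack()] supplying the fit's layers (an error
#'   names any missing layer).
#' @param cells integer cell indices to predict at.
#' @return numeric suitability in \[0, 1\], one value per cell.
#' @export
predict_sdm <- function(fit, stack, cells) {
  stopifnot(inherits(fit, "sdm_fit"))
  X <- env_at(stack, cells, fit$kept_layers)
  predict_sdm_env(fit, X)
}

# prediction on a raw environment matrix (columns = kept_layers)
predict_sdm_env <- function(fit, X) {
  Z <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  m <- fit$model
  p <- switch(
    m$type,
    sre = {
      inside <- rep(TRUE, nrow(Z))
      for (j in seq_len(ncol(Z)))
        inside <- inside & Z[, j] >= m$lo[j] & Z[, j] <= m$hi[j]
      as.numeric(inside)
    },
    glm = as.numeric(stats::predict(m$fit, quad_features(Z),
                                    type = "response")),
    cta = as.numeric(stats::predict(m$fit, data.frame(Z))),
    rf = {
      pr <- stats::predict(m$fit, data.frame(Z), num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    maxlike = {
      s <- log_dmvnorm(Z, m$pres$mu, m$pres$S) -
           log_dmvnorm(Z, m$bg$mu, m$bg$S)
      stats::plogis(s)
    })
  pmin(1, pmax(0, p))
}

#' Evaluate presence/absence scores with AUC and max-TSS
#'
#' AUC is the pairwise concordance probability (ties counted 1/2),
#' equivalently the normalized Mann-Whitney statistic. TSS = sensitivity +
#' specificity - 1 is maximized over the fixed threshold grid
#' 0.00, 0.01, ..., 1.00 with a cell scored presence when its suitability is
#' >= the threshold; TSS ties are broken by the lowest threshold.
#'
#' @param pres_scores,abs_scores numeric score vectors (both non-empty).
#' @return an `evaluation_result`: `auc`, `tss`, `tss_threshold`,
#'   `sensitivity`, `specificity` (the last two at `tss_threshold`).
#' @export
evaluate <- function(pres_scores, abs_scores) {
  stopifnot(length(pres_scores) > 0, length(abs_scores) > 0)
  np <- length(pres_scores); na <- length(abs_scores)
  r <- rank(c(pres_scores, abs_scores))  # midranks: ties count 1/2
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
  thr <- (0:100) / 100
  sens <- vapply(thr, function(t) mean(pres_scores >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(abs_scores < t), numeric(1))
  tss <- sens + spec - 1
  best <- which.max(tss)  # which.max returns the first (lowest) maximizer
  structure(
    list(auc = auc, tss = tss[best], tss_threshold = thr[best],
         sensitivity = sens[best], specificity = spec[best]),
    class = "evaluation_result")
}

#' Permutation variable contributions
#'
#' Contribution of each predictor = mean drop in training AUC when that
#' predictor's values are randomly permuted across training records
#' (`n_perm` permutations, seeded). Returned in descending order; the first
#' two rows are the "top-2" variables reported per species.
#'
#' @param fit an `sdm_fit`.
#' @param train the `training_set` the fit was trained on.
#' @param stack the calibration [climate_stack()].
#' @param n_perm permutations per layer (default 5).
#' @param seed integer seed.
#' @return data.frame `layer`, `contribution`, sorted descending.
#' @export
variable_contributions <- function(fit, train, stack, n_perm = 5L, seed = 1L) {
  tf <- training_frame(train, stack, fit$kept_layers)
  base_auc <- evaluate(predict_sdm_env(fit, tf$X)[tf$y == 1L],
                       predict_sdm_env(fit, tf$X)[tf$y == 0L])$auc
  set.seed(as.integer(seed))
  drops <- vapply(seq_along(fit$kept_layers), function(j) {
    mean(vapply(seq_len(n_perm), function(k) {
      Xp <- tf$X
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      p <- predict_sdm_env(fit, Xp)
      base_auc - evaluate(p[tf$y == 1L], p[tf$y == 0L])$auc
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(layer = fit$kept_layers, contribution = drops)
  out[order(-out$contribution), , drop = FALSE]
}
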