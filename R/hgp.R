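# Hierarchical Gaussian process regression for recovery trajectories.
#
# Two-level model: a shared population process plus an independent
# per-subject deviation process plus i.i.d. Gaussian noise, realised as an
# additive kernel
#
#   K(i, j) = k_pop(x_i, x_j) + [subj_i == subj_j] k_subj(x_i, x_j)
#             + [i == j] sigma_n^2
#
# with squared-exponential kernels (per-dimension length-scales) at both
# levels and a fitted constant mean. Hyperparameters are chosen by
# multi-start gradient ascent on the log marginal likelihood with analytic
# gradients. Inputs are time in days post-operation (and, for the outcome
# maps, volume per unit BMI); outcomes are volume/BMI, MRC grade, or SPONEA
# on the 11-point decile scale.

sq_dists <- function(a, b = a) {
  # per-dimension squared distances, list of length d
  lapply(seq_len(ncol(a)), function(k) outer(a[, k], b[, k], "-")^2)
}

se_kernel <- function(d2_list, var, ls) {
  expo <- 0
  for (k in seq_along(d2_list)) expo <- expo + d2_list[[k]] / ls[k]^2
  var * exp(-0.5 * expo)
}

chol_jitter <- function(K) {
  scale <- mean(diag(K))
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4) * max(scale, 1)) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is not positive definite")
}

unpack_params <- function(p, d, two_level) {
  i <- 1
  out <- list(var_pop = exp(p[i])); i <- i + 1
  out$ls_pop <- exp(p[i:(i + d - 1)]); i <- i + d
  if (two_level) {
    out$var_subj <- exp(p[i]); i <- i + 1
    out$ls_subj <- exp(p[i:(i + d - 1)]); i <- i + d
  } else {
    out$var_subj <- 0
    out$ls_subj <- rep(1, d)
  }
  out$var_noise <- exp(p[i]); i <- i + 1
  out$mean <- p[i]
  out
}

hgp_neg_lml <- function(p, d2, same_subj, y, d, two_level, grad = FALSE) {
  th <- unpack_params(p, d, two_level)
  n <- length(y)
  Kpop <- se_kernel(d2, th$var_pop, th$ls_pop)
  Ksub <- if (two_level) se_kernel(d2, th$var_subj, th$ls_subj) * same_subj else
    matrix(0, n, n)
  K <- Kpop + Ksub + diag(th$var_noise, n)
  L <- chol_jitter(K)
  r <- y - th$mean
  alpha <- backsolve(L, forwardsolve(t(L), r))
  nll <- 0.5 * sum(r * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!grad) return(nll)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv # dLML/dtheta = 0.5 sum(W * dK)
  g <- numeric(length(p))
  i <- 1
  g[i] <- 0.5 * sum(W * Kpop); i <- i + 1
  for (k in seq_len(d)) {
    g[i] <- 0.5 * sum(W * (Kpop * d2[[k]] / th$ls_pop[k]^2)); i <- i + 1
  }
  if (two_level) {
    g[i] <- 0.5 * sum(W * Ksub); i <- i + 1
    for (k in seq_len(d)) {
      g[i] <- 0.5 * sum(W * (Ksub * d2[[k]] / th$ls_subj[k]^2)); i <- i + 1
    }
  }
  g[i] <- 0.5 * sum(diag(W)) * th$var_noise; i <- i + 1
  g[i] <- sum(alpha)
  list(value = nll, gradient = -g)
}

#' Fit a hierarchical Gaussian process
#'
#' Core fitting routine behind [fit_volume_hgp()] and [fit_outcome_map()].
#' With a single subject the subject-level process is unidentifiable and is
#' pinned to zero variance, reducing the model to a standard GP.
#'
#' @param x Numeric matrix (or vector) of inputs, one row per observation.
#' @param y Numeric outcome vector.
#' @param subject Subject identifiers (coerced to factor).
#' @param n_starts Number of optimisation restarts (default 3; the first
#'   start is data-driven, the rest rescale the initial length-scales).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return An object of class `hgp_model`.
#' @export
hgp_fit <- function(x, y, subject, n_starts = 3L, maxit = 100L) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n || length(subject) != n) {
    stop_input("x, y and subject must have matching lengths")
  }
  if (n < 3L) stop_input("at least 3 observations required")
  if (any(apply(X, 2, function(col) diff(range(col))) == 0)) {
    stop_input("degenerate input: an input dimension is constant")
  }
  subject <- factor(subject)
  two_level <- nlevels(subject) >= 2L
  d <- ncol(X)
  d2 <- sq_dists(X)
  same_subj <- outer(as.character(subject), as.character(subject), "==") * 1

  var_y <- stats::var(y)
  if (var_y == 0) var_y <- 1e-6
  ranges <- apply(X, 2, function(col) diff(range(col)))
  base_ls <- ranges / 3
  ls_scales <- c(1, 1 / 3, 3, 1 / 9, 9)[seq_len(n_starts)]

  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- c(log(0.5 * var_y), log(base_ls * ls_scales[s]))
    if (two_level) p0 <- c(p0, log(0.25 * var_y), log(base_ls * ls_scales[s]))
    p0 <- c(p0, log(0.1 * var_y), mean(y))
    n_par <- length(p0)
    lower <- c(rep(log(1e-6 * var_y), 1), log(ranges * 1e-3))
    upper <- c(rep(log(1e3 * var_y), 1), log(ranges * 1e2))
    if (two_level) {
      lower <- c(lower, log(1e-6 * var_y), log(ranges * 1e-3))
      upper <- c(upper, log(1e3 * var_y), log(ranges * 1e2))
    }
    lower <- c(lower, log(1e-6 * var_y), mean(y) - 10 * sqrt(var_y))
    upper <- c(upper, log(1e3 * var_y), mean(y) + 10 * sqrt(var_y))
    fit <- tryCatch(
      stats::optim(
        p0,
        fn = function(p) hgp_neg_lml(p, d2, same_subj, y, d, two_level),
        gr = function(p) hgp_neg_lml(p, d2, same_subj, y, d, two_level,
                                     grad = TRUE)$gradient,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = maxit)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("hyperparameter optimisation failed on all starts")
  th <- unpack_params(best$par, d, two_level)
  make_hgp_model(th, X, y, subject, two_level, log_marginal = -best$value)
}

# assemble a model object (posterior cache included) from fixed
# hyperparameters; also the re-instantiation path used by hgp_read()
make_hgp_model <- function(params, X, y, subject, two_level,
                           log_marginal = NA_real_, outcome = NULL) {
  X <- as.matrix(X)
  subject <- factor(subject)
  n <- length(y)
  d2 <- sq_dists(X)
  same_subj <- outer(as.character(subject), as.character(subject), "==") * 1
  Kpop <- se_kernel(d2, params$var_pop, params$ls_pop)
  Ksub <- if (two_level) se_kernel(d2, params$var_subj, params$ls_subj) * same_subj else
    matrix(0, n, n)
  L <- chol_jitter(Kpop + Ksub + diag(params$var_noise, n))
  alpha <- backsolve(L, forwardsolve(t(L), y - params$mean))
  structure(
    list(X = X, y = y, subject = subject, d = ncol(X), params = params,
         two_level = two_level, L = L, alpha = alpha,
         log_marginal = log_marginal, outcome = outcome,
         input_names = colnames(X)),
    class = "hgp_model"
  )
}

#' @export
print.hgp_model <- function(x, ...) {
  p <- x$params
  cat("Hierarchical Gaussian process model\n")
  cat(sprintf("  %d observations, %d subject(s), %d input dim(s)\n",
              length(x$y), nlevels(x$subject), x$d))
  cat(sprintf("  population: variance %.3g, length-scale(s) %s\n",
              p$var_pop, paste(signif(p$ls_pop, 3), collapse = ", ")))
  if (x$two_level) {
    cat(sprintf("  subject:    variance %.3g, length-scale(s) %s\n",
                p$var_subj, paste(signif(p$ls_subj, 3), collapse = ", ")))
  }
  cat(sprintf("  noise variance %.3g, mean %.3g\n", p$var_noise, p$mean))
  cat(sprintf("  log marginal likelihood %.3f\n", x$log_marginal))
  invisible(x)
}

#' Posterior predictions from a fitted HGP
#'
#' Known subjects use their own deviation process; unknown subjects (or
#' `subject = NULL`) are predicted from the population process with the
#' subject-level variance added to the predictive variance;
#' `level = "population"` drops the subject-level variance entirely.
#'
#' @param model A fitted [hgp_fit()] model.
#' @param x New inputs (matrix or vector, same dimensionality as training).
#' @param subject Subject id per row (`NULL` = new subject).
#' @param level `"subject"` (default) or `"population"`.
#' @param include_noise Add the observation-noise variance to the
#'   predictive variance (default `TRUE`; required when scoring held-out
#'   observations).
#' @param y_actual Optional held-out observations; when given, per-point
#'   Gaussian predictive log densities are returned.
#' @return Data frame with `mean`, `variance` and optionally `log_lik`.
#' @export
hgp_predict <- function(model, x, subject = NULL,
                        level = c("subject", "population"),
                        include_noise = TRUE, y_actual = NULL) {
  level <- match.arg(level)
  Xs <- as.matrix(x)
  if (ncol(Xs) != model$d) {
    if (nrow(Xs) == model$d && ncol(Xs) == 1L) Xs <- t(Xs) else
      if (model$d == 1L) Xs <- matrix(as.numeric(x), ncol = 1) else
        stop_input("x has the wrong number of input dimensions")
  }
  m <- nrow(Xs)
  th <- model$params
  d2x <- sq_dists(model$X, Xs)
  Kx <- se_kernel(d2x, th$var_pop, th$ls_pop)
  if (model$two_level && !is.null(subject) && level == "subject") {
    subject <- rep_len(as.character(subject), m)
    same <- outer(as.character(model$subject), subject, "==") * 1
    Kx <- Kx + se_kernel(d2x, th$var_subj, th$ls_subj) * same
  }
  prior_var <- th$var_pop +
    if (level == "subject" && model$two_level) th$var_subj else 0
  mu <- th$mean + drop(crossprod(Kx, model$alpha))
  V <- forwardsolve(t(model$L), Kx)
  var <- pmax(prior_var - colSums(V^2), 1e-12)
  if (include_noise) var <- var + th$var_noise
  out <- data.frame(mean = mu, variance = var)
  if (!is.null(y_actual)) {
    out$log_lik <- stats::dnorm(y_actual, mu, sqrt(var), log = TRUE)
  }
  out
}

#' Fit the volume-recovery HGP
#'
#' Models volume per unit BMI as a function of days post-operation with a
#' population process shared across patients and per-patient deviation
#' processes. Pre-operative visits enter with negative day values.
#'
#' @param table Data frame with columns `subject`, `day`,
#'   `volume_per_bmi` (e.g. from [generate_cohort()]).
#' @param ... Passed to [hgp_fit()].
#' @return An `hgp_model`.
#' @export
fit_volume_hgp <- function(table, ...) {
  need <- c("subject", "day", "volume_per_bmi")
  if (!all(need %in% names(table))) {
    stop_input("table must have columns ", paste(need, collapse = ", "))
  }
  X <- matrix(table$day, ncol = 1, dimnames = list(NULL, "day"))
  model <- hgp_fit(X, table$volume_per_bmi, table$subject, ...)
  model$outcome <- "volume_per_bmi"
  model
}

#' Predict volume per unit BMI at given days
#'
#' @param model Model from [fit_volume_hgp()].
#' @param day Days post-operation.
#' @param subject Subject id (`NULL` = population-level / new subject).
#' @param ... Passed to [hgp_predict()].
#' @return Data frame with `day`, `mean`, `variance`.
#' @export
predict_volume <- function(model, day, subject = NULL, ...) {
  out <- hgp_predict(model, matrix(day, ncol = 1), subject = subject, ...)
  cbind(day = day, out)
}

#' Fit an outcome map from (day, volume/BMI) to MRC grade or SPONEA
#'
#' The clinical outcome is treated as a continuous regression target over
#' the 2-D input (days post-op, volume per unit BMI). SPONEA is modelled on
#' the 11-point decile scale (score / 10) so that "one point" is one decile;
#' MRC predictions are additionally reported rounded to the nearest integer
#' grade and clipped to \[0, 5\].
#'
#' @param table Data frame with columns `subject`, `day`, `volume_per_bmi`
#'   and the outcome column (`mrc` or `sponea`).
#' @param outcome `"mrc"` or `"sponea"`.
#' @param ... Passed to [hgp_fit()].
#' @return An `hgp_model` carrying the outcome metadata.
#' @export
fit_outcome_map <- function(table, outcome = c("mrc", "sponea"), ...) {
  outcome <- match.arg(outcome)
  need <- c("subject", "day", "volume_per_bmi", outcome)
  if (!all(need %in% names(table))) {
    stop_input("table must have columns ", paste(need, collapse = ", "))
  }
  y <- table[[outcome]]
  if (outcome == "sponea") y <- y / 10 # decile scale
  X <- cbind(day = table$day, volume_per_bmi = table$volume_per_bmi)
  model <- hgp_fit(X, y, table$subject, ...)
  model$outcome <- outcome
  model
}

#' Predict a clinical outcome from (day, volume/BMI)
#'
#' @param model Model from [fit_outcome_map()].
#' @param day,volume_per_bmi New inputs.
#' @param subject Subject id (`NULL` = new subject).
#' @param ... Passed to [hgp_predict()].
#' @return Data frame with the latent `mean` and `variance`; for MRC also
#'   `grade` (rounded, clipped to 0-5), for SPONEA also `sponea`
#'   (percentage scale).
#' @export
predict_outcome <- function(model, day, volume_per_bmi, subject = NULL, ...) {
  out <- hgp_predict(model, cbind(day = day, volume_per_bmi = volume_per_bmi),
                     subject = subject, ...)
  if (identical(model$outcome, "mrc")) {
    out$grade <- pmin(pmax(round(out$mean), 0), 5)
  } else if (identical(model$outcome, "sponea")) {
    out$sponea <- pmin(pmax(10 * round(out$mean), 0), 100)
  }
  out
}

#' Cross-validated evaluation of an HGP analysis
#'
#' Refits the model on each training fold and scores the held-out visits:
#' leave-one-subject-out (held-out subjects are predicted as new subjects
#' from the population process) or leave-one-visit-out. MAE is reported on
#' the outcome's native scale (rounded grades for MRC, decile points for
#' SPONEA, mL/BMI for volume); the mean predictive log density is computed
#' under the Gaussian posterior including noise.
#'
#' @param table Cohort table (see [fit_volume_hgp()] / [fit_outcome_map()]).
#' @param outcome `"volume"`, `"mrc"` or `"sponea"`.
#' @param scheme `"loso"` (default) or `"lovo"`.
#' @param ... Passed to [hgp_fit()].
#' @return An `hgp_evaluation` list with `mae`, `mean_log_likelihood`,
#'   `n_heldout`, `scheme` and the per-point `predictions` table.
#' @export
evaluate_hgp <- function(table, outcome = c("volume", "mrc", "sponea"),
                         scheme = c("loso", "lovo"), ...) {
  outcome <- match.arg(outcome)
  scheme <- match.arg(scheme)
  if (scheme == "loso" && length(unique(table$subject)) < 2L) {
    stop_input("leave-one-subject-out requires at least 2 subjects")
  }
  folds <- if (scheme == "loso") {
    split(seq_len(nrow(table)), table$subject)
  } else {
    as.list(seq_len(nrow(table)))
  }
  fit_fun <- function(tab) {
    if (outcome == "volume") fit_volume_hgp(tab, ...) else
      fit_outcome_map(tab, outcome, ...)
  }
  preds <- lapply(folds, function(idx) {
    train <- table[-idx, , drop = FALSE]
    test <- table[idx, , drop = FALSE]
    model <- fit_fun(train)
    y_true <- switch(outcome,
      volume = test$volume_per_bmi,
      mrc = test$mrc,
      sponea = test$sponea / 10
    )
    Xs <- if (outcome == "volume") matrix(test$day, ncol = 1) else
      cbind(day = test$day, volume_per_bmi = test$volume_per_bmi)
    subj <- if (scheme == "lovo") as.character(test$subject) else NULL
    p <- hgp_predict(model, Xs, subject = subj, include_noise = TRUE,
                     y_actual = y_true)
    err <- if (outcome == "mrc") {
      abs(pmin(pmax(round(p$mean), 0), 5) - y_true)
    } else {
      abs(p$mean - y_true)
    }
    data.frame(subject = test$subject, day = test$day, actual = y_true,
               predicted = p$mean, variance = p$variance,
               abs_error = err, log_lik = p$log_lik)
  })
  preds <- do.call(rbind, preds)
  structure(
    list(
      mae = mean(preds$abs_error),
      mean_log_likelihood = mean(preds$log_lik),
      n_heldout = nrow(preds),
      scheme = scheme, outcome = outcome,
      predictions = preds
    ),
    class = "hgp_evaluation"
  )
}

#' @export
print.hgp_evaluation <- function(x, ...) {
  cat(sprintf(
    "HGP evaluation (%s, %s): MAE %.3f, mean log-likelihood %.3f over %d held-out points\n",
    x$outcome, x$scheme, x$mae, x$mean_log_likelihood, x$n_heldout
  ))
  invisible(x)
}

#' Simulate data from a known hierarchical GP
#'
#' Draws one shared population function, independent per-subject deviation
#' functions and i.i.d. noise at the given visit times; used for parameter
#' recovery and coverage checks of the fitting code.
#'
#' @param n_subjects Number of subjects.
#' @param times Either a numeric vector of visit days shared by all
#'   subjects, or a list of per-subject day vectors.
#' @param params List with `var_pop`, `ls_pop`, `var_subj`, `ls_subj`,
#'   `var_noise`, `mean` (length-scales may be vectors for multi-d inputs).
#' @param seed Optional seed.
#' @return Data frame `subject`, `day`, `y`.
#' @export
simulate_hgp_data <- function(n_subjects, times, params, seed = NULL) {
  if (!is.list(times)) times <- rep(list(sort(times)), n_subjects)
  stopifnot(length(times) == n_subjects)
  with_seed(seed, {
    all_times <- sort(unique(unlist(times)))
    Xu <- matrix(all_times, ncol = 1)
    d2u <- sq_dists(Xu)
    Kpop <- se_kernel(d2u, params$var_pop, params$ls_pop)
    Lp <- chol_jitter(Kpop + diag(1e-10 * params$var_pop, nrow(Kpop)))
    f_pop <- drop(crossprod(Lp, stats::rnorm(length(all_times))))
    rows <- lapply(seq_len(n_subjects), function(s) {
      tt <- times[[s]]
      Xs <- matrix(tt, ncol = 1)
      Ks <- se_kernel(sq_dists(Xs), params$var_subj, params$ls_subj)
      Ls <- chol_jitter(Ks + diag(1e-10 * max(params$var_subj, 1), length(tt)))
      f_s <- drop(crossprod(Ls, stats::rnorm(length(tt))))
      y <- params$mean + f_pop[match(tt, all_times)] + f_s +
        stats::rnorm(length(tt), 0, sqrt(params$var_noise))
      data.frame(subject = sprintf("S%03d", s), day = tt, y = y)
    })
    do.call(rbind, rows)
  })
}

#' Save / load an HGP model as JSON
#'
#' The full parameter set and training index are stored as plain text so a
#' fitted model can be re-instantiated without refitting.
#'
#' @param model An `hgp_model`.
#' @param path File path.
#' @return `hgp_write` returns `path` invisibly; `hgp_read` the model.
#' @export
hgp_write <- function(model, path) {
  obj <- list(
    params = model$params, X = model$X, y = model$y,
    subject = as.character(model$subject), two_level = model$two_level,
    log_marginal = model$log_marginal, outcome = model$outcome,
    input_names = colnames(model$X)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname hgp_write
#' @export
hgp_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(obj$X)
  colnames(X) <- obj$input_names
  make_hgp_model(obj$params, X, obj$y, obj$subject, obj$two_level,
                 log_marginal = obj$log_marginal, outcome = obj$outcome)
}

#' Sample size for a two-arm trial of a volumetric endpoint
#'
#' Two-sample, two-sided normal-approximation sample size
#' `n = ceiling(2 (z_{1-alpha/2} + z_{power})^2 sigma^2 / delta^2)` per
#' group. The effect can be given directly (`delta`) or as a fractional
#' improvement of a mean volume (`effect_fraction * mean_volume`); the SD is
#' the between-subject SD of volume per unit BMI at the planned assessment
#' day. A simulation mode re-estimates power empirically at the analytic
#' `n` by repeated two-sample t-tests.
#'
#' @param delta Absolute group difference in mL/BMI (or use
#'   `mean_volume` + `effect_fraction`).
#' @param sd Between-subject SD of the endpoint.
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.80).
#' @param mean_volume,effect_fraction Alternative effect specification.
#' @param model,day Alternatively, a fitted [fit_volume_hgp()] model and
#'   assessment day: the mean is the population prediction at `day` and the
#'   SD combines the subject-level and noise variances.
#' @param mode `"analytic"` (default) or `"simulation"`.
#' @param n_trials Simulated trials in simulation mode (default 2000).
#' @param seed Seed for simulation mode.
#' @return List with `n_per_group`, `delta`, `sd`, `alpha`, `power`, and in
#'   simulation mode `empirical_power`.
#' @export
power_calculation <- function(delta = NULL, sd = NULL, alpha = 0.05,
                              power = 0.80, mean_volume = NULL,
                              effect_fraction = NULL, model = NULL,
                              day = NULL, mode = c("analytic", "simulation"),
                              n_trials = 2000L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(model)) {
    if (is.null(day)) stop_input("day required when using a fitted model")
    pr <- hgp_predict(model, matrix(day, ncol = 1), level = "population",
                      include_noise = FALSE)
    mean_volume <- pr$mean
    sd <- sqrt(model$params$var_subj + model$params$var_noise)
  }
  if (is.null(delta)) {
    if (is.null(mean_volume) || is.null(effect_fraction)) {
      stop_input("supply delta, or mean_volume and effect_fraction")
    }
    delta <- effect_fraction * mean_volume
  }
  if (is.null(sd) || sd <= 0) stop_input("sd must be positive")
  if (delta <= 0) stop_input("delta must be positive")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- as.integer(max(ceiling(2 * z^2 * sd^2 / delta^2), 2))
  out <- list(n_per_group = n, delta = delta, sd = sd, alpha = alpha,
              power = power)
  if (mode == "simulation") {
    out$empirical_power <- with_seed(seed, {
      hits <- vapply(seq_len(n_trials), function(i) {
        a <- stats::rnorm(n, 0, sd)
        b <- stats::rnorm(n, delta, sd)
        stats::t.test(a, b, var.equal = TRUE)$p.value < alpha
      }, logical(1))
      mean(hits)
    })
    out$n_trials <- n_trials
  }
  out
}
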