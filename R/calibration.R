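# Bayesian calibration of SPAC parameters against diurnal A_net
# observations: random 70/30 calibration/validation split, bounded-uniform
# priors, differential-evolution MCMC with snooker updates sampling from an
# archive of past states (DEzs), Gelman-Rubin convergence diagnostics, and
# RMSE / percent-bias / Nash-Sutcliffe goodness-of-fit on the held-out set.

#' Random calibration/validation split
#'
#' Disjoint, exhaustive partition of observation indices; the calibration set
#' has `round(fraction * n)` members. Seeded and reproducible.
#'
#' @param n_obs Number of observations (>= 10), or a data.frame whose rows
#'   are split.
#' @param fraction Calibration fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return List with integer index vectors `calibration` and `validation`.
#' @export
split_calibration <- function(n_obs, fraction = 0.7, seed = 1) {
  if (is.data.frame(n_obs)) n_obs <- nrow(n_obs)
  if (fraction <= 0 || fraction >= 1) .fail("fraction must be in (0, 1)")
  if (n_obs < 10) .fail("need >= 10 observations, got %d", n_obs)
  n_cal <- round(fraction * n_obs)
  cal <- with_seed(seed_stream(seed, 11L), sort(sample.int(n_obs, n_cal)))
  list(calibration = cal, validation = setdiff(seq_len(n_obs), cal))
}

#' Build a log-posterior for SPAC parameter calibration
#'
#' Gaussian log-likelihood of observed A_net given forward-model predictions
#' from [solve_leaf_states()], with bounded-uniform (flat) priors and the
#' residual standard deviation as the last, nuisance, free parameter.
#' Outside the prior support the density is `-Inf`; forward-model
#' non-convergence at a proposal incurs a large finite penalty.
#'
#' @param obs Calibration observations: met rows plus an `anet_obs` column
#'   (see [generate_diurnal_anet()]).
#' @param params Base [species_params()]; free parameters override its
#'   elements by name.
#' @param free Named list of `c(lower, upper)` prior bounds for each free
#'   parameter; a `"sigma"` entry bounds the residual sd (appended
#'   automatically as `c(0.01, 5)` if absent).
#' @param ... Passed to [solve_leaf_states()] (e.g. `acclimation`).
#' @return List with `log_posterior(theta)`, `lower`, `upper`,
#'   `par_names`, and `predict(theta)` returning model A_net.
#' @export
make_log_posterior <- function(obs, params, free, ...) {
  if (!"sigma" %in% names(free)) free$sigma <- c(0.01, 5)
  par_names <- names(free)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(lower >= upper)) .fail("prior bounds need lower < upper")
  phys <- setdiff(par_names, "sigma")
  dots <- list(...)
  predict_fun <- function(theta, newdata = obs) {
    p <- params
    p[phys] <- as.list(theta[match(phys, par_names)])
    st <- do.call(solve_leaf_states, c(list(newdata, p), dots))
    list(a_net = st$a_net, ok = all(st$converged))
  }
  log_posterior <- function(theta) {
    if (any(theta < lower | theta > upper)) return(-Inf)
    pr <- predict_fun(theta)
    sigma <- theta[match("sigma", par_names)]
    ll <- sum(stats::dnorm(obs$anet_obs, pr$a_net, sigma, log = TRUE))
    if (!pr$ok || !is.finite(ll)) return(-1e8) # penalised, not -Inf
    ll
  }
  list(log_posterior = log_posterior, lower = lower, upper = upper,
       par_names = par_names, predict = predict_fun)
}

#' Differential-evolution MCMC with snooker updates (DEzs)
#'
#' Samples `n_chains` interacting chains whose jumps are differences of
#' states drawn from a thinned archive of past states, with occasional
#' snooker updates (ter Braak & Vrugt 2008). Deterministic for a given seed.
#'
#' @param log_posterior Function of a parameter vector returning a log
#'   density (`-Inf` outside support).
#' @param lower,upper Numeric prior bounds (define the initial population).
#' @param n_chains Number of chains (>= 3).
#' @param n_iter Iterations per chain.
#' @param seed Integer seed.
#' @param snooker_prob Probability of a snooker update (default 0.1).
#' @param archive_thin Append current states to the archive every this many
#'   generations.
#' @param jitter Small uniform jitter width `e` on proposals.
#' @return A `demc_fit` list: `samples` (array iter x chain x parameter),
#'   `log_post` (iter x chain), `acceptance_rate` per chain, `n_chains`,
#'   `n_iter`.
#' @export
demc_sample <- function(log_posterior, lower, upper, n_chains = 3,
                        n_iter = 2000, seed = 1, snooker_prob = 0.1,
                        archive_thin = 10, jitter = 1e-6) {
  if (n_chains < 3) .fail("need >= 3 chains")
  d <- length(lower)
  gamma0 <- 2.38 / sqrt(2 * d)
  with_seed(seed_stream(seed, 101L), {
    m0 <- max(10 * d, n_chains + 2)
    Z <- matrix(stats::runif(m0 * d, lower, upper), ncol = d, byrow = TRUE)
    X <- Z[seq_len(n_chains), , drop = FALSE]
    lp <- apply(X, 1, log_posterior)
    # make sure every chain starts at finite density
    tries <- 0
    while (any(!is.finite(lp)) && tries < 200) {
      bad <- which(!is.finite(lp))
      X[bad, ] <- matrix(stats::runif(length(bad) * d, lower, upper),
                         ncol = d, byrow = TRUE)
      lp[bad] <- apply(X[bad, , drop = FALSE], 1, log_posterior)
      tries <- tries + 1
    }
    samples <- array(NA_real_, c(n_iter, n_chains, d))
    lpost <- matrix(NA_real_, n_iter, n_chains)
    accepts <- numeric(n_chains)
    all_rejected_epochs <- 0L
    for (it in seq_len(n_iter)) {
      acc_this <- 0
      for (ch in seq_len(n_chains)) {
        x <- X[ch, ]
        if (stats::runif(1) < snooker_prob) {
          # snooker: jump along the line towards a random archive state
          zi <- Z[sample.int(nrow(Z), 3), , drop = FALSE]
          dz <- x - zi[1, ]
          nrm <- sum(dz^2)
          gs <- stats::runif(1, 1.2, 2.2)
          proj <- if (nrm > 0)
            ((zi[2, ] - zi[3, ]) %*% dz)[1] / nrm * dz else 0 * dz
          xp <- x + gs * proj
          dz_new <- xp - zi[1, ]
          lr <- if (nrm > 0 && sum(dz_new^2) > 0)
            (d - 1) / 2 * (log(sum(dz_new^2)) - log(nrm)) else 0
        } else {
          zi <- Z[sample.int(nrow(Z), 2), , drop = FALSE]
          g <- if (it %% 10 == 0) 1 else gamma0
          xp <- x + g * (zi[1, ] - zi[2, ]) +
            stats::runif(d, -jitter, jitter)
          lr <- 0
        }
        lp_new <- log_posterior(xp)
        if (is.finite(lp_new) &&
            log(stats::runif(1)) < lp_new - lp[ch] + lr) {
          X[ch, ] <- xp
          lp[ch] <- lp_new
          accepts[ch] <- accepts[ch] + 1
          acc_this <- acc_this + 1
        }
      }
      if (acc_this == 0) all_rejected_epochs <- all_rejected_epochs + 1L
      if (it %% archive_thin == 0) Z <- rbind(Z, X)
      samples[it, , ] <- X
      lpost[it, ] <- lp
    }
    if (all_rejected_epochs > 0.9 * n_iter)
      warning("DE-MC: >90% of generations rejected all proposals",
              call. = FALSE)
    structure(list(
      samples = samples, log_post = lpost,
      acceptance_rate = accepts / n_iter,
      n_chains = n_chains, n_iter = n_iter
    ), class = "demc_fit")
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per parameter from between- and within-chain variances of
#' equal-length chains. Chains with zero variance everywhere are the
#' exactly-converged special case and report 1.
#'
#' @param chains Either a `demc_fit`, an iteration x chain x parameter
#'   array, or a list of iteration x parameter matrices (>= 2 chains of
#'   equal length >= 10).
#' @param burn_in Fraction of initial iterations to discard (default 0,
#'   i.e. the chains are assumed already trimmed).
#' @return Named numeric vector of PSRF values, one per parameter.
#' @export
gelman_rubin <- function(chains, burn_in = 0) {
  arr <- if (inherits(chains, "demc_fit")) chains$samples
  else if (is.array(chains) && length(dim(chains)) == 3) chains
  else if (is.list(chains)) {
    lens <- vapply(chains, nrow, integer(1))
    if (length(unique(lens)) != 1) .fail("chains must have equal lengths")
    a <- array(NA_real_, c(lens[1], length(chains), ncol(chains[[1]])))
    for (i in seq_along(chains)) a[, i, ] <- chains[[i]]
    a
  } else .fail("unsupported chains object")
  n_all <- dim(arr)[1]
  if (burn_in > 0) arr <- arr[seq.int(floor(burn_in * n_all) + 1, n_all), , ,
                              drop = FALSE]
  n <- dim(arr)[1]; m <- dim(arr)[2]; d <- dim(arr)[3]
  if (m < 2) .fail("need >= 2 chains")
  if (n < 3) .fail("need chains of length >= 3")
  out <- numeric(d)
  for (j in seq_len(d)) {
    x <- arr[, , j]
    means <- colMeans(x)
    w <- mean(apply(x, 2, stats::var))
    b <- n * stats::var(means)
    if (w == 0) { out[j] <- 1; next } # degenerate zero-variance case
    var_plus <- (n - 1) / n * w + b / n
    out[j] <- sqrt(var_plus / w)
  }
  out
}

#' Goodness-of-fit metrics for model evaluation
#'
#' @param observed,modeled Equal-length finite numeric vectors (n >= 2).
#' @return List with `rmse` (root mean squared error), `pbias_pct`
#'   (`100 * sum(mod - obs) / sum(obs)`) and `nse` (Nash-Sutcliffe
#'   efficiency, `NA` when the observations have zero variance).
#' @export
gof_metrics <- function(observed, modeled) {
  if (length(observed) != length(modeled)) .fail("length mismatch")
  if (length(observed) < 2) .fail("need >= 2 values")
  if (any(!is.finite(observed)) || any(!is.finite(modeled)))
    .fail("values must be finite")
  rmse <- sqrt(mean((modeled - observed)^2))
  pbias <- 100 * sum(modeled - observed) / sum(observed)
  ss_tot <- sum((observed - mean(observed))^2)
  nse <- if (ss_tot == 0) NA_real_ else 1 - sum((observed - modeled)^2) / ss_tot
  list(rmse = rmse, pbias_pct = pbias, nse = nse)
}

#' Calibrate SPAC parameters against diurnal observations
#'
#' End-to-end calibration: 70/30 split, DEzs sampling of the free parameters
#' on the calibration set, Gelman-Rubin diagnostics after burn-in, posterior
#' summaries, and goodness-of-fit of the posterior-median model on the
#' held-out validation set.
#'
#' @param obs Observations (met rows + `anet_obs`).
#' @param params Base [species_params()].
#' @param free Named list of prior bounds (see [make_log_posterior()]).
#' @param n_chains,n_iter Sampler size (the field protocol used 3 chains;
#'   iteration counts are configurable).
#' @param burn_in Fraction of iterations discarded before diagnostics
#'   (default 0.5).
#' @param cal_fraction Calibration fraction (default 0.7).
#' @param seed Integer seed governing split and sampler.
#' @param ... Passed to [solve_leaf_states()].
#' @return A `calibration_result` list: `fit` (the `demc_fit`),
#'   `gelman_rubin`, `posterior_summary` (median and 95% interval per
#'   parameter), `gof` on the validation set, `split`, `cal_fraction`,
#'   `par_names`.
#' @export
calibrate_spac <- function(obs, params, free, n_chains = 3, n_iter = 2000,
                           burn_in = 0.5, cal_fraction = 0.7, seed = 1, ...) {
  sp <- split_calibration(nrow(obs), cal_fraction, seed)
  cal <- obs[sp$calibration, , drop = FALSE]
  val <- obs[sp$validation, , drop = FALSE]
  post <- make_log_posterior(cal, params, free, ...)
  fit <- demc_sample(post$log_posterior, post$lower, post$upper,
                     n_chains = n_chains, n_iter = n_iter, seed = seed)
  keep <- seq.int(floor(burn_in * n_iter) + 1, n_iter)
  sub <- fit$samples[keep, , , drop = FALSE]
  gr <- gelman_rubin(sub)
  names(gr) <- post$par_names
  flat <- apply(sub, 3, c)
  summ <- data.frame(
    parameter = post$par_names,
    median = apply(flat, 2, stats::median),
    q2.5 = apply(flat, 2, stats::quantile, 0.025),
    q97.5 = apply(flat, 2, stats::quantile, 0.975)
  )
  med <- summ$median
  names(med) <- post$par_names
  pred_val <- post$predict(med, newdata = val)
  structure(list(
    fit = fit, gelman_rubin = gr, posterior_summary = summ,
    gof = gof_metrics(val$anet_obs, pred_val$a_net),
    split = sp, cal_fraction = cal_fraction, par_names = post$par_names
  ), class = "calibration_result")
}
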