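#' Standardize summary statistics and compute Euclidean distances
#'
#' Each statistic is scaled by its median absolute deviation (MAD) across
#' the reference table; statistics with zero MAD are dropped with a warning.
#' The distance of every reference row to the observed vector is the
#' Euclidean norm of the scaled differences.
#'
#' @param stats numeric matrix of simulated statistics (rows = simulations),
#'   with column names.
#' @param observed named numeric vector with the same layout.
#' @return list with `distance` (per-row), `z` (standardized matrix),
#'   `z_obs`, `scale` (the MADs) and `kept` (column names used).
#' @export
standardize_and_distance <- function(stats, observed) {
  stats <- as.matrix(stats)
  observed <- unlist(observed)
  if (is.null(colnames(stats)) || is.null(names(observed)))
    stop("statistics must be named")
  diff_cols <- c(setdiff(colnames(stats), names(observed)),
                 setdiff(names(observed), colnames(stats)))
  if (length(diff_cols))
    stop(sprintf("summary-statistic layout mismatch: %s",
                 paste(unique(diff_cols), collapse = ", ")))
  observed <- observed[colnames(stats)]
  scale <- apply(stats, 2, stats::mad)
  drop <- !is.finite(scale) | scale == 0 | !is.finite(observed)
  if (any(drop))
    warning(sprintf("dropping statistic(s) with zero/undefined MAD: %s",
                    paste(colnames(stats)[drop], collapse = ", ")))
  if (all(drop)) stop("no usable summary statistics left")
  keep <- which(!drop)
  z <- sweep(stats[, keep, drop = FALSE], 2, scale[keep], "/")
  z_obs <- observed[keep] / scale[keep]
  d <- sqrt(rowSums(sweep(z, 2, z_obs, "-")^2))
  list(distance = unname(d), z = z, z_obs = z_obs, scale = scale[keep],
       kept = colnames(stats)[keep])
}

#' ABC rejection step
#'
#' Retains the `ceiling(tolerance * N)` reference rows with the smallest
#' standardized Euclidean distance to the observed statistics (ties broken
#' by original row order).
#'
#' @param table a `"reference_table"` (see [build_reference_table()]).
#' @param observed named statistic vector.
#' @param tolerance fraction of rows to retain, in (0, 1].
#' @return an object of class `"retained_set"`: `index`, `distance` (sorted
#'   non-decreasing), `model`, `params`, `z`, `z_obs`, `tolerance`.
#' @export
abc_reject <- function(table, observed, tolerance) {
  stopifnot(inherits(table, "reference_table"))
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1)
    stop("tolerance must be in (0, 1]")
  N <- nrow(table$stats)
  if (N == 0L) stop("empty reference table")
  sd_ <- standardize_and_distance(table$stats, observed)
  keep_n <- ceiling(tolerance * N)
  ord <- order(sd_$distance)[seq_len(keep_n)]
  structure(list(index = ord, distance = sd_$distance[ord],
                 model = table$model[ord],
                 params = table$params[ord, , drop = FALSE],
                 z = sd_$z[ord, , drop = FALSE], z_obs = sd_$z_obs,
                 tolerance = tolerance),
            class = "retained_set")
}

#' Posterior model probabilities by rejection
#'
#' The posterior probability of each model is its share of the retained
#' simulations; models declared in the reference table but absent from the
#' retained set get probability 0.
#'
#' @param retained a [abc_reject()] result.
#' @return named probability vector summing to 1.
#' @export
model_posterior_rejection <- function(retained) {
  stopifnot(inherits(retained, "retained_set"))
  tab <- table(retained$model)
  p <- as.numeric(tab) / length(retained$model)
  names(p) <- names(tab)
  p
}

# Weighted multinomial logistic regression by Newton iterations on the
# reference-class parameterization; returns NULL on failure/separation.
multinom_logit <- function(X, y, w, max_iter = 100L, tol = 1e-8,
                           ridge = 1e-8) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  n <- nrow(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, p, K - 1L) # class 1 is the reference
  w <- w / sum(w)
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, X %*% B)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta)
    P <- P / rowSums(P)
    G <- crossprod(X, w * (Y[, -1L, drop = FALSE] - P[, -1L, drop = FALSE]))
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (a in seq_len(K - 1L)) for (b in a:(K - 1L)) {
      wab <- w * (P[, a + 1L] * ((a == b) - P[, b + 1L]))
      blk <- crossprod(X, wab * X)
      ia <- (a - 1L) * p + seq_len(p)
      ib <- (b - 1L) * p + seq_len(p)
      H[ia, ib] <- blk
      H[ib, ia] <- t(blk)
    }
    diag(H) <- diag(H) + ridge
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    B_new <- B + matrix(step, p, K - 1L)
    if (max(abs(B_new)) > 1e4) return(NULL) # diverging: separation
    done <- max(abs(B_new - B)) < tol
    B <- B_new
    if (done) break
  }
  list(coef = B, levels = levels(y))
}

#' Posterior model probabilities by multinomial logistic regression
#'
#' Regresses the model label of the retained simulations on their
#' standardized statistics, weighting by an Epanechnikov kernel in distance
#' (weight 0 at the largest retained distance), and evaluates the fitted
#' class probabilities at the observed point.  On perfect separation or a
#' failed fit it falls back to the rejection proportions with a warning.
#'
#' @inheritParams abc_reject
#' @return named probability vector summing to 1.
#' @export
model_posterior_logistic <- function(table, observed, tolerance) {
  retained <- abc_reject(table, observed, tolerance)
  models <- droplevels(retained$model)
  if (nlevels(models) < 2L) {
    full <- stats::setNames(numeric(nlevels(retained$model)),
                            levels(retained$model))
    full[levels(models)] <- 1
    return(full)
  }
  dmax <- max(retained$distance)
  w <- if (dmax > 0) 1 - (retained$distance / dmax)^2 else
    rep(1, length(retained$distance))
  w[w <= 0] <- min(w[w > 0], 1e-12) / 2 # keep the boundary row estimable
  fit <- multinom_logit(retained$z, models, w)
  if (is.null(fit)) {
    warning("multinomial regression failed (separation?); falling back to rejection proportions")
    return(model_posterior_rejection(retained))
  }
  eta <- c(0, c(1, retained$z_obs) %*% fit$coef)
  eta <- eta - max(eta)
  p <- exp(eta) / sum(exp(eta))
  names(p) <- fit$levels
  # declared models absent from the retained set get probability 0
  full <- stats::setNames(numeric(nlevels(retained$model)),
                          levels(retained$model))
  full[names(p)] <- p
  full
}

#' Bayes-factor matrix from posterior model probabilities
#'
#' `BF[i, j] = P(i) / P(j)` (equal prior model weights); a zero denominator
#' yields `Inf`.
#'
#' @param probs named probability vector (must sum to 1).
#' @return square matrix of Bayes factors.
#' @export
bayes_factors <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  bf <- outer(probs, probs, function(a, b) ifelse(b == 0, Inf, a / b))
  diag(bf) <- 1
  dimnames(bf) <- list(names(probs), names(probs))
  bf
}

#' Marginal-density p-value (model-fit diagnostic)
#'
#' Fits a product-Gaussian kernel density to the retained standardized
#' statistics and reports the fraction of retained simulations whose density
#' is strictly lower than the observed point's.  A low p-value means the
#' observed statistics sit outside what the model typically produces.
#'
#' @param retained a [abc_reject()] result.
#' @return p-value in `[0, 1]`.
#' @export
marginal_density_pvalue <- function(retained) {
  stopifnot(inherits(retained, "retained_set"))
  Z <- retained$z
  sds <- apply(Z, 2, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (!length(keep)) stop("retained statistics are all constant")
  if (length(keep) < ncol(Z))
    warning("dropping constant/collinear statistic column(s) for the density")
  Z <- Z[, keep, drop = FALSE]
  m <- nrow(Z)
  d <- ncol(Z)
  h <- apply(Z, 2, stats::sd) * m^(-1 / (d + 4))
  ld <- rcpp_kde_logdens(Z, h, rbind(Z, retained$z_obs[keep]))
  mean(ld[seq_len(m)] < ld[m + 1L])
}

#' Local-linear regression adjustment of retained parameters
#'
#' Weighted local-linear ABC regression with heteroscedasticity correction.
#' Each (transformed) parameter is regressed on the standardized retained
#' statistics with Epanechnikov weights; the adjusted sample is the
#' observed-point prediction plus the residuals, rescaled by the ratio of a
#' fitted conditional scale at the observed point to the scale at each
#' retained point (the scale is fitted by regressing log squared residuals
#' on the same design).  Parameters with a log-uniform prior are adjusted on
#' the log10 scale and back-transformed; adjusted values outside the prior
#' bounds are kept but flagged.
#'
#' @param retained a [abc_reject()] result carrying parameters.
#' @param spec the [model_spec()] of the model whose draws are adjusted
#'   (used for transforms and prior bounds); retained rows of other models
#'   are ignored.
#' @param hcorr apply the heteroscedasticity correction (default `TRUE`).
#' @return an object of class `"parameter_posterior"`: `sample` (adjusted
#'   draws, linear scale), `weights` (normalized), `transforms`,
#'   `outside_prior` flags.
#' @export
loclinear_adjust <- function(retained, spec, hcorr = TRUE) {
  stopifnot(inherits(retained, "retained_set"), inherits(spec, "model_spec"))
  rows <- which(retained$model == spec$model_id)
  if (!length(rows)) stop(sprintf("no retained rows for model %s",
                                  spec$model_id))
  Z <- retained$z[rows, , drop = FALSE]
  d <- retained$distance[rows]
  params <- retained$params[rows, , drop = FALSE]
  params <- params[, colSums(!is.na(params)) > 0, drop = FALSE]
  params <- params[, names(params) %in% names(spec$priors), drop = FALSE]
  if (nrow(Z) < ncol(Z) + 2L)
    stop("fewer retained rows than statistics + 1; cannot regress")
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  w[w <= 0] <- min(w[w > 0], 1e-12) / 2
  w <- w / sum(w)
  X <- cbind(1, sweep(Z, 2, retained$z_obs, "-")) # prediction at obs = intercept
  transforms <- vapply(names(params), function(nm)
    if (spec$priors[[nm]]$kind == "loguniform") "log10" else "identity",
    character(1))
  theta <- as.matrix(params)
  for (j in seq_along(transforms))
    if (transforms[j] == "log10") theta[, j] <- log10(theta[, j])
  fit <- stats::lm.wfit(X, theta, w)
  pred_obs <- fit$coefficients[1L, , drop = FALSE]
  resid <- fit$residuals
  if (!is.matrix(resid)) resid <- matrix(resid, ncol = ncol(theta))
  adj <- matrix(NA_real_, nrow(theta), ncol(theta),
                dimnames = dimnames(theta))
  for (j in seq_len(ncol(theta))) {
    e <- resid[, j]
    if (hcorr && stats::sd(e) > 0) {
      lfit <- stats::lm.wfit(X, log(e^2 + 1e-300), w)
      sig <- exp(lfit$fitted.values / 2)
      sig_obs <- exp(lfit$coefficients[1L] / 2)
      adj[, j] <- pred_obs[1L, j] + e * (sig_obs / pmax(sig, 1e-300))
    } else {
      adj[, j] <- pred_obs[1L, j] + e
    }
  }
  outside <- matrix(FALSE, nrow(adj), ncol(adj), dimnames = dimnames(adj))
  for (j in seq_len(ncol(adj))) {
    nm <- colnames(adj)[j]
    pr <- spec$priors[[nm]]
    lo <- pr$min; hi <- pr$max # exponents already match the log10 scale
    if (!is.null(pr$scale_by)) next
    outside[, j] <- adj[, j] < lo | adj[, j] > hi
    if (transforms[j] == "log10") adj[, j] <- 10^adj[, j]
  }
  structure(list(sample = as.data.frame(adj), weights = w,
                 transforms = transforms, outside_prior = outside,
                 model_id = spec$model_id),
            class = "parameter_posterior")
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_mode <- function(x, w, bw = NULL) {
  w <- w / sum(w)
  if (stats::sd(x) == 0) return(x[1])
  if (is.null(bw)) bw <- stats::bw.nrd0(x)
  dens <- stats::density(x, weights = w, bw = bw)
  dens$x[which.max(dens$y)]
}

weighted_hpd <- function(x, w, level = 0.95) {
  ord <- order(x)
  x <- x[ord]
  cw <- c(0, cumsum(w[ord]) / sum(w))
  n <- length(x)
  best <- c(x[1], x[n])
  best_len <- Inf
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && cw[j + 1L] - cw[i] < level) j <- j + 1L
    if (cw[j + 1L] - cw[i] >= level) {
      len <- x[j] - x[i]
      if (len < best_len) { best_len <- len; best <- c(x[i], x[j]) }
    }
  }
  best
}

#' Posterior summaries of an adjusted parameter sample
#'
#' Weighted 5% quantile, mean, median, kernel-density mode (Silverman
#' bandwidth), and 95% highest-posterior-density interval, on the linear
#' scale.
#'
#' @param post a [loclinear_adjust()] result (or any list with `sample` and
#'   `weights`).
#' @param level HPD mass (default 0.95).
#' @return data.frame with one row per parameter and columns `q5, mean,
#'   median, mode, hpd_lower, hpd_upper`.
#' @export
posterior_summaries <- function(post, level = 0.95) {
  s <- as.data.frame(post$sample)
  w <- post$weights / sum(post$weights)
  out <- do.call(rbind, lapply(names(s), function(nm) {
    x <- s[[nm]]
    hpd <- weighted_hpd(x, w, level)
    data.frame(parameter = nm,
               q5 = weighted_quantile(x, w, 0.05),
               mean = sum(w * x),
               median = weighted_quantile(x, w, 0.5),
               mode = weighted_mode(x, w),
               hpd_lower = hpd[1], hpd_upper = hpd[2])
  }))
  rownames(out) <- NULL
  out
}
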