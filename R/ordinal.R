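#' Fit a proportional-odds (cumulative logit) ordinal regression
#'
#' Maximizes the cumulative-logit likelihood
#' \eqn{P(Y \le j \mid x) = \mathrm{logit}^{-1}(\alpha_j - x^\top\beta)}
#' by Newton's method with step-halving, starting from the empirical
#' cumulative logits with \eqn{\beta = 0}. A single slope vector is shared
#' across cut-points (the proportional-odds assumption); with the design's
#' exposure sign-flipped to "per 1 SD lower", an odds ratio above 1 reads
#' "lower energetics, greater odds of a higher severity stratum".
#'
#' @param y Ordered factor outcome (J >= 2 levels, each observed at least
#'   once).
#' @param X Design matrix of predictors *without* an intercept column (the
#'   thresholds absorb it).
#' @param exposure Name of the exposure column for odds-ratio reporting.
#' @param max_iter,tol Newton iteration cap and gradient sup-norm target.
#' @return Object of class `ordinal_fit`: `thresholds` (strictly
#'   increasing), `beta`, `se`, `cov`, `or_per_sd` (odds ratio with 95% CI
#'   for `exposure`), `loglik`, `n`, plus `brant_stat`/`brant_df`/`brant_p`
#'   once [brant_wald()] has been run.
#' @export
ordinal_fit <- function(y, X, exposure = colnames(X)[1],
                        max_iter = 100, tol = 1e-8) {
  y <- as.ordered(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  lev <- levels(y)
  J <- length(lev)
  if (J < 2) stop("outcome needs at least two levels")
  counts <- table(y)
  if (any(counts == 0)) {
    stop("empty outcome level(s): ", paste(lev[counts == 0], collapse = ", "))
  }
  yi <- as.integer(y)
  n <- length(yi)
  p <- ncol(X)

  cumprop <- cumsum(counts)[-J] / n
  par <- c(stats::qlogis(cumprop), rep(0, p))  # (alpha_1..alpha_{J-1}, beta)

  ll_fun <- function(par) .po_loglik(par, yi, X, J)
  gr_fun <- function(par) .po_grad(par, yi, X, J)

  ll <- ll_fun(par)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gr_fun(par)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- .fd_jacobian(gr_fun, par)
    H <- (H + t(H)) / 2
    newton <- tryCatch(solve(H, g), error = function(e) NULL)
    # Newton ascent (H is the loglik Hessian); fall back to gradient ascent
    step <- if (is.null(newton)) g * 1e-3 else -newton
    # step-halve until the likelihood improves and thresholds stay ordered
    ok <- FALSE
    for (h in 0:40) {
      cand <- par + step / 2^h
      a <- cand[seq_len(J - 1)]
      if (J > 2 && any(diff(a) <= 0)) next
      llc <- ll_fun(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        par <- cand; ll <- llc; ok <- TRUE; break
      }
    }
    if (!ok) break
    if (max(abs(par[J:(J - 1 + p)])) > 30) {
      stop("apparent complete separation: slope diverging")
    }
  }
  g <- gr_fun(par)
  if (!converged && max(abs(g)) > 1e-4) {
    stop(sprintf("ordinal fit did not converge: gradient sup-norm %.3g",
                 max(abs(g))))
  }

  H <- .fd_jacobian(gr_fun, par)
  info <- -(H + t(H)) / 2
  cov_all <- tryCatch(solve(info), error = function(e)
    stop("singular information in ordinal fit (separation?)"))
  alpha <- par[seq_len(J - 1)]
  beta <- par[J:(J - 1 + p)]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(0, diag(cov_all)[J:(J - 1 + p)]))
  names(se) <- colnames(X)
  orci <- NULL
  if (!is.null(exposure) && exposure %in% colnames(X)) {
    b <- beta[exposure]; s <- se[exposure]
    orci <- c(or = exp(b), lower = exp(b - 1.96 * s), upper = exp(b + 1.96 * s))
  }
  structure(
    list(thresholds = alpha, beta = beta, se = se,
         cov = cov_all, or_per_sd = orci, loglik = ll, n = n,
         levels = lev, exposure = exposure,
         brant_stat = NULL, brant_df = NULL, brant_p = NULL),
    class = "ordinal_fit"
  )
}

.po_cumprob <- function(par, X, J) {
  alpha <- par[seq_len(J - 1)]
  beta <- par[J:(J - 1 + ncol(X))]
  eta <- drop(X %*% beta)
  F <- cbind(0, stats::plogis(outer(-eta, alpha, `+`)), 1)
  F
}

.po_loglik <- function(par, yi, X, J) {
  F <- .po_cumprob(par, X, J)
  pr <- F[cbind(seq_along(yi), yi + 1L)] - F[cbind(seq_along(yi), yi)]
  if (any(pr <= 0)) return(-Inf)
  sum(log(pr))
}

.po_grad <- function(par, yi, X, J) {
  n <- length(yi)
  p <- ncol(X)
  alpha <- par[seq_len(J - 1)]
  beta <- par[J:(J - 1 + p)]
  eta <- drop(X %*% beta)
  Fm <- cbind(0, stats::plogis(outer(-eta, alpha, `+`)), 1)
  fm <- cbind(0, stats::dlogis(outer(-eta, alpha, `+`)), 0)  # dF/dalpha_j
  pr <- Fm[cbind(seq_len(n), yi + 1L)] - Fm[cbind(seq_len(n), yi)]
  pr <- pmax(pr, 1e-300)
  f_up <- fm[cbind(seq_len(n), yi + 1L)]
  f_lo <- fm[cbind(seq_len(n), yi)]
  g_alpha <- numeric(J - 1)
  for (j in seq_len(J - 1)) {
    g_alpha[j] <- sum(ifelse(yi == j, f_up / pr,
                             ifelse(yi == j + 1L, -f_lo / pr, 0)))
  }
  w <- (f_up - f_lo) / pr                  # d log pr / d eta = -(f_up - f_lo)/pr * ... sign below
  g_beta <- -drop(crossprod(X, w))
  c(g_alpha, g_beta)
}

#' Brant–Wald test of the proportional-odds assumption
#'
#' Fits the J-1 separate binary logistic regressions of
#' \eqn{I(Y > j)} on the predictors, then tests equality of each
#' predictor's slope across cut-points with a Wald chi-square using
#' Brant's expression for the joint covariance of the per-logit estimates
#' (\eqn{\widehat{\mathrm{cov}}(\hat\beta_j,\hat\beta_l) =
#' (X^\top W_{jj}X)^{-1} X^\top W_{jl}X (X^\top W_{ll}X)^{-1}} with
#' \eqn{W_{jl} = \mathrm{diag}\{\pi_l - \pi_j\pi_l\}}, \eqn{j \le l}).
#' The statistic is chi-squared with `(J - 2) * p` degrees of freedom
#' under proportionality.
#'
#' @param y Ordered factor with J >= 3 levels.
#' @param X Predictor matrix without intercept (as in [ordinal_fit()]).
#' @return List `statistic`, `df`, `p.value`.
#' @export
brant_wald <- function(y, X) {
  y <- as.ordered(y)
  X <- as.matrix(X)
  J <- nlevels(y)
  if (J < 3) stop("Brant test needs at least 3 outcome levels")
  if (any(table(y) < 10)) {
    warning("fewer than 10 observations in some outcome level: ",
            "Brant test may be unstable")
  }
  yi <- as.integer(y)
  n <- nrow(X)
  p <- ncol(X)
  Xi <- cbind(`(Intercept)` = 1, X)

  betas <- vector("list", J - 1)
  pis <- matrix(0, n, J - 1)
  for (j in seq_len(J - 1)) {
    z <- as.integer(yi > j)
    gf <- suppressWarnings(
      stats::glm.fit(Xi, z, family = stats::binomial())
    )
    if (!gf$converged || any(abs(gf$coefficients) > 30)) {
      stop("binary sub-model ", j, " failed (possible separation)")
    }
    betas[[j]] <- gf$coefficients
    pis[, j] <- gf$fitted.values
  }

  q <- p + 1
  V <- matrix(0, (J - 1) * q, (J - 1) * q)
  XtWX_inv <- vector("list", J - 1)
  for (j in seq_len(J - 1)) {
    XtWX_inv[[j]] <- solve(crossprod(Xi, Xi * (pis[, j] * (1 - pis[, j]))))
  }
  for (j in seq_len(J - 1)) for (l in j:(J - 1)) {
    # pi_l <= pi_j for l >= j (P(Y > l) decreasing in l)
    W_jl <- pis[, l] - pis[, j] * pis[, l]
    blk <- XtWX_inv[[j]] %*% crossprod(Xi, Xi * W_jl) %*% XtWX_inv[[l]]
    ri <- ((j - 1) * q + 1):(j * q)
    ci <- ((l - 1) * q + 1):(l * q)
    V[ri, ci] <- blk
    V[ci, ri] <- t(blk)
  }

  # keep slopes only (drop intercept rows/cols per logit)
  keep <- as.vector(vapply(seq_len(J - 1),
                           function(j) (j - 1) * q + 1 + seq_len(p),
                           numeric(p)))
  b <- unlist(lapply(betas, function(bb) bb[-1]))
  Vb <- V[keep, keep, drop = FALSE]

  # contrasts: beta_j - beta_{j+1} for all predictors
  D <- matrix(0, (J - 2) * p, (J - 1) * p)
  for (j in seq_len(J - 2)) {
    rows <- ((j - 1) * p + 1):(j * p)
    D[rows, rows] <- diag(p)
    D[rows, rows + p] <- -diag(p)
  }
  d <- drop(D %*% b)
  stat <- drop(t(d) %*% solve(D %*% Vb %*% t(D), d))
  df <- (J - 2) * p
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit: n = %d, logLik = %.2f\n", x$n, x$loglik))
  cat("thresholds:", paste(sprintf("%.3f", x$thresholds), collapse = " < "),
      "\n")
  if (!is.null(x$or_per_sd)) {
    cat(sprintf("OR (%s) = %.3f [%.3f, %.3f]\n", x$exposure,
                x$or_per_sd["or"], x$or_per_sd["lower"], x$or_per_sd["upper"]))
  }
  invisible(x)
}
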