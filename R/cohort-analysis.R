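#' Standardize the energetics exposures
#'
#' Adds, for each exposure, a z-score column (`z_<name>`, complete-case
#' mean 0, SD 1) and a sign-flipped copy (`z_<name>_lower`) so that model
#' coefficients read "per 1 SD *lower* energetics". The complete-case SDs
#' are recorded in the `sd_registry` attribute for reporting on the
#' natural units.
#'
#' @param table A `cohort_table` ([simulate_cohort()] or
#'   [read_cohort_csv()]).
#' @param exposures Exposure column names.
#' @return The table with z-columns added and attribute `sd_registry`
#'   (named vector of complete-case SDs).
#' @export
standardize_exposures <- function(table, exposures = .exposure_names) {
  sds <- numeric(0)
  for (e in exposures) {
    x <- table[[e]]
    if (is.null(x)) stop("missing exposure column: ", e)
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance in exposure ", e)
    z <- (x - m) / s
    table[[paste0("z_", e)]] <- z
    table[[paste0("z_", e, "_lower")]] <- -z
    sds[e] <- s
  }
  attr(table, "sd_registry") <- sds
  table
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from \eqn{t = r_s\sqrt{(n-2)/(1-r_s^2)}} on
#' \eqn{n - 2} df. Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors; at least 4 complete pairs required.
#' @return List `estimate`, `p.value`, `n`.
#' @examples
#' spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$estimate  # 0.8
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(estimate = r, p.value = p, n = n)
}

# default Table-1-style variable plan: summary type and trend-test family
# are pre-declared per variable, not decided by a runtime normality test
.default_table1_plan <- function() {
  data.frame(
    variable = c("ppfi", "max_oxphos", "max_ets", "atp_max",
                 "age", "height_cm", "weight_kg", "sppb",
                 "total_activity_count", "sex", "race"),
    type = c(rep("skewed", 4), rep("normal", 5), rep("categorical", 2)),
    stringsAsFactors = FALSE
  )
}

#' Severity-stratum descriptives with trend tests
#'
#' Builds a Table-1-style block: per variable, a summary per severity
#' stratum (median with 25th–75th percentiles for pre-declared skewed
#' variables,
#' mean +/- SD for normal ones, n (%) for categoricals) and a trend
#' p-value from the matching family — Kruskal–Wallis for skewed, one-way
#' ANOVA for normal, chi-square for categorical. The plan is declared up
#' front (see `plan`), not inferred from the data at run time.
#'
#' @param table A `cohort_table` with `stratum` assigned.
#' @param plan Data frame `variable`, `type`
#'   (`skewed`/`normal`/`categorical`); defaults cover the generator's
#'   columns.
#' @return Data frame: `variable`, `type`, one summary column per stratum,
#'   `p_trend`, `test`.
#' @export
describe_by_strata <- function(table, plan = .default_table1_plan()) {
  strata <- .severity_levels
  counts <- table(factor(table$stratum, levels = strata))
  if (any(counts == 0)) {
    warning("empty severity stratum: ",
            paste(strata[counts == 0], collapse = ", "),
            "; trend tests skipped")
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    v <- plan$variable[i]; ty <- plan$type[i]
    x <- table[[v]]
    g <- factor(table$stratum, levels = strata)
    summ <- vapply(strata, function(s) {
      xs <- x[g == s]
      xs_ok <- xs[!is.na(xs)]
      if (length(xs_ok) == 0) return("n = 0")
      if (ty == "skewed") {
        q <- stats::quantile(xs_ok, c(0.5, 0.25, 0.75), names = FALSE)
        sprintf("%.2f [%.2f, %.2f]", q[1], q[2], q[3])
      } else if (ty == "normal") {
        sprintf("%.1f ± %.1f", mean(xs_ok), stats::sd(xs_ok))
      } else {
        tab <- sort(table(xs_ok), decreasing = TRUE)
        sprintf("%s: %d (%.1f%%)", names(tab)[1], tab[1],
                100 * tab[1] / length(xs_ok))
      }
    }, character(1))
    p <- NA_real_; test <- NA_character_
    if (all(counts > 0)) {
      ok <- !is.na(x)
      if (ty == "skewed") {
        p <- stats::kruskal.test(x[ok], g[ok])$p.value
        test <- "kruskal-wallis"
      } else if (ty == "normal") {
        p <- summary(stats::aov(x[ok] ~ g[ok]))[[1]][["Pr(>F)"]][1]
        test <- "anova"
      } else {
        tab <- table(g[ok], x[ok])
        ch <- suppressWarnings(stats::chisq.test(tab))
        p <- ch$p.value
        test <- "chi-square"
      }
    }
    data.frame(variable = v, type = ty,
               none = summ[1], mild = summ[2], moderate_to_severe = summ[3],
               p_trend = p, test = test, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# covariate accumulation of the three progressive model tiers
.tier_covariates <- function(tier) {
  base <- c("site_tech", "age", "sex", "race")
  if (tier >= 2) base <- c(base, "height_cm", "weight_kg")
  if (tier >= 3) base <- c(base, "total_activity_count")
  base
}

# complete-case design for one exposure/tier; exposure standardized on the
# analytic rows and sign-flipped ("per 1 SD lower")
.build_design <- function(table, exposure, tier) {
  covs <- .tier_covariates(tier)
  need <- c("ppfi", "stratum", "sex", exposure, covs)
  cc <- stats::complete.cases(table[, unique(need)])
  d <- table[cc, , drop = FALSE]
  x <- d[[exposure]]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance in exposure ", exposure)
  zl <- -(x - mean(x)) / s
  mm <- stats::model.matrix(
    stats::reformulate(covs), data = d
  )
  Xcov <- mm[, -1, drop = FALSE]          # drop intercept; added separately
  ename <- paste0("z_", exposure, "_lower")
  X <- cbind(stats::setNames(data.frame(zl), ename), Xcov)
  X <- as.matrix(X)
  colnames(X)[1] <- ename
  list(y = d$ppfi, stratum = droplevels(d$stratum), X = X,
       exposure = ename, n = nrow(d), sd = s, rows = which(cc), data = d)
}

#' Fit the progressive tobit and ordinal model tiers for one exposure
#'
#' Model 1 adjusts for technician/site, age, sex and race; Model 2 adds
#' height and weight; Model 3 adds total activity count. For each tier the
#' continuous PPFI is fitted by tobit ML (with the exposure's partial
#' R-squared against the exposure-free reduced model) and the severity
#' strata by proportional-odds regression with the Brant–Wald diagnostic.
#' Rows with a missing exposure are dropped for that exposure only
#' (complete-case per exposure); the exposure is standardized on the
#' analytic rows and sign-flipped so estimates read per 1 SD lower.
#'
#' @param table A `cohort_table`.
#' @param exposure One of `max_oxphos`, `max_ets`, `atp_max` (or any
#'   numeric column).
#' @param tiers Which model tiers to fit.
#' @param ordinal Also fit the ordinal models (set `FALSE` to skip, e.g.
#'   in large simulation loops).
#' @return List of class `model_sequence`; per tier: `tobit`
#'   (`tobit_fit`), `partial_r2`, `ordinal` (`ordinal_fit` with Brant
#'   fields filled, or `NULL`), `n`.
#' @export
run_model_sequence <- function(table, exposure, tiers = 1:3, ordinal = TRUE) {
  out <- list()
  for (tier in tiers) {
    des <- .build_design(table, exposure, tier)
    Xfull <- cbind(`(Intercept)` = 1, des$X)
    tf <- tobit_fit(des$y, Xfull, exposure = des$exposure)
    Xred <- Xfull[, colnames(Xfull) != des$exposure, drop = FALSE]
    tr <- tobit_fit(des$y, Xred, exposure = NA)
    pr2 <- partial_r2(tf, tr)
    of <- NULL
    if (ordinal) {
      of <- ordinal_fit(des$stratum, des$X, exposure = des$exposure)
      bw <- brant_wald(des$stratum, des$X)
      of$brant_stat <- bw$statistic
      of$brant_df <- bw$df
      of$brant_p <- bw$p.value
    }
    out[[paste0("model", tier)]] <- list(tobit = tf, partial_r2 = pr2,
                                         ordinal = of, n = des$n,
                                         exposure_sd = des$sd)
  }
  structure(out, class = "model_sequence", exposure = exposure)
}

#' Tidy coefficient table of a model sequence
#'
#' @param seq A `model_sequence` from [run_model_sequence()].
#' @return Data frame with one row per tier: exposure beta, 95% CI,
#'   partial R-squared, odds ratio with CI, Brant statistics, n.
#' @export
tidy_model_sequence <- function(seq) {
  exposure <- attr(seq, "exposure")
  rows <- lapply(names(seq), function(nm) {
    m <- seq[[nm]]
    e <- m$tobit$exposure
    or <- if (!is.null(m$ordinal)) m$ordinal$or_per_sd else
      c(or = NA, lower = NA, upper = NA)
    data.frame(
      exposure = exposure, model = nm, n = m$n,
      beta = unname(m$tobit$beta[e]),
      ci_lo = unname(m$tobit$ci95[e, 1]), ci_hi = unname(m$tobit$ci95[e, 2]),
      partial_r2 = m$partial_r2,
      or = unname(or[1]), or_lo = unname(or[2]), or_hi = unname(or[3]),
      brant_stat = if (!is.null(m$ordinal)) m$ordinal$brant_stat else NA,
      brant_p = if (!is.null(m$ordinal)) m$ordinal$brant_p else NA,
      exposure_sd = m$exposure_sd,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Effect-modification and physical-function-stratified analyses
#'
#' Adds an exposure-by-modifier product term to the Model-3 tobit fit and
#' reports its Wald p-value; for the SPPB modifier, also fits separate
#' Model-3 tobits within the better- (SPPB >= 10) and worse-function
#' (SPPB < 10) strata.
#'
#' @param table A `cohort_table`.
#' @param exposure Exposure column name.
#' @param modifier `"sex"` or `"sppb_binary"` (SPPB dichotomized at >= 10).
#' @return List: `interaction_p`, `interaction_beta`, `fit` (the tobit fit
#'   with the product term) and, for `sppb_binary`, `stratified` — a list
#'   with `high`/`low` `tobit_fit`s (an element is `NULL`, with a warning,
#'   when its stratum is too small).
#' @export
interaction_and_strata <- function(table, exposure,
                                   modifier = c("sex", "sppb_binary")) {
  modifier <- match.arg(modifier)
  des <- .build_design(table, exposure, tier = 3)
  mod <- switch(modifier,
                sex = as.numeric(des$data$sex == "female"),
                sppb_binary = as.numeric(des$data$sppb >= 10))
  if (length(unique(mod)) < 2) stop("modifier is constant in the data")
  zl <- des$X[, des$exposure]
  Xint <- cbind(`(Intercept)` = 1, des$X,
                interaction = zl * mod)
  if (modifier == "sppb_binary") {
    Xint <- cbind(Xint, modifier_main = mod)
  }
  tf <- tobit_fit(des$y, Xint, exposure = des$exposure)
  b <- tf$beta["interaction"]; s <- tf$se["interaction"]
  pint <- 2 * stats::pnorm(-abs(b / s))

  out <- list(interaction_p = unname(pint), interaction_beta = unname(b),
              fit = tf)
  if (modifier == "sppb_binary") {
    strat <- list(high = NULL, low = NULL)
    for (lvl in c("high", "low")) {
      sel <- if (lvl == "high") mod == 1 else mod == 0
      nmin <- ncol(des$X) + 1 + 5
      if (sum(sel) < nmin) {
        warning("SPPB ", lvl, " stratum too small (n = ", sum(sel),
                "); stratified fit skipped")
        next
      }
      Xs <- cbind(`(Intercept)` = 1, des$X[sel, , drop = FALSE])
      keep <- c(TRUE, apply(des$X[sel, , drop = FALSE], 2,
                            function(col) stats::var(col) > 0))
      strat[[lvl]] <- tobit_fit(des$y[sel], Xs[, keep, drop = FALSE],
                                exposure = des$exposure)
    }
    out$stratified <- strat
  }
  out
}
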