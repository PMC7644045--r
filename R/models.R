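#' Standardized mean difference for a continuous variable
#'
#' \deqn{d = |m_a - m_b| / \sqrt{(s_a^2 + s_b^2)/2}}
#' Binary variables are treated as proportions with variance `p(1-p)` (see
#' [smd_binary()]).
#'
#' @param mean_a,sd_a,mean_b,sd_b group summaries (sds >= 0).
#' @return The absolute standardized difference; `NA` with a warning when
#'   both sds are 0 and the means differ.
#' @export
smd_continuous <- function(mean_a, sd_a, mean_b, sd_b) {
  stopifnot(sd_a >= 0, sd_b >= 0)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) {
    if (mean_a == mean_b) return(0)
    warning("undefined SMD: zero variance in both groups with unequal means")
    return(NA_real_)
  }
  abs(mean_a - mean_b) / pooled
}

#' @rdname smd_continuous
#' @param p_a,p_b group proportions.
#' @export
smd_binary <- function(p_a, p_b) {
  smd_continuous(p_a, sqrt(p_a * (1 - p_a)), p_b, sqrt(p_b * (1 - p_b)))
}

#' Standardized difference for a multi-level categorical variable
#'
#' Generalized (Mahalanobis-type) standardized difference over the first
#' `L - 1` levels, using the average of the two within-group multinomial
#' covariance matrices:
#' \deqn{d = \sqrt{T' S^{-1} T}, \quad T = p_a - p_b, \quad
#'       S = [\mathrm{Cov}(p_a) + \mathrm{Cov}(p_b)]/2}
#' With two levels this reduces exactly to [smd_binary()].
#'
#' @param freqs_a,freqs_b named frequency vectors over the same levels, each
#'   summing to 1.
#' @return The absolute generalized standardized difference.
#' @export
smd_categorical <- function(freqs_a, freqs_b) {
  if (!setequal(names(freqs_a), names(freqs_b)) || is.null(names(freqs_a)))
    stop("frequency vectors must be named over the same level set")
  freqs_b <- freqs_b[names(freqs_a)]
  if (abs(sum(freqs_a) - 1) > 1e-6 || abs(sum(freqs_b) - 1) > 1e-6)
    stop("frequency vectors must sum to 1")
  L <- length(freqs_a)
  if (L < 2) stop("need at least two levels")
  pa <- freqs_a[-L]; pb <- freqs_b[-L]
  Tvec <- pa - pb
  covm <- function(p) diag(p, nrow = length(p)) - outer(p, p)
  S <- (covm(pa) + covm(pb)) / 2
  sq <- tryCatch(drop(t(Tvec) %*% solve(S, Tvec)),
                 error = function(e) drop(t(Tvec) %*% MASS_ginv(S) %*% Tvec))
  sqrt(max(sq, 0))
}

# Moore-Penrose inverse via SVD (degenerate covariance fallback)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Maximum absolute standardized mean difference across team types
#'
#' Evaluates the SMD for every unordered pair of groups and reports the
#' maximum absolute value; 0.1 or greater is conventionally flagged as a
#' potentially meaningful imbalance.
#'
#' @param x the variable (numeric, logical, or factor/character for
#'   categorical).
#' @param group group labels (>= 2 distinct values).
#' @param variable variable name carried into the result.
#' @return An object of class `smd_result`: list with `variable`, `type`,
#'   `group_summaries`, `pairwise` (data.frame `group_a`, `group_b`, `smd`),
#'   `max_abs_smd`, `meaningful`.
#' @export
max_abs_smd <- function(x, group, variable = deparse(substitute(x))) {
  group <- as.character(group)
  ok <- !is.na(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]
  groups <- sort(unique(group))
  if (length(groups) < 2) stop("need at least two groups")
  categorical <- is.character(x) || is.factor(x)
  if (categorical) {
    x <- as.character(x)
    lv <- sort(unique(x))
    summ <- lapply(groups, function(g) {
      p <- table(factor(x[group == g], levels = lv)) / sum(group == g)
      stats::setNames(as.numeric(p), lv)
    })
  } else {
    x <- as.numeric(x)
    summ <- lapply(groups, function(g)
      c(mean = mean(x[group == g]), sd = stats::sd(x[group == g]),
        n = sum(group == g)))
  }
  names(summ) <- groups
  pairs <- utils::combn(groups, 2)
  smds <- apply(pairs, 2, function(pr) {
    a <- summ[[pr[1]]]; b <- summ[[pr[2]]]
    if (categorical) smd_categorical(a, b)
    else smd_continuous(a[["mean"]], a[["sd"]], b[["mean"]], b[["sd"]])
  })
  res <- list(variable = variable,
              type = if (categorical) "categorical" else "continuous",
              group_summaries = summ,
              pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                                    smd = smds, stringsAsFactors = FALSE),
              max_abs_smd = max(abs(smds)),
              meaningful = max(abs(smds)) >= 0.1)
  class(res) <- "smd_result"
  res
}

#' @export
print.smd_result <- function(x, ...) {
  cat(sprintf("SMD [%s, %s]: max |d| = %.4f%s\n", x$variable, x$type,
              x$max_abs_smd, if (x$meaningful) " (>= 0.1, meaningful)" else ""))
  invisible(x)
}

#' Covariate balance table across team types
#'
#' @param data data frame.
#' @param vars variable names to balance-check. Logical variables are treated
#'   as proportions, characters/factors as categorical, numerics as
#'   continuous.
#' @param group grouping column name (default `"team_type"`).
#' @return Data frame `variable`, `type`, `max_abs_smd`, `meaningful`.
#' @export
balance_table <- function(data, vars, group = "team_type") {
  rows <- lapply(vars, function(v) {
    r <- max_abs_smd(data[[v]], data[[group]], variable = v)
    data.frame(variable = v, type = r$type, max_abs_smd = r$max_abs_smd,
               meaningful = r$meaningful, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

GLMM_FAMILIES <- c("binomial_logit", "normal_identity", "negbin_log")

#' Practice-clustered random-intercept generalized linear mixed model
#'
#' Fits `outcome ~ team_type + covariates + (1 | cluster)` with a Gaussian
#' random intercept per practice. Binary outcomes use a binomial-logit model
#' estimated by adaptive Gauss-Hermite quadrature (`nAGQ` points); continuous
#' outcomes a linear mixed model by REML; counts a negative-binomial
#' log-link model (Laplace approximation). Team-type contrasts are reported
#' against the reference group as odds ratios (binomial), rate ratios and
#' adjusted means (negative binomial), or adjusted means (normal).
#'
#' @param data model data; one row per patient.
#' @param outcome outcome column name.
#' @param family one of `"binomial_logit"`, `"normal_identity"`,
#'   `"negbin_log"`.
#' @param covariates character vector of adjustment column names (may be
#'   empty).
#' @param cluster clustering column (default `"practice_id"`).
#' @param team_var team-type column (default `"team_type"`), reference level
#'   `ref`.
#' @param ref reference team (default `"PCP"`).
#' @param nAGQ quadrature points for the binomial family (default 7).
#' @param conf_level Wald confidence level (default 0.95).
#' @return An object of class `glmm_fit`: outcome, family, `coefficients`
#'   (link scale with Wald CIs), `team_effects` (response-scale contrasts
#'   and, for continuous/count families, adjusted means), variance components,
#'   `icc`, sample sizes, `converged`, `logLik`, and the underlying `model`.
#' @export
fit_glmm <- function(data, outcome, family = GLMM_FAMILIES,
                     covariates = character(0), cluster = "practice_id",
                     team_var = "team_type", ref = "PCP", nAGQ = 7,
                     conf_level = 0.95) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(data), cluster %in% names(data))
  use <- stats::complete.cases(data[, c(outcome, cluster, team_var, covariates)])
  d <- data[use, , drop = FALSE]
  if (length(unique(d[[cluster]])) < 2)
    stop("need at least two clusters to fit a random-intercept model")
  d[[team_var]] <- stats::relevel(factor(d[[team_var]]), ref = ref)
  rhs <- paste(c(team_var, covariates, sprintf("(1 | %s)", cluster)),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))

  fit <- switch(family,
    binomial_logit = lme4::glmer(form, data = d, family = stats::binomial(),
                                 nAGQ = nAGQ),
    normal_identity = lme4::lmer(form, data = d, REML = TRUE),
    negbin_log = lme4::glmer.nb(form, data = d))

  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) ||
    !any(grepl("failed to converge", unlist(msgs), ignore.case = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == cluster & vc$var1 == "(Intercept)"][1]
  s2e <- if (family == "normal_identity") stats::sigma(fit)^2 else NA_real_
  theta <- if (family == "negbin_log") lme4::getME(fit, "glmer.nb.theta")
           else NA_real_

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      std_error = unname(se),
                      ci_lower = unname(beta - z * se),
                      ci_upper = unname(beta + z * se),
                      stringsAsFactors = FALSE)

  team_terms <- grep(paste0("^", team_var), coefs$term, value = TRUE)
  te <- coefs[coefs$term %in% team_terms, ]
  te$group <- sub(paste0("^", team_var), "", te$term)
  if (family %in% c("binomial_logit", "negbin_log")) {
    te$ratio <- exp(te$estimate)
    te$ratio_lcl <- exp(te$ci_lower)
    te$ratio_ucl <- exp(te$ci_upper)
  }
  team_effects <- te[, setdiff(names(te), c("term"))]

  adjusted_means <- NULL
  if (family %in% c("normal_identity", "negbin_log")) {
    em <- emmeans::emmeans(fit, stats::as.formula(paste("~", team_var)),
                           type = "response")
    adjusted_means <- as.data.frame(summary(em, level = conf_level))
  }

  mu_hat <- mean(stats::fitted(fit))
  res <- list(outcome = outcome, family = family, coefficients = coefs,
              team_effects = team_effects, adjusted_means = adjusted_means,
              sigma2_practice = s2b, sigma2_residual = s2e, theta = theta,
              mean_response = mu_hat,
              n_patients = nrow(d),
              n_practices = length(unique(d[[cluster]])),
              converged = converged, convergence_messages = msgs,
              logLik = as.numeric(stats::logLik(fit)), model = fit)
  class(res) <- "glmm_fit"
  res$icc <- icc_glmm(res)$icc
  res
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("GLMM fit [%s, %s]: %d patients in %d practices%s\n",
              x$outcome, x$family, x$n_patients, x$n_practices,
              if (!x$converged) " (NOT CONVERGED)" else ""))
  cat(sprintf("  practice intercept variance %.4f, ICC %.4f\n",
              x$sigma2_practice, x$icc))
  print(x$team_effects, row.names = FALSE)
  invisible(x)
}

#' Intraclass correlation attributable to practices
#'
#' Share of outcome variance carried by the practice random intercept. For
#' the normal family this is \eqn{\sigma^2_b / (\sigma^2_b + \sigma^2_e)} on
#' the observed scale; for binomial-logit the latent-scale version with
#' residual variance \eqn{\pi^2/3}; for the negative binomial the
#' latent-scale version with a log-normal unit-level variance approximation
#' \eqn{\ln(1 + 1/\mu + 1/\theta)} (overridable via `unit_variance`).
#'
#' @param fit a `glmm_fit` (must have converged).
#' @param unit_variance optional override of the unit-level latent variance
#'   for the negative-binomial family.
#' @return List with `outcome`, `icc` in `[0, 1]` and `scale_note`
#'   (`"latent"` or `"observed"`).
#' @export
icc_glmm <- function(fit, unit_variance = NULL) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged)
    stop("ICC requested from a non-converged fit for '", fit$outcome, "'")
  s2b <- fit$sigma2_practice
  out <- switch(fit$family,
    normal_identity = list(icc = s2b / (s2b + fit$sigma2_residual),
                           scale_note = "observed"),
    binomial_logit = list(icc = s2b / (s2b + pi^2 / 3),
                          scale_note = "latent"),
    negbin_log = {
      uv <- if (!is.null(unit_variance)) unit_variance
            else log(1 + 1 / fit$mean_response + 1 / fit$theta)
      list(icc = s2b / (s2b + uv), scale_note = "latent")
    })
  list(outcome = fit$outcome, icc = out$icc, scale_note = out$scale_note)
}

#' Tidy one-row-per-term model results
#'
#' @param fit a `glmm_fit`.
#' @return Data frame mirroring a results-table layout: `outcome`, `term`,
#'   `estimate`, `lcl`, `ucl`, `family`, `icc`, `n_practices`, `n_patients`.
#'   Estimates are odds/rate ratios for log-link families and raw
#'   differences for the normal family.
#' @export
tidy_glmm <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  te <- fit$team_effects
  ratio <- fit$family %in% c("binomial_logit", "negbin_log")
  data.frame(outcome = fit$outcome,
             term = paste0("team_", te$group, "_vs_PCP"),
             estimate = if (ratio) te$ratio else te$estimate,
             lcl = if (ratio) te$ratio_lcl else te$ci_lower,
             ucl = if (ratio) te$ratio_ucl else te$ci_upper,
             family = fit$family, icc = fit$icc,
             n_practices = fit$n_practices, n_patients = fit$n_patients,
             stringsAsFactors = FALSE)
}
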