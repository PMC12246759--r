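#' OLS with town-clustered (CR1) robust standard errors
#'
#' Fits ordinary least squares and reports cluster-robust sandwich standard
#' errors with the CR1 small-sample factor
#' \eqn{G/(G-1) \cdot (N-1)/(N-K)} (the Stata `cluster()` convention), where
#' \eqn{G} is the number of clusters (towns), \eqn{N} the number of
#' observations and \eqn{K} the number of columns of the design matrix.
#' P-values use a t distribution with \eqn{G - 1} degrees of freedom, the
#' conservative convention for few-cluster inference.
#'
#' @param formula Model formula (intercept included unless removed
#'   explicitly).
#' @param data Data frame holding outcome, regressors and the cluster column.
#' @param cluster Name of the cluster (town id) column in `data`, or a vector
#'   of cluster labels of length `nrow(data)`.
#' @param type `"CR1"` (default) or `"CR0"` (no small-sample factor).
#' @return A list of class `cluster_ols`: `coefficients`, `robust_se`,
#'   `t_values`, `p_values` (all named by term), `vcov`, `r_squared`,
#'   `n_obs`, `n_clusters`, `df`, and the fitted `residuals`.
#' @examples
#' d <- data.frame(y = rnorm(40), x = rnorm(40), town = rep(letters[1:8], 5))
#' fit <- fit_ols_cluster(y ~ x, d, cluster = "town")
#' fit$robust_se
#' @export
fit_ols_cluster <- function(formula, data, cluster, type = c("CR1", "CR0")) {
  type <- match.arg(type)
  cl_all <- if (length(cluster) == 1L && is.character(cluster)) {
    if (!cluster %in% names(data)) stop("cluster column '", cluster, "' not in data")
    data[[cluster]]
  } else {
    if (length(cluster) != nrow(data)) stop("cluster vector length must match data")
    cluster
  }
  keep <- stats::complete.cases(data[intersect(all.vars(formula), names(data))])
  mf <- stats::model.frame(formula, data[keep, , drop = FALSE])
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit_ols_cluster_xy(y, X, cl_all[keep], type = type)
}

#' @rdname fit_ols_cluster
#' @param y Outcome vector.
#' @param X Design matrix (include the intercept column yourself).
#' @param cluster_ids Cluster labels, one per row of `X`.
#' @export
fit_ols_cluster_xy <- function(y, X, cluster_ids, type = c("CR1", "CR0")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  stopifnot(nrow(X) == n, length(cluster_ids) == n)
  cl <- as.character(cluster_ids)
  G <- length(unique(cl))
  if (G < 2L) stop("cluster-robust inference requires at least 2 clusters")

  qr_x <- qr(X)
  if (qr_x$rank < k) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - as.vector(X %*% beta)

  # sandwich: bread (X'X)^-1, meat sum_g (X_g' e_g)(X_g' e_g)'
  bread <- chol2inv(chol(crossprod(X)))
  scores <- rowsum(X * resid, cl)            # G x k matrix of cluster scores
  meat <- crossprod(scores)
  adj <- if (type == "CR1") G / (G - 1) * (n - 1) / (n - k) else 1
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))

  se <- sqrt(pmax(diag(V), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  df <- G - 1L
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)

  structure(
    list(
      coefficients = stats::setNames(as.vector(beta), colnames(X)),
      robust_se = stats::setNames(se, colnames(X)),
      t_values = stats::setNames(as.vector(tval), colnames(X)),
      p_values = stats::setNames(as.vector(pval), colnames(X)),
      vcov = V,
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      n_obs = n,
      n_clusters = G,
      df = df,
      residuals = resid,
      se_type = type
    ),
    class = "cluster_ols"
  )
}

#' @export
print.cluster_ols <- function(x, digits = 4, ...) {
  cat(sprintf(
    "OLS with %s town-clustered SEs (%d obs, %d clusters, R2 = %.3f)\n",
    x$se_type, x$n_obs, x$n_clusters, x$r_squared
  ))
  print(round(data.frame(
    estimate = x$coefficients,
    robust_se = x$robust_se,
    t = x$t_values,
    p = x$p_values
  ), digits))
  invisible(x)
}

#' Tidy a cluster_ols fit into a term-level data frame
#' @param fit A [fit_ols_cluster()] result.
#' @return Data frame with `term`, `estimate`, `robust_se`, `t`, `p`.
#' @export
tidy_cluster_ols <- function(fit) {
  stopifnot(inherits(fit, "cluster_ols"))
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    robust_se = unname(fit$robust_se),
    t = unname(fit$t_values),
    p = unname(fit$p_values),
    stringsAsFactors = FALSE
  )
}

#' One-tailed paired t test
#'
#' Classical paired t test on the within-pair differences, one-tailed; used to
#' assess the temporal stability of town fragmentation indices measured at two
#' time points.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by position.
#' @param alternative Direction of the alternative for `mean(a - b)`:
#'   `"greater"` (default) or `"less"`.
#' @return List with `t`, `p` (one-tailed), `df`, `mean_diff`.
#' @export
paired_t_one_tailed <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("paired t test degenerate: differences have zero variance")
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(
    t = unname(ht$statistic),
    p = ht$p.value,
    df = unname(ht$parameter),
    mean_diff = unname(ht$estimate)
  )
}

#' Predicted difference between two covariate profiles
#'
#' Linear effect contrast: `sum_term coef[term] * (a[term] - b[term])`, exact
#' linear algebra with no refit. Terms of the model not named in the profiles
#' are held equal across the two profiles and cancel. Used for worked-example
#' effects such as "highest-fragmentation platform user vs
#' lowest-fragmentation non-user".
#'
#' @param coefficients Named coefficient vector, or a `cluster_ols` fit.
#' @param profile_a,profile_b Named numeric vectors of covariate settings.
#'   Every name must be a model term; names present in only one profile
#'   default to 0 in the other.
#' @return A list of class `effect_contrast` with `predicted_difference` and
#'   the per-term `contributions`.
#' @export
predicted_contrast <- function(coefficients, profile_a, profile_b) {
  if (inherits(coefficients, "cluster_ols")) coefficients <- coefficients$coefficients
  terms_used <- union(names(profile_a), names(profile_b))
  if (length(terms_used) == 0L) stop("profiles name no terms")
  unknown <- setdiff(terms_used, names(coefficients))
  if (length(unknown) > 0L) {
    stop("term(s) not in the model: ", paste(unknown, collapse = ", "))
  }
  a <- stats::setNames(rep(0, length(terms_used)), terms_used)
  b <- a
  a[names(profile_a)] <- profile_a
  b[names(profile_b)] <- profile_b
  contrib <- coefficients[terms_used] * (a - b)
  structure(
    list(
      predicted_difference = sum(contrib),
      contributions = contrib,
      profile_a = a,
      profile_b = b
    ),
    class = "effect_contrast"
  )
}

#' @export
print.effect_contrast <- function(x, ...) {
  cat(sprintf("<effect_contrast: predicted difference %.4f>\n", x$predicted_difference))
  invisible(x)
}

#' Restrict analysis to towns with sufficient edge coverage
#'
#' Robustness subset: towns whose average edge coverage exceeds the threshold
#' strictly are retained; poorly covered crawls are more prone to biased
#' fragmentation estimates.
#'
#' @param town_coverage Named numeric vector: edge-coverage fraction per town.
#' @param threshold Coverage threshold (default 0.15).
#' @return Character vector of retained town ids, with attributes `n_retained`
#'   and `mean_coverage` (mean coverage of the retained set, `NaN` if empty).
#' @export
robustness_subset <- function(town_coverage, threshold = 0.15) {
  stopifnot(all(town_coverage >= 0 & town_coverage <= 1))
  keep <- town_coverage > threshold
  ids <- names(town_coverage)[keep]
  structure(
    ids,
    n_retained = sum(keep),
    mean_coverage = mean(town_coverage[keep])
  )
}
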