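#' Generalized estimating equations for repeated fetal scans
#'
#' Gaussian GEE with identity link for clustered observations (mothers with
#' up to two scans), the Liang-Zeger moment estimator for the working
#' correlation, and the robust (sandwich) covariance over clusters. With an
#' exchangeable working correlation any two scans of a mother share a common
#' correlation `alpha`; with singleton clusters (or `corstr =
#' "independence"`) the coefficients reduce exactly to ordinary least
#' squares. Rows with missing values in the outcome or covariates are dropped
#' (complete case), mirroring how scans without distress scores leave
#' distress-adjusted models.
#'
#' @param data Data frame of scans.
#' @param formula Model formula, e.g. `vol_wm ~ cohort + ga_mri_weeks + sex`.
#' @param id Name of the cluster (subject) column.
#' @param corstr Working correlation: exchangeable or independence.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param maxit Maximum number of Fisher-scoring iterations.
#' @return An object of class `gee_fit` with coefficients, robust covariance,
#'   two-sided Wald p-values, working-correlation estimate, and the model
#'   frame (for [ls_means()]).
#' @export
fit_gee <- function(data, formula, id = "subject_id",
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  stopifnot(is.data.frame(data))
  if (!id %in% names(data)) stop("cluster column not found: ", id, call. = FALSE)

  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, unique(c(vars, id)), drop = FALSE]
  complete <- stats::complete.cases(df[, vars, drop = FALSE])
  df <- df[complete, , drop = FALSE]

  mf <- stats::model.frame(formula, data = df)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  cluster <- as.character(df[[id]])
  n <- nrow(X)
  p <- ncol(X)
  clusters <- split(seq_len(n), cluster)
  n_clus <- length(clusters)
  if (n_clus < 2) stop("need at least 2 clusters after filtering", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient: ", paste(colnames(X), collapse = ", "),
         call. = FALSE)
  }
  if (var(y) == 0) {
    # constant outcome: slopes are exactly 0, intercept the constant
    beta <- c(y[1], rep(0, p - 1))
    names(beta) <- colnames(X)
    fit <- list(coefficients = beta, vcov = matrix(0, p, p,
                                                   dimnames = list(colnames(X), colnames(X))),
                alpha = 0, n_obs = n, n_clusters = n_clus, converged = TRUE,
                corstr = corstr, formula = formula, data = df, id = id,
                sigma2 = 0)
    class(fit) <- "gee_fit"
    return(fit)
  }

  # initial estimate: OLS
  beta <- qr.solve(X, y)
  alpha <- 0
  max_ni <- max(lengths(clusters))
  n_pairs <- sum(vapply(lengths(clusters), function(m) m * (m - 1) / 2,
                        numeric(1)))

  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - as.vector(X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable" && n_pairs > 0) {
      cross <- sum(vapply(clusters, function(ix) {
        ri <- r[ix]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, numeric(1)))
      alpha <- cross / ((n_pairs - p) * phi)
      if (n_pairs <= p) alpha <- cross / (n_pairs * phi)  # tiny designs
      alpha <- max(min(alpha, 0.99), -0.99 / max(max_ni - 1, 1))
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in clusters) {
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      m <- length(ix)
      if (m == 1 || alpha == 0) {
        Wyi <- yi
        WXi <- Xi
      } else {
        # (R^-1) x = (x - alpha/(1+(m-1)alpha) * sum(x)) / (1 - alpha)
        f <- alpha / (1 + (m - 1) * alpha)
        Wyi <- (yi - f * sum(yi)) / (1 - alpha)
        WXi <- (Xi - f * matrix(colSums(Xi), m, p, byrow = TRUE)) / (1 - alpha)
      }
      A <- A + crossprod(Xi, WXi)
      b <- b + crossprod(Xi, Wyi)
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("GEE did not converge in ", maxit, " iterations", call. = FALSE)
  }

  # robust sandwich covariance over clusters
  r <- y - as.vector(X %*% beta)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ix in clusters) {
    Xi <- X[ix, , drop = FALSE]
    ri <- r[ix]
    m <- length(ix)
    if (m == 1 || alpha == 0) {
      WXi <- Xi
      Wri <- ri
    } else {
      f <- alpha / (1 + (m - 1) * alpha)
      WXi <- (Xi - f * matrix(colSums(Xi), m, p, byrow = TRUE)) / (1 - alpha)
      Wri <- (ri - f * sum(ri)) / (1 - alpha)
    }
    A <- A + crossprod(Xi, WXi)
    g <- crossprod(WXi, ri)
    B <- B + tcrossprod(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  fit <- list(coefficients = beta, vcov = V, alpha = alpha,
              n_obs = n, n_clusters = n_clus, converged = converged,
              corstr = corstr, formula = formula, data = df, id = id,
              sigma2 = sum(r^2) / (n - p))
  class(fit) <- "gee_fit"
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (gaussian/identity,", x$corstr, "working correlation)\n")
  cat("  ", deparse(x$formula), "\n")
  cat("  ", x$n_obs, "scans in", x$n_clusters, "subjects; alpha =",
      signif(x$alpha, 3), "\n")
  print(tidy.gee_fit(x))
  invisible(x)
}

#' Tidy a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` (robust), `statistic`
#'   (Wald z), `p.value` (two-sided).
#' @importFrom generics tidy
#' @export tidy.gee_fit
#' @export
tidy.gee_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- ifelse(se > 0, x$coefficients / se, NA_real_)
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @export
generics::tidy

#' One-row model summary of a GEE fit
#'
#' @param x A `gee_fit`.
#' @param ... Unused.
#' @return Tibble with observation/cluster counts, the working-correlation
#'   estimate, residual variance, and convergence flag.
#' @importFrom generics glance
#' @export glance.gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_clusters = x$n_clusters, alpha = x$alpha,
    sigma2 = x$sigma2, converged = x$converged, corstr = x$corstr
  )
}

#' @export
generics::glance

#' Least-squares (adjusted) means per cohort
#'
#' Model predictions at the reference grid: every other covariate fixed at
#' its sample mean (factors at their sample proportions, via model-matrix
#' column means), evaluated at cohort = 0 and 1. With the identity link the
#' LS-mean difference equals the cohort coefficient exactly. Interaction
#' columns involving the grouping variable are rebuilt as (mean of the other
#' factor) x (group value).
#'
#' @param fit A `gee_fit` whose model contains `group_var`.
#' @param group_var Name of the 0/1 grouping covariate (default "cohort").
#' @param levels Values of the grouping variable to predict at.
#' @return Tibble with `group`, `lsmean`, `se` (delta method on the robust
#'   covariance).
#' @export
ls_means <- function(fit, group_var = "cohort", levels = c(0, 1)) {
  stopifnot(inherits(fit, "gee_fit"))
  mf <- stats::model.frame(fit$formula, data = fit$data)
  X <- stats::model.matrix(fit$formula, mf)
  cn <- colnames(X)
  if (!group_var %in% cn) {
    stop("model does not contain the grouping variable ", group_var, call. = FALSE)
  }
  xbar <- colMeans(X)
  is_inter <- grepl(":", cn) & vapply(strsplit(cn, ":"), function(parts) {
    group_var %in% parts
  }, logical(1))

  purrr::map_dfr(levels, function(g) {
    xg <- xbar
    xg[group_var] <- g
    for (ic in which(is_inter)) {
      others <- setdiff(strsplit(cn[ic], ":")[[1]], group_var)
      xg[ic] <- prod(xbar[others]) * g
    }
    est <- sum(xg * fit$coefficients)
    se <- sqrt(drop(t(xg) %*% fit$vcov %*% xg))
    tibble::tibble(group = g, lsmean = est, se = se)
  })
}
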