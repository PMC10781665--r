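# Beta-binomial engine: sampler, log-likelihood and per-taxon ML fitting.
#
# Parameterization throughout: counts C ~ Binomial(N, p) with
# p ~ Beta(a, b), a = mu (1 - rho) / rho, b = (1 - mu) (1 - rho) / rho,
# so E[C] = N mu and Var[C] = N mu (1 - mu) (1 + (N - 1) rho). rho in [0, 1)
# is the intra-sample correlation; rho = 0 degenerates to Binomial(N, mu).

#' Draw beta-binomial counts
#'
#' @param n_draws number of draws.
#' @param size number of trials `N` (positive integer, scalar or vector).
#' @param prob mean success probability in (0, 1).
#' @param rho overdispersion correlation in `[0, 1)`; 0 gives plain binomial.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer vector of length `n_draws`.
#' @export
sample_beta_binomial <- function(n_draws, size, prob, rho = 0, seed = NULL) {
  stopifnot(n_draws >= 0, all(size >= 1), all(prob > 0 & prob < 1))
  if (any(rho < 0) || any(rho >= 1))
    stop("rho must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    if (all(rho == 0)) {
      stats::rbinom(n_draws, size, prob)
    } else {
      a <- prob * (1 - rho) / rho
      b <- (1 - prob) * (1 - rho) / rho
      p <- stats::rbeta(n_draws, a, b)
      stats::rbinom(n_draws, size, p)
    }
  })
}

#' Build a niche-enrichment regression model
#'
#' Bundles the design matrix and the count/depth vectors for one taxon at one
#' site. The design always contains an intercept and the binary sample-type
#' indicator (1 = mucosa, 0 = lumen or gastric juice); subject covariates are
#' appended as given.
#'
#' @param counts integer vector `C` of taxon reads per sample.
#' @param depths integer vector `N` of library sizes per sample.
#' @param type binary vector, 1 = mucosa, 0 = lumen/gastric juice.
#' @param covariates optional numeric matrix or data frame of subject
#'   covariates (factors are expanded via [stats::model.matrix()]).
#' @return object of class `enrichment_model` with elements `X`, `C`, `N` and
#'   `type_col` (index of the sample-type column in `X`).
#' @export
enrichment_model <- function(counts, depths, type, covariates = NULL) {
  counts <- as.numeric(counts); depths <- as.numeric(depths)
  type <- as.numeric(type)
  stopifnot(length(counts) == length(depths),
            length(type) == length(counts))
  if (!all(type %in% c(0, 1)))
    stop("sample-type indicator must be binary (1 = mucosa)", call. = FALSE)
  if (any(counts < 0) || any(depths < counts))
    stop("need N >= C >= 0 elementwise", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, type = type)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
    chr <- vapply(cv, is.character, logical(1))
    cv[chr] <- lapply(cv[chr], factor)
    mm <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  structure(list(X = X, C = counts, N = depths, type_col = 2L),
            class = "enrichment_model")
}

#' Beta-binomial log-likelihood of a niche-enrichment model
#'
#' Evaluates `sum_i [ logChoose(N_i, C_i) + logBeta(C_i + a_i, N_i - C_i + b_i)
#' - logBeta(a_i, b_i) ]` with `p_i = logistic(x_i' beta)`,
#' `a_i = p_i (1 - rho) / rho`, `b_i = (1 - p_i)(1 - rho) / rho`. At
#' `rho = 0` the binomial log-likelihood limit is returned. Invalid parameter
#' corners yield `-Inf` rather than an error, so numerical optimizers stay
#' safe.
#'
#' @param beta coefficient vector matching the columns of `model$X`.
#' @param rho overdispersion correlation in `[0, 1)`.
#' @param model an `enrichment_model`.
#' @return scalar log-likelihood.
#' @export
betabinom_loglik <- function(beta, rho, model) {
  X <- model$X; C <- model$C; N <- model$N
  if (length(beta) != ncol(X) || !all(is.finite(beta)) ||
      !is.finite(rho) || rho < 0 || rho >= 1) {
    return(-Inf)
  }
  p <- stats::plogis(drop(X %*% beta))
  # below ~1e-8 the beta-binomial is binomial to well under double precision
  # of the lbeta differences, which would otherwise cancel catastrophically
  if (rho < 1e-8) return(sum(stats::dbinom(C, N, p, log = TRUE)))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  ll <- lchoose(N, C) + lbeta(C + a, N - C + b) - lbeta(a, b)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

#' Fit the beta-binomial logistic regression for one taxon
#'
#' Maximum-likelihood estimation of the coefficients and a single scalar
#' overdispersion `rho` per fit, by quasi-Newton optimization initialized from
#' a plain binomial logistic fit and `rho = 0.05`. `rho` is optimized on a
#' logit scale to respect its `(0, 1)` box. Standard errors come from the
#' inverse observed information at the optimum; the Wald p-value is the
#' two-sided normal tail for the sample-type coefficient.
#'
#' Complete separation or a singular information matrix never crashes: the fit
#' is returned with `converged = FALSE`, infinite `se` and `wald_p = 1`.
#'
#' @param model an `enrichment_model`.
#' @param rho_init initial overdispersion (default 0.05).
#' @return list with elements `beta` (named vector), `beta_type`, `se`,
#'   `wald_p`, `rho_hat`, `loglik`, `converged`.
#' @export
fit_taxon <- function(model, rho_init = 0.05) {
  X <- model$X; C <- model$C; N <- model$N
  if (length(unique(X[, model$type_col])) < 2)
    stop("need both sample types represented", call. = FALSE)
  if (sum(C) == 0)
    stop("all counts are zero; nothing to fit", call. = FALSE)
  g0 <- suppressWarnings(
    stats::glm.fit(X, cbind(C, N - C), family = stats::binomial()))
  beta0 <- g0$coefficients
  beta0[!is.finite(beta0)] <- 0
  obj <- function(theta) {
    k <- length(theta)
    betabinom_loglik(theta[-k], stats::plogis(theta[k]), model)
  }
  theta0 <- c(beta0, stats::qlogis(rho_init))
  fit <- try(stats::optim(theta0, obj, method = "BFGS",
                          control = list(fnscale = -1, maxit = 500),
                          hessian = TRUE), silent = TRUE)
  k <- ncol(X)
  failed <- inherits(fit, "try-error") || !all(is.finite(fit$par))
  se <- Inf; wald_p <- 1; converged <- FALSE
  beta <- stats::setNames(rep(NA_real_, k), colnames(X))
  rho_hat <- NA_real_; ll <- -Inf
  if (!failed) {
    beta <- stats::setNames(fit$par[seq_len(k)], colnames(X))
    rho_hat <- unname(stats::plogis(fit$par[k + 1]))
    ll <- fit$value
    info <- -fit$hessian
    cov <- try(solve(info), silent = TRUE)
    if (!inherits(cov, "try-error") &&
        all(is.finite(diag(cov))) && all(diag(cov) > 0)) {
      se <- sqrt(diag(cov))[model$type_col]
      wald_p <- 2 * stats::pnorm(-abs(beta[model$type_col] / se))
      converged <- fit$convergence == 0 && is.finite(se)
    }
  }
  list(beta = beta, beta_type = unname(beta[model$type_col]), se = unname(se),
       wald_p = unname(wald_p), rho_hat = rho_hat, loglik = ll,
       converged = converged)
}
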