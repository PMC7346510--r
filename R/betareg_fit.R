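#' Beta regression by maximum likelihood
#'
#' Fits a beta regression for a response strictly inside (0, 1) — here
#' the proportion of the night elapsed at take-off — with a logit link
#' for the mean and a constant precision \eqn{\phi}. The response is
#' modelled as \eqn{y_i \sim Beta(\mu_i\phi, (1-\mu_i)\phi)} with
#' \eqn{logit(\mu_i) = x_i'\beta}, and \eqn{(\beta, \log\phi)} maximise
#' the likelihood by quasi-Newton iteration (analytic gradient) from a
#' logit-scale least-squares warm start. Standard errors come from the
#' observed information at the optimum; the pseudo-R-squared is the
#' squared Pearson correlation between the fitted linear predictor and
#' the logit of the response.
#'
#' @param formula model formula for the mean, e.g.
#'   \code{proportion ~ species + stores}.
#' @param data data frame holding the variables.
#' @param tol convergence tolerance on the gradient norm.
#' @return An object of class \code{"beta_reg"} with components
#'   \code{coefficients} (mean model, logit scale), \code{se},
#'   \code{z}, \code{p}, \code{phi}, \code{phi_se}, \code{pseudo_r2},
#'   \code{loglik}, \code{vcov}, \code{fitted}, \code{linear_predictor},
#'   \code{y}, \code{x}, \code{n} and \code{converged}.
#' @seealso [summary.beta_reg()], [predict.beta_reg()],
#'   [simulate.beta_reg()]
#' @export
beta_reg <- function(formula, data, tol = 1e-8) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y <= 0 | y >= 1))
    stop("beta regression needs a response strictly inside (0, 1); ",
         "found values on or outside the boundary. Nocturnal departures ",
         "strictly between sunset and sunrise satisfy this by construction.")
  n <- length(y)
  if (n <= ncol(X)) stop("more parameters than observations")

  fit <- .beta_reg_ml(y, X, tol = tol)

  k <- ncol(X)
  se <- sqrt(diag(fit$vcov))[seq_len(k)]
  z <- fit$beta / se
  eta <- drop(X %*% fit$beta)
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    phi = fit$phi,
    phi_se = fit$phi * sqrt(fit$vcov[k + 1, k + 1]), # delta method from log(phi)
    pseudo_r2 = if (stats::sd(eta) == 0) NA_real_ else
      stats::cor(eta, stats::qlogis(y))^2,
    loglik = fit$loglik,
    vcov = fit$vcov,
    linear_predictor = eta,
    fitted = stats::plogis(eta),
    y = y, x = X, n = n,
    converged = fit$converged,
    call = match.call(), formula = formula
  ), class = "beta_reg")
}

# log-likelihood of the beta regression at (beta, log phi)
.beta_reg_ll <- function(par, y, X) {
  k <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(k)]))
  phi <- exp(par[k + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

.beta_reg_grad <- function(par, y, X) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(par[k + 1])
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y))
  c(gb, gphi * phi) # chain rule for log(phi)
}

.beta_reg_ml <- function(y, X, tol = 1e-8) {
  k <- ncol(X)
  # warm start: least squares on the logit scale; method-of-moments phi
  ols <- stats::lm.fit(X, stats::qlogis(y))
  mu0 <- stats::plogis(drop(X %*% ols$coefficients))
  v <- stats::var(y - mu0)
  phi0 <- max(1, mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1)
  par0 <- c(ols$coefficients, log(phi0))

  opt <- stats::optim(par0, fn = .beta_reg_ll, gr = .beta_reg_grad,
                      y = y, X = X, method = "BFGS", hessian = TRUE,
                      control = list(fnscale = -1, maxit = 500, reltol = 1e-14))
  gn <- sqrt(sum(.beta_reg_grad(opt$par, y, X)^2))
  if (gn > tol * max(1, abs(opt$value))) { # polish with a restart
    opt <- stats::optim(opt$par, fn = .beta_reg_ll, gr = .beta_reg_grad,
                        y = y, X = X, method = "BFGS", hessian = TRUE,
                        control = list(fnscale = -1, maxit = 500, reltol = 1e-14))
    gn <- sqrt(sum(.beta_reg_grad(opt$par, y, X)^2))
  }
  converged <- opt$convergence == 0 && gn < 1e-4 * max(1, abs(opt$value))
  if (!converged)
    stop("beta regression did not converge (gradient norm ", format(gn),
         ", optim code ", opt$convergence, ")")
  vcov <- tryCatch(solve(-opt$hessian), error = function(e)
    stop("observed information is singular at the optimum: ", conditionMessage(e)))
  list(beta = unname(opt$par[seq_len(k)]), phi = unname(exp(opt$par[k + 1])),
       loglik = opt$value, vcov = vcov, converged = converged)
}

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit mean link, ML)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, 4))
  cat("\nphi =", format(x$phi, digits = 4),
      " pseudo-R2 =", format(x$pseudo_r2, digits = 3),
      " logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Summarise a beta regression fit
#'
#' @param object a \code{"beta_reg"} fit.
#' @param ... unused.
#' @return A list of class \code{"summary.beta_reg"} with the
#'   coefficient table (estimate, SE, z, p), precision and pseudo-R2.
#' @export
summary.beta_reg <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(call = object$call, coefficients = tab,
                 phi = object$phi, phi_se = object$phi_se,
                 pseudo_r2 = object$pseudo_r2, loglik = object$loglik,
                 n = object$n),
            class = "summary.beta_reg")
}

#' @export
print.summary.beta_reg <- function(x, ...) {
  cat("Beta regression (logit mean link, ML), n =", x$n, "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nPrecision phi =", format(x$phi, digits = 4),
      "(SE", format(x$phi_se, digits = 3), ")\n")
  cat("pseudo-R2 =", format(x$pseudo_r2, digits = 3),
      " logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.beta_reg <- function(object, ...) object$coefficients

#' @export
logLik.beta_reg <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
vcov.beta_reg <- function(object, ...) object$vcov

#' Predict from a beta regression
#'
#' @param object a \code{"beta_reg"} fit.
#' @param newdata optional data frame; defaults to the fitting data.
#' @param type \code{"response"} for the mean of y, \code{"link"} for
#'   the linear predictor.
#' @param ... unused.
#' @export
predict.beta_reg <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$linear_predictor
  else drop(stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                                newdata) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.beta_reg <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "response") return(r)
  mu <- object$fitted
  r / sqrt(mu * (1 - mu) / (1 + object$phi))
}

#' @export
fitted.beta_reg <- function(object, ...) object$fitted

#' Simulate responses from a fitted beta regression
#'
#' @param object a \code{"beta_reg"} fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with \code{nsim} columns, as for
#'   \code{\link[stats]{simulate}} methods.
#' @export
simulate.beta_reg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- replicate(nsim, stats::rbeta(length(mu), mu * object$phi,
                                      (1 - mu) * object$phi), simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}
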