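## Efron partial likelihood machinery on counting-format data ----------------
## Risk set at event time t: intervals with start < t <= stop.
## For tied events (d deaths at t), Efron's correction subtracts the tied
## subjects' weights in d graded steps.

cox_loglik <- function(beta, X, risk, death, ties = "efron") {
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)          # guard overflow; cancels in ratios
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  wX <- w * X
  for (k in seq_along(risk)) {
    R <- risk[[k]]; D <- death[[k]]
    d <- length(D)
    sR <- sum(w[R]);              sD <- sum(w[D])
    xR <- colSums(wX[R, , drop = FALSE])
    xD <- colSums(wX[D, , drop = FALSE])
    xxR <- crossprod(X[R, , drop = FALSE], wX[R, , drop = FALSE])
    xxD <- crossprod(X[D, , drop = FALSE], wX[D, , drop = FALSE])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      frac <- if (ties == "breslow") 0 else l / d
      phi <- sR - frac * sD
      sx <- xR - frac * xD
      sxx <- xxR - frac * xxD
      ll <- ll - log(phi)
      grad <- grad - sx / phi
      hess <- hess - (sxx / phi - tcrossprod(sx / phi))
    }
    grad <- grad + colSums(X[D, , drop = FALSE])
  }
  list(loglik = ll, grad = grad, hess = hess)
}

cox_newton <- function(X, risk, death, tol = 1e-8, max_iter = 50,
                       allow_nonconverge = FALSE, ties = "efron") {
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_loglik(beta, X, risk, death, ties)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(cur$grad^2)) < tol)
      return(list(beta = beta, fit = cur, iterations = it - 1L,
                  converged = TRUE))
    step <- tryCatch(solve(-cur$hess, cur$grad), error = function(e) NULL)
    if (is.null(step)) {
      if (allow_nonconverge)
        return(list(beta = beta, fit = cur, iterations = it - 1L,
                    converged = FALSE))
      stop("singular information matrix; check for redundant covariate levels")
    }
    ## step halving if the likelihood does not improve; the acceptance
    ## margin scales with |loglik| so floating-point noise near the
    ## optimum cannot veto full Newton steps
    lambda <- 1
    margin <- 1e-9 * (abs(cur$loglik) + 1)
    repeat {
      cand <- beta + lambda * step
      new <- cox_loglik(cand, X, risk, death, ties)
      if (new$loglik >= cur$loglik - margin || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    cur <- new
    trace <- c(trace, cur$loglik)
  }
  if (sqrt(sum(cur$grad^2)) < tol || allow_nonconverge)
    return(list(beta = beta, fit = cur, iterations = max_iter,
                converged = sqrt(sum(cur$grad^2)) < tol))
  stop("Newton-Raphson failed to converge after ", max_iter,
       " iterations; log-likelihood trace: ",
       paste(signif(trace, 8), collapse = ", "))
}

#' Fit a Cox proportional-hazards model on counting-format records
#'
#' Maximises the counting-process partial likelihood with Efron's
#' correction for tied event times by Newton-Raphson (gradient norm below
#' `tol` or `max_iter` iterations, with step halving). Covariates given as
#' factors are expanded to indicator columns against their reference
#' (first) level: the lowest abundance bin, the lowest IndVal bin and
#' hitting-set non-membership carry no coefficient. Wald inference:
#' `z = coef / se`, two-tailed normal p-values, 95% CIs as
#' `exp(coef +/- 1.96 se)`.
#'
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @param records data.frame with `start`, `stop`, `event` columns (from
#'   [build_loss_records()] or [build_deposition_records()], or any
#'   counting-format table).
#' @param covariates column names to include; factors expand to indicator
#'   terms, logicals to a TRUE indicator, numerics enter as is.
#' @param tol,max_iter Newton-Raphson controls.
#' @return a `microtrace_coxfit` with coefficients, standard errors, hazard
#'   ratios, CIs, Wald z and p, log partial likelihood, counts, and an
#'   `unstable` flag per coefficient (complete separation: a level whose
#'   intervals are all or never event intervals, or a diverging estimate).
#' @export
cox_fit <- function(records, covariates = c("abund_bin", "indval_bin", "hs_member"),
                    ties = c("efron", "breslow"), tol = 1e-8, max_iter = 50) {
  ties <- match.arg(ties)
  stopifnot(all(c("start", "stop", "event") %in% names(records)))
  if (any(records$start >= records$stop)) stop("intervals must satisfy start < stop")
  if (sum(records$event) < 1) stop("no events in records")
  missing <- setdiff(covariates, names(records))
  if (length(missing)) stop("missing covariate column(s): ",
                            paste(missing, collapse = ", "))

  cols <- list()
  for (cv in covariates) {
    x <- records[[cv]]
    if (is.factor(x)) {
      for (lev in levels(x)[-1])
        cols[[paste0(cv, ":", lev)]] <- as.numeric(x == lev)
    } else if (is.logical(x)) {
      cols[[paste0(cv, ":TRUE")]] <- as.numeric(x)
    } else {
      cols[[cv]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  keep <- apply(X, 2, function(c) stats::var(c) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    message("dropping constant covariate column(s): ",
            paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no varying covariate columns")

  times <- sort(unique(records$stop[records$event == 1]))
  risk <- lapply(times, function(t) which(records$start < t & t <= records$stop))
  death <- lapply(times, function(t) which(records$event == 1 & records$stop == t))

  ## separation pre-check: an indicator constant among event intervals while
  ## varying overall has a monotone partial likelihood; fit best-effort and
  ## flag instead of failing
  ev <- records$event == 1
  separated <- vapply(seq_len(ncol(X)), function(j) {
    xv <- X[, j]
    all(xv[ev] == xv[ev][1]) && stats::var(xv) > 0 && all(xv %in% c(0, 1))
  }, logical(1))

  nr <- cox_newton(X, risk, death, tol, max_iter,
                   allow_nonconverge = any(separated), ties = ties)
  beta <- nr$beta
  info <- -nr$fit$hess
  vcov <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  se <- sqrt(pmax(diag(vcov), 0))
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))

  unstable <- separated | abs(beta) > 15
  if (any(unstable))
    warning("possible complete separation; unstable coefficient(s): ",
            paste(colnames(X)[unstable], collapse = ", "))

  z <- beta / se
  structure(list(coefficients = beta, se = se, vcov = vcov,
                 hazard_ratio = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 z = z, p = 2 * pnorm(-abs(z)),
                 loglik = nr$fit$loglik,
                 n = length(unique(if ("subject" %in% names(records))
                   records$subject else seq_len(nrow(records)))),
                 nevent = sum(records$event),
                 iterations = nr$iterations, converged = nr$converged,
                 unstable = unstable, dropped = dropped),
            class = "microtrace_coxfit")
}

#' @export
print.microtrace_coxfit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (Efron ties): %d subjects, %d events\n",
              x$n, x$nevent))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = x$hazard_ratio,
                    se = x$se, z = x$z, p = x$p, check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("log partial likelihood: %.4f (%d iterations)\n",
              x$loglik, x$iterations))
  invisible(x)
}

#' @export
summary.microtrace_coxfit <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             coef = object$coefficients,
             hazard_ratio = object$hazard_ratio,
             ci_lower = object$ci_lower, ci_upper = object$ci_upper,
             se = object$se, z = object$z, p = object$p,
             unstable = object$unstable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
coef.microtrace_coxfit <- function(object, ...) object$coefficients

#' @export
vcov.microtrace_coxfit <- function(object, ...) object$vcov

#' @export
confint.microtrace_coxfit <- function(object, parm, level = 0.95, ...) {
  q <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Combined hazard-ratio report across the three model families
#'
#' @param skin_loss,surface_loss,deposition fits from [cox_fit()].
#' @return data.frame with `model`, `term`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `z`, `p`, `significant` (two-tailed p < 0.05).
#' @export
hazard_report <- function(skin_loss, surface_loss, deposition) {
  fits <- list(skin_loss = skin_loss, surface_loss = surface_loss,
               deposition = deposition)
  rows <- lapply(names(fits), function(nm) {
    s <- summary(fits[[nm]])
    data.frame(model = nm, term = s$term, hazard_ratio = s$hazard_ratio,
               ci_lower = s$ci_lower, ci_upper = s$ci_upper,
               z = s$z, p = s$p, significant = s$p < 0.05,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
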