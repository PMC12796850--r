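# Cox partial likelihood machinery (Efron tie handling), written directly
# on the (time, status, X) representation of gap-time risk intervals.
# Evaluation walks event times in decreasing order, growing the risk-set
# sums S0 = sum w, S1 = sum w x, S2 = sum w x x' incrementally, so one
# (loglik, score, information) evaluation is O(n p^2).

cox_eval <- function(time, status, X, beta) {
  n <- length(time); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)            # guard overflow; cancels in all ratios
  w <- exp(eta)
  o <- order(-time, status)        # decreasing time
  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t_i <- time[o[i]]
    j <- i
    while (j <= n && time[o[j]] == t_i) j <- j + 1L
    blk <- o[i:(j - 1L)]
    for (k in blk) {
      xk <- X[k, ]
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * xk
      S2 <- S2 + w[k] * tcrossprod(xk)
    }
    D <- blk[status[blk] == 1L]
    d <- length(D)
    if (d > 0) {
      S0d <- sum(w[D])
      Xd <- X[D, , drop = FALSE]
      S1d <- colSums(Xd * w[D])
      S2d <- crossprod(Xd * sqrt(w[D]))
      loglik <- loglik + sum(eta[D])
      score <- score + colSums(Xd)
      for (r in seq_len(d) - 1L) {
        f <- r / d
        Z <- S0 - f * S0d
        M <- (S1 - f * S1d) / Z
        loglik <- loglik - log(Z)
        score <- score - M
        info <- info + (S2 - f * S2d) / Z - tcrossprod(M)
      }
    }
    i <- j
  }
  # the max-shift of eta cancels exactly: each event time contributes d
  # shifted linear terms and d shifted log(Z) terms
  list(loglik = loglik, score = score, info = info)
}

# Newton-Raphson with step-halving on a (possibly penalized) Cox partial
# likelihood. `penalty` is a diagonal precision vector (0 = unpenalized).
cox_newton <- function(time, status, X, penalty = NULL, beta0 = NULL,
                       tol = 1e-8, max_iter = 50, divergence_limit = 15) {
  p <- ncol(X)
  if (is.null(penalty)) penalty <- numeric(p)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  pen_ll <- function(ev, b) ev$loglik - sum(penalty * b^2) / 2
  ev <- cox_eval(time, status, X, beta)
  ll <- pen_ll(ev, beta)
  iter <- 0L; converged <- FALSE
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- ev$score - penalty * beta
    H <- ev$info + diag(penalty, p)
    step <- tryCatch(solve(H, U), error = function(e) {
      solve(H + diag(1e-8, p), U)
    })
    halv <- 0L
    repeat {
      beta_new <- beta + step
      ev_new <- cox_eval(time, status, X, beta_new)
      ll_new <- pen_ll(ev_new, beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      halv <- halv + 1L
      if (halv > 30L) break
    }
    delta <- ll_new - ll
    beta <- beta_new; ev <- ev_new; ll <- ll_new
    trace <- c(trace, ll)
    if (max(abs(beta[penalty == 0])) > divergence_limit) {
      stop(sprintf(paste0("Cox partial likelihood appears monotone (|beta| > %g ",
                          "after %d iterations): no finite MLE; check for a ",
                          "covariate that perfectly separates events"),
                   divergence_limit, iter))
    }
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, loglik = ll, unpenalized_loglik = ev$loglik,
       score = ev$score - penalty * beta,
       info = ev$info + diag(penalty, p),
       info_unpen = ev$info,
       iter = iter, converged = converged, trace = trace)
}

# Build the fixed-effects design matrix from risk intervals: treatment
# coding of `unit` against the reference plus the body-weight covariate.
cox_design <- function(intervals, reference_level = NULL) {
  stopifnot(all(c("unit", "event") %in% names(intervals)))
  time <- if (!is.null(intervals$time)) intervals$time else intervals$t_stop - intervals$t_start
  if (any(time <= 0)) stop("non-positive interval duration")
  unit <- as.character(intervals$unit)
  if (is.null(reference_level)) {
    # default reference: the jurisdiction with the highest empirical
    # crossing rate (events per day at risk), so all HRs are <= ~1
    rate <- vapply(split(seq_along(unit), unit),
                   function(ii) sum(intervals$event[ii]) / sum(time[ii]), numeric(1))
    reference_level <- names(rate)[which.max(rate)]
  }
  if (!reference_level %in% unit) stop("reference level not present in data")
  lev <- c(reference_level, setdiff(sort(unique(unit)), reference_level))
  X <- if (length(lev) > 1) {
    vapply(lev[-1], function(l) as.numeric(unit == l), numeric(length(unit)))
  } else {
    matrix(numeric(0), nrow = length(unit), ncol = 0)
  }
  if (!is.matrix(X)) X <- matrix(X, ncol = length(lev) - 1)
  if (ncol(X)) colnames(X) <- paste0("unit", lev[-1])
  if (!is.null(intervals$weight_kg) && !all(is.na(intervals$weight_kg))) {
    X <- cbind(X, weight_kg = intervals$weight_kg)
  }
  if (!ncol(X)) stop("no covariates: single jurisdiction and no weight")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("degenerate covariate(s) with zero variance: ",
         paste(colnames(X)[v == 0], collapse = ", "))
  }
  list(time = time, status = as.integer(intervals$event), X = X,
       reference = reference_level, levels = lev)
}

#' Cox proportional-hazards model for cross-boundary hazard (fixed effects)
#'
#' Fits h(t) = h0(t) exp(b1 X1 + b2 X2) by maximizing the Cox partial
#' likelihood with Efron tie handling by Newton-Raphson, where X1 is the
#' departure management jurisdiction (treatment-coded against a reference
#' level) and X2 the animal's body weight at tagging. Standard errors come
#' from the observed information at the optimum; hazard ratios are
#' exp(beta).
#'
#' @param intervals risk-interval data.frame from [build_risk_intervals()]
#'   (columns `unit`, `event`, `weight_kg`, and `time` or
#'   `t_start`/`t_stop`).
#' @param reference_level jurisdiction used as the reference; default is
#'   the unit with the highest empirical crossing rate (events per day at
#'   risk), so that all other jurisdictions are compared against the one
#'   seals were most likely to leave.
#' @param tol convergence tolerance on the change in log partial
#'   likelihood (default 1e-8).
#' @param max_iter maximum Newton-Raphson iterations (default 50), with
#'   step-halving on any likelihood decrease.
#' @return object of class `cox_fit` with elements `coefficients`, `se`,
#'   `hr`, `z`, `p_value`, `vcov`, `loglik`, `reference`, `sigma2_b`
#'   (NULL for the fixed model), `converged`, `iter`.
#' @seealso [cox_frailty()] for the per-seal Gaussian random-intercept
#'   version.
#' @export
cox_fixed <- function(intervals, reference_level = NULL, tol = 1e-8,
                      max_iter = 50) {
  d <- cox_design(intervals, reference_level)
  fit <- cox_newton(d$time, d$status, d$X, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    stop("cox_fixed did not converge in ", max_iter,
         " iterations; last loglik trace: ",
         paste(format(utils::tail(fit$trace, 5)), collapse = ", "))
  }
  V <- solve(fit$info)
  new_cox_fit(beta = stats::setNames(fit$beta, colnames(d$X)), vcov = V,
              loglik = fit$loglik, reference = d$reference,
              n = length(d$time), n_events = sum(d$status),
              iter = fit$iter, sigma2_b = NULL, frailty = NULL,
              model = "fixed")
}

#' Cox proportional-hazards model with Gaussian per-seal frailty
#'
#' Fits h(t) = h0(t) exp(b1 X1 + b2 X2 + b) where b is a Gaussian random
#' intercept per seal on the log hazard, accounting for individual
#' variability and repeated spells per animal. For a given frailty
#' variance the fixed and random effects maximize the penalized partial
#' likelihood (Efron ties, Newton-Raphson on the joint parameter with
#' penalty b'b / (2 sigma^2)); the variance itself maximizes the
#' Laplace-approximate integrated likelihood, profiled by a 1-D search
#' over log(sigma^2).
#'
#' @inheritParams cox_fixed
#' @param sigma2_interval search interval for the frailty variance
#'   (default `c(1e-6, 100)`), searched on the log scale.
#' @return object of class `cox_fit`; `sigma2_b` holds the estimated
#'   frailty variance and `frailty` the per-seal random effects (modes).
#'   If the profile maximum collapses below 1e-8 the fixed-effects fit is
#'   returned with `sigma2_b = 0` and a note.
#' @export
cox_frailty <- function(intervals, reference_level = NULL, tol = 1e-8,
                        max_iter = 50, sigma2_interval = c(1e-6, 100)) {
  stopifnot(!is.null(intervals$seal_id))
  d <- cox_design(intervals, reference_level)
  id <- factor(intervals$seal_id)
  if (nlevels(id) < 2) stop("frailty model needs at least two seals")
  Z <- stats::model.matrix(~ id - 1)
  colnames(Z) <- levels(id)
  XZ <- cbind(d$X, Z)
  p <- ncol(d$X); q <- ncol(Z)

  profile <- function(log_s2, beta0 = NULL) {
    s2 <- exp(log_s2)
    penalty <- c(numeric(p), rep(1 / s2, q))
    fit <- cox_newton(d$time, d$status, XZ, penalty = penalty, beta0 = beta0,
                      tol = tol, max_iter = max_iter)
    Hbb <- fit$info[(p + 1):(p + q), (p + 1):(p + q)]
    ld <- as.numeric(determinant(Hbb, logarithm = TRUE)$modulus)
    # Laplace: log int exp(l(b)) N(b; 0, s2 I) db
    #   ~= l_pen(b_hat) - (q/2) log(s2) - (1/2) logdet(H_pen_bb)
    list(ill = fit$loglik - (q / 2) * log(s2) - ld / 2, fit = fit)
  }

  warm <- NULL
  obj <- function(ls2) {
    pr <- profile(ls2, beta0 = warm)
    warm <<- pr$fit$beta
    pr$ill
  }
  opt <- stats::optimize(obj, interval = log(sigma2_interval), maximum = TRUE,
                         tol = 1e-4)
  s2_hat <- exp(opt$maximum)
  note <- NULL
  if (s2_hat < 1e-8 ||
      profile(log(sigma2_interval[1]))$ill >= opt$objective - 1e-6) {
    # variance collapses to the boundary: no detectable heterogeneity
    fx <- cox_fixed(intervals, reference_level = d$reference, tol = tol,
                    max_iter = max_iter)
    fx$sigma2_b <- 0
    fx$note <- "frailty variance collapsed to 0; returning fixed-effects fit"
    fx$model <- "frailty"
    return(fx)
  }
  pr <- profile(log(s2_hat))
  fit <- pr$fit
  if (!fit$converged) {
    stop("cox_frailty inner Newton-Raphson did not converge; trace: ",
         paste(format(utils::tail(fit$trace, 5)), collapse = ", "))
  }
  Vfull <- solve(fit$info)
  V <- Vfull[seq_len(p), seq_len(p), drop = FALSE]
  new_cox_fit(beta = stats::setNames(fit$beta[seq_len(p)], colnames(d$X)),
              vcov = V, loglik = fit$loglik, reference = d$reference,
              n = length(d$time), n_events = sum(d$status),
              iter = fit$iter, sigma2_b = s2_hat,
              frailty = stats::setNames(fit$beta[(p + 1):(p + q)], colnames(Z)),
              model = "frailty", integrated_loglik = opt$objective)
}

new_cox_fit <- function(beta, vcov, loglik, reference, n, n_events, iter,
                        sigma2_b, frailty, model, integrated_loglik = NULL) {
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(coefficients = beta, se = se, hr = exp(beta), z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), vcov = vcov,
                 loglik = loglik, integrated_loglik = integrated_loglik,
                 reference = reference, n = n, n_events = n_events,
                 iter = iter, sigma2_b = sigma2_b, frailty = frailty,
                 model = model, note = NULL),
            class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Per-seal random effects of a frailty fit
#' @param object a `cox_fit` from [cox_frailty()].
#' @param ... unused.
#' @return named numeric vector of per-seal log-hazard offsets (modes).
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.cox_fit <- function(object, ...) object$frailty

#' Coefficient table of a Cox fit
#'
#' @param object a `cox_fit`.
#' @param ... unused.
#' @return data.frame with columns `term`, `beta`, `exp_beta`, `se`, `z`,
#'   `p` (the usual hazard-ratio table layout).
#' @export
summary.cox_fit <- function(object, ...) {
  tab <- data.frame(term = names(object$coefficients),
                    beta = unname(object$coefficients),
                    exp_beta = unname(object$hr), se = unname(object$se),
                    z = unname(object$z), p = unname(object$p_value))
  structure(list(table = tab, model = object$model,
                 reference = object$reference, sigma2_b = object$sigma2_b,
                 loglik = object$loglik, n = object$n,
                 n_events = object$n_events, note = object$note),
            class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards (%s effects), reference level: %s\n",
              x$model, x$reference))
  cat(sprintf("%d risk intervals, %d cross-boundary events\n", x$n, x$n_events))
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = digits)
  print(tab, digits = digits, row.names = FALSE)
  if (!is.null(x$sigma2_b)) {
    cat(sprintf("Frailty (seal ID) variance sigma^2_b = %.4g\n", x$sigma2_b))
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
print.cox_fit <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}

#' Serialize a Cox fit to JSON
#'
#' Writes the coefficient table (beta, exp(beta), SE, z, p), reference
#' level, frailty variance and per-seal effects to a JSON file.
#'
#' @param fit a `cox_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cox_json <- function(fit, path) {
  s <- summary(fit)
  jsonlite::write_json(list(model = s$model, reference = s$reference,
                            coefficients = s$table, sigma2_b = s$sigma2_b,
                            frailty = as.list(fit$frailty %||% list()),
                            loglik = s$loglik, n = s$n, n_events = s$n_events),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
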