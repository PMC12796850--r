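#' Kaplan-Meier curves for time to boundary crossing
#'
#' Product-limit estimate of the probability that a seal at risk in a
#' jurisdiction has not yet performed a cross-boundary haul-out by gap
#' time t: S(t) = prod over event times t_i <= t of (1 - d_i / n_i).
#' Greenwood's formula supplies the variance.
#'
#' @param intervals data.frame of risk intervals with columns `event` and
#'   either `time` or (`t_start`, `t_stop`) — duration is
#'   `t_stop - t_start`.
#' @param group_by optional column name to stratify by (e.g. `"unit"`);
#'   `NULL` fits a single pooled curve. Groups with zero intervals are
#'   skipped with a warning.
#' @return object of class `km_curve_list`: a named list of `km_curve`
#'   objects, each with `group`, `time` (distinct event times), `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `se` (Greenwood), and `median`.
#' @examples
#' d <- data.frame(time = c(5, 10, 15, 20, 25), event = c(0, 1, 1, 0, 1))
#' km <- km_fit(d)
#' km[[1]]$surv     # 0.75 at t = 10, 0.50 at t = 15
#' median_survival(km[[1]])
#' @export
km_fit <- function(intervals, group_by = NULL) {
  stopifnot(is.data.frame(intervals), !is.null(intervals$event))
  time <- if (!is.null(intervals$time)) intervals$time else intervals$t_stop - intervals$t_start
  if (any(time <= 0)) stop("non-positive interval duration")
  grp <- if (is.null(group_by)) rep("all", length(time)) else as.character(intervals[[group_by]])
  curves <- lapply(split(seq_along(time), grp), function(ii) {
    km_one(time[ii], intervals$event[ii], grp[ii[1]])
  })
  structure(curves, class = "km_curve_list")
}

km_one <- function(time, status, group) {
  o <- order(time)
  time <- time[o]; status <- as.integer(status[o])
  ut <- sort(unique(time[status == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & status == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & status == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  cur <- structure(list(group = group, time = ut, n_risk = n_risk,
                        n_event = n_event, n_censor = n_censor,
                        surv = surv, se = se, n = length(time),
                        median = NA_real_),
                   class = "km_curve")
  cur$median <- median_survival(cur)
  cur
}

#' Median time to boundary crossing from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param curve a `km_curve` object.
#' @return numeric days, or `NA`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5)
  if (!length(hit)) NA_real_ else curve$time[hit[1]]
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `km_curve`.
#' @param t numeric times.
#' @return step-function values S(t).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(ti) {
    i <- which(curve$time <= ti)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve [%s]: %d at risk, %d crossings, median %s days\n",
              x$group, x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median, digits = 4)))
  invisible(x)
}

#' @export
print.km_curve_list <- function(x, ...) {
  for (cur in x) print(cur)
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  data.frame(group = rep(object$group, length(object$time)), time = object$time,
             n_risk = object$n_risk, n_event = object$n_event,
             surv = object$surv, se = object$se)
}

#' @export
as.data.frame.km_curve_list <- function(x, ...) {
  out <- do.call(rbind, lapply(x, summary))
  rownames(out) <- NULL
  out
}

#' @export
plot.km_curve_list <- function(x, col = seq_along(x), xlab = "Days",
                               ylab = "P(no cross-boundary haul-out)", ...) {
  xmax <- max(unlist(lapply(x, function(c) max(c(c$time, 1)))))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x)) {
    cur <- x[[i]]
    graphics::lines(stats::stepfun(cur$time, c(1, cur$surv)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = vapply(x, `[[`, "", "group"),
                   col = col, lty = 1, bty = "n")
  invisible(x)
}
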