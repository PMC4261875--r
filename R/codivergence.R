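#' Extract codivergent branch pairs from a reconciliation
#'
#' Walks the virus tree and emits one pair per virus branch that traces a
#' joint virus-host history: the parent end of the branch must be a
#' cospeciation event, and the child end must be either another
#' cospeciation event or an associated tip. Each pair couples the virus
#' branch length (amino-acid substitutions/site) with the host duration
#' spanned by the corresponding host nodes (parent host-node age minus
#' child host-node age, in Myr). Branches whose child end is a duplication
#' or switch event are excluded — those branches do not track host time.
#' The virus root branch has no parent event and is never emitted.
#'
#' @param recon An [reconcile()] result produced from these trees.
#' @param vtree,htree The trees used for the reconciliation.
#' @param ages A [node_ages()] table for the host tree (tips default to 0).
#' @return A data frame of class \code{branch_pairs} with columns
#'   \code{virus_branch}, \code{host_branch},
#'   \code{virus_branch_length}, \code{host_duration}.
#' @export
extract_branch_pairs <- function(recon, vtree, htree, ages) {
  stopifnot(inherits(recon, "fv_reconciliation"), inherits(vtree, "phylo"),
            inherits(htree, "phylo"), inherits(ages, "node_ages"))
  if (is.null(vtree$edge.length))
    stop("virus tree has no branch lengths", call. = FALSE)
  ev <- recon$events
  ntip_v <- length(vtree$tip.label)
  host_of <- ev$host_node[match(seq_len(ntip_v + vtree$Nnode), ev$virus_node)]
  event_of <- ev$event[match(seq_len(ntip_v + vtree$Nnode), ev$virus_node)]
  out <- list()
  for (e in seq_len(nrow(vtree$edge))) {
    p <- vtree$edge[e, 1L]; ch <- vtree$edge[e, 2L]
    if (is.na(event_of[p]) || event_of[p] != "cospeciation") next
    ok_child <- !is.na(event_of[ch]) &&
      (event_of[ch] == "cospeciation" || event_of[ch] == "tip")
    if (!ok_child) next
    hp <- host_of[p]; hc <- host_of[ch]
    dur <- host_node_age(htree, hp, ages) - host_node_age(htree, hc, ages)
    if (dur < 0)
      stop("negative host duration; node age table inconsistent with the ",
           "reconciliation", call. = FALSE)
    vlab <- if (ch <= ntip_v) vtree$tip.label[ch] else
      paste(sort(vtree$tip.label[descendant_tips(vtree, ch)]), collapse = "+")
    hlab <- if (hc <= length(htree$tip.label)) htree$tip.label[hc] else
      paste(sort(htree$tip.label[descendant_tips(htree, hc)]), collapse = "+")
    if (dur == 0) {
      warning("dropping zero-duration host branch to ", hlab, call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      virus_branch = vlab, host_branch = hlab,
      virus_branch_length = vtree$edge.length[e], host_duration = dur,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(virus_branch = character(0), host_branch = character(0),
               virus_branch_length = numeric(0), host_duration = numeric(0))
  class(res) <- c("branch_pairs", "data.frame")
  res
}

#' Fit the virus-host codivergence regression with outlier pruning
#'
#' Ordinary least squares of virus branch length (response, amino-acid
#' substitutions/site) on host duration (predictor, Myr), with an intercept.
#' Influential points are pruned iteratively by Cook's distance: the
#' threshold is set to \code{cook_factor} times the mean of the Cook's
#' distances observed in the initial fit, and while the largest current
#' Cook's distance exceeds it, the single most influential point is removed
#' and the model refitted. Every removal is recorded in order.
#'
#' Fixing the threshold at the scale observed before pruning is what makes
#' the procedure stop once the gross outliers are gone: Cook's distances
#' are strongly right-skewed, so on outlier-free Gaussian data the largest
#' distance exceeds \code{cook_factor} times the current mean in almost
#' every dataset, and a threshold recomputed after each removal keeps
#' firing and erodes the sample. Set \code{recompute_threshold = TRUE} for
#' that fully iterative variant.
#'
#' @param pairs A [extract_branch_pairs()] data frame (or any data frame
#'   with \code{virus_branch_length} and \code{host_duration} columns).
#' @param cook_factor Pruning threshold multiplier (default 3).
#' @param recompute_threshold Logical; recompute the threshold from the
#'   current fit after every removal instead of fixing it at the initial
#'   scale (default \code{FALSE}).
#' @return An object of class \code{codivergence_fit}: \code{slope}
#'   (subs/site per Myr), \code{intercept}, \code{slope_se},
#'   \code{r_squared}, \code{p_value} (of the slope), \code{n_used},
#'   \code{removed} (data frame: branch labels, Cook's distance, removal
#'   order), \code{residual_variance}, \code{df}, \code{vcov} (2x2
#'   coefficient covariance), and the retained \code{pairs}.
#' @export
fit_codivergence <- function(pairs, cook_factor = 3,
                             recompute_threshold = FALSE) {
  stopifnot(is.data.frame(pairs),
            all(c("virus_branch_length", "host_duration") %in% names(pairs)))
  if (nrow(pairs) < 4L)
    stop("need at least 4 branch pairs to fit and prune", call. = FALSE)
  if (!is.numeric(cook_factor) || cook_factor <= 0)
    stop("cook_factor must be positive", call. = FALSE)
  dat <- as.data.frame(pairs)
  dat$.row <- seq_len(nrow(dat))
  removed <- list()
  threshold <- NULL
  repeat {
    if (nrow(dat) < 3L)
      stop("pruning removed too many points; fit degenerate", call. = FALSE)
    if (stats::var(dat$host_duration) == 0)
      stop("degenerate predictor: no variance in host durations",
           call. = FALSE)
    fit <- stats::lm(virus_branch_length ~ host_duration, data = dat)
    # a numerically perfect fit has no outliers; its Cook's distances are
    # floating-point noise
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((dat$virus_branch_length - mean(dat$virus_branch_length))^2)
    if (rss <= 1e-20 * max(tss, 1e-300)) break
    cd <- stats::cooks.distance(fit)
    if (!all(is.finite(cd))) break
    if (is.null(threshold) || recompute_threshold)
      threshold <- cook_factor * mean(cd)
    if (max(cd) <= threshold) break
    worst <- which.max(cd)
    removed[[length(removed) + 1L]] <- data.frame(
      virus_branch = if ("virus_branch" %in% names(dat))
        dat$virus_branch[worst] else as.character(dat$.row[worst]),
      host_duration = dat$host_duration[worst],
      virus_branch_length = dat$virus_branch_length[worst],
      cooks_distance = unname(cd[worst]),
      order = length(removed) + 1L,
      stringsAsFactors = FALSE)
    dat <- dat[-worst, , drop = FALSE]
  }
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         slope_se = sm$coefficients[2L, 2L],
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L],
         n_used = nrow(dat),
         removed = if (length(removed)) do.call(rbind, removed) else
           data.frame(virus_branch = character(0), host_duration = numeric(0),
                      virus_branch_length = numeric(0),
                      cooks_distance = numeric(0), order = integer(0)),
         residual_variance = sm$sigma^2,
         df = fit$df.residual,
         vcov = stats::vcov(fit),
         pairs = dat[, setdiff(names(dat), ".row"), drop = FALSE]),
    class = "codivergence_fit"
  )
}

#' @export
print.codivergence_fit <- function(x, ...) {
  cat(sprintf(paste0("<codivergence_fit> N = %d, slope %.4g subs/site/Myr ",
                     "(SE %.3g), intercept %.4g, R^2 = %.3f, p = %.3g; ",
                     "%d outlier(s) pruned\n"),
              x$n_used, x$slope, x$slope_se, x$intercept, x$r_squared,
              x$p_value, nrow(x$removed)))
  invisible(x)
}

#' Date a virus node by calibrated inverse prediction
#'
#' Given a fitted codivergence regression, inverts it at a new virus branch
#' length to estimate the duration that branch represents, and subtracts
#' that duration from a host calibration age to date the virus node:
#' \eqn{\hat d = (\ell - \hat a) / \hat b} (clipped at 0), point estimate
#' \eqn{= \mathrm{calibration} - \hat d}. The 95\% interval propagates the
#' coefficient covariance through the inverse prediction to first order
#' (delta method) with a t quantile on the fit's residual degrees of
#' freedom, then maps it through the same subtraction.
#'
#' @param fit A [fit_codivergence()] result with positive slope.
#' @param branch_length New virus branch length, amino-acid subs/site.
#' @param calibration_age Host calibration age in Myr (the age of the host
#'   node from which the branch descends).
#' @return An object of class \code{node_date}: \code{point} (Ma),
#'   \code{ci95}, \code{duration} (inverse-predicted Myr),
#'   \code{duration_ci95}, \code{branch_length}, \code{calibration_age}.
#' @export
estimate_node_date <- function(fit, branch_length, calibration_age) {
  stopifnot(inherits(fit, "codivergence_fit"))
  if (!is.numeric(branch_length) || branch_length < 0)
    stop("branch_length must be non-negative", call. = FALSE)
  if (fit$slope <= 0)
    stop("cannot invert non-informative fit (slope <= 0)", call. = FALSE)
  d <- (branch_length - fit$intercept) / fit$slope
  d <- max(d, 0)
  # delta method: gradient of (y0 - a)/b wrt (a, b) is (-1/b, -d/b)
  g <- c(-1 / fit$slope, -d / fit$slope)
  se_d <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  tq <- stats::qt(0.975, df = fit$df)
  d_ci <- c(max(d - tq * se_d, 0), d + tq * se_d)
  point <- calibration_age - d
  ci <- sort(calibration_age - d_ci)
  structure(list(point = point, ci95 = ci, duration = d,
                 duration_ci95 = d_ci, branch_length = branch_length,
                 calibration_age = calibration_age),
            class = "node_date")
}

#' @export
print.node_date <- function(x, ...) {
  cat(sprintf("<node_date> %.3f (%.3f-%.3f) Ma  [branch %.4g subs/site below calibration %.4g Ma]\n",
              x$point, x$ci95[1L], x$ci95[2L], x$branch_length,
              x$calibration_age))
  invisible(x)
}
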