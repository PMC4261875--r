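#' Monte-Carlo simulation grid for ERV dating
#'
#' The dating procedure mutates a model sequence in silico over a grid of
#' hypothetical durations and asks, at each duration, how often the
#' simulated stop-codon frequency reaches the observed one. The defaults —
#' 5 to 200 Myr in steps of 5 Myr with 1,000 replicates per grid time — are
#' the study conditions for mammalian foamy-virus ERVs.
#'
#' @param t_min,t_max,step Grid of durations in Myr; \code{t_min > 0},
#'   \code{step > 0}, and \code{t_max - t_min} must be divisible by
#'   \code{step}.
#' @param n_reps Independent replicates per grid time (default 1000).
#' @param seed Master seed; per-(model sequence, grid time) substreams are
#'   derived from it deterministically.
#' @return An object of class \code{simulation_grid}.
#' @export
simulation_grid <- function(t_min = 5, t_max = 200, step = 5,
                            n_reps = 1000L, seed = 1L) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(step))
  if (t_min <= 0) stop("t_min must be > 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (t_max < t_min) stop("t_max must be >= t_min", call. = FALSE)
  k <- (t_max - t_min) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(t_max - t_min) must be divisible by step", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max, step = step,
                 times = seq(t_min, t_max, by = step),
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "simulation_grid")
}

# Deterministic substream seed from master seed, sequence content and grid
# position. Kept below 2^31 - 1; content hash makes identical model
# sequences reproduce identical streams regardless of their ids.
derive_seed <- function(master, bases, k) {
  m <- 2147483647
  codes <- utf8ToInt(bases)
  h <- 0
  w <- (seq_along(codes) %% 64L) + 1L
  h <- sum((codes * w) %% m) %% m
  (((master %% m) * 69069) %% m + (k * 1000003) %% m + h) %% m
}

#' Simulate stop-codon frequencies over a time grid
#'
#' For each grid duration, draws \code{n_reps} independent neutrally mutated
#' copies of the model sequence (endpoint sampling of the equal-rates chain)
#' and censuses in-frame stop codons with the same framing rules as
#' [census_stop_codons()].
#'
#' @param seq A [coding_sequence()] model sequence (typically an intact,
#'   stop-free pol reading frame of an extant relative).
#' @param model A [neutral_model()].
#' @param grid A [simulation_grid()].
#' @param stop_set Stop codons; standard code by default.
#' @return An object of class \code{frequency_matrix}: list with \code{freq}
#'   (matrix, rows = replicates, columns = grid times), \code{times},
#'   \code{model_id}, \code{rate}, \code{grid}.
#' @export
simulate_stop_frequencies <- function(seq, model, grid,
                                      stop_set = c("TAA", "TAG", "TGA")) {
  stopifnot(inherits(seq, "coding_sequence"), inherits(model, "neutral_model"),
            inherits(grid, "simulation_grid"))
  cv <- codon_view(seq)
  countable <- cv$countable
  if (!any(countable))
    stop("empty reading frame: no countable codons in '", seq$id, "'",
         call. = FALSE)
  # raw positions (within the gap-stripped framed span) of countable codons
  s <- gsub("-", "", seq$bases, fixed = TRUE)
  if (seq$frame_offset > 0L) s <- substring(s, seq$frame_offset + 1L)
  starts <- 3L * (cv$index[countable] - 1L) + 1L
  sites <- as.vector(rbind(starts, starts + 1L, starts + 2L))
  base0 <- match(strsplit(s, "")[[1]][sites], .BASES)   # 1..4, all ACGT
  n_sites <- length(sites)
  n_cod <- n_sites %/% 3L
  stop_codes <- vapply(stop_set, function(cd) {
    b <- match(strsplit(cd, "")[[1]], .BASES) - 1L
    b[1L] * 16L + b[2L] * 4L + b[3L]
  }, integer(1))

  n_reps <- grid$n_reps
  times <- grid$times
  freq <- matrix(NA_real_, nrow = n_reps, ncol = length(times))
  base_mat0 <- matrix(rep(base0, each = n_reps), nrow = n_reps)
  i1 <- seq(1L, n_sites, by = 3L)
  for (k in seq_along(times)) {
    set.seed(derive_seed(grid$seed, seq$bases, k))
    ps <- p_same(model$rate, times[k] * 1e6)
    m <- base_mat0
    change <- matrix(stats::runif(n_reps * n_sites), nrow = n_reps) > ps
    n_ch <- sum(change)
    if (n_ch > 0L) {
      shift <- sample.int(3L, n_ch, replace = TRUE)
      m[change] <- ((m[change] - 1L + shift) %% 4L) + 1L
    }
    val <- (m[, i1, drop = FALSE] - 1L) * 16L +
      (m[, i1 + 1L, drop = FALSE] - 1L) * 4L +
      (m[, i1 + 2L, drop = FALSE] - 1L)
    is_stop <- matrix(val %in% stop_codes, nrow = n_reps)
    freq[, k] <- rowSums(is_stop) / n_cod
  }
  structure(list(freq = freq, times = times, model_id = seq$id,
                 rate = model$rate, grid = grid),
            class = "frequency_matrix")
}

#' Build the age CDF for an observed stop-codon frequency
#'
#' At each grid duration \eqn{t_k} the raw exceedance probability
#' \eqn{\hat q(t_k)} is the fraction of replicates whose simulated frequency
#' reached the observed frequency \eqn{f_{obs}}. Because stop-codon
#' accumulation is (near-)monotone in time, \eqn{\hat q} is interpreted as a
#' first-passage CDF of the time needed to accumulate stops at frequency
#' \eqn{f_{obs}}; Monte-Carlo noise is smoothed by taking the running
#' maximum over increasing \eqn{t}. The \code{reached} flag records whether
#' the CDF attains 0.99 by the end of the grid; summaries refuse to
#' renormalise a CDF that does not.
#'
#' @param fm A [simulate_stop_frequencies()] result.
#' @param f_obs Observed stop-codon frequency in \code{[0, 1]}.
#' @return An object of class \code{age_cdf}: \code{times}, \code{q_raw},
#'   \code{q} (monotone), \code{f_obs}, \code{reached}, \code{model_id},
#'   \code{grid}.
#' @export
build_age_cdf <- function(fm, f_obs) {
  stopifnot(inherits(fm, "frequency_matrix"))
  if (!is.numeric(f_obs) || length(f_obs) != 1L || is.na(f_obs) ||
      f_obs < 0 || f_obs > 1)
    stop("f_obs must be a single frequency in [0, 1]", call. = FALSE)
  q_raw <- colMeans(fm$freq >= f_obs)
  q <- cummax(q_raw)
  structure(list(times = fm$times, q_raw = q_raw, q = q, f_obs = f_obs,
                 reached = q[length(q)] >= 0.99, model_id = fm$model_id,
                 grid = fm$grid),
            class = "age_cdf")
}

#' Summarize an age CDF into an integration-age estimate
#'
#' Converts the (renormalised) discrete CDF into point and interval
#' summaries: probability mass \eqn{\Delta q_k = q(t_k) - q(t_{k-1})}
#' renormalised by \eqn{q(t_{max})}; mean \eqn{\sum t_k \Delta q_k}; median
#' the smallest grid time with \eqn{q \ge 0.5}; mode the grid cell with the
#' largest mass; 95\% interval from the 0.025 and 0.975 crossings.
#'
#' @param cdf An [build_age_cdf()] result with \code{reached = TRUE}.
#' @return An object of class \code{age_summary}: \code{mean},
#'   \code{median}, \code{mode} (Myr interval \code{c(lo, hi)}),
#'   \code{ci95}, \code{model_id}, \code{f_obs}.
#' @export
summarize_age <- function(cdf) {
  stopifnot(inherits(cdf, "age_cdf"))
  if (!isTRUE(cdf$reached))
    stop("target frequency not attained on grid (q(t_max) < 0.99); ",
         "extend the grid or reconsider the model sequence", call. = FALSE)
  qn <- cdf$q / cdf$q[length(cdf$q)]
  dq <- diff(c(0, qn))
  step <- cdf$grid$step
  k_mode <- which.max(dq)
  structure(
    list(mean = sum(cdf$times * dq),
         median = cdf$times[which(qn >= 0.5)[1L]],
         mode = c(cdf$times[k_mode] - step, cdf$times[k_mode]),
         ci95 = c(cdf$times[which(qn >= 0.025)[1L]],
                  cdf$times[which(qn >= 0.975)[1L]]),
         model_id = cdf$model_id, f_obs = cdf$f_obs),
    class = "age_summary"
  )
}

#' @export
print.age_summary <- function(x, ...) {
  cat(sprintf(paste0("<age_summary> model %s, f_obs %s: mean %.1f Myr, ",
                     "median %g Myr, mode (%g, %g], 95%% CI [%g, %g] Myr\n"),
              x$model_id, format_sig3(x$f_obs), x$mean, x$median,
              x$mode[1L], x$mode[2L], x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Date an ERV integration from several model sequences
#'
#' Runs the full grid-simulation / CDF / summary chain once per model
#' sequence and reports both the per-model summaries and a pooled view: the
#' min-max range of per-model mean ages (the presentation convention for
#' multi-model estimates) plus a pooled summary computed from the average of
#' the per-model renormalised masses.
#'
#' @param seqs A list of [coding_sequence()] model sequences (or one).
#' @param model A [neutral_model()].
#' @param grid A [simulation_grid()].
#' @param f_obs Observed stop-codon frequency of the ERV reading frame.
#' @return An object of class \code{erv_dating_report}: \code{per_model}
#'   (list of [summarize_age()] results), \code{mean_range} (min-max of
#'   per-model means), \code{pooled} (summary from pooled mass),
#'   \code{f_obs}, \code{rate}.
#' @export
date_erv <- function(seqs, model, grid, f_obs) {
  if (inherits(seqs, "coding_sequence")) seqs <- list(seqs)
  stopifnot(length(seqs) >= 1L,
            all(vapply(seqs, inherits, logical(1), "coding_sequence")))
  cdfs <- lapply(seqs, function(s)
    build_age_cdf(simulate_stop_frequencies(s, model, grid), f_obs))
  summaries <- lapply(cdfs, summarize_age)
  means <- vapply(summaries, `[[`, numeric(1), "mean")
  # pooled mass: average of per-model renormalised masses
  qn_mat <- vapply(cdfs, function(cd) cd$q / cd$q[length(cd$q)],
                   numeric(length(grid$times)))
  q_pool <- rowMeans(as.matrix(qn_mat))
  pooled_cdf <- structure(list(times = grid$times, q_raw = q_pool,
                               q = q_pool, f_obs = f_obs, reached = TRUE,
                               model_id = "pooled", grid = grid),
                          class = "age_cdf")
  structure(list(per_model = summaries,
                 mean_range = range(means),
                 pooled = summarize_age(pooled_cdf),
                 f_obs = f_obs, rate = model$rate),
            class = "erv_dating_report")
}

#' @export
print.erv_dating_report <- function(x, ...) {
  cat(sprintf("<erv_dating_report> f_obs %s, rate %g subs/site/year, %d model sequence(s)\n",
              format_sig3(x$f_obs), x$rate, length(x$per_model)))
  cat(sprintf("  mean age range: %.1f-%.1f Myr\n",
              x$mean_range[1L], x$mean_range[2L]))
  cat(sprintf("  pooled: mean %.1f, median %g, mode (%g, %g], 95%% CI [%g, %g] Myr\n",
              x$pooled$mean, x$pooled$median, x$pooled$mode[1L],
              x$pooled$mode[2L], x$pooled$ci95[1L], x$pooled$ci95[2L]))
  invisible(x)
}
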