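#' FRET efficiency from donor/acceptor intensities
#'
#' `E_t = A_t / (A_t + D_t)`, masked (`NA`) where the total intensity is
#' zero. Efficiency is invariant to rescaling both channels by the same
#' positive constant.
#'
#' @param donor,acceptor Non-negative intensity vectors of equal length.
#' @return Numeric efficiency series in `[0, 1]` with `NA` at masked frames.
#' @export
fret_efficiency <- function(donor, acceptor) {
  if (length(donor) != length(acceptor)) {
    stop("donor and acceptor must have equal length", call. = FALSE)
  }
  if (any(donor < 0, na.rm = TRUE) || any(acceptor < 0, na.rm = TRUE)) {
    stop("negative intensity", call. = FALSE)
  }
  total <- donor + acceptor
  e <- acceptor / total
  e[total == 0] <- NA_real_
  e
}

#' FRET trajectory container
#'
#' @param donor,acceptor Per-frame intensities.
#' @param frame_interval_s Frame interval in seconds (0.06 or 0.1 typical).
#' @param truth_path Optional known state path (synthetic data only).
#' @return A `fret_trajectory` list with the efficiency series attached.
#' @export
fret_trajectory <- function(donor, acceptor, frame_interval_s = 0.1,
                            truth_path = NULL) {
  structure(
    list(donor = donor, acceptor = acceptor,
         frame_interval_s = frame_interval_s,
         efficiency = fret_efficiency(donor, acceptor),
         idealized = NULL, truth_path = truth_path),
    class = "fret_trajectory"
  )
}

.trace_efficiency <- function(x) {
  if (inherits(x, "fret_trajectory")) x$efficiency else as.numeric(x)
}

#' FRET histogram
#'
#' Bins efficiencies of all frames of all traces into left-closed bins of
#' width `bin` over `[0, 1]` (the last bin is closed). With
#' `use_idealized = TRUE`, idealized state values are binned instead.
#'
#' @param traces List of [fret_trajectory] objects or numeric vectors.
#' @param bin Bin width; must divide 1.
#' @param use_idealized Bin idealized state means instead of raw E.
#' @return Data frame `lower`, `upper`, `count`.
#' @export
fret_histogram <- function(traces, bin = 0.02, use_idealized = FALSE) {
  if (length(traces) == 0L) stop("no traces", call. = FALSE)
  nb <- round(1 / bin)
  if (abs(nb * bin - 1) > 1e-9) stop("bin must divide 1", call. = FALSE)
  vals <- unlist(lapply(traces, function(tr) {
    if (use_idealized) {
      if (is.null(tr$idealized)) stop("trace lacks idealization", call. = FALSE)
      tr$idealized$state_means[tr$idealized$path]
    } else {
      .trace_efficiency(tr)
    }
  }))
  vals <- vals[!is.na(vals)]
  # epsilon keeps values lying exactly on a bin edge in the upper bin
  idx <- pmin(pmax(floor(vals / bin + 1e-9), 0), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  data.frame(lower = (seq_len(nb) - 1L) * bin, upper = seq_len(nb) * bin,
             count = counts)
}

# ---- Gaussian-emission HMM (maximum-likelihood stand-in for ebFRET) -----

.hmm_em <- function(x, n_states, max_iter, tol, sd_floor = 1e-4) {
  n <- length(x)
  # deterministic quantile-seeded k-means initialization
  centers <- stats::quantile(x, probs = (seq_len(n_states) - 0.5) / n_states,
                             names = FALSE)
  centers <- centers + seq_len(n_states) * 1e-9 # break exact ties
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers),
                                       iter.max = 50L))
  mu <- as.numeric(km$centers)
  sd <- vapply(seq_len(n_states), function(k) {
    v <- stats::sd(x[km$cluster == k])
    if (is.na(v) || v < sd_floor) sd_floor else v
  }, numeric(1))
  A <- matrix(1 / n_states, n_states, n_states)
  pi0 <- rep(1 / n_states, n_states)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(n_states),
                function(k) stats::dnorm(x, mu[k], sd[k]), numeric(n))
    B <- pmax(B, 1e-300)
    # forward-backward with scaling
    alpha <- matrix(0, n, n_states)
    cscale <- numeric(n)
    alpha[1L, ] <- pi0 * B[1L, ]
    cscale[1L] <- sum(alpha[1L, ]); alpha[1L, ] <- alpha[1L, ] / cscale[1L]
    for (t in 2:n) {
      a <- (alpha[t - 1L, ] %*% A) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta <- matrix(0, n, n_states)
    beta[n, ] <- 1
    for (t in (n - 1L):1L) {
      beta[t, ] <- (A %*% (B[t + 1L, ] * beta[t + 1L, ])) / cscale[t + 1L]
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, n_states, n_states)
    for (t in seq_len(n - 1L)) {
      xi <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * A
      xi_num <- xi_num + xi / sum(xi)
    }
    pi0 <- gamma[1L, ]
    A <- xi_num / pmax(rowSums(xi_num), 1e-300)
    occ <- colSums(gamma)
    mu <- colSums(gamma * x) / occ
    sd <- sqrt(colSums(gamma * (outer(x, mu, "-")^2)) / occ)
    sd <- pmax(sd, sd_floor)
    ll <- sum(log(cscale))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sd = sd, A = A, pi0 = pi0, gamma = gamma, loglik = ll_old,
       converged = converged)
}

.hmm_viterbi <- function(x, mu, sd, A, pi0) {
  n <- length(x); K <- length(mu)
  logB <- vapply(seq_len(K),
                 function(k) stats::dnorm(x, mu[k], sd[k], log = TRUE),
                 numeric(n))
  logB <- matrix(logB, nrow = n)
  logA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1L, ] <- log(pmax(pi0, 1e-300)) + logB[1L, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1L, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Idealize a FRET trace with a Gaussian-emission HMM
#'
#' Maximum-likelihood stand-in for empirical-Bayes HMM idealization: a
#' Gaussian-emission hidden Markov model is fitted by Baum-Welch EM with a
#' deterministic quantile-seeded k-means initialization, and the Viterbi
#' path returned. States occupying less than `min_weight` of frames are
#' merged into their nearest surviving state. States are relabelled in
#' order of decreasing mean (state 1 = highest FRET).
#'
#' @param trace A [fret_trajectory] or numeric efficiency vector.
#' @param n_states Number of states (>= 1); trace must have at least
#'   `10 * n_states` frames.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param min_weight Occupancy below which a state is degenerate.
#' @return List: `path` (per-frame state index), `state_means`,
#'   `state_sds`, `transition_counts`, `converged`, `loglik`.
#' @export
idealize_states <- function(trace, n_states, max_iter = 200L, tol = 1e-6,
                            min_weight = 0.01) {
  x <- .trace_efficiency(trace)
  x <- x[!is.na(x)]
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  if (length(x) < 10L * n_states) {
    stop("trace too short for requested number of states", call. = FALSE)
  }
  if (n_states == 1L) {
    return(list(path = rep(1L, length(x)), state_means = mean(x),
                state_sds = stats::sd(x), transition_counts = matrix(0, 1, 1),
                converged = TRUE, loglik = NA_real_))
  }
  fit <- .hmm_em(x, n_states, max_iter, tol)
  if (!fit$converged) {
    warning("EM did not converge; returning best-so-far fit", call. = FALSE)
  }
  path <- .hmm_viterbi(x, fit$mu, fit$sd, fit$A, fit$pi0)
  # merge degenerate states into nearest surviving mean
  occ <- tabulate(path, nbins = n_states) / length(path)
  live <- which(occ >= min_weight)
  if (length(live) == 0L) live <- which.max(occ)
  if (length(live) < n_states) {
    for (k in setdiff(seq_len(n_states), live)) {
      tgt <- live[which.min(abs(fit$mu[live] - fit$mu[k]))]
      path[path == k] <- tgt
    }
  }
  # relabel by decreasing mean
  means <- fit$mu[live]
  ord <- order(-means)
  relabel <- integer(n_states)
  relabel[live[ord]] <- seq_along(live)
  path <- relabel[path]
  means <- means[ord]
  sds <- fit$sd[live][ord]
  K <- length(means)
  tc <- matrix(0L, K, K)
  for (t in seq_len(length(path) - 1L)) {
    tc[path[t], path[t + 1L]] <- tc[path[t], path[t + 1L]] + 1L
  }
  list(path = path, state_means = means, state_sds = sds,
       transition_counts = tc, converged = fit$converged,
       loglik = fit$loglik)
}

# first frame index of a sustained (>= k consecutive frames) drop below the
# threshold, or NA if the trace never crosses
.sync_start <- function(e, threshold, k) {
  below <- !is.na(e) & e < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

#' Post-synchronization histogram
#'
#' Traces are synchronized at their transcription start, defined as the
#' first frame where efficiency drops below `threshold` for at least `k`
#' consecutive frames (a sustained-crossing rule that excludes false
#' decreases due to single noisy frames). Traces that never cross are
#' excluded and counted. Each included trace contributes all frames from
#' `pre_window_s` seconds before its start onward, with time re-zeroed at
#' the start, accumulated into a 2-D histogram of `fret_bin` x `time_bin_s`
#' bins.
#'
#' @param traces List of [fret_trajectory] objects.
#' @param fret_bin FRET bin width (default 0.05).
#' @param time_bin_s Time bin width in seconds (default 10).
#' @param threshold FRET threshold separating the initial high state from
#'   transcribing states (default 0.75).
#' @param pre_window_s Seconds of pre-start signal included (default 10).
#' @param k Consecutive sub-threshold frames required (default 3).
#' @return List of class `ps_histogram`: `counts` (FRET bins x time bins),
#'   `fret_edges`, `time_edges`, `n_included`, `n_excluded`.
#' @export
post_sync_histogram <- function(traces, fret_bin = 0.05, time_bin_s = 10,
                                threshold = 0.75, pre_window_s = 10, k = 3L) {
  if (length(traces) == 0L) stop("no traces", call. = FALSE)
  nb <- round(1 / fret_bin)
  if (abs(nb * fret_bin - 1) > 1e-9) {
    stop("fret_bin must divide 1", call. = FALSE)
  }
  starts <- integer(0)
  included <- list()
  n_excluded <- 0L
  for (tr in traces) {
    if (is.null(tr$frame_interval_s) || is.na(tr$frame_interval_s)) {
      stop("trace lacks frame interval", call. = FALSE)
    }
    s <- .sync_start(tr$efficiency, threshold, k)
    if (is.na(s)) {
      n_excluded <- n_excluded + 1L
      next
    }
    included[[length(included) + 1L]] <- tr
    starts[length(included)] <- s
  }
  if (length(included) == 0L) {
    stop("no trace crosses the threshold", call. = FALSE)
  }
  max_t <- max(vapply(seq_along(included), function(i) {
    (length(included[[i]]$efficiency) - starts[i]) *
      included[[i]]$frame_interval_s
  }, numeric(1)))
  time_edges <- seq(-pre_window_s,
                    ceiling(max_t / time_bin_s) * time_bin_s + time_bin_s,
                    by = time_bin_s)
  nt <- length(time_edges) - 1L
  counts <- matrix(0L, nrow = nb, ncol = nt)
  for (i in seq_along(included)) {
    tr <- included[[i]]
    dt <- tr$frame_interval_s
    times <- (seq_along(tr$efficiency) - starts[i]) * dt
    sel <- times >= -pre_window_s & !is.na(tr$efficiency)
    e <- pmin(pmax(tr$efficiency[sel], 0), 1)
    fi <- pmin(floor(e / fret_bin + 1e-9), nb - 1L) + 1L
    ti <- pmin(floor((times[sel] + pre_window_s) / time_bin_s + 1e-9),
               nt - 1L) + 1L
    for (j in seq_along(fi)) counts[fi[j], ti[j]] <- counts[fi[j], ti[j]] + 1L
  }
  structure(list(counts = counts,
                 fret_edges = (0:nb) * fret_bin,
                 time_edges = time_edges,
                 n_included = length(included), n_excluded = n_excluded),
            class = "ps_histogram")
}

#' Rule-based classification of idealized traces
#'
#' An interpretation layer (not a primary algorithm): labels an idealized
#' trace as `"complete"` (reaches and stays below `complete_below`),
#' `"static"` (never leaves the top state), `"backtracked"` (any upward
#' state transition after leaving the top state) or `"stalled"` (leaves the
#' top state but neither completes nor backtracks).
#'
#' @param idealization Output of [idealize_states()].
#' @param complete_below Final-state FRET level counted as completed
#'   transcription.
#' @return A character label.
#' @export
classify_fret_trace <- function(idealization, complete_below = 0.05) {
  path <- idealization$path
  means <- idealization$state_means
  if (all(path == 1L)) return("static")
  lev <- means[path]
  n <- length(lev)
  final_low <- lev[n] < complete_below
  after_leave <- which(path > 1L)[1L]
  ups <- any(diff(lev[after_leave:n]) > 1e-9)
  if (final_low && !ups) return("complete")
  if (ups) return("backtracked")
  "stalled"
}
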