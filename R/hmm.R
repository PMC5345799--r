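#' Two-state Gaussian HMM parameters
#'
#' @param means,sds numeric length-2 emission means and SDs (score units).
#' @param transition 2x2 transition matrix, rows summing to 1.
#' @param initial length-2 initial state distribution summing to 1.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(means, sds, transition, initial) {
  stopifnot(length(means) == 2, length(sds) == 2,
            is.matrix(transition), all(dim(transition) == c(2, 2)),
            length(initial) == 2)
  if (any(sds <= 0)) stop("emission SDs must be > 0")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  structure(list(means = as.numeric(means), sds = as.numeric(sds),
                 transition = transition, initial = as.numeric(initial)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: means %.4g/%.4g, sds %.4g/%.4g, stay %.4g/%.4g\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2],
              x$transition[1, 1], x$transition[2, 2]))
  invisible(x)
}

# internal: n x 2 emission log-density matrix; missing bins get 0 rows so
# the emission term is omitted while transitions propagate through gaps
emission_loglik <- function(x, means, sds) {
  le <- cbind(stats::dnorm(x, means[1], sds[1], log = TRUE),
              stats::dnorm(x, means[2], sds[2], log = TRUE))
  le[is.na(x), ] <- 0
  le
}

# internal: one EM fit from a given starting point
em_fit <- function(x, means, sds, transition, initial, tol, max_iter, sd_floor) {
  obs <- !is.na(x)
  ll_trace <- numeric(0)
  converged <- FALSE
  clamped <- FALSE
  for (iter in seq_len(max_iter)) {
    fb <- hmm_forward_backward(emission_loglik(x, means, sds), transition, initial)
    ll_trace <- c(ll_trace, fb$loglik)
    g <- fb$gamma
    w <- g[obs, , drop = FALSE]
    xo <- x[obs]
    means <- colSums(w * xo) / colSums(w)
    sds <- sqrt(colSums(w * (outer(xo, means, "-"))^2) / colSums(w))
    if (any(sds < sd_floor)) {
      sds <- pmax(sds, sd_floor)
      clamped <- TRUE
    }
    transition <- fb$xi_sum / rowSums(fb$xi_sum)
    initial <- g[1, ]
    if (iter > 1) {
      delta <- (ll_trace[iter] - ll_trace[iter - 1]) /
        max(1, abs(ll_trace[iter - 1]))
      if (is.finite(delta) && delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(params = hmm_params(means, sds, transition, initial),
       loglik = ll_trace[length(ll_trace)], trace = ll_trace,
       converged = converged, clamped = clamped)
}

#' Fit a two-state Gaussian HMM to one chromosome of a binned track
#'
#' Expectation-maximisation over the non-missing bins; missing bins
#' contribute no emission term but transitions propagate through them.
#' Initialisation is deterministic: the track is split at its median,
#' each half supplying a state's empirical mean and SD, with stay
#' probability 0.95.  Optional seeded random restarts (`n_starts > 1`)
#' perturb the initial means and keep the best-likelihood fit.
#'
#' @param track a [binned_track()].
#' @param chrom chromosome to fit.
#' @param seed integer seed (used only when `n_starts > 1`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param sd_floor lower clamp for emission SDs (degenerate-fit guard).
#' @param n_starts number of EM starting points.
#' @return An `hmm_params` object with attributes `loglik`,
#'   `loglik_trace` (monotone non-decreasing), `converged` and
#'   `sd_clamped`.
#' @export
fit_two_state_hmm <- function(track, chrom, seed = 1L, tol = 1e-6,
                              max_iter = 500L, sd_floor = 1e-3,
                              n_starts = 1L) {
  stopifnot(inherits(track, "binned_track"))
  x <- track$scores[[chrom]]
  if (is.null(x)) stop("no track on chromosome ", chrom)
  if (all(is.na(x))) stop("all bins missing on ", chrom)
  if (sum(!is.na(x)) < 100) {
    stop("need at least 100 non-missing bins on ", chrom)
  }
  xo <- x[!is.na(x)]
  med <- stats::median(xo)
  lower <- xo[xo <= med]
  upper <- xo[xo > med]
  init_means <- c(mean(lower), mean(upper))
  init_sds <- pmax(c(stats::sd(lower), stats::sd(upper)), sd_floor, na.rm = TRUE)
  init_sds[is.na(init_sds)] <- sd_floor
  trans0 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  fits <- list(em_fit(x, init_means, init_sds, trans0, c(0.5, 0.5),
                      tol, max_iter, sd_floor))
  if (n_starts > 1L) {
    set.seed(seed)
    spread <- stats::sd(xo)
    for (k in seq_len(n_starts - 1L)) {
      m <- sort(init_means + stats::rnorm(2, 0, spread / 2))
      fits[[k + 1L]] <- em_fit(x, m, init_sds, trans0, c(0.5, 0.5),
                               tol, max_iter, sd_floor)
    }
  }
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  if (!best$converged) {
    warning("EM did not converge within ", max_iter, " iterations on ", chrom)
  }
  if (best$clamped) warning("emission SD clamped at floor on ", chrom)
  ca_log("fit_two_state_hmm: %s loglik %.2f after %d iterations",
         chrom, best$loglik, length(best$trace))
  p <- best$params
  attr(p, "loglik") <- best$loglik
  attr(p, "loglik_trace") <- best$trace
  attr(p, "converged") <- best$converged
  attr(p, "sd_clamped") <- best$clamped
  p
}

#' Decode per-bin states
#'
#' Most-probable state path (joint MAP, the default) or per-bin posterior
#' maximisation.  Missing bins receive `NA`; the path still propagates
#' through them.
#'
#' @param track a [binned_track()].
#' @param chrom chromosome to decode.
#' @param params an [hmm_params()].
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return Integer vector of states (1/2) with `NA` at missing bins.
#' @export
decode_states <- function(track, chrom, params,
                          method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  stopifnot(inherits(track, "binned_track"), inherits(params, "hmm_params"))
  x <- track$scores[[chrom]]
  if (is.null(x)) stop("no track on chromosome ", chrom)
  le <- emission_loglik(x, params$means, params$sds)
  states <- if (method == "viterbi") {
    hmm_viterbi(le, params$transition, params$initial)
  } else {
    fb <- hmm_forward_backward(le, params$transition, params$initial)
    ifelse(fb$gamma[, 1] >= fb$gamma[, 2], 1L, 2L)
  }
  states[is.na(x)] <- NA_integer_
  states
}

#' Map HMM states to D/E labels
#'
#' The state with the lower emission mean is the depleted (D) state.
#'
#' @param params an [hmm_params()].
#' @return Character vector of length 2 mapping state index to label.
#' @export
label_states <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  if (params$means[1] == params$means[2]) {
    stop("equal emission means; D/E labelling undefined")
  }
  if (params$means[1] < params$means[2]) c("D", "E") else c("E", "D")
}

#' Combine per-bin labels into regions
#'
#' Maximal runs of identical labels become intervals (run-length
#' encoding); runs of missing bins become `"gap"` intervals.
#'
#' @param labels character vector of per-bin labels (`"D"`/`"E"`, `NA`
#'   for missing bins).
#' @param bin_width bin width in bp.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp (truncates the final bin).
#' @return A [domain_map()].
#' @export
bins_to_regions <- function(labels, bin_width, chrom = "chr",
                            chrom_length = length(labels) * bin_width) {
  lab <- ifelse(is.na(labels), "gap", labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  domain_map(rep(chrom, length(r$values)), starts * bin_width,
             pmin(ends * bin_width, chrom_length), r$values)
}

#' Close probe gaps flanked by a single state
#'
#' A `"gap"` interval flanked on both sides by regions of the same label
#' is absorbed, merging the three into one region.  Gaps flanked by
#' different labels, or touching a chromosome end, remain unassigned.
#' Idempotent.
#'
#' @param map a [domain_map()] whose `"gap"` intervals are exactly the
#'   missing-bin runs.
#' @return A [domain_map()] with closable gaps merged.
#' @export
close_probe_gaps <- function(map) {
  stopifnot(inherits(map, "domain_map"))
  out <- list()
  for (cn in unique(map$chrom)) {
    sub <- map[map$chrom == cn, , drop = FALSE]
    lab <- sub$label
    for (i in seq_along(lab)) {
      if (lab[i] == "gap" && i > 1 && i < length(lab) &&
          lab[i - 1] != "gap" && lab[i - 1] == lab[i + 1]) {
        lab[i] <- lab[i - 1]
      }
    }
    r <- rle(lab)
    ends_i <- cumsum(r$lengths)
    starts_i <- c(1L, ends_i[-length(ends_i)] + 1L)
    out[[cn]] <- data.frame(chrom = cn, start = sub$start[starts_i],
                            end = sub$end[ends_i], label = r$values,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  domain_map(all$chrom, all$start, all$end, all$label)
}

#' Segment a binned track into a D/E domain map
#'
#' Convenience pipeline: per-chromosome HMM fit, decoding, D/E
#' labelling, run-length region building and probe-gap closing.
#'
#' @param track a [binned_track()].
#' @param seed integer seed forwarded to [fit_two_state_hmm()].
#' @param ... further arguments to [fit_two_state_hmm()].
#' @return A [domain_map()]; fitted per-chromosome parameters are
#'   attached as attribute `params`.
#' @export
segment_track <- function(track, seed = 1L, ...) {
  stopifnot(inherits(track, "binned_track"))
  len <- chrom_lengths(track$genome)
  maps <- list()
  params <- list()
  for (cn in names(track$scores)) {
    p <- fit_two_state_hmm(track, cn, seed = seed, ...)
    states <- decode_states(track, cn, p)
    labels <- label_states(p)[states]
    maps[[cn]] <- close_probe_gaps(
      bins_to_regions(labels, track$bin_width, cn, len[[cn]]))
    params[[cn]] <- p
  }
  all <- do.call(rbind, c(lapply(maps, as.data.frame),
                          list(make.row.names = FALSE)))
  out <- domain_map(all$chrom, all$start, all$end, all$label)
  attr(out, "params") <- params
  out
}
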