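#' Multinomial mixture parameters
#'
#' The model: each contig i carries a latent species label z_i with
#' P(z_i = k) = pi_k, and given z_i = k its read-count vector across the P
#' samples is Multinomial(n_i, a_k), where a_k (row k of `A`) is species k's
#' *sample profile* -- the proportion of its reads contributed by each
#' sample. Both `pi` and every row of `A` live on the probability simplex.
#'
#' @param pi Numeric vector of K mixing weights, non-negative, summing to 1.
#' @param A Numeric K x P matrix of sample profiles, rows on the simplex.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(pi, A) {
  A <- as.matrix(A)
  pi <- as.numeric(pi)
  if (length(pi) != nrow(A)) {
    stop("length(pi) must equal nrow(A)", call. = FALSE)
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10) {
    stop("`pi` must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-10)) {
    stop("every row of `A` must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(rownames(A))) rownames(A) <- paste0("bin_", seq_len(nrow(A)))
  names(pi) <- rownames(A)
  structure(list(pi = pi, A = A), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params> K = %d components, P = %d samples\n",
              length(x$pi), ncol(x$A)))
  invisible(x)
}

#' Log weight of one mixture component for one contig
#'
#' Computes log pi_k + sum_j x_j log a_kj, the log of the component's
#' contribution to the mixture likelihood up to the multinomial coefficient,
#' which is constant across components and therefore omitted throughout the
#' package (E-step, log-likelihood and BIC are all consistent under this
#' convention; absolute log-likelihoods are not comparable with
#' implementations that keep the coefficient).
#'
#' @param x Length-P non-negative count vector with positive total.
#' @param a Length-P profile on the simplex.
#' @param pi_k Component weight in \[0, 1\].
#' @return The log score; `-Inf` when the contig has reads in a sample where
#'   the profile is exactly zero (never an error).
#' @examples
#' log_component_weight(c(3, 0), c(0.9, 0.1), 0.5)
#' @export
log_component_weight <- function(x, a, pi_k) {
  stopifnot(length(x) == length(a), sum(x) > 0)
  # 0 * log(0) is a vacuous term, not NaN
  lp <- ifelse(x > 0, x * log(a), 0)
  log(pi_k) + sum(lp)
}

# N x K matrix of log component weights for all contigs at once.
# log(A) entries at exact zeros become -Inf; a count of 0 against them must
# contribute 0, so zeros in X are routed around the -Inf columns.
.log_weights <- function(X, params) {
  logA <- t(log(params$A))           # P x K
  if (any(!is.finite(logA))) {
    # exact zeros in profiles: compute with a finite stand-in, then overwrite
    # the affected (contig, component) cells with -Inf
    neg <- !is.finite(logA)
    logA_f <- logA
    logA_f[neg] <- 0
    S <- X %*% logA_f
    hit <- (X > 0) %*% (neg + 0) > 0   # contig has reads where profile is 0
    S[hit] <- -Inf
  } else {
    S <- X %*% logA
  }
  sweep(S, 2, log(params$pi), "+")
}

.logsumexp_rows <- function(S) {
  m <- apply(S, 1, max)
  out <- m + log(rowSums(exp(S - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' E-step: posterior species responsibilities
#'
#' Bayes' rule on the multinomial component weights, computed in log space
#' with the log-sum-exp trick (literal products of a_kj^x_ij underflow for
#' realistic contig depths). Row i of the result gives q_ik, the posterior
#' probability that contig i derives from species k.
#'
#' @param x An [rcmm] (or coercible count table).
#' @param params A [mixture_params].
#' @return N x K numeric matrix with rows on the simplex.
#' @export
e_step <- function(x, params) {
  x <- as_rcmm(x)
  S <- .log_weights(x$counts, params)
  norm <- .logsumexp_rows(S)
  dead <- !is.finite(norm)
  if (any(dead)) {
    stop("contig(s) with zero likelihood under every component: ",
         paste(utils::head(rownames(x$counts)[dead], 5), collapse = ", "),
         call. = FALSE)
  }
  q <- exp(S - norm)
  q / rowSums(q)   # renormalize away round-off
}

#' M-step: maximum-likelihood parameter update
#'
#' Given responsibilities q, the updates are pi_k proportional to the total
#' responsibility sum_i q_ik and a_kj proportional to the
#' responsibility-weighted counts sum_i q_ik x_ij. A small pseudo-count
#' (default 1e-10) is added to every profile numerator before row
#' normalization so that no profile entry is exactly zero, which would pin
#' -Inf log-scores onto contigs with any reads in that sample.
#'
#' A component whose total responsibility collapses below 1e-12 is
#' re-seeded with the empirical profile of the currently worst-fit contig
#' (lowest maximum posterior), keeping K fixed during a fit.
#'
#' @param x An [rcmm].
#' @param q N x K responsibility matrix, rows on the simplex.
#' @param smoothing Pseudo-count added to profile numerators.
#' @return A [mixture_params].
#' @export
m_step <- function(x, q, smoothing = 1e-10) {
  x <- as_rcmm(x)
  X <- x$counts
  q <- as.matrix(q)
  wk <- colSums(q)
  num <- t(q) %*% X + smoothing
  empty <- wk < 1e-12
  if (any(empty)) {
    # profile reseed prevents a 0/0 row; the weight stays at its update value
    worst <- which.min(apply(q, 1, max))
    prof <- X[worst, ] / sum(X[worst, ])
    for (k in which(empty)) num[k, ] <- prof + smoothing
  }
  A <- num / rowSums(num)
  pi <- wk / sum(wk)
  mixture_params(pi, A)
}

#' Observed-data log-likelihood
#'
#' The mixture log-likelihood with the latent labels summed out:
#' sum_i log sum_k exp(log pi_k + sum_j x_ij log a_kj). Multinomial
#' coefficients are omitted consistently (see [log_component_weight()]);
#' differences across iterations or across K are unaffected.
#'
#' @inheritParams e_step
#' @return A scalar; `-Inf` (with a diagnostic attribute listing offending
#'   contigs) when some contig has zero likelihood under every component.
#' @export
observed_loglik <- function(x, params) {
  x <- as_rcmm(x)
  ll_i <- .logsumexp_rows(.log_weights(x$counts, params))
  dead <- !is.finite(ll_i)
  if (any(dead)) {
    out <- -Inf
    attr(out, "offending_contigs") <- rownames(x$counts)[dead]
    return(out)
  }
  sum(ll_i)
}

#' Fit the multinomial mixture by EM
#'
#' Alternates [e_step()] and [m_step()] from a starting point (by default the
#' hierarchical-clustering initialization of [hclust_init()]) until the
#' relative change in observed-data log-likelihood drops below `tol` or
#' `max_iter` is reached. Each iteration provably does not decrease the
#' log-likelihood; the trace is recorded and checked.
#'
#' Hard labels are the posterior argmax per contig, ties broken toward the
#' lowest component index.
#'
#' @param x An [rcmm] or count table (see [as_rcmm()]).
#' @param K Number of species components (>= 1, <= number of contigs).
#' @param init Optional [mixture_params] starting point; default
#'   `hclust_init(x, K)`.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param smoothing Profile pseudo-count passed to [m_step()].
#' @return A `mixbin_fit`: list with `params`, `posterior`, `labels`
#'   (named integer vector), `loglik`, `loglik_trace`, `bic`, `converged`,
#'   `n_iter`, `K`, and the data dimensions.
#' @seealso [select_k()] to choose K, [tidy.mixbin_fit()] and
#'   [glance.mixbin_fit()] for tibble summaries, [autoplot.mixbin_fit()].
#' @examples
#' sim <- simulate_community(K = 2, P = 6, N = 80, seed = 1)
#' fit <- fit_em(sim$rcmm, K = 2)
#' glance(fit)
#' @export
fit_em <- function(x, K, init = NULL, tol = 1e-6, max_iter = 500,
                   smoothing = 1e-10) {
  x <- as_rcmm(x)
  N <- nrow(x$counts)
  P <- ncol(x$counts)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > N) stop("K = ", K, " exceeds the number of contigs (", N, ")",
                  call. = FALSE)
  if (any(rowSums(x$counts) == 0)) {
    stop("contigs with zero mapped reads carry no profile; drop them with filter_contigs()",
         call. = FALSE)
  }
  params <- init %||% hclust_init(x, K)
  if (length(params$pi) != K || ncol(params$A) != P) {
    stop("`init` dimensions do not match (K, P)", call. = FALSE)
  }

  trace <- numeric(0)
  ll <- observed_loglik(x, params)
  if (!is.finite(ll)) stop("non-finite log-likelihood at initialization", call. = FALSE)
  converged <- FALSE
  q <- NULL
  for (it in seq_len(max_iter)) {
    q <- e_step(x, params)
    params <- m_step(x, q, smoothing = smoothing)
    ll_new <- observed_loglik(x, params)
    if (!is.finite(ll_new)) {
      stop("non-finite log-likelihood at iteration ", it, call. = FALSE)
    }
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * abs(ll)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  q <- e_step(x, params)
  labels <- max.col(q, ties.method = "first")
  names(labels) <- rownames(x$counts)
  dimnames(q) <- list(rownames(x$counts), rownames(params$A))

  structure(list(
    params = params,
    posterior = q,
    labels = labels,
    loglik = ll,
    loglik_trace = trace,
    bic = bic_score(ll, K = K, P = P, N = N),
    converged = converged,
    n_iter = length(trace),
    K = K, N = N, P = P,
    sample_ids = colnames(x$counts)
  ), class = "mixbin_fit")
}

#' @export
print.mixbin_fit <- function(x, ...) {
  cat(sprintf(
    "<mixbin_fit> K = %d bins over %d contigs x %d samples\n  loglik %.2f, BIC %.2f, %d EM iterations (%s)\n",
    x$K, x$N, x$P, x$loglik, x$bic, x$n_iter,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Tidy per-contig bin assignments
#'
#' @param x A `mixbin_fit`.
#' @param ... Unused.
#' @return A tibble with one row per contig: `contig_id`, `bin` (hard
#'   label), and `posterior` (that label's posterior probability).
#' @method tidy mixbin_fit
#' @export
tidy.mixbin_fit <- function(x, ...) {
  tibble::tibble(
    contig_id = names(x$labels),
    bin = unname(x$labels),
    posterior = x$posterior[cbind(seq_along(x$labels), x$labels)]
  )
}

#' One-row fit summary
#'
#' @param x A `mixbin_fit`.
#' @param ... Unused.
#' @return A tibble with `K`, `loglik`, `bic`, `n_iter`, `converged`,
#'   `n_contigs`, `n_samples`.
#' @method glance mixbin_fit
#' @export
glance.mixbin_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, loglik = x$loglik, bic = x$bic, n_iter = x$n_iter,
    converged = x$converged, n_contigs = x$N, n_samples = x$P
  )
}

#' Tidy sample-profile matrix of a fit
#'
#' @param fit A `mixbin_fit`.
#' @return A tibble with columns `bin`, `sample`, `profile` (a_kj) and the
#'   bin's mixing weight `pi`.
#' @export
profiles <- function(fit) {
  A <- fit$params$A
  samples <- colnames(A) %||% paste0("sample_", seq_len(ncol(A)))
  tibble::tibble(
    bin = rep(seq_len(nrow(A)), each = ncol(A)),
    sample = rep(samples, times = nrow(A)),
    profile = as.vector(t(A)),
    pi = rep(unname(fit$params$pi), each = ncol(A))
  )
}

#' Log-likelihood trace plot
#'
#' @param object A `mixbin_fit`.
#' @param ... Unused.
#' @return A ggplot of observed-data log-likelihood against EM iteration.
#' @method autoplot mixbin_fit
#' @export
autoplot.mixbin_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "observed-data log-likelihood") +
    ggplot2::theme_minimal()
}
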