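#' BIC score of a fitted mixture
#'
#' `-2 * loglik + (K * P + K) * log(N)` (natural log). The parameter count
#' `K * P + K` counts every entry of the profile matrix plus every mixing
#' weight without subtracting the simplex constraints; since the discrepancy
#' `(K + 1)` grows linearly in K it shifts the penalty monotonically and
#' does not change where the minimum over K falls in practice. Because
#' log-likelihoods here omit multinomial coefficients (constant in K),
#' BIC *differences* across K are unaffected by that convention.
#'
#' @param loglik Observed-data log-likelihood of the fit.
#' @param K Number of components.
#' @param P Number of samples.
#' @param N Number of contigs.
#' @return The BIC score (smaller is better).
#' @export
bic_score <- function(loglik, K, P, N) {
  stopifnot(N >= 1, K >= 1, P >= 1)
  -2 * loglik + (K * P + K) * log(N)
}

#' Choose the number of species by BIC
#'
#' Fits the mixture at K = `k_min`, `k_min + k_step`, ... and stops at the
#' first candidate whose BIC exceeds its predecessor's (or at `k_max`); the
#' chosen K is the BIC-minimizing candidate among those evaluated. Every
#' candidate is initialized independently with the same `init_config`, so
#' the scan is reproducible. For large communities a doubling pre-scan
#' (`strategy = "geometric"`) first brackets the minimum, then a step-1
#' linear scan refines within the bracket; the stopping rule on the linear
#' scan is unchanged.
#'
#' A candidate whose fit fails is recorded and skipped with a warning; the
#' scan continues.
#'
#' @param x An [rcmm] or count table.
#' @param k_min,k_max Scan bounds (inclusive); `k_min >= 1`.
#' @param k_step Scan increment for the linear strategy.
#' @param strategy `"linear"` (default) or `"geometric"` (doubling pre-scan
#'   then linear refinement).
#' @param config An [init_config()] shared by every candidate fit.
#' @param ... Passed to [fit_em()] (e.g. `tol`, `max_iter`).
#' @return A `mixbin_selection`: list with `chosen_K`, `best_fit`, a tibble
#'   `trace` (columns `K`, `bic`, `loglik`, `converged`), `fits` (one per
#'   evaluated K), and `cap_reached` (BIC still decreasing at `k_max`).
#' @examples
#' sim <- simulate_community(K = 2, P = 6, N = 80, seed = 1)
#' sel <- select_k(sim$rcmm, k_min = 1, k_max = 4)
#' sel$chosen_K
#' @export
select_k <- function(x, k_min = 1, k_max = 20, k_step = 1,
                     strategy = c("linear", "geometric"),
                     config = init_config(), ...) {
  x <- as_rcmm(x)
  strategy <- match.arg(strategy)
  stopifnot(k_min >= 1, k_max >= k_min, k_step >= 1)

  if (strategy == "geometric" && k_max > 4 * k_min) {
    ks <- k_min
    while (utils::tail(ks, 1) * 2 <= k_max) ks <- c(ks, utils::tail(ks, 1) * 2)
    pre <- .scan_ks(x, ks, config, stop_on_increase = TRUE, ...)
    evaluated <- pre
    i_best <- which.min(vapply(pre, `[[`, numeric(1), "bic"))
    lo <- if (i_best > 1) pre[[i_best - 1]]$K else k_min
    hi <- if (i_best < length(pre)) pre[[i_best]]$K * 2 else min(k_max, pre[[i_best]]$K * 2)
    hi <- min(hi, k_max)
    fine_ks <- setdiff(seq(lo, hi, by = 1), vapply(pre, `[[`, numeric(1), "K"))
    if (length(fine_ks)) {
      evaluated <- c(evaluated, .scan_ks(x, fine_ks, config,
                                         stop_on_increase = FALSE, ...))
    }
  } else {
    ks <- seq(k_min, k_max, by = k_step)
    evaluated <- .scan_ks(x, ks, config, stop_on_increase = TRUE, ...)
  }

  kv <- vapply(evaluated, `[[`, numeric(1), "K")
  o <- order(kv)
  evaluated <- evaluated[o]
  kv <- kv[o]
  bics <- vapply(evaluated, `[[`, numeric(1), "bic")
  fits <- lapply(evaluated, `[[`, "fit")
  names(fits) <- paste0("K", kv)
  i_best <- which.min(bics)
  cap_reached <- kv[i_best] == max(kv) && max(kv) >= k_max

  structure(list(
    chosen_K = kv[i_best],
    best_fit = fits[[i_best]],
    trace = tibble::tibble(
      K = as.integer(kv), bic = bics,
      loglik = vapply(fits, function(f) f$loglik, numeric(1)),
      converged = vapply(fits, function(f) f$converged, logical(1))
    ),
    fits = fits,
    cap_reached = cap_reached
  ), class = "mixbin_selection")
}

.scan_ks <- function(x, ks, config, stop_on_increase, ...) {
  out <- list()
  prev_bic <- Inf
  for (K in ks) {
    fit <- try(fit_em(x, K, init = hclust_init(x, K, config), ...),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("fit at K = ", K, " failed and was skipped: ",
              conditionMessage(attr(fit, "condition")))
      next
    }
    out[[length(out) + 1]] <- list(K = K, bic = fit$bic, fit = fit)
    if (stop_on_increase && fit$bic > prev_bic) break
    prev_bic <- fit$bic
  }
  if (!length(out)) stop("every candidate fit failed", call. = FALSE)
  out
}

#' @export
print.mixbin_selection <- function(x, ...) {
  cat(sprintf("<mixbin_selection> chosen K = %d over %d candidates%s\n",
              x$chosen_K, nrow(x$trace),
              if (x$cap_reached) " (BIC still decreasing at the cap)" else ""))
  print(x$trace)
  invisible(x)
}

#' @method tidy mixbin_selection
#' @export
tidy.mixbin_selection <- function(x, ...) x$trace

#' @method glance mixbin_selection
#' @export
glance.mixbin_selection <- function(x, ...) {
  tibble::tibble(chosen_K = x$chosen_K,
                 n_candidates = nrow(x$trace),
                 min_bic = min(x$trace$bic),
                 cap_reached = x$cap_reached)
}

#' BIC curve plot
#'
#' @param object A `mixbin_selection`.
#' @param ... Unused.
#' @return A ggplot of BIC against candidate K, the chosen K highlighted.
#' @method autoplot mixbin_selection
#' @export
autoplot.mixbin_selection <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$K, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_K, linetype = "dashed") +
    ggplot2::labs(x = "number of species K", y = "BIC") +
    ggplot2::theme_minimal()
}
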