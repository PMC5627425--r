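#' Non-negative matrix factorization of the count matrix
#'
#' Alternative view of the binning problem: if noise is ignored, the count
#' matrix factors as X = M E, where M (N x K) is a *signature* matrix --
#' entry (i, k) is the number of reads one copy of contig i produces when it
#' belongs to species k, zero otherwise -- and E (K x P) is the species'
#' total abundance per sample. Minimizing the Frobenius norm ||X - M E||_F
#' over non-negative factors recovers both; row-normalizing E gives the
#' sample-profile matrix A. The factorization serves as a diagnostic
#' cross-check of the EM fit: it offers no principled choice of K and no
#' uncertainty, so it is not the primary fit path.
#'
#' Optimization uses the classical multiplicative updates for the Frobenius
#' objective, which never increase the residual, from a seeded random
#' non-negative start scaled to the data mean.
#'
#' @param x An [rcmm] or count table.
#' @param K Factorization rank (number of species); `K <= min(N, P)`.
#' @param max_iter Maximum update sweeps.
#' @param tol Relative residual change declaring convergence.
#' @param seed Integer seed for the random initialization.
#' @return A `mixbin_nmf`: list with `M`, `E`, `profiles` (row-normalized
#'   E), `residual` (final Frobenius norm of X - M E), `residual_trace`,
#'   `converged`, `n_iter`.
#' @seealso [nmf_labels()] for hard assignments comparable with the EM fit.
#' @export
nmf_factorize <- function(x, K, max_iter = 500, tol = 1e-6, seed = 1) {
  x <- as_rcmm(x)
  X <- x$counts
  storage.mode(X) <- "double"
  N <- nrow(X); P <- ncol(X)
  if (K < 1 || K > min(N, P)) {
    stop("K must be between 1 and min(N, P) = ", min(N, P), call. = FALSE)
  }
  eps <- .Machine$double.eps

  with_preserved_seed(seed, {
    M <- matrix(stats::runif(N * K, min = eps), N, K)
    E <- matrix(stats::runif(K * P, min = eps), K, P)
  })
  # scale so the initial product matches X's mean
  sc <- mean(X) / mean(M %*% E)
  M <- M * sqrt(sc); E <- E * sqrt(sc)

  normX <- sqrt(sum(X^2))
  res <- sqrt(sum((X - M %*% E)^2))
  trace <- res
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- E * (t(M) %*% X) / (t(M) %*% M %*% E + eps)
    M <- M * (X %*% t(E)) / (M %*% (E %*% t(E)) + eps)
    res_new <- sqrt(sum((X - M %*% E)^2))
    trace <- c(trace, res_new)
    if (abs(res - res_new) <= tol * max(res, eps)) {
      converged <- TRUE
      res <- res_new
      break
    }
    res <- res_new
  }

  rs <- rowSums(E)
  profiles <- E / ifelse(rs > 0, rs, 1)
  dimnames(M) <- list(rownames(X), paste0("bin_", seq_len(K)))
  dimnames(E) <- list(paste0("bin_", seq_len(K)), colnames(X))
  dimnames(profiles) <- dimnames(E)

  structure(list(
    M = M, E = E, profiles = profiles,
    residual = res, relative_residual = res / max(normX, eps),
    residual_trace = trace, converged = converged,
    n_iter = length(trace) - 1L
  ), class = "mixbin_nmf")
}

#' @export
print.mixbin_nmf <- function(x, ...) {
  cat(sprintf(
    "<mixbin_nmf> rank %d; relative residual %.3g after %d iterations (%s)\n",
    ncol(x$M), x$relative_residual, x$n_iter,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' Hard bin labels from an NMF factorization
#'
#' Assigns each contig to the species whose signature column dominates its
#' row of M (lowest-index tie-break), making the factorization directly
#' comparable with the EM labeling through [evaluate_binning()]. A contig
#' whose M row is entirely zero gets the sentinel label `NA`.
#'
#' @param result A `mixbin_nmf` from [nmf_factorize()].
#' @return Named integer vector of length N (NA for all-zero rows).
#' @export
nmf_labels <- function(result) {
  stopifnot(inherits(result, "mixbin_nmf"))
  lab <- max.col(result$M, ties.method = "first")
  lab[rowSums(result$M) == 0] <- NA_integer_
  names(lab) <- rownames(result$M)
  lab
}

#' @method tidy mixbin_nmf
#' @export
tidy.mixbin_nmf <- function(x, ...) {
  tibble::tibble(
    contig_id = rownames(x$M) %||% as.character(seq_len(nrow(x$M))),
    bin = unname(nmf_labels(x))
  )
}

#' @method glance mixbin_nmf
#' @export
glance.mixbin_nmf <- function(x, ...) {
  tibble::tibble(K = ncol(x$M), residual = x$residual,
                 relative_residual = x$relative_residual,
                 n_iter = x$n_iter, converged = x$converged)
}
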