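#' Cosine distance between two count profiles
#'
#' `1 - cos(x1, x2)`: one minus the inner product over the product of
#' Euclidean norms. Scale-invariant, so raw count rows and normalized sample
#' profiles give the same distance; symmetric; 0 for parallel vectors and 1
#' for orthogonal ones (non-negative inputs keep it in \[0, 1\]).
#'
#' @param x1,x2 Non-negative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return Distance in \[0, 1\].
#' @examples
#' cosine_distance(c(1, 0), c(1, 1))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  if (any(x1 < 0) || any(x2 < 0)) stop("vectors must be non-negative", call. = FALSE)
  n1 <- sqrt(sum(x1^2))
  n2 <- sqrt(sum(x2^2))
  if (n1 == 0 || n2 == 0) stop("all-zero vector has no direction", call. = FALSE)
  d <- 1 - sum(x1 * x2) / (n1 * n2)
  min(max(d, 0), 1)
}

# full pairwise cosine distance matrix for the rows of X, as stats::dist
.cosine_dist_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("all-zero rows have no direction", call. = FALSE)
  G <- (X / nrm) %*% t(X / nrm)
  D <- 1 - G
  D[D < 0] <- 0
  stats::as.dist(D)
}

#' Initialization settings for the EM fit
#'
#' @param top_fraction Fraction of contigs, selected by descending total
#'   mapped reads, used for the hierarchical pre-clustering. Values in
#'   \[0.10, 0.30\] are the recommended range (deep contigs carry the least
#'   noisy profiles); values outside it warn but are honored.
#' @param linkage Agglomeration method for [stats::hclust()]; `"average"`
#'   (default), `"complete"` or `"ward.D2"`.
#' @param restarts Number of additional initializations obtained by
#'   resampling the selected subset; used by [fit_best()].
#' @return A list of class `init_config`.
#' @export
init_config <- function(top_fraction = 0.20,
                        linkage = c("average", "complete", "ward.D2"),
                        restarts = 0) {
  linkage <- match.arg(linkage)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  }
  if (top_fraction < 0.10 || top_fraction > 0.30) {
    warning("top_fraction outside the recommended [0.10, 0.30] range")
  }
  structure(list(top_fraction = top_fraction, linkage = linkage,
                 restarts = restarts), class = "init_config")
}

#' Starting parameters from hierarchical clustering of deep contigs
#'
#' Selects the `top_fraction` of contigs with the largest total mapped reads
#' (ties broken by input order), clusters them under [cosine_distance()]
#' with the configured linkage, cuts the tree at K clusters, and returns
#' starting parameters: each profile a_k is the mean of the cluster's
#' row-normalized count vectors (renormalized to the simplex) and pi_k is
#' the cluster's share of the selected contigs. Deterministic given the
#' inputs: no randomness is involved.
#'
#' @param x An [rcmm] or count table.
#' @param K Number of clusters; must not exceed the selected contig count.
#' @param config An [init_config()].
#' @return A [mixture_params] suitable as `init` for [fit_em()].
#' @export
hclust_init <- function(x, K, config = init_config()) {
  x <- as_rcmm(x)
  X <- x$counts
  n_sel <- ceiling(config$top_fraction * nrow(X))
  if (K > nrow(X)) {
    stop("K = ", K, " exceeds the number of contigs; reduce K", call. = FALSE)
  }
  if (K > n_sel) {
    stop("K = ", K, " exceeds the ", n_sel,
         " selected contigs; increase top_fraction or reduce K", call. = FALSE)
  }
  ord <- order(rowSums(X), decreasing = TRUE)   # stable: ties keep input order
  sel <- sort(ord[seq_len(n_sel)])
  Xs <- X[sel, , drop = FALSE]
  if (K == 1) {
    cl <- rep(1L, nrow(Xs))
  } else {
    hc <- stats::hclust(.cosine_dist_matrix(Xs), method = config$linkage)
    cl <- stats::cutree(hc, k = K)
  }
  Xn <- Xs / rowSums(Xs)
  A <- matrix(0, nrow = K, ncol = ncol(X))
  for (k in seq_len(K)) {
    A[k, ] <- colMeans(Xn[cl == k, , drop = FALSE])
  }
  A <- A / rowSums(A)
  colnames(A) <- colnames(X)
  pi <- as.numeric(tabulate(cl, nbins = K)) / length(cl)
  mixture_params(pi, A)
}

#' EM fit with random restarts
#'
#' Runs [fit_em()] from the deterministic [hclust_init()] start plus
#' `restarts` perturbed starts, each obtained by re-running the
#' hierarchical initialization on a random subsample (without replacement)
#' of the selected deep contigs, and returns the fit with the highest
#' log-likelihood.
#'
#' @inheritParams fit_em
#' @param config An [init_config()]; its `restarts` field sets the number of
#'   extra starts.
#' @param seed Integer seed controlling the restart subsamples.
#' @return The best-log-likelihood `mixbin_fit`.
#' @export
fit_best <- function(x, K, config = init_config(), seed = 1, ...) {
  x <- as_rcmm(x)
  best <- fit_em(x, K, init = hclust_init(x, K, config), ...)
  if (config$restarts > 0) {
    X <- x$counts
    n_sel <- max(K, ceiling(config$top_fraction * nrow(X)))
    ord <- order(rowSums(X), decreasing = TRUE)
    pool <- ord[seq_len(min(nrow(X), ceiling(1.5 * n_sel)))]
    with_preserved_seed(seed, {
      for (r in seq_len(config$restarts)) {
        take <- sort(sample(pool, size = min(length(pool), n_sel)))
        sub <- rcmm(X[take, , drop = FALSE], lengths = x$lengths[take])
        init_r <- try(hclust_init(sub, K, config), silent = TRUE)
        if (inherits(init_r, "try-error")) next
        fit_r <- try(fit_em(x, K, init = init_r, ...), silent = TRUE)
        if (!inherits(fit_r, "try-error") && fit_r$loglik > best$loglik) {
          best <- fit_r
        }
      }
    })
  }
  best
}

# evaluate `code` under a seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
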