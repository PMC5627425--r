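#' Simulate a synthetic metagenomic community
#'
#' Generates a contigs-by-samples count matrix with exactly the statistical
#' structure the mixture model assumes, plus its ground truth, so every
#' stage of the pipeline can be tested end to end without sequence data.
#' The generative process:
#'
#' 1. species sample profiles a_k ~ Dirichlet(alpha * 1_P);
#' 2. optionally, each (species, sample) entry is zeroed independently with
#'    probability `missing_fraction` and the row renormalized, emulating
#'    species absent from some samples; a row losing every sample is
#'    redrawn (warning after 100 attempts);
#' 3. contig labels z_i ~ Categorical(pi);
#' 4. contig lengths ~ LogNormal(`length_meanlog`, `length_sdlog`), bp;
#' 5. contig totals n_i ~ Poisson(length_i * depth), coupling read depth to
#'    contig length as pooled-assembly coverage does;
#' 6. counts x_i ~ Multinomial(n_i, a_\{z_i\}).
#'
#' Contigs drawing n_i = 0 carry no profile and are dropped (their ids are
#' reported in the truth). The same seed reproduces the output bit for bit;
#' the caller's RNG state is left untouched.
#'
#' @param K Number of species.
#' @param P Number of samples.
#' @param N Number of contigs drawn (the returned matrix may have fewer
#'   rows after zero-count contigs are dropped).
#' @param dirichlet_alpha Dirichlet concentration of the species profiles;
#'   1 (default) gives uniformly random profiles.
#' @param pi Mixing weights: `"uniform"` (default) or a length-K vector.
#' @param length_meanlog,length_sdlog Log-normal contig-length parameters;
#'   defaults give a median of 2000 bp, comfortably above the usual 1000 bp
#'   screening floor.
#' @param depth Expected pooled reads per bp; when `NULL` (default) it is
#'   set so the mean contig total equals `mean_reads`.
#' @param mean_reads Target mean reads per contig when `depth` is `NULL`
#'   (default 200).
#' @param missing_fraction Probability a species is absent from a given
#'   sample; in \[0, 1).
#' @param A Optional K x P profile matrix overriding step 1-2 (rows must be
#'   on the simplex); used e.g. to construct species with identical
#'   profiles as a negative control.
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `mixbin_sim` with `rcmm` (the [rcmm]) and
#'   `truth`: `labels` (named, retained contigs), `A_true` (K x P),
#'   `pi_true`, `b_true` (K x P true relative abundances on the same scale
#'   as [relative_abundance()]), and `dropped` (ids of zero-count contigs).
#' @examples
#' sim <- simulate_community(K = 3, P = 8, N = 200, seed = 42)
#' sim$rcmm
#' table(sim$truth$labels)
#' @export
simulate_community <- function(K, P, N, dirichlet_alpha = 1, pi = "uniform",
                               length_meanlog = log(2000), length_sdlog = 0.5,
                               depth = NULL, mean_reads = 200,
                               missing_fraction = 0, A = NULL, seed = 1) {
  stopifnot(K >= 1, P >= 1, N >= 1,
            missing_fraction >= 0, missing_fraction < 1)
  if (identical(pi, "uniform")) pi <- rep(1 / K, K)
  stopifnot(length(pi) == K, all(pi > 0))
  pi <- pi / sum(pi)
  if (is.null(depth)) {
    depth <- mean_reads / exp(length_meanlog + length_sdlog^2 / 2)
  }

  with_preserved_seed(seed, {
    if (is.null(A)) {
      A <- .rdirichlet(K, rep(dirichlet_alpha, P))
      if (missing_fraction > 0) {
        for (k in seq_len(K)) {
          for (attempt in seq_len(101)) {
            keep <- stats::runif(P) >= missing_fraction
            if (any(keep)) break
            if (attempt > 100) {
              warning("species ", k, " kept no sample after 100 draws; forcing one")
              keep[sample.int(P, 1)] <- TRUE
            }
          }
          row <- A[k, ] * keep
          A[k, ] <- row / sum(row)
        }
      }
    } else {
      A <- as.matrix(A)
      stopifnot(nrow(A) == K, ncol(A) == P,
                all(A >= 0), all(abs(rowSums(A) - 1) < 1e-8))
      A <- A / rowSums(A)
    }

    z <- sample.int(K, N, replace = TRUE, prob = pi)
    len <- pmax(1L, as.integer(round(stats::rlnorm(N, length_meanlog, length_sdlog))))
    n_i <- stats::rpois(N, lambda = len * depth)
    X <- matrix(0L, N, P)
    pos <- which(n_i > 0)
    for (i in pos) {
      X[i, ] <- as.integer(stats::rmultinom(1, n_i[i], A[z[i], ]))
    }
  })

  ids <- sprintf("contig_%0*d", nchar(N), seq_len(N))
  dimnames(X) <- list(ids, sprintf("sample_%02d", seq_len(P)))
  keep <- n_i > 0
  dropped <- ids[!keep]
  x <- rcmm(X[keep, , drop = FALSE], lengths = len[keep],
            library_sizes = colSums(X))
  labels <- z[keep]
  names(labels) <- ids[keep]

  b_true <- .true_abundance(A, labels, x)

  structure(list(
    rcmm = x,
    truth = list(labels = labels, A_true = A, pi_true = pi,
                 b_true = b_true, dropped = dropped),
    config = list(K = K, P = P, N = N, dirichlet_alpha = dirichlet_alpha,
                  depth = depth, missing_fraction = missing_fraction,
                  seed = seed)
  ), class = "mixbin_sim")
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# ground-truth analogue of relative_abundance(): same normalization, true
# labels and profiles; species with no retained contig get zero abundance
.true_abundance <- function(A, labels, x) {
  K <- nrow(A)
  n_i <- rowSums(x$counts)
  L_k <- vapply(seq_len(K), function(k) sum(as.numeric(x$lengths[labels == k])),
                numeric(1))
  reads_k <- vapply(seq_len(K), function(k) sum(n_i[labels == k]), numeric(1))
  T_j <- library_sizes(x)
  scale_k <- ifelse(L_k > 0, reads_k / pmax(L_k, 1), 0)
  b <- 1e9 * (A * scale_k) %*% diag(1 / T_j, length(T_j))
  colnames(b) <- colnames(x$counts)
  b
}

#' @export
print.mixbin_sim <- function(x, ...) {
  cat(sprintf("<mixbin_sim> K = %d species, %d contigs retained (%d dropped), %d samples\n",
              x$config$K, nrow(x$rcmm$counts), length(x$truth$dropped),
              x$config$P))
  invisible(x)
}

#' Per-sample accuracy of estimated relative abundances
#'
#' Matches fitted bins to true species by their sample profiles (Hungarian
#' assignment on L1 distance), computes the fitted relative abundances, and
#' returns the per-sample Pearson correlation between the estimated and
#' true abundance columns. Requires the fitted K to equal the simulated K.
#'
#' @param fit A `mixbin_fit` fitted to `sim$rcmm`.
#' @param sim A `mixbin_sim` from [simulate_community()].
#' @return A tibble with `sample` and `correlation`.
#' @export
abundance_recovery <- function(fit, sim) {
  stopifnot(inherits(fit, "mixbin_fit"), inherits(sim, "mixbin_sim"))
  K <- nrow(sim$truth$A_true)
  if (fit$K != K) {
    stop("fitted K (", fit$K, ") differs from simulated K (", K, ")",
         call. = FALSE)
  }
  perm <- match_components(fit$params$A, sim$truth$A_true)
  b_est <- abundance_matrix(relative_abundance(fit, sim$rcmm))[perm, , drop = FALSE]
  b_true <- sim$truth$b_true
  tibble::tibble(
    sample = colnames(b_true),
    correlation = vapply(seq_len(ncol(b_true)), function(j) {
      stats::cor(b_est[, j], b_true[, j])
    }, numeric(1))
  )
}

#' Run the pipeline over a grid of simulated communities
#'
#' For each row of `configs` (columns are [simulate_community()] arguments;
#' missing columns take that function's defaults): simulate, fit (at the
#' true K, or by [select_k()] when `select = TRUE`), and score the result
#' against the ground truth. Individual failures are recorded in the
#' `error` column and the sweep continues.
#'
#' @param configs A data frame, one simulated community per row.
#' @param select If `TRUE`, choose K by BIC (scan 1..`k_max`) instead of
#'   fitting at the true K.
#' @param k_max Scan cap when `select = TRUE`; default `2 * K + 2` per row.
#' @param ... Passed to [fit_em()].
#' @return A tibble: the config columns plus `ari`, `precision`, `recall`,
#'   `chosen_K`, `mean_abundance_cor`, `error`.
#' @examples
#' grid <- tibble::tibble(K = 2, P = 6, N = 80, mean_reads = 100, seed = 1:2)
#' sim_sweep(grid)
#' @export
sim_sweep <- function(configs, select = FALSE, k_max = NULL, ...) {
  configs <- tibble::as_tibble(configs)
  sim_args <- intersect(names(configs), names(formals(simulate_community)))
  rows <- purrr::map(seq_len(nrow(configs)), function(i) {
    cfg <- as.list(configs[i, sim_args, drop = FALSE])
    res <- tryCatch({
      sim <- do.call(simulate_community, cfg)
      if (select) {
        sel <- select_k(sim$rcmm, k_min = 1,
                        k_max = k_max %||% (2 * cfg$K + 2), ...)
        fit <- sel$best_fit
        chosen <- sel$chosen_K
      } else {
        fit <- fit_em(sim$rcmm, K = cfg$K, ...)
        chosen <- cfg$K
      }
      ev <- evaluate_binning(fit$labels, sim$truth$labels)
      ab_cor <- if (fit$K == cfg$K) {
        mean(abundance_recovery(fit, sim)$correlation)
      } else {
        NA_real_
      }
      tibble::tibble(ari = ev$ari, precision = ev$precision,
                     recall = ev$recall, chosen_K = chosen,
                     mean_abundance_cor = ab_cor, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(ari = NA_real_, precision = NA_real_, recall = NA_real_,
                     chosen_K = NA_integer_, mean_abundance_cor = NA_real_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(configs[i, , drop = FALSE], res)
  })
  dplyr::bind_rows(rows)
}
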