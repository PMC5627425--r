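#' Cross-tabulate two labelings
#'
#' Builds the r x s contingency table n_ij = number of items carrying
#' predicted label i and true label j, the sufficient statistic for every
#' clustering-agreement metric in this package. Labels may be any atomic
#' values; `NA` labels are rejected.
#'
#' @param pred,truth Equal-length label vectors (N >= 2 items).
#' @return Integer matrix of class `contingency` with predicted clusters in
#'   rows and true clusters in columns.
#' @export
contingency <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("label vectors differ in length (", length(pred), " vs ",
         length(truth), ")", call. = FALSE)
  }
  if (length(pred) < 2) stop("need at least 2 items", call. = FALSE)
  if (anyNA(pred) || anyNA(truth)) stop("NA labels not allowed", call. = FALSE)
  tab <- table(pred = pred, truth = truth)
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  class(m) <- c("contingency", class(m))
  m
}

.as_contingency <- function(x, truth = NULL) {
  if (inherits(x, "contingency")) return(x)
  if (is.matrix(x) && is.null(truth)) {
    m <- x
    storage.mode(m) <- "integer"
    class(m) <- c("contingency", class(m))
    return(m)
  }
  contingency(x, truth)
}

# exact C(n, 2); doubles hold these integers exactly for any realistic N
.choose2 <- function(n) n * (n - 1) / 2

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions:
#' (sum_ij C(n_ij,2) - E) / (0.5 * \[sum_i C(r_i,2) + sum_j C(c_j,2)\] - E)
#' with E = sum_i C(r_i,2) * sum_j C(c_j,2) / C(N,2). Equals 1 for
#' identical partitions, is near 0 for independent ones, and can be
#' negative. All binomial sums are computed in exact integer arithmetic
#' (doubles represent them exactly), so no cancellation error accrues at
#' large N.
#'
#' When both partitions are trivial (the denominator is 0: both all-in-one
#' or both all-singletons) the partitions are necessarily identical and the
#' index is defined as 1.
#'
#' @param x Either a `contingency` table (or plain matrix of counts), or a
#'   predicted label vector (then supply `truth`).
#' @param truth True label vector when `x` is a label vector.
#' @return The ARI, a scalar in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2, 2, 1), c(1, 1, 1, 2, 2, 2))  # -1/9
#' @export
adjusted_rand_index <- function(x, truth = NULL) {
  tab <- .as_contingency(x, truth)
  N <- sum(tab)
  r <- rowSums(tab)
  cc <- colSums(tab)
  sum_ij <- sum(.choose2(as.numeric(tab)))
  sum_r <- sum(.choose2(as.numeric(r)))
  sum_c <- sum(.choose2(as.numeric(cc)))
  E <- sum_r * sum_c / .choose2(N)
  denom <- (sum_r + sum_c) / 2 - E
  if (denom == 0) {
    # both partitions trivial; they can only be the same partition
    return(1)
  }
  (sum_ij - E) / denom
}

#' Binning precision
#'
#' Fraction of items correctly grouped under the most favorable assignment
#' of a true species to each predicted cluster:
#' sum over predicted clusters of their largest overlap with any true
#' cluster, over N. High precision means predicted bins are pure.
#'
#' @inheritParams adjusted_rand_index
#' @return Precision in (0, 1\].
#' @export
binning_precision <- function(x, truth = NULL) {
  tab <- .as_contingency(x, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}

#' Binning recall
#'
#' How well the best predicted cluster for each true species regroups that
#' species' items: sum over true clusters of their largest overlap with any
#' predicted cluster, over N. High recall means species are not fragmented
#' across bins.
#'
#' @inheritParams adjusted_rand_index
#' @return Recall in (0, 1\].
#' @export
binning_recall <- function(x, truth = NULL) {
  tab <- .as_contingency(x, truth)
  sum(apply(tab, 2, max)) / sum(tab)
}

#' Evaluate a binning against ground truth
#'
#' One-call wrapper computing the three standard clustering-agreement
#' metrics from a pair of labelings.
#'
#' @param pred Predicted label vector (or a data frame with columns
#'   `contig_id` and `bin`, as written by the CLI; then `truth` must be in
#'   the same form and is joined on `contig_id`).
#' @param truth True labels in the same form as `pred`.
#' @return A one-row tibble with `ari`, `precision`, `recall`, `n`.
#' @examples
#' evaluate_binning(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
evaluate_binning <- function(pred, truth) {
  if (is.data.frame(pred)) {
    stopifnot(is.data.frame(truth),
              all(c("contig_id", "bin") %in% names(pred)),
              all(c("contig_id", "bin") %in% names(truth)))
    joined <- dplyr::inner_join(pred, truth, by = "contig_id",
                                suffix = c("_pred", "_true"))
    if (nrow(joined) < length(unique(pred$contig_id))) {
      warning("contig_ids not shared by both labelings were dropped")
    }
    pred <- joined$bin_pred
    truth <- joined$bin_true
  }
  tab <- contingency(pred, truth)
  tibble::tibble(
    ari = adjusted_rand_index(tab),
    precision = binning_precision(tab),
    recall = binning_recall(tab),
    n = sum(tab)
  )
}

#' Match estimated components to reference components
#'
#' Resolves label switching: finds the one-to-one assignment of estimated
#' profile rows to reference profile rows minimizing the total L1 profile
#' distance (Hungarian algorithm). Used by recovery checks that compare a
#' fitted profile matrix against the generating truth.
#'
#' @param A_est,A_ref Matrices with the same number of rows (components) and
#'   columns (samples).
#' @return Integer permutation `perm` such that `A_est[perm\[k\], ]`
#'   corresponds to `A_ref[k, ]`.
#' @export
match_components <- function(A_est, A_ref) {
  stopifnot(nrow(A_est) == nrow(A_ref), ncol(A_est) == ncol(A_ref))
  K <- nrow(A_ref)
  cost <- matrix(0, K, K)
  for (k in seq_len(K)) {
    cost[k, ] <- colSums(abs(t(A_est) - A_ref[k, ]))
  }
  as.integer(clue::solve_LSAP(cost))
}
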