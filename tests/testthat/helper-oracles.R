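# Independent oracles used across the suite. Each deliberately avoids the
# package's own computational path (no log-space tricks, no contingency
# formula): direct products, pair enumeration, permutation search.

# Posterior responsibilities by direct Bayes arithmetic on raw products;
# valid only for tiny counts where a^x does not underflow.
oracle_posterior <- function(X, pi, A) {
  out <- matrix(0, nrow(X), length(pi))
  for (i in seq_len(nrow(X))) {
    w <- vapply(seq_along(pi), function(k) pi[k] * prod(A[k, ]^X[i, ]),
                numeric(1))
    out[i, ] <- w / sum(w)
  }
  out
}

# Adjusted Rand by brute-force enumeration of all C(N,2) item pairs.
oracle_pair_ari <- function(pred, truth) {
  n <- length(pred)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- pred[i] == pred[j]
      st <- truth[i] == truth[j]
      if (sp && st) n11 <- n11 + 1
      if (sp) n10 <- n10 + 1   # together in pred (incl. both)
      if (st) n01 <- n01 + 1   # together in truth (incl. both)
    }
  }
  total <- n * (n - 1) / 2
  expected <- n10 * n01 / total
  max_index <- (n10 + n01) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

random_partition <- function(n, max_groups) {
  sample.int(max_groups, n, replace = TRUE)
}

# Best component matching by exhaustive permutation search (K <= 7),
# independent of the Hungarian solver used in the package.
oracle_match <- function(A_est, A_ref) {
  K <- nrow(A_ref)
  stopifnot(K <= 7)
  perms <- .permutations(K)
  costs <- apply(perms, 1, function(p) sum(abs(A_est[p, ] - A_ref)))
  as.integer(perms[which.min(costs), ])
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE]))
  }
  unname(out)
}

# small valid parameter set and count matrix for property loops
random_instance <- function(N, P, K) {
  A <- matrix(rgamma(K * P, 1), K)
  A <- A / rowSums(A)
  pi <- rgamma(K, 1); pi <- pi / sum(pi)
  z <- sample.int(K, N, replace = TRUE)
  n_i <- rpois(N, 30) + 1
  X <- t(vapply(seq_len(N), function(i) {
    as.integer(rmultinom(1, n_i[i], A[z[i], ]))
  }, integer(P)))
  list(x = rcmm(X, lengths = rep(1000L, N)),
       params = mixture_params(pi, A), z = z)
}

# minimal SAM text for alignment-counting tests
write_sam <- function(path, targets, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, rname, pos = 1, flag = 0, mapq = 60,
                       seq = "ACGTACGTAC") {
  cigar <- if (bitwAnd(flag, 4L)) "*" else paste0(nchar(seq), "M")
  if (bitwAnd(flag, 4L)) { rname <- "*"; pos <- 0; mapq <- 0 }
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
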