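#' Per-sample relative abundance of each species bin
#'
#' RPKM-style normalization of the fitted mixture into comparable
#' abundances: for bin k and sample j,
#'
#'   b_kj = 1e9 * a_kj * (total mapped reads in bin k) / (L_k * T_j),
#'
#' where a_kj is the bin's fitted sample profile, L_k the summed length (bp)
#' of the bin's contigs -- a proxy for the species' genome length -- and
#' T_j the sample's library size (see [library_sizes()] for the fallback
#' when none was recorded). The 1e9 constant puts values in a convenient
#' range, as in RPKM. A species is called *significant* in a sample when its
#' abundance is at least 0.1% of that sample's total abundance (inclusive);
#' smaller values are dominated by estimation error.
#'
#' Counts corrected externally (e.g. for GC bias) can be supplied by
#' building the [rcmm] from the corrected table; no correction is applied
#' here.
#'
#' @param fit A `mixbin_fit` from [fit_em()], or a [mixture_params] (then
#'   `labels` must be given).
#' @param x The [rcmm] the model was fitted to.
#' @param labels Optional hard bin labels (defaults to `fit$labels`).
#' @param cutoff Significance cutoff as a fraction of the per-sample total
#'   abundance (default 0.001).
#' @return A tibble of class `mixbin_abundance` with one row per
#'   (bin, sample): columns `bin`, `sample`, `abundance`, `significant`,
#'   `bin_length` (L_k), `bin_reads` (total mapped reads in the bin).
#' @seealso [significant_species()], [abundance_matrix()]
#' @export
relative_abundance <- function(fit, x, labels = NULL, cutoff = 0.001) {
  x <- as_rcmm(x)
  if (inherits(fit, "mixbin_fit")) {
    params <- fit$params
    labels <- labels %||% fit$labels
  } else if (inherits(fit, "mixture_params")) {
    params <- fit
    if (is.null(labels)) stop("`labels` required with bare mixture_params", call. = FALSE)
  } else {
    stop("`fit` must be a mixbin_fit or mixture_params", call. = FALSE)
  }
  K <- length(params$pi)
  N <- nrow(x$counts)
  if (length(labels) != N) stop("labels length must match contig count", call. = FALSE)
  if (any(labels < 1 | labels > K)) stop("labels outside 1..K", call. = FALSE)

  n_i <- rowSums(x$counts)
  L_k <- vapply(seq_len(K), function(k) sum(as.numeric(x$lengths[labels == k])),
                numeric(1))
  reads_k <- vapply(seq_len(K), function(k) sum(n_i[labels == k]), numeric(1))
  if (any(L_k == 0)) {
    stop("empty bin(s): ", paste(which(L_k == 0), collapse = ", "),
         "; drop them (refit with smaller K) before computing abundance",
         call. = FALSE)
  }
  T_j <- library_sizes(x)

  # b = 1e9 * a_kj * reads_k / (L_k * T_j), K x P; a zero-read sample
  # (T_j = 0) has zero abundance everywhere rather than 0/0
  inv_T <- ifelse(T_j > 0, 1 / T_j, 0)
  b <- 1e9 * (params$A * reads_k / L_k) %*% diag(inv_T, length(inv_T))
  colnames(b) <- colnames(x$counts)

  col_tot <- colSums(b)
  zero_col <- col_tot == 0
  if (any(zero_col)) {
    warning("sample(s) with zero total abundance: ",
            paste(colnames(b)[zero_col], collapse = ", "))
  }
  sig <- sweep(b, 2, ifelse(zero_col, Inf, cutoff * col_tot), ">=")

  out <- tibble::tibble(
    bin = rep(seq_len(K), each = ncol(b)),
    sample = rep(colnames(b), times = K),
    abundance = as.vector(t(b)),
    significant = as.vector(t(sig)),
    bin_length = rep(L_k, each = ncol(b)),
    bin_reads = rep(reads_k, each = ncol(b))
  )
  class(out) <- c("mixbin_abundance", class(out))
  attr(out, "cutoff") <- cutoff
  out
}

#' Wide K x P abundance matrix
#'
#' @param abund A `mixbin_abundance` tibble from [relative_abundance()].
#' @param value Which value to spread: `"abundance"` or `"significant"`.
#' @return A K x P matrix, bins in rows and samples in columns.
#' @export
abundance_matrix <- function(abund, value = c("abundance", "significant")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(abund), "bin", "sample",
                  dplyr::all_of(value)),
    names_from = "sample", values_from = dplyr::all_of(value)
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- paste0("bin_", wide$bin)
  m
}

#' Count significant species per sample
#'
#' A species is significant in a sample when its relative abundance is at
#' least `cutoff` (default 0.1%) of the sample's total relative abundance,
#' inclusive. The per-sample count of significant species is a simple
#' biodiversity summary comparable across groups of samples.
#'
#' @param abund A `mixbin_abundance` from [relative_abundance()] (its stored
#'   cutoff is reused).
#' @return A tibble with one row per sample: `sample`, `n_significant`.
#' @export
significant_species <- function(abund) {
  stopifnot(inherits(abund, "mixbin_abundance"))
  tibble::as_tibble(abund) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_significant = sum(.data$significant), .groups = "drop") |>
    dplyr::arrange(match(.data$sample, unique(abund$sample)))
}

#' Abundance heatmap
#'
#' @param object A `mixbin_abundance`.
#' @param ... Unused.
#' @return A ggplot tile map of log10(1 + abundance), significant cells
#'   outlined.
#' @method autoplot mixbin_abundance
#' @export
autoplot.mixbin_abundance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, factor(.data$bin))) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(1 + .data$abundance))) +
    ggplot2::geom_tile(data = df[df$significant, , drop = FALSE],
                       fill = NA, colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "log10(1 + b)") +
    ggplot2::labs(x = "sample", y = "bin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
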