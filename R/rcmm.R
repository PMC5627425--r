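#' Contigs-by-samples read-count matrix
#'
#' An `rcmm` (read counts mapping matrix) holds the central data structure of
#' the package: an N x P matrix of non-negative integer read counts, one row
#' per assembled contig and one column per metagenomic sample, together with
#' contig lengths (bp) and, optionally, per-sample library sizes (the total
#' number of reads sequenced in each sample, used for abundance
#' normalization). Each row, normalized to sum to one, is the contig's
#' *sample profile* -- the proportions of its mapped reads contributed by
#' each sample -- which is the only signal used for binning.
#'
#' @param counts Numeric matrix of non-negative integer counts, contigs in
#'   rows and samples in columns. Dimnames, when present, supply contig and
#'   sample identifiers.
#' @param lengths Positive integer vector of contig lengths in base pairs,
#'   one per row of `counts`.
#' @param library_sizes Optional positive numeric vector of per-sample total
#'   read counts (one per column). Each entry must be at least the
#'   corresponding column sum. When absent, downstream code falls back to
#'   column sums (i.e., treats every sequenced read as mapped).
#' @param contig_ids,sample_ids Optional character identifiers; default to
#'   the dimnames of `counts` or generated `contig_<i>` / `sample_<j>` names.
#'
#' @return An object of class `rcmm`: a list with elements `counts`
#'   (integer matrix with dimnames), `lengths` (named integer vector) and
#'   `library_sizes` (named numeric vector or `NULL`).
#' @seealso [read_count_table()], [count_from_alignments()],
#'   [filter_contigs()], [as_rcmm()]
#' @examples
#' x <- rcmm(matrix(c(2, 1, 0, 4), nrow = 2), lengths = c(1500, 2000))
#' x
#' @export
rcmm <- function(counts, lengths, library_sizes = NULL,
                 contig_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending entry at row %d, column %d (value %s)",
      ij[1], ij[2], format(counts[bad[1]])
    ), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  p <- ncol(counts)

  contig_ids <- contig_ids %||% rownames(counts) %||% paste0("contig_", seq_len(n))
  sample_ids <- sample_ids %||% colnames(counts) %||% paste0("sample_", seq_len(p))
  contig_ids <- as.character(contig_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(contig_ids)) {
    stop("duplicate contig_id: ", contig_ids[duplicated(contig_ids)][1], call. = FALSE)
  }
  if (length(contig_ids) != n || length(sample_ids) != p) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }

  lengths <- as.numeric(lengths)
  if (length(lengths) != n || any(!is.finite(lengths)) || any(lengths < 1) ||
      any(lengths != round(lengths))) {
    stop("`lengths` must be positive integers, one per contig", call. = FALSE)
  }
  lengths <- as.integer(lengths)
  names(lengths) <- contig_ids

  if (!is.null(library_sizes)) {
    library_sizes <- as.numeric(library_sizes)
    if (length(library_sizes) != p || any(!is.finite(library_sizes)) ||
        any(library_sizes < 0)) {
      stop("`library_sizes` must be non-negative, one per sample", call. = FALSE)
    }
    short <- library_sizes < colSums(counts)
    if (any(short)) {
      stop("library_sizes smaller than mapped counts for sample(s): ",
           paste(sample_ids[short], collapse = ", "), call. = FALSE)
    }
    names(library_sizes) <- sample_ids
  }

  dimnames(counts) <- list(contig_ids, sample_ids)
  structure(
    list(counts = counts, lengths = lengths, library_sizes = library_sizes),
    class = "rcmm"
  )
}

#' @export
print.rcmm <- function(x, ...) {
  cat(sprintf(
    "<rcmm> %d contigs x %d samples; %s mapped reads; lengths %d-%d bp%s\n",
    nrow(x$counts), ncol(x$counts), format(sum(as.numeric(x$counts)), big.mark = ","),
    min(x$lengths), max(x$lengths),
    if (is.null(x$library_sizes)) "" else "; library sizes set"
  ))
  invisible(x)
}

#' @export
dim.rcmm <- function(x) dim(x$counts)

#' Coerce tabular count data to an `rcmm`
#'
#' The tabular layout mirrors the on-disk TSV format: a `contig_id` column,
#' a `length` column (bp), then one integer count column per sample.
#'
#' @param x A data frame in count-table layout, a numeric matrix, or an
#'   `rcmm` (returned unchanged).
#' @param library_sizes Optional per-sample total read counts.
#' @param ... Unused.
#' @return An [rcmm] object.
#' @examples
#' tbl <- tibble::tibble(contig_id = c("c1", "c2"), length = c(1500L, 2000L),
#'                       s1 = c(2L, 1L), s2 = c(0L, 4L))
#' as_rcmm(tbl)
#' @export
as_rcmm <- function(x, ...) UseMethod("as_rcmm")

#' @export
as_rcmm.rcmm <- function(x, ...) x

#' @export
as_rcmm.matrix <- function(x, library_sizes = NULL, ...) {
  # matrices carry no length information; assume unit-length contigs so the
  # object is usable for fitting (abundance needs real lengths)
  rcmm(x, lengths = rep(1L, nrow(x)), library_sizes = library_sizes)
}

#' @rdname as_rcmm
#' @export
as_rcmm.data.frame <- function(x, library_sizes = NULL, ...) {
  need <- c("contig_id", "length")
  if (!all(need %in% names(x))) {
    stop("count table must have columns `contig_id` and `length` before the sample columns",
         call. = FALSE)
  }
  sample_cols <- setdiff(names(x), need)
  if (!length(sample_cols)) stop("count table has no sample columns", call. = FALSE)
  counts <- as.matrix(x[sample_cols])
  for (j in seq_along(sample_cols)) {
    v <- counts[, j]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("invalid count at contig_id '%s', sample '%s': %s",
                   x$contig_id[bad[1]], sample_cols[j], format(v[bad[1]])),
           call. = FALSE)
    }
  }
  rcmm(counts, lengths = x$length, library_sizes = library_sizes,
       contig_ids = x$contig_id, sample_ids = sample_cols)
}

#' @export
as.data.frame.rcmm <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' Tidy view of an `rcmm`
#'
#' @param x An [rcmm].
#' @param ... Unused.
#' @return A tibble in count-table layout (`contig_id`, `length`, one column
#'   per sample).
#' @importFrom tibble as_tibble
#' @method as_tibble rcmm
#' @export
as_tibble.rcmm <- function(x, ...) {
  tibble::as_tibble(cbind(
    tibble::tibble(contig_id = rownames(x$counts), length = unname(x$lengths)),
    tibble::as_tibble(x$counts)
  ))
}

#' Read / write a contigs-by-samples count table
#'
#' The TSV format has a header row `contig_id`, `length`, then one column per
#' sample; body rows hold integer counts. `write_count_table()` and
#' [read_count_table()] round-trip an `rcmm` exactly (library sizes are not
#' stored in the table; pass them separately on read).
#'
#' @param path Path to a tab-separated count table.
#' @param library_sizes Optional per-sample total read counts to attach.
#' @return An [rcmm].
#' @export
read_count_table <- function(path, library_sizes = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (anyDuplicated(tbl$contig_id)) {
    stop("duplicate contig_id in ", path, ": ",
         tbl$contig_id[duplicated(tbl$contig_id)][1], call. = FALSE)
  }
  as_rcmm(tbl, library_sizes = library_sizes)
}

#' @rdname read_count_table
#' @param x An [rcmm] to write.
#' @export
write_count_table <- function(x, path) {
  x <- as_rcmm(x)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Build the read-count matrix from per-sample alignments
#'
#' Counts, for each contig, the number of read records from each sample whose
#' primary alignment maps to it, producing the contigs-by-samples matrix the
#' mixture model clusters. One SAM or BAM file per sample; all files must be
#' aligned against the same contig set (identical reference headers). Contig
#' lengths are taken from the headers; `library_sizes` are the total read
#' records per file (primary mapped + unmapped), so that unmapped reads count
#' toward a sample's sequencing effort.
#'
#' @param alignment_paths Character vector of SAM/BAM paths, one per sample.
#' @param sample_ids Sample names; default is the file base names.
#' @param min_mapq Minimum mapping quality for a record to be counted.
#' @param primary_only If `TRUE` (default) secondary and supplementary
#'   alignments are never counted, so each read contributes to at most one
#'   contig's evidence.
#' @return An [rcmm] with contig metadata from the alignment headers.
#' @export
count_from_alignments <- function(alignment_paths, sample_ids = NULL,
                                  min_mapq = 0, primary_only = TRUE) {
  if (!length(alignment_paths)) stop("no alignment files given", call. = FALSE)
  sample_ids <- sample_ids %||%
    sub("\\.(sam|bam)$", "", basename(alignment_paths), ignore.case = TRUE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids", call. = FALSE)

  bams <- vapply(alignment_paths, .as_bam, character(1))

  headers <- lapply(bams, function(b) Rsamtools::scanBamHeader(b)[[1]]$targets)
  ref <- headers[[1]]
  if (!length(ref)) {
    stop("no reference sequences in header of ", alignment_paths[1], call. = FALSE)
  }
  for (i in seq_along(headers)[-1]) {
    if (!identical(headers[[i]], ref)) {
      stop("reference headers in ", alignment_paths[i],
           " do not match those in ", alignment_paths[1], call. = FALSE)
    }
  }

  counts <- matrix(0L, nrow = length(ref), ncol = length(bams),
                   dimnames = list(names(ref), sample_ids))
  lib <- numeric(length(bams))
  for (j in seq_along(bams)) {
    flag <- Rsamtools::scanBamFlag(
      isSecondaryAlignment = if (primary_only) FALSE else NA,
      isSupplementaryAlignment = if (primary_only) FALSE else NA
    )
    prm <- Rsamtools::ScanBamParam(flag = flag, what = "rname",
                                   mapqFilter = if (min_mapq > 0) min_mapq else NA_integer_)
    rn <- Rsamtools::scanBam(bams[j], param = prm)[[1]]$rname
    if (!length(rn)) {
      # distinguish "no records at all" from "none mapped"
      n_any <- Rsamtools::countBam(bams[j])$records
      if (n_any == 0) stop("empty alignment file: ", alignment_paths[j], call. = FALSE)
    }
    tab <- table(factor(rn[!is.na(rn)], levels = names(ref)))
    counts[, j] <- as.integer(tab)
    # total read records: primary mapped + unmapped (secondary/supplementary
    # records re-describe a read already counted)
    lib_flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                       isSupplementaryAlignment = FALSE)
    lib[j] <- Rsamtools::countBam(
      bams[j], param = Rsamtools::ScanBamParam(flag = lib_flag)
    )$records
  }

  rcmm(counts, lengths = unname(ref), library_sizes = lib,
       contig_ids = names(ref), sample_ids = sample_ids)
}

.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = ".bam")
  Rsamtools::asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Screen contigs by length and coverage
#'
#' Short contigs carry noisy sample profiles and very low-coverage contigs
#' carry almost no signal; both are routinely trimmed before fitting. The
#' default 1000 bp floor matches common practice for coverage-profile
#' binning. Thresholds are inclusive. Library sizes are left unchanged: they
#' describe the samples, not the retained matrix.
#'
#' @param x An [rcmm] (or count table coercible with [as_rcmm()]).
#' @param min_length Minimum contig length in bp to retain (inclusive).
#' @param min_total_count Minimum total mapped reads across samples
#'   (row sum) to retain (inclusive).
#' @return The filtered [rcmm].
#' @export
filter_contigs <- function(x, min_length = 1000, min_total_count = 0) {
  x <- as_rcmm(x)
  stopifnot(min_length >= 0, min_total_count >= 0)
  keep <- x$lengths >= min_length & rowSums(x$counts) >= min_total_count
  if (!any(keep)) {
    stop("filter removed all contigs (min_length = ", min_length,
         ", min_total_count = ", min_total_count, ")", call. = FALSE)
  }
  rcmm(x$counts[keep, , drop = FALSE], lengths = x$lengths[keep],
       library_sizes = x$library_sizes)
}

#' Per-sample library sizes with fallback
#'
#' Returns the stored library sizes, or the per-sample mapped-read totals
#' (column sums) when none were recorded -- a bare count table cannot know
#' how many reads went unmapped.
#'
#' @param x An [rcmm].
#' @return Named numeric vector, one entry per sample.
#' @export
library_sizes <- function(x) {
  x <- as_rcmm(x)
  x$library_sizes %||% colSums(x$counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
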