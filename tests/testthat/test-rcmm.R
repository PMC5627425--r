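test_that("rcmm construction validates counts, ids and library sizes", {
  x <- rcmm(matrix(c(2, 1, 0, 4), 2), lengths = c(1500, 2000))
  expect_s3_class(x, "rcmm")
  expect_equal(dim(x), c(2L, 2L))
  expect_identical(unname(x$counts[, 1]), c(2L, 1L))

  expect_error(rcmm(matrix(c(-1, 1, 0, 4), 2), lengths = c(10, 10)),
               "row 1, column 1")
  expect_error(rcmm(matrix(c(0.5, 1, 0, 4), 2), lengths = c(10, 10)),
               "non-negative integers")
  expect_error(rcmm(matrix(1:4, 2), lengths = c(0, 10)), "positive integers")
  expect_error(rcmm(matrix(1:4, 2, dimnames = list(c("a", "a"), NULL)),
                    lengths = c(10, 10)), "duplicate contig_id")
  # library sizes must cover the mapped counts
  expect_error(rcmm(matrix(c(2, 1, 0, 4), 2), lengths = c(10, 10),
                    library_sizes = c(2, 4)), "smaller than mapped")
  expect_silent(rcmm(matrix(c(2, 1, 0, 4), 2), lengths = c(10, 10),
                     library_sizes = c(3, 4)))
})

test_that("count table read/write round trip is bit-exact", {
  x <- rcmm(matrix(c(2L, 1L, 0L, 4L, 7L, 0L), 3),
            lengths = c(1500, 2000, 999),
            contig_ids = c("c1", "c2", "c3"), sample_ids = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(x, path)
  y <- read_count_table(path)
  expect_identical(y$counts, x$counts)
  expect_identical(y$lengths, x$lengths)
  expect_null(y$library_sizes)  # not stored in the table

  # library sizes can be re-attached on read
  z <- read_count_table(path, library_sizes = c(10, 20))
  expect_equal(unname(library_sizes(z)), c(10, 20))
})

test_that("tabular coercion reports the offending cell", {
  tbl <- tibble::tibble(contig_id = c("c1", "c2"), length = c(100L, 100L),
                        s1 = c(1L, -1L), s2 = c(0L, 2L))
  expect_error(as_rcmm(tbl), "c2.*s1")
  expect_error(as_rcmm(tbl[, c("contig_id", "length")]), "no sample columns")
  expect_error(as_rcmm(tibble::tibble(s1 = 1)), "contig_id")
})

test_that("filter_contigs applies inclusive length and count thresholds", {
  x <- rcmm(matrix(c(5L, 0L, 3L, 0L, 0L, 6L), 3),
            lengths = c(999, 1000, 1500),
            contig_ids = c("a", "b", "c"))
  f <- filter_contigs(x, min_length = 1000)
  expect_identical(rownames(f$counts), c("b", "c"))

  x2 <- rcmm(matrix(c(3L, 5L, 9L), 3), lengths = rep(2000L, 3),
             contig_ids = c("a", "b", "c"))
  f2 <- filter_contigs(x2, min_length = 0, min_total_count = 5)
  expect_identical(rownames(f2$counts), c("b", "c"))

  expect_identical(filter_contigs(x, 0, 0)$counts, x$counts)
  expect_error(filter_contigs(x, min_length = 1e6), "removed all contigs")

  # library sizes describe samples, not the filtered matrix
  x3 <- rcmm(x$counts, lengths = x$lengths, library_sizes = c(100, 100))
  expect_equal(unname(filter_contigs(x3, 1000)$library_sizes), c(100, 100))
})

test_that("alignment counting matches a hand-built SAM fixture", {
  targets <- c(c1 = 1000L, c2 = 2000L)
  s1 <- write_sam(withr::local_tempfile(fileext = ".sam"), targets, c(
    sam_record("r1", "c1"), sam_record("r2", "c1"), sam_record("r3", "c2"),
    sam_record("r4", "*", flag = 4)   # unmapped, counts toward library size
  ))
  s2 <- write_sam(withr::local_tempfile(fileext = ".sam"), targets, c(
    sam_record("q1", "c2"), sam_record("q2", "c2"),
    sam_record("q3", "c2"), sam_record("q4", "c2")
  ))
  x <- count_from_alignments(c(s1, s2), sample_ids = c("s1", "s2"))
  expect_identical(unname(x$counts), matrix(c(2L, 1L, 0L, 4L), 2))
  expect_equal(unname(x$lengths), c(1000L, 2000L))
  expect_equal(unname(x$library_sizes), c(4, 4))
  # entries sum to the number of retained primary alignments
  expect_equal(sum(x$counts), 7)
})

test_that("secondary alignments and low-MAPQ records are excluded", {
  targets <- c(c1 = 1000L, c2 = 2000L)
  s1 <- write_sam(withr::local_tempfile(fileext = ".sam"), targets, c(
    sam_record("r1", "c1", mapq = 60),
    sam_record("r1", "c2", flag = 256, mapq = 60),  # secondary copy of r1
    sam_record("r2", "c2", mapq = 5)
  ))
  x <- count_from_alignments(s1, sample_ids = "s1")
  expect_identical(unname(x$counts[, 1]), c(1L, 1L))

  xq <- count_from_alignments(s1, sample_ids = "s1", min_mapq = 10)
  expect_identical(unname(xq$counts[, 1]), c(1L, 0L))
})

test_that("mismatched reference headers name the offending file", {
  s1 <- write_sam(withr::local_tempfile(fileext = ".sam"),
                  c(c1 = 1000L, c2 = 2000L), sam_record("r1", "c1"))
  s2 <- write_sam(withr::local_tempfile(fileext = ".sam"),
                  c(c1 = 1000L, c3 = 500L), sam_record("r1", "c1"))
  expect_error(count_from_alignments(c(s1, s2)), basename(s2))
})
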