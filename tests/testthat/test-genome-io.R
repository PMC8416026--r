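write_pairs_file <- function(lines, lens = c(chr1 = 1e6)) {
  path <- tempfile(fileext = ".pairs")
  hdr <- c(
    "## pairs format v1.0",
    sprintf("#chromsize: %s %d", names(lens), lens)
  )
  writeLines(c(hdr, lines), path)
  path
}

test_that("binning tiles chromosomes without gaps, last bin clipped", {
  gb <- genomic_binning(c(chr1 = 95000, chr2 = 40000), bin_width = 10000)
  expect_equal(unname(gb$n_bins), c(10L, 4L))
  bt <- bin_table(gb)
  expect_equal(sum(bt$end - bt$start), 95000 + 40000)
  b1 <- bt[bt$chrom == "chr1", ]
  expect_equal(b1$start, seq(0, 90000, by = 10000))
  expect_equal(b1$end[10], 95000) # short last bin
  expect_true(all(b1$start[-1] == b1$end[-10])) # no gaps or overlaps
})

test_that("a single cis pair lands in the right bins; symmetry under swap", {
  p1 <- write_pairs_file("r1\tchr1\t1500\tchr1\t25500\t+\t-")
  m1 <- read_contacts(p1, bin_width = 10000, format = "pairs")
  expect_equal(m1$pixels$bin1, 0L)
  expect_equal(m1$pixels$bin2, 2L)
  expect_equal(m1$pixels$count, 1)
  p2 <- write_pairs_file("r1\tchr1\t25500\tchr1\t1500\t-\t+")
  m2 <- read_contacts(p2, bin_width = 10000, format = "pairs")
  expect_identical(m1$pixels, m2$pixels)
})

test_that("binned pairs match a brute-force tally, and counts are conserved", {
  set.seed(42)
  n <- 20
  pos1 <- sample(1:1e6, n)
  pos2 <- sample(1:1e6, n)
  lines <- sprintf("r%d\tchr1\t%d\tchr1\t%d\t+\t+", 1:n, pos1, pos2)
  path <- write_pairs_file(lines)
  m <- read_contacts(path, bin_width = 50000, format = "pairs")
  oracle <- oracle_dense_from_pairs("chr1", pos1, pos2, 1e6, 50000)
  expect_equal(as_dense_matrix(m, "chr1"), oracle)
  expect_equal(total_contacts(m), n) # conservation of cis pairs
})

test_that("minimal 4-column pairs and explicit chrom_lengths work", {
  path <- tempfile()
  writeLines(c("chr1 100 chr1 5200", "chr1 9000 chr2 100"), path)
  m <- read_contacts(path,
    bin_width = 1000, format = "pairs",
    chrom_lengths = c(chr1 = 10000, chr2 = 5000)
  )
  expect_equal(total_contacts(m), 1) # one cis pair
  expect_equal(nrow(m$trans), 1) # trans pair kept separately
  expect_equal(m$pixels$bin1, 0L)
  expect_equal(m$pixels$bin2, 5L)
})

test_that("pairs reader errors name the offender", {
  path <- write_pairs_file("r1\tchrUn\t100\tchr1\t200\t+\t+")
  expect_error(read_contacts(path, bin_width = 1000, format = "pairs"), "chrUn")
  path2 <- write_pairs_file(c(
    "r1\tchr1\t100\tchr1\t200\t+\t+",
    "r2\tchr1\tnot_a_number\tchr1\t300\t+\t+"
  ))
  expect_error(read_contacts(path2, bin_width = 1000, format = "pairs"), "line 4")
  path3 <- write_pairs_file("r1\tchr1\t100\tchr1\t200\t+\t+")
  expect_error(read_contacts(path3, format = "pairs"), "bin_width")
})

test_that("dense text round-trips a contact matrix exactly", {
  set.seed(7)
  gb <- genomic_binning(c(chrA = 55000), 10000)
  px <- tibble::tibble(
    chrom = "chrA",
    bin1 = c(0L, 0L, 1L, 2L, 4L),
    bin2 = c(0L, 3L, 4L, 2L, 5L),
    count = c(4, 1, 7, 2, 3)
  )
  m <- contact_matrix(gb, px)
  path <- tempfile()
  write_contacts_dense(m, path)
  m2 <- read_contacts(path, format = "dense")
  expect_equal(m2$pixels, m$pixels)
  expect_equal(m2$binning$chrom_lengths, m$binning$chrom_lengths)
  # auto-detection via the header line
  m3 <- read_contacts(path)
  expect_equal(m3$pixels, m$pixels)
})

test_that("P(s) tables round-trip at 12 significant digits", {
  gb <- genomic_binning(c(chr1 = 1e6), 10000)
  px <- tibble::tibble(
    chrom = "chr1", bin1 = c(0L, 1L, 10L),
    bin2 = c(5L, 40L, 90L), count = c(3, 1, 2)
  )
  ps <- suppressWarnings(
    compute_ps(contact_matrix(gb, px), log_bin_scheme(1e4, 1e6, 4))
  )
  path <- tempfile()
  write_ps_table(ps, path)
  back <- read_ps_table(path)
  expect_equal(nrow(back), nrow(ps))
  expect_equal(back$value, signif(ps$p, 12), tolerance = 1e-12)
  expect_equal(back$s_mid, signif(ps$s_mid, 12), tolerance = 1e-12)

  empty <- ps[0, ]
  class(empty) <- class(ps)
  p2 <- tempfile()
  write_ps_table(empty, p2)
  expect_equal(length(readLines(p2)), 1L) # header only

  three <- ps[1:3, ]
  class(three) <- class(ps)
  p3 <- tempfile()
  write_ps_table(three, p3)
  expect_equal(length(readLines(p3)), 4L) # header + 3 data lines
})

test_that("cooler HDF5 containers are read and multi-resolution rejected", {
  py <- Sys.which("python")
  expect_true(nzchar(py)) # python with h5py ships with the analysis stack
  cool <- tempfile(fileext = ".cool")
  writer <- tempfile(fileext = ".py")
  writeLines(c(
    "import h5py, numpy as np, sys",
    "f = h5py.File(sys.argv[1], 'w')",
    "f.attrs['bin-size'] = 10000",
    "f.create_dataset('chroms/name', data=[b'chr1', b'chr2'])",
    "f.create_dataset('chroms/length', data=[50000, 30000])",
    "f.create_dataset('bins/chrom', data=[0,0,0,0,0,1,1,1])",
    "f.create_dataset('bins/start', data=[0,10000,20000,30000,40000,0,10000,20000])",
    "f.create_dataset('bins/end', data=[10000,20000,30000,40000,50000,10000,20000,30000])",
    "f.create_dataset('pixels/bin1_id', data=[0,0,2,5,1])",
    "f.create_dataset('pixels/bin2_id', data=[0,3,4,7,6])",
    "f.create_dataset('pixels/count', data=[5,2,1,4,3])",
    "f.close()"
  ), writer)
  res <- system2(py, c(writer, cool), stdout = TRUE, stderr = TRUE)
  expect_null(attr(res, "status"))
  m <- read_contacts(cool, format = "cooler")
  expect_equal(m$binning$bin_width, 10000)
  expect_equal(unname(m$binning$chrom_lengths), c(50000, 30000))
  expect_equal(total_contacts(m), 5 + 2 + 1 + 4) # cis only
  expect_equal(m$trans$count, 3) # the chr1-chr2 pixel
  expect_equal(
    as_dense_matrix(m, "chr1")[1, 4], 2
  )
  # multi-resolution container is rejected with the resolution path
  mcool <- tempfile(fileext = ".mcool")
  writer2 <- tempfile(fileext = ".py")
  writeLines(c(
    "import h5py, sys",
    "f = h5py.File(sys.argv[1], 'w')",
    "f.create_group('resolutions/10000')",
    "f.create_group('resolutions/50000')",
    "f.close()"
  ), writer2)
  system2(py, c(writer2, mcool), stdout = TRUE, stderr = TRUE)
  expect_error(
    read_contacts(mcool, format = "cooler"),
    "resolutions/10000"
  )
})
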