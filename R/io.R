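#' Read a pair list from 4DN-style pairs text
#'
#' Reads whitespace- or tab-separated pair records. Header lines start with
#' `#`; `#chromsize:` header lines define chromosome lengths. Body lines may
#' be either the standard seven-plus-column layout
#' (`readID chrom1 pos1 chrom2 pos2 strand1 strand2 ...`) or a minimal
#' four-column layout (`chrom1 pos1 chrom2 pos2`). Strand fields are parsed
#' and discarded: the contact decay analysis is strand-agnostic. Positions
#' are 1-based bp, as in the pairs standard.
#'
#' @param path Path to a pairs text file.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   overrides or supplements `#chromsize:` headers.
#' @return A tibble with columns `chrom1`, `pos1`, `chrom2`, `pos2` and
#'   attribute `chrom_lengths`.
#' @export
read_pairs <- function(path, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "#")
  cs <- lines[is_header & startsWith(lines, "#chromsize:")]
  lens <- chrom_lengths
  if (length(cs)) {
    fields <- strsplit(trimws(sub("^#chromsize:\\s*", "", cs)), "\\s+")
    hdr <- stats::setNames(
      as.numeric(vapply(fields, `[[`, "", 2L)),
      vapply(fields, `[[`, "", 1L)
    )
    lens <- c(hdr[setdiff(names(hdr), names(lens))], lens)
  }
  body_idx <- which(!is_header & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    out <- tibble::tibble(
      chrom1 = character(), pos1 = numeric(),
      chrom2 = character(), pos2 = numeric()
    )
    attr(out, "chrom_lengths") <- lens
    return(out)
  }
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  nf <- lengths(fields)
  first <- fields[[1]]
  standard <- length(first) >= 5 &&
    !is.na(suppressWarnings(as.numeric(first[3]))) &&
    !is.na(suppressWarnings(as.numeric(first[5])))
  need <- if (standard) 5L else 4L
  if (any(nf < need)) {
    bad <- body_idx[which(nf < need)[1]]
    stop("malformed pair record at line ", bad, " of ", path)
  }
  pick <- function(k) vapply(fields, `[[`, "", k)
  if (standard) {
    chrom1 <- pick(2L); pos1 <- suppressWarnings(as.numeric(pick(3L)))
    chrom2 <- pick(4L); pos2 <- suppressWarnings(as.numeric(pick(5L)))
  } else {
    chrom1 <- pick(1L); pos1 <- suppressWarnings(as.numeric(pick(2L)))
    chrom2 <- pick(3L); pos2 <- suppressWarnings(as.numeric(pick(4L)))
  }
  bad <- which(is.na(pos1) | is.na(pos2) | pos1 < 1 | pos2 < 1)
  if (length(bad)) {
    stop("malformed pair record at line ", body_idx[bad[1]], " of ", path)
  }
  if (!is.null(lens)) {
    unknown <- setdiff(unique(c(chrom1, chrom2)), names(lens))
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
    over <- which(pos1 > lens[chrom1] | pos2 > lens[chrom2])
    if (length(over)) {
      stop(
        "position beyond chromosome end at line ", body_idx[over[1]],
        " of ", path
      )
    }
  }
  out <- tibble::tibble(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2)
  attr(out, "chrom_lengths") <- lens
  out
}

#' Read contact data into a binned contact matrix
#'
#' Reads cis contacts from a pairs text file, a dense whitespace matrix with
#' a one-line header, or a single-resolution cooler-format HDF5 container,
#' and aggregates them at `bin_width`. Trans contacts from pairs input are
#' retained in the `trans` table of the result but are not used by the
#' cis-only contact probability decay analysis.
#'
#' The cooler reader handles single-resolution containers only; a
#' multi-resolution (`.mcool`) container is rejected with a message naming
#' the resolution paths it holds. Reading cooler files requires a `python`
#' interpreter with `h5py` on the PATH.
#'
#' @param path Input file.
#' @param bin_width Bin width in bp. Required for pairs input; for dense and
#'   cooler input it is read from the file (and checked against this
#'   argument if supplied).
#' @param format One of `"auto"`, `"pairs"`, `"dense"`, `"cooler"`. With
#'   `"auto"`, `.pairs` files are read as pairs, `.cool`/`.mcool` as cooler,
#'   and files whose first line is a `mitoscale dense` header as dense text.
#' @param chrom_lengths Optional named chromosome lengths for pairs input
#'   lacking `#chromsize:` headers.
#' @return A [contact_matrix()].
#' @export
read_contacts <- function(path, bin_width = NULL,
                          format = c("auto", "pairs", "dense", "cooler"),
                          chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cool", "mcool")) {
      "cooler"
    } else if (ext == "pairs") {
      "pairs"
    } else {
      first <- readLines(path, n = 1L)
      if (grepl("mitoscale dense", first, fixed = TRUE)) "dense" else "pairs"
    }
  }
  switch(format,
    pairs = read_contacts_pairs(path, bin_width, chrom_lengths),
    dense = read_contacts_dense(path),
    cooler = read_contacts_cooler(path, bin_width)
  )
}

read_contacts_pairs <- function(path, bin_width, chrom_lengths) {
  if (is.null(bin_width)) stop("`bin_width` is required for pairs input")
  pairs <- read_pairs(path, chrom_lengths)
  lens <- attr(pairs, "chrom_lengths")
  if (is.null(lens)) {
    stop(
      "chromosome lengths unavailable: supply `chrom_lengths` or use a ",
      "pairs file with #chromsize: headers"
    )
  }
  binning <- genomic_binning(lens, bin_width)
  cis <- pairs[pairs$chrom1 == pairs$chrom2, ]
  pixels <- bin_cis_pairs(
    tibble::tibble(chrom = cis$chrom1, pos1 = cis$pos1, pos2 = cis$pos2),
    binning
  )
  tr <- pairs[pairs$chrom1 != pairs$chrom2, ]
  trans <- NULL
  if (nrow(tr)) {
    trans <- dplyr::count(
      tibble::tibble(
        chrom1 = tr$chrom1, bin1 = pos_to_bin(tr$pos1, bin_width),
        chrom2 = tr$chrom2, bin2 = pos_to_bin(tr$pos2, bin_width)
      ),
      .data$chrom1, .data$bin1, .data$chrom2, .data$bin2,
      name = "count"
    )
  }
  contact_matrix(binning, pixels, trans = trans)
}

#' Write a contact matrix as dense text
#'
#' Writes one chromosome's symmetric count matrix as whitespace-separated
#' dense text with a one-line header carrying the bin width, chromosome name
#' and length. `read_contacts(format = "dense")` reproduces the matrix
#' exactly.
#'
#' @param x A [contact_matrix()].
#' @param path Output path.
#' @param chrom Chromosome to write; defaults to the first.
#' @return `path`, invisibly.
#' @export
write_contacts_dense <- function(x, path, chrom = NULL) {
  stopifnot(inherits(x, "contact_matrix"))
  if (is.null(chrom)) chrom <- names(x$binning$chrom_lengths)[1]
  m <- as_dense_matrix(x, chrom)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# mitoscale dense binsize=%s chrom=%s length=%s",
    format(x$binning$bin_width, scientific = FALSE),
    chrom,
    format(x$binning$chrom_lengths[[chrom]], scientific = FALSE)
  ), con)
  utils::write.table(m,
    con,
    sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_contacts_dense <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(
    first,
    regexec("binsize=(\\d+)\\s+chrom=(\\S+)\\s+length=(\\d+)", first)
  )[[1]]
  if (length(m) != 4) stop("missing or malformed dense header in ", path)
  bw <- as.numeric(m[2])
  chrom <- m[3]
  len <- as.numeric(m[4])
  mat <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(mat) <- NULL
  n <- ceiling(len / bw)
  if (nrow(mat) != n || ncol(mat) != n) {
    stop(
      "dense matrix is ", nrow(mat), "x", ncol(mat),
      " but header implies ", n, " bins"
    )
  }
  if (max(abs(mat - t(mat))) > 0) stop("dense matrix is not symmetric")
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  pixels <- tibble::tibble(
    chrom = chrom,
    bin1 = as.integer(idx[, 1] - 1L),
    bin2 = as.integer(idx[, 2] - 1L),
    count = mat[idx]
  ) |>
    dplyr::arrange(.data$bin1, .data$bin2)
  contact_matrix(genomic_binning(stats::setNames(len, chrom), bw), pixels)
}

read_contacts_cooler <- function(path, bin_width = NULL) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("reading cooler files requires `python` with h5py on the PATH")
  script <- system.file("python", "cooler_dump.py", package = "mitoscale")
  outdir <- tempfile("cooler")
  dir.create(outdir)
  res <- suppressWarnings(system2(py, c(script, shQuote(path), shQuote(outdir)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("cooler read failed: ", paste(res, collapse = "\n"))
  }
  chroms <- utils::read.table(file.path(outdir, "chroms.tsv"),
    header = TRUE, sep = "\t", colClasses = c("character", "numeric")
  )
  bins <- utils::read.table(file.path(outdir, "bins.tsv"),
    header = TRUE, sep = "\t"
  )
  pixels <- utils::read.table(file.path(outdir, "pixels.tsv"),
    header = TRUE, sep = "\t"
  )
  bw <- as.numeric(readLines(file.path(outdir, "binsize.txt"), n = 1L))
  if (!is.null(bin_width) && bin_width != bw) {
    stop("cooler file is binned at ", bw, " bp, not the requested ", bin_width)
  }
  lens <- stats::setNames(chroms$length, chroms$name)
  binning <- genomic_binning(lens, bw)
  # map global bin ids to (chrom, local bin)
  offsets <- c(0, cumsum(binning$n_bins))
  names(offsets) <- c(names(lens), "_end")
  gchrom <- as.character(bins$chrom)
  glocal <- bins$bin_id - offsets[gchrom]
  c1 <- gchrom[pixels$bin1_id + 1L]
  c2 <- gchrom[pixels$bin2_id + 1L]
  b1 <- as.integer(glocal[pixels$bin1_id + 1L])
  b2 <- as.integer(glocal[pixels$bin2_id + 1L])
  cis <- c1 == c2
  px <- tibble::tibble(
    chrom = c1[cis],
    bin1 = pmin(b1[cis], b2[cis]),
    bin2 = pmax(b1[cis], b2[cis]),
    count = as.numeric(pixels$count[cis])
  ) |>
    dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
  trans <- NULL
  if (any(!cis)) {
    trans <- tibble::tibble(
      chrom1 = c1[!cis], bin1 = b1[!cis],
      chrom2 = c2[!cis], bin2 = b2[!cis],
      count = as.numeric(pixels$count[!cis])
    )
  }
  weights <- NULL
  if ("weight" %in% names(bins)) {
    weights <- tibble::tibble(
      chrom = gchrom,
      bin = as.integer(glocal),
      weight = as.numeric(bins$weight)
    )
  }
  contact_matrix(binning, px,
    trans = trans, weights = weights,
    n_masked_diagonals = 0L,
    converged = if (is.null(weights)) NA else TRUE
  )
}

#' Write a P(s) or derivative curve as tab-separated text
#'
#' Writes columns `s_lo`, `s_hi`, `s_mid`, `value`, `n_obs` at 12
#' significant digits, so that [read_ps_table()] round-trips the numeric
#' values losslessly at that precision. For derivative curves the `value`
#' column holds the smoothed slope and `s_lo`/`s_hi`/`n_obs` are `NA`.
#'
#' @param curve A `ps_curve` or `deriv_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ps_table <- function(curve, path) {
  if (inherits(curve, "deriv_curve")) {
    tab <- tibble::tibble(
      s_lo = NA_real_, s_hi = NA_real_, s_mid = curve$s_mid,
      value = curve$slope_smooth, n_obs = NA_real_
    )
  } else {
    stopifnot(all(c("s_lo", "s_hi", "s_mid", "p", "n_obs") %in% names(curve)))
    tab <- tibble::tibble(
      s_lo = curve$s_lo, s_hi = curve$s_hi, s_mid = curve$s_mid,
      value = curve$p, n_obs = curve$n_obs
    )
  }
  fmt <- function(v) {
    ifelse(is.na(v), "NA", sprintf("%.12g", v))
  }
  lines <- c(
    paste(names(tab), collapse = "\t"),
    if (nrow(tab)) {
      do.call(paste, c(lapply(tab, fmt), sep = "\t"))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a curve written by [write_ps_table()]
#'
#' @param path Input path.
#' @return A tibble with columns `s_lo`, `s_hi`, `s_mid`, `value`, `n_obs`.
#' @export
read_ps_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA")
  tibble::as_tibble(tab)
}
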