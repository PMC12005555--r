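#' Construct a contact map
#'
#' A `ContactMap` is the central observable of the package: a square,
#' symmetric, non-negative matrix `H` of contact frequencies (raw counts or
#' probabilities) between equally sized genomic bins, together with the
#' genomic metadata needed to interpret it.
#'
#' @param values Square numeric matrix of non-negative contact frequencies.
#'   Symmetrized by averaging with its transpose when the relative asymmetry
#'   is at most `1e-6`; larger asymmetry is an error.
#' @param resolution_bp Bin size in base pairs (typically 50000 or 100000).
#' @param chrom Chromosome label.
#' @param start_bp Genomic coordinate of the first bin.
#' @param is_normalized Logical; `TRUE` once [normalize_map()] has been
#'   applied (first off-diagonal mean 0.1, unit main diagonal).
#' @return An object of class `ContactMap` with fields `values`,
#'   `resolution_bp`, `chrom`, `start_bp`, `is_normalized`.
#' @examples
#' H <- contact_map(matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3))
#' dim(H$values)
#' @export
contact_map <- function(values, resolution_bp = 50000L, chrom = "chr?",
                        start_bp = 0L, is_normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("contact map must be square, got ", nrow(values), "x", ncol(values))
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("contact map values must be numeric and non-missing")
  }
  if (any(values < 0)) stop("contact map values must be non-negative")
  asym <- max(abs(values - t(values)))
  scale <- max(abs(values), 1e-300)
  if (asym / scale > 1e-6) {
    stop("matrix asymmetry ", signif(asym / scale, 3),
         " exceeds relative tolerance 1e-6")
  }
  values <- (values + t(values)) / 2
  structure(
    list(values = unname(values),
         resolution_bp = as.integer(resolution_bp),
         chrom = as.character(chrom),
         start_bp = as.integer(start_bp),
         is_normalized = isTRUE(is_normalized)),
    class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  m <- nrow(x$values)
  cat(sprintf("ContactMap: %d x %d bins @ %d bp (%s:%d-%d)%s\n",
              m, m, x$resolution_bp, x$chrom, x$start_bp,
              x$start_bp + m * x$resolution_bp,
              if (x$is_normalized) " [normalized]" else ""))
  invisible(x)
}

#' @export
dim.ContactMap <- function(x) dim(x$values)

.map_magic <- "HICSTRUCT-DENSE-1"

#' Read a contact map from disk
#'
#' Two dense on-disk representations are supported: `dense_text`
#' (whitespace-delimited matrix, one row per line, no metadata) and
#' `dense_binary` (a small self-describing container holding the metadata
#' header plus little-endian doubles, written by [save_contact_map()];
#' round-trips are bit exact). Multi-resolution Hi-C containers
#' (cooler / .hic) are not readable in this build because no HDF5 or
#' straw binding is available; requesting `hic_container` is an error
#' directing the user to export a dense matrix instead.
#'
#' @param path File to read.
#' @param format One of `"dense_text"`, `"dense_binary"`, `"hic_container"`.
#' @param resolution_bp,chrom,start_bp Metadata used for `dense_text`
#'   input (ignored for `dense_binary`, which stores its own).
#' @return A [contact_map()] of raw counts.
#' @seealso [save_contact_map()]
#' @export
load_contact_map <- function(path,
                             format = c("dense_text", "dense_binary",
                                        "hic_container"),
                             resolution_bp = 50000L, chrom = "chr?",
                             start_bp = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense_text") {
    values <- as.matrix(utils::read.table(path, header = FALSE))
    return(contact_map(values, resolution_bp = resolution_bp,
                       chrom = chrom, start_bp = start_bp))
  }
  if (format == "dense_binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, nchars = nchar(.map_magic), useBytes = TRUE)
    if (!identical(magic, .map_magic)) stop("not a dense_binary contact map")
    hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
    m <- hdr[1]; res <- hdr[2]; start <- hdr[3]; nch <- hdr[4]
    chrom <- readChar(con, nchars = nch, useBytes = TRUE)
    normed <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    vals <- readBin(con, "double", n = m * m, size = 8L, endian = "little")
    return(contact_map(matrix(vals, m, m), resolution_bp = res,
                       chrom = chrom, start_bp = start,
                       is_normalized = normed == 1L))
  }
  stop("hic_container input requires an HDF5/straw binding that is not ",
       "available; export the region as a dense matrix and use dense_text")
}

#' Write a contact map to disk
#'
#' @param map A [contact_map()].
#' @param path Output file.
#' @param format `"dense_text"` or `"dense_binary"` (see
#'   [load_contact_map()]).
#' @return `path`, invisibly.
#' @export
save_contact_map <- function(map, path,
                             format = c("dense_text", "dense_binary")) {
  stopifnot(inherits(map, "ContactMap"))
  format <- match.arg(format)
  if (format == "dense_text") {
    utils::write.table(map$values, path, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(.map_magic, con, eos = NULL, useBytes = TRUE)
    writeBin(as.integer(c(nrow(map$values), map$resolution_bp, map$start_bp,
                          nchar(map$chrom, type = "bytes"))),
             con, size = 4L, endian = "little")
    writeChar(map$chrom, con, eos = NULL, useBytes = TRUE)
    writeBin(as.integer(map$is_normalized), con, size = 4L,
             endian = "little")
    writeBin(as.double(map$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}
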