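# Plain-text file formats. Text is the canonical dialect for fixtures and
# interchange; an RDS-based binary container is offered for large sets.
#
# Stimulus-set format: one header line "N d N_lvl", one line of N_lvl level
# values, then one row per stimulus: the level index followed by d stimulus
# values, whitespace-delimited, full double precision.
#
# Filter format: header "d q", then d rows of q values.

.fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Read and write labeled stimulus sets
#'
#' `write_stimulus_set()` writes the delimited text format (or, with
#' `binary = TRUE`, a lossless serialized container); `read_stimulus_set()`
#' reads either, validating the header and the contrast normalization of
#' every row.
#'
#' @param set a [labeled_stimulus_set()].
#' @param path file path.
#' @param binary use the binary container instead of delimited text.
#' @return `read_stimulus_set()` returns a [labeled_stimulus_set()];
#'   `write_stimulus_set()` returns `path` invisibly.
#' @export
write_stimulus_set <- function(set, path, binary = FALSE) {
  if (binary) {
    saveRDS(set, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(set$stimuli), ncol(set$stimuli),
                   length(set$levels)), con)
  writeLines(paste(.fmt(set$levels), collapse = " "), con)
  body <- cbind(set$labels, set$stimuli)
  writeLines(apply(body, 1, function(r)
    paste(c(format(r[1]), .fmt(r[-1])), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path, binary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (binary) {
    set <- readRDS(path)
    if (!inherits(set, "labeled_stimulus_set"))
      stop("binary container does not hold a labeled_stimulus_set")
    return(set)
  }
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed stimulus-set file: too few lines")
  header <- scan(text = lines[1], quiet = TRUE)
  if (length(header) != 3) stop("malformed header: expected 'N d N_lvl'")
  N <- as.integer(header[1]); d <- as.integer(header[2])
  n_lvl <- as.integer(header[3])
  levels <- scan(text = lines[2], quiet = TRUE)
  if (length(levels) != n_lvl)
    stop("header promises ", n_lvl, " levels but ", length(levels), " found")
  if (length(lines) != N + 2L)
    stop("header promises ", N, " stimuli but ", length(lines) - 2L, " rows found")
  body <- matrix(scan(text = lines[-(1:2)], quiet = TRUE), nrow = N,
                 byrow = TRUE)
  if (ncol(body) != d + 1L)
    stop("rows have ", ncol(body) - 1L, " values; header promises d = ", d)
  labels <- as.integer(body[, 1])
  labeled_stimulus_set(body[, -1, drop = FALSE], labels, levels)
}

#' Read and write filter banks
#'
#' Delimited text: a "d q" header then d rows of q values at full double
#' precision.
#'
#' @param filters a [filter_bank()].
#' @param path file path.
#' @return `read_filters()` returns a [filter_bank()]; `write_filters()`
#'   returns `path` invisibly.
#' @export
write_filters <- function(filters, path) {
  F <- unclass(as.matrix(filters))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(F), ncol(F)), con)
  writeLines(apply(F, 1, function(r) paste(.fmt(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_filters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- scan(text = lines[1], quiet = TRUE)
  if (length(header) != 2) stop("malformed filter header: expected 'd q'")
  d <- as.integer(header[1]); q <- as.integer(header[2])
  if (length(lines) != d + 1L)
    stop("header promises ", d, " rows but ", length(lines) - 1L, " found")
  F <- matrix(scan(text = lines[-1], quiet = TRUE), nrow = d, byrow = TRUE)
  if (ncol(F) != q) stop("rows have ", ncol(F), " values; header promises q = ", q)
  filter_bank(F)
}
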