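#' Labeled distance matrices
#'
#' A `mfnj_dist` object is a plain numeric matrix of pairwise evolutionary
#' distances with taxon labels as `dimnames`, validated to be square,
#' symmetric, non-negative and zero on the diagonal. Taxon order is
#' preserved exactly as given: it is semantically meaningful for
#' reproducing neighbor-joining tie-breaks.
#'
#' @param values square numeric matrix of pairwise distances.
#' @param labels character vector of unique, non-empty taxon names; defaults
#'   to `rownames(values)`.
#' @param symmetrize_tol maximum relative asymmetry tolerated before the
#'   matrix is rejected. Values within tolerance are symmetrized by
#'   averaging so downstream arithmetic sees an exactly symmetric matrix.
#' @return a `mfnj_dist`: a labeled numeric matrix.
#' @examples
#' dist_matrix(matrix(c(0, 5, 5, 0), 2, 2), c("A", "B"))
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        symmetrize_tol = 1e-8) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    stop_validation("distance matrix has no taxon labels")
  }
  labels <- as.character(labels)
  n <- length(labels)
  if (nrow(values) != ncol(values) || nrow(values) != n) {
    stop_validation("distance matrix must be square (%d x %d) with %d labels",
                    nrow(values), ncol(values), n)
  }
  if (n < 2) {
    stop_validation("a distance matrix needs at least 2 taxa, got %d", n)
  }
  if (anyDuplicated(labels)) {
    stop_validation("duplicate taxon labels: %s",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop_validation("taxon labels must be non-empty")
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop_validation("distance matrix contains missing values")
  scale <- max(abs(values), 1)
  asym <- max(abs(values - t(values)))
  if (asym > symmetrize_tol * scale) {
    stop_validation("matrix is asymmetric (max |D_ij - D_ji| = %g)", asym)
  }
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) {
    stop_validation("diagonal entries must be zero")
  }
  if (any(values < 0)) {
    stop_validation("negative off-diagonal distance found")
  }
  dimnames(values) <- list(labels, labels)
  class(values) <- c("mfnj_dist", class(values))
  values
}

#' @export
print.mfnj_dist <- function(x, ...) {
  cat(sprintf("Distance matrix over %d taxa\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

# tokenize a text stream/file/string into non-empty lines of tokens
read_lines_any <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else if (length(source) == 1 && !grepl("\n", source) &&
             file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  lines[nzchar(trimws(lines))]
}

#' Read a PHYLIP distance matrix
#'
#' Reads the PHYLIP square or lower-triangular distance-matrix dialect: a
#' first line holding the taxon count, then one row per taxon of
#' `label value value ...`. Labels are relaxed (any whitespace-delimited
#' token, no 10-character limit). Lower-triangular rows carry `i - 1`
#' values (implied zero diagonal) and are mirrored to a full square matrix.
#'
#' @param source file path, connection, or a string holding the matrix text.
#' @return a [dist_matrix()] object.
#' @examples
#' read_phylip_dist("3\nA 0 1 2\nB 1 0 3\nC 2 3 0")
#' @seealso [write_phylip_dist()], [read_delim_dist()]
#' @export
read_phylip_dist <- function(source) {
  lines <- read_lines_any(source)
  if (length(lines) == 0) stop_parse("empty input")
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n) || n < 2) {
    stop_parse("first token must be the taxon count (>= 2), got '%s'",
               trimws(lines[1]))
  }
  body <- lines[-1]
  if (length(body) != n) {
    stop_parse("header says %d taxa but found %d data rows", n, length(body))
  }
  labels <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    labels[i] <- tok[1]
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals)) {
      stop_parse("non-numeric value in row %d ('%s')", i, labels[i])
    }
    rows[[i]] <- vals
  }
  len <- lengths(rows)
  if (all(len == n)) {
    values <- do.call(rbind, rows)
  } else if (all(len == seq_len(n) - 1)) {
    values <- matrix(0, n, n)
    for (i in seq_len(n)[-1]) {
      values[i, seq_len(i - 1)] <- rows[[i]]
    }
    values <- values + t(values)
  } else {
    bad <- which(len != n & len != seq_len(n) - 1)[1]
    stop_parse(paste0("row %d ('%s') has %d values; expected %d (square) ",
                      "or %d (lower-triangular)"),
               bad, labels[bad], len[bad], n, bad - 1)
  }
  dist_matrix(values, labels)
}

#' Read a delimited distance matrix
#'
#' Reads a full square matrix from delimited text (CSV/TSV/...) with a
#' header row of taxon labels; each body row starts with its label, which
#' must match the header order.
#'
#' @inheritParams read_phylip_dist
#' @param delimiter single field-separator character, default `","`.
#' @return a [dist_matrix()] object.
#' @export
read_delim_dist <- function(source, delimiter = ",") {
  lines <- read_lines_any(source)
  if (length(lines) < 2) stop_parse("need a header row and at least 2 body rows")
  split1 <- function(s) strsplit(s, delimiter, fixed = TRUE)[[1]]
  header <- trimws(split1(lines[1]))
  labels <- header[-1]  # leading cell above the row labels is ignored
  n <- length(labels)
  body <- lines[-1]
  if (length(body) != n) {
    stop_parse("header names %d taxa but found %d data rows", n, length(body))
  }
  values <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- trimws(split1(body[i]))
    if (tok[1] != labels[i]) {
      stop_parse("row %d is labeled '%s' but the header says '%s'",
                 i, tok[1], labels[i])
    }
    if (length(tok) != n + 1) {
      stop_parse("row %d ('%s') has %d values; expected %d",
                 i, tok[1], length(tok) - 1, n)
    }
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals)) stop_parse("non-numeric value in row %d ('%s')", i, tok[1])
    values[i, ] <- vals
  }
  dist_matrix(values, labels)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm a [dist_matrix()] object.
#' @param sink file path or connection; omit to return the text invisibly
#'   without writing.
#' @param digits significant digits used for the values; the default (15)
#'   round-trips doubles through [read_phylip_dist()] to within 1e-12.
#' @return the formatted text, invisibly.
#' @export
write_phylip_dist <- function(dm, sink = NULL, digits = 15) {
  labels <- rownames(dm)
  n <- nrow(dm)
  rows <- vapply(seq_len(n), function(i) {
    paste(labels[i],
          paste(sprintf("%.*g", digits, dm[i, ]), collapse = " "))
  }, character(1))
  txt <- paste0(paste(c(n, rows), collapse = "\n"), "\n")
  if (!is.null(sink)) writeLines(sub("\n$", "", txt), sink)
  invisible(txt)
}

#' The nine-bear distance matrix
#'
#' Pairwise percentage differences among mitochondrial DNA sequences of
#' nine brown bears (*Ursus arctos*), a classic worked example of the
#' ties-in-proximity problem in neighbor joining: at the fifth agglomeration
#' step two pairs of OTUs share the minimal selection criterion, so classic
#' NJ can return two different trees depending on input order, while the
#' multifurcating variant resolves the tie as a single polytomy.
#'
#' The matrix ships as a lower-triangular PHYLIP file in
#' `system.file("extdata", "bears.phy", package = "mfnj")`.
#'
#' @return a 9-taxon [dist_matrix()] with labels Abruzzo, Pyrenees, Kodiak,
#'   Captive-3, Captive-4, Captive-5, Grizzly, Polar-2, Black.
#' @examples
#' bear_matrix()["Grizzly", "Polar-2"]  # 0.3
#' @export
bear_matrix <- function() {
  read_phylip_dist(system.file("extdata", "bears.phy", package = "mfnj",
                               mustWork = TRUE))
}
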