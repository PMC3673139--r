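# Mother-wavelet registry.
#
# Analysis/synthesis filter coefficients for the 49 supported wavelets are
# embedded as a plain-text table (inst/extdata/wavelet_filters.csv, 17
# significant digits) rather than generated at run time, so that decompositions
# are bit-reproducible across platforms and can be checked against published
# coefficient tables.

.wavelet_cache <- new.env(parent = emptyenv())

.wavelet_table <- function() {
  if (!is.null(.wavelet_cache$table)) {
    return(.wavelet_cache$table)
  }
  path <- system.file("extdata", "wavelet_filters.csv",
                      package = "sportdwt", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer",
                                        "character", "character", "character",
                                        "character"))
  split_num <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
  tbl <- lapply(seq_len(nrow(raw)), function(i) {
    structure(
      list(name       = raw$name[i],
           family     = raw$family[i],
           orthogonal = raw$orthogonal[i] == 1L,
           dec_lo     = split_num(raw$dec_lo[i]),
           dec_hi     = split_num(raw$dec_hi[i]),
           rec_lo     = split_num(raw$rec_lo[i]),
           rec_hi     = split_num(raw$rec_hi[i])),
      class = "wavelet_spec")
  })
  names(tbl) <- raw$name
  .wavelet_cache$table <- tbl
  tbl
}

#' Names of the supported mother wavelets
#'
#' The registry covers the families commonly used in accelerometer signal
#' analysis: Haar, Daubechies (db1--db10), Coiflet (coif1--coif5), Symlet
#' (sym2--sym10), biorthogonal and reverse biorthogonal (the twelve standard
#' members 1.1--3.9 of each).
#'
#' @param family optional family filter, one of `"haar"`, `"db"`, `"coif"`,
#'   `"sym"`, `"bior"`, `"rbio"`.
#' @return character vector of wavelet names accepted by [get_wavelet()].
#' @export
wavelet_names <- function(family = NULL) {
  tbl <- .wavelet_table()
  nm <- names(tbl)
  if (!is.null(family)) {
    family <- match.arg(family, c("haar", "db", "coif", "sym", "bior", "rbio"))
    nm <- nm[vapply(tbl, function(w) w$family, "") == family]
  }
  nm
}

#' Look up a mother wavelet
#'
#' @param name a wavelet name such as `"haar"`, `"db4"`, `"coif3"`, `"sym5"`,
#'   `"bior1.1"` or `"rbio3.9"`; see [wavelet_names()]. A `wavelet_spec` is
#'   returned unchanged.
#' @return a `wavelet_spec`: decomposition and reconstruction low/high-pass
#'   filter coefficient vectors plus an orthogonality flag. Biorthogonal
#'   filters are zero-padded to a common even length.
#' @export
get_wavelet <- function(name) {
  if (inherits(name, "wavelet_spec")) {
    return(name)
  }
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("`name` must be a single wavelet name string", call. = FALSE)
  }
  tbl <- .wavelet_table()
  if (!name %in% names(tbl)) {
    stop(sprintf(
      "unknown wavelet '%s'; supported families: haar, db1-db10, coif1-coif5, sym2-sym10, bior1.1-bior3.9, rbio1.1-rbio3.9 (see wavelet_names())",
      name), call. = FALSE)
  }
  tbl[[name]]
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s (%s family, %s, %d-tap filters)\n",
              x$name, x$family,
              if (x$orthogonal) "orthogonal" else "biorthogonal",
              length(x$dec_lo)))
  invisible(x)
}
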