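## SpectrumSet: counts on a (q, omega) grid with Poisson errors — the
## universal currency of the pipeline.

#' Instrument configuration
#'
#' Describes an IN16B-like backscattering instrument: the momentum-transfer
#' grid and a symmetric energy-transfer window.  Defaults follow the
#' Si(111) configuration: 16 detectors covering 0.2--1.9 1/Angstrom and a
#' +/- 30 micro-eV window.
#'
#' @param q_grid strictly increasing momentum transfers (1/Angstrom) in
#'   \[0.2, 1.9\].
#' @param energy_window half-width of the usable energy range (micro-eV).
#' @param channel_count number of energy channels (uniform binning).
#' @return an object of class \code{"instrument_config"} with fields
#'   \code{q_grid}, \code{omega_grid} (channel centres, symmetric about 0),
#'   \code{omega_edges}, \code{energy_window}, \code{channel_count}.
#' @export
instrument_config <- function(q_grid = seq(0.2, 1.9, length.out = 16),
                              energy_window = 30,
                              channel_count = 1024L) {
  q_grid <- as.numeric(q_grid)
  if (any(diff(q_grid) <= 0)) stop("q_grid must be strictly increasing")
  if (min(q_grid) < 0.2 - 1e-9 || max(q_grid) > 1.9 + 1e-9)
    stop("q_grid must lie within [0.2, 1.9] 1/Angstrom")
  if (energy_window <= 0) stop("energy_window must be positive")
  channel_count <- as.integer(channel_count)
  if (channel_count < 8L) stop("channel_count too small")
  edges <- seq(-energy_window, energy_window, length.out = channel_count + 1L)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(q_grid = q_grid, omega_grid = centres, omega_edges = edges,
                 energy_window = energy_window,
                 channel_count = channel_count, hbar = hbar_ueV_ns),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config> ", length(x$q_grid), " q in [",
      min(x$q_grid), ", ", max(x$q_grid), "] 1/A; ",
      x$channel_count, " channels over +/-", x$energy_window,
      " ueV\n", sep = "")
  invisible(x)
}

#' Construct a SpectrumSet
#'
#' @param q momentum transfers (1/Angstrom), one per row of \code{counts}.
#' @param omega energy transfers (micro-eV), one per column.
#' @param counts numeric matrix \code{length(q) x length(omega)} of counts.
#' @param errors optional matrix of count uncertainties; defaults to
#'   \code{sqrt(counts)} (Poisson).
#' @param meta named list of metadata (temperature, concentrations, seed,
#'   kind, ...).
#' @return object of class \code{"spectrum_set"}.
#' @export
spectrum_set <- function(q, omega, counts, errors = NULL, meta = list()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(q) || ncol(counts) != length(omega))
    stop("counts must be a length(q) x length(omega) matrix")
  if (is.null(errors)) errors <- sqrt(pmax(counts, 0))
  errors <- as.matrix(errors)
  if (!all(dim(errors) == dim(counts)))
    stop("errors must have the same shape as counts")
  structure(list(q = as.numeric(q), omega = as.numeric(omega),
                 counts = counts, errors = errors, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", length(x$q), " q x ", length(x$omega),
      " channels; total counts ", format(sum(x$counts), digits = 6), sep = "")
  if (!is.null(x$meta$kind)) cat(" [", x$meta$kind, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.spectrum_set <- function(x, ...) {
  data.frame(q = rep(x$q, times = length(x$omega)),
             omega = rep(x$omega, each = length(x$q)),
             counts = as.vector(x$counts),
             error = as.vector(x$errors))
}

#' Read/write a SpectrumSet as long-format CSV
#'
#' Columns \code{q, omega, counts, error}; metadata is carried in
#' \code{#}-prefixed header lines of the form \code{# key: value}.
#'
#' @param x a \code{spectrum_set}.
#' @param path file path.
#' @return \code{write_spectrum_csv} returns \code{path} invisibly;
#'   \code{read_spectrum_csv} returns a \code{spectrum_set}.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(x$meta)) {
    v <- x$meta[[k]]
    if (is.numeric(v) || is.character(v) || is.logical(v))
      writeLines(sprintf("# %s: %s", k, paste(format(v, digits = 17),
                                              collapse = ",")), con)
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: *", "", kv)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[key]] <- if (anyNA(num)) val else num
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  q <- sort(unique(df$q)); omega <- sort(unique(df$omega))
  counts <- matrix(NA_real_, length(q), length(omega))
  errors <- counts
  iq <- match(df$q, q); io <- match(df$omega, omega)
  counts[cbind(iq, io)] <- df$counts
  errors[cbind(iq, io)] <- df$error
  spectrum_set(q, omega, counts, errors, meta)
}

## internal: check two spectrum sets share a grid
grids_match <- function(a, b, tol = 1e-9) {
  length(a$q) == length(b$q) && length(a$omega) == length(b$omega) &&
    max(abs(a$q - b$q)) < tol && max(abs(a$omega - b$omega)) < tol
}
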