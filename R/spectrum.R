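#' Construct a negative-mode MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z (> 0).
#' @param fragments Numeric vector of fragment m/z, or a two-column
#'   matrix/data.frame of (m/z, relative intensity in `[0, 1]`).
#' @param retention_time Retention time in minutes, or `NA`.
#' @param title Optional identifier carried through annotation output.
#' @return An `msms_spectrum`: list with `precursor_mz`, `fragments`
#'   (data frame `mz`, `intensity`, sorted ascending by m/z),
#'   `retention_time`, `polarity = "negative"`, `title`.
#' @examples
#' msms_spectrum(991.5483, c(945.541, 783.488, 621.437, 459.385))
#' @export
msms_spectrum <- function(precursor_mz, fragments,
                          retention_time = NA_real_, title = NA_character_) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  if (is.null(dim(fragments))) {
    fragments <- data.frame(mz = as.numeric(fragments),
                            intensity = rep(1, length(fragments)))
  } else {
    fragments <- data.frame(mz = as.numeric(fragments[, 1]),
                            intensity = as.numeric(fragments[, 2]))
  }
  if (any(fragments$mz <= 0)) stop("fragment m/z must be positive")
  if (any(fragments$mz > precursor_mz + 0.5)) {
    stop("fragment m/z exceeds precursor m/z + 0.5")
  }
  if (any(fragments$intensity < 0 | fragments$intensity > 1)) {
    stop("relative intensities must lie in [0, 1]")
  }
  fragments <- fragments[order(fragments$mz), , drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(precursor_mz = precursor_mz, fragments = fragments,
                 retention_time = retention_time, polarity = "negative",
                 title = title),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> precursor %.5f (-), %d fragments",
              x$precursor_mz, nrow(x$fragments)))
  if (!is.na(x$retention_time)) cat(sprintf(", RT %.2f min", x$retention_time))
  cat("\n")
  invisible(x)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with the standard `PEPMASS`,
#' `CHARGE`, `RTINSECONDS`, and `TITLE` headers; peak lines are
#' whitespace-separated m/z and (optional) intensity. Intensities are
#' rescaled to relative `[0, 1]` per spectrum.
#'
#' @param path MGF file path.
#' @return List of `msms_spectrum`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      pep <- NA_real_; rt <- NA_real_; title <- NA_character_
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^PEPMASS=", ln)) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1])
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        } else if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^[0-9]", ln)) {
          xs <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          mz <- c(mz, xs[1])
          int <- c(int, if (length(xs) > 1) xs[2] else 1)
        }
        i <- i + 1L
      }
      if (is.na(pep)) {
        stop("MGF block without PEPMASS near line ", i, " in ", path)
      }
      if (length(int) && max(int) > 0) int <- int / max(int)
      spectra[[length(spectra) + 1L]] <-
        msms_spectrum(pep, cbind(mz, int), retention_time = rt, title = title)
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `msms_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    writeLines("BEGIN IONS", con)
    title <- if (is.na(s$title)) paste0("spectrum_", k) else s$title
    writeLines(paste0("TITLE=", title), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines("CHARGE=1-", con)
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time * 60), con)
    }
    writeLines(sprintf("%.6f %.6f", s$fragments$mz, s$fragments$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
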