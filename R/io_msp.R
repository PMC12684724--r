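# Minimal MSP (NIST text) spectral-library reader/writer. Blocks are
# separated by blank lines; recognized header fields are NAME,
# PRECURSORMZ / PRECURSOR_MZ, RETENTIONTIME (seconds) and "Num Peaks",
# followed by "mz intensity" peak lines.

#' Construct an MS2 spectrum
#'
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param peaks Two-column matrix or data frame of (mz, intensity); sorted by
#'   mz on construction.
#' @param rt Retention time in seconds (`NA` allowed).
#' @param name Optional spectrum/compound name.
#' @return An `ms2_spectrum` list.
#' @export
ms2_spectrum <- function(precursor_mz, peaks, rt = NA_real_, name = NA_character_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2) stop("peaks must have two columns (mz, intensity)",
                             call. = FALSE)
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, "intensity"] < 0)) stop("negative peak intensity",
                                          call. = FALSE)
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(list(name = name, precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), peaks = peaks),
            class = "ms2_spectrum")
}

#' Read an MSP spectral library
#'
#' @param path MSP text file.
#' @return List of [ms2_spectrum()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  spectra <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$peaks) || !nrow(cur$peaks)) return(NULL)
    ms2_spectrum(cur$precursor_mz, cur$peaks, rt = cur$rt, name = cur$name)
  }
  new_block <- function() list(name = NA_character_, precursor_mz = NA_real_,
                               rt = NA_real_, peaks = NULL)
  cur <- new_block()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) {
      s <- flush(cur)
      if (!is.null(s)) spectra[[length(spectra) + 1L]] <- s
      cur <- new_block()
      next
    }
    if (grepl(":", ln, fixed = TRUE) && !grepl("^[0-9]", ln)) {
      key <- toupper(trimws(sub(":.*$", "", ln)))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key == "NAME") cur$name <- val
      else if (key %in% c("PRECURSORMZ", "PRECURSOR_MZ"))
        cur$precursor_mz <- as.numeric(val)
      else if (key %in% c("RETENTIONTIME", "RT")) cur$rt <- as.numeric(val)
      # "Num Peaks" and unknown fields are informational; peak lines follow
      next
    }
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) >= 2) {
      mzi <- suppressWarnings(as.numeric(parts[1:2]))
      if (!any(is.na(mzi))) cur$peaks <- rbind(cur$peaks, mzi)
    }
  }
  s <- flush(cur)
  if (!is.null(s)) spectra[[length(spectra) + 1L]] <- s
  spectra
}

#' Write an MSP spectral library
#' @param spectra List of [ms2_spectrum()] objects.
#' @param path Output path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      paste0("NAME: ", if (is.na(s$name)) "unknown" else s$name),
      paste0("PRECURSORMZ: ", sprintf("%.15g", s$precursor_mz)),
      if (!is.na(s$rt)) paste0("RETENTIONTIME: ", sprintf("%.15g", s$rt)),
      paste0("Num Peaks: ", nrow(s$peaks)),
      sprintf("%.15g %.15g", s$peaks[, 1], s$peaks[, 2]),
      ""), con)
  }
  invisible(path)
}
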