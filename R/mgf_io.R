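# Mascot Generic Format (MGF) I/O. MGF is a simple line-oriented text
# format (BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE headers
# followed by "m/z intensity" peak lines); no pre-installed R package
# reads it, so the reader/writer lives here.

#' Read fragment spectra from an MGF file
#'
#' @param path Path to an MGF file.
#' @return A list of spectra; each is a list with `id`, `precursor_mz`,
#'   `charge` (integer or NA), `rt` (seconds, or NA) and `peaks` (a
#'   two-column matrix `mz`, `intensity`, sorted by m/z).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS / END IONS blocks")
  }
  spectra <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[hdr])
    vals <- sub("^[^=]*=", "", block[hdr])
    get <- function(key) {
      i <- match(key, keys)
      if (is.na(i)) NA_character_ else vals[i]
    }
    title <- get("TITLE")
    pep <- get("PEPMASS")
    mz <- if (is.na(pep)) NA_real_ else as.numeric(strsplit(pep, "\\s+")[[1]][1])
    chg <- get("CHARGE")
    charge <- if (is.na(chg)) NA_integer_ else {
      as.integer(sub("\\+$", "", sub("^([0-9]+)[+-]?$", "\\1", chg)))
    }
    rt <- get("RTINSECONDS")
    pk <- block[!hdr & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(x) {
        as.numeric(x[1:2])
      }))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    spectra[[k]] <- list(
      id = if (is.na(title)) paste0("spectrum_", k) else title,
      precursor_mz = mz, charge = charge,
      rt = if (is.na(rt)) NA_real_ else as.numeric(rt),
      peaks = peaks
    )
  }
  spectra
}

#' Write fragment spectra to an MGF file
#'
#' @param spectra List of spectra as produced by [read_mgf()] or
#'   [simulate_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$id), con)
    writeLines(paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)), con)
    if (!is.null(sp$charge) && !is.na(sp$charge)) {
      writeLines(paste0("CHARGE=", sp$charge, "+"), con)
    }
    if (!is.null(sp$rt) && !is.na(sp$rt)) {
      writeLines(paste0("RTINSECONDS=", format(sp$rt, digits = 8)), con)
    }
    if (nrow(sp$peaks)) {
      writeLines(paste(format(sp$peaks[, 1], digits = 10, trim = TRUE),
                       format(sp$peaks[, 2], digits = 6, trim = TRUE)), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
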