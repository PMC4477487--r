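#' Read a radial profile from plain text
#'
#' Reads the two-column text dialect used throughout the package: numeric rows
#' `q intensity [sigma]` separated by whitespace or commas, with `#` comment
#' lines. Header comments of the form `# key = value` populate the profile
#' metadata (recognised keys: `radiation`, `wavelength_nm`, `axis`; others are
#' kept verbatim). `q` is expected in nm^-1; Angstrom^-1 input is converted
#' when `unit = "angstrom"`.
#'
#' @param path Path to the file.
#' @param unit Unit of the q column: `"nm"` (default, nm^-1) or `"angstrom"`
#'   (Angstrom^-1, converted to nm^-1 on read).
#' @return A [radial_profile()].
#' @export
read_profile <- function(path, unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "fs_io")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  rows <- list()
  row_lines <- integer()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      if (grepl("=", kv, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", kv))
        val <- trimws(sub("^[^=]*=", "", kv))
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (is.na(num)) val else num
      }
      next
    }
    fields <- strsplit(ln, "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)) || !(length(vals) %in% c(2L, 3L))) {
      abort(sprintf("non-numeric or malformed row at line %d of %s", i, path),
            class = "fs_format")
    }
    rows[[length(rows) + 1L]] <- vals
    row_lines[[length(row_lines) + 1L]] <- i
  }
  if (length(rows) < 4L) {
    abort(sprintf("%s: need at least 4 data rows, found %d", path, length(rows)),
          class = "fs_format")
  }
  ncol <- length(rows[[1L]])
  if (!all(vapply(rows, length, 1L) == ncol)) {
    abort(sprintf("%s: inconsistent number of columns", path),
          class = "fs_format")
  }
  m <- do.call(rbind, rows)
  q <- m[, 1L]
  if (unit == "angstrom") q <- q * 10
  bad <- which(diff(q) <= 0)
  if (length(bad)) {
    abort(sprintf("%s: q not strictly increasing at line %d", path,
                  row_lines[bad[1L] + 1L]),
          class = "fs_format")
  }
  radial_profile(
    q = q, intensity = m[, 2L],
    sigma = if (ncol == 3L) m[, 3L] else NULL,
    radiation = meta$radiation %||% NA_character_,
    wavelength = meta$wavelength_nm %||% NA_real_,
    axis = meta$axis %||% NA_character_,
    meta = meta[setdiff(names(meta), c("radiation", "wavelength_nm", "axis"))]
  )
}

#' Write a radial profile to plain text
#'
#' Inverse of [read_profile()]: writes a `# key = value` metadata header
#' followed by whitespace-separated `q intensity [sigma]` rows, q in nm^-1.
#'
#' @param profile A [radial_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  meta <- profile_meta(profile)
  meta <- meta[!vapply(meta, function(v) length(v) != 1L || is.na(v), TRUE)]
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s = %s", k, if (is.numeric(v)) format(v, digits = 17) else v)
  }, "")
  has_sigma <- "sigma" %in% names(profile)
  body <- if (has_sigma) {
    sprintf("%.12g %.12g %.12g", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.12g %.12g", profile$q, profile$intensity)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read / write a 2D pattern grid as CSV
#'
#' CSV matrix layout: the first row holds the azimuthal angles (first cell is
#' a label), the first column the q values, the body the intensities.
#'
#' @param path File path.
#' @return A [pattern_grid()].
#' @export
read_pattern_grid <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "fs_io")
  }
  m <- as.matrix(utils::read.csv(path, header = FALSE, check.names = FALSE))
  angle <- suppressWarnings(as.numeric(m[1L, -1L]))
  q <- suppressWarnings(as.numeric(m[-1L, 1L]))
  body <- apply(m[-1L, -1L, drop = FALSE], 2L, as.numeric)
  if (any(is.na(angle)) || any(is.na(q)) || any(is.na(body))) {
    abort(sprintf("%s: non-numeric entries in pattern grid", path),
          class = "fs_format")
  }
  pattern_grid(q = q, angle = angle, intensity = body)
}

#' @param grid A [pattern_grid()].
#' @rdname read_pattern_grid
#' @export
write_pattern_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pattern_grid"))
  header <- paste(c("q_angle", format(grid$angle, digits = 12)), collapse = ",")
  rows <- vapply(seq_along(grid$q), function(i) {
    paste(format(c(grid$q[i], grid$intensity[i, ]), digits = 12),
          collapse = ",")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
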