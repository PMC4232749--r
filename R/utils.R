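#' Round half away from zero
#'
#' Report-time rounding used throughout the package. Printed tables in the
#' fragile-site literature use conventional half-up rounding (e.g. 1.2147
#' per-kb prints as 1.215), which differs from [base::round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 after decimal
  # representation error still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

MB <- 1e6
KB <- 1e3

#' Path to a bundled example/reference file
#'
#' @param file File name under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
fragsites_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fragsites")))
  }
  path <- system.file("extdata", file, package = "fragsites")
  if (!nzchar(path)) {
    stop("no bundled file named '", file, "'", call. = FALSE)
  }
  path
}

# strip thousands separators and coerce to double (bp coordinates can
# exceed .Machine$integer.max on no chromosome, but doubles are exact here)
parse_bp <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", "", trimws(x))))
  out
}

# split a ';'-separated feature-list cell into a character vector
split_list_cell <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

# standard comment header written at the top of every pipeline output file
output_header <- function(seed = NULL, config_hash = NULL) {
  c(
    paste0("# fragsites ", as.character(utils::packageVersion("fragsites"))),
    "# coordinates: 0-based half-open",
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config_hash)) paste0("# config_hash: ", config_hash)
  )
}

write_tsv_with_header <- function(x, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
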