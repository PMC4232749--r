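#' Read a chrom.sizes table into a genome assembly
#'
#' A genome assembly is the ordered table of chromosome names and lengths
#' that fixes the genome-length denominator used by all fraction and density
#' computations. The bundled `grch37.chrom.sizes` covers GRCh37/hg19
#' chr1-22, X and Y (3,095,677,412 bp); mitochondrial and unplaced contigs
#' are deliberately excluded, since haploid-genome fractions are only
#' consistent with the primary chromosomes.
#'
#' @param x Path to a two-column whitespace-separated chrom.sizes file, or a
#'   data frame with columns `chrom` and `length`.
#' @param name Text label for the assembly.
#' @return A tibble with columns `chrom` and `length`, class `fs_assembly`,
#'   in file order.
#' @examples
#' asm <- read_chrom_sizes(fragsites_extdata("grch37.chrom.sizes"))
#' genome_length(asm)
#' @export
read_chrom_sizes <- function(x, name = if (is.character(x)) basename(x) else "assembly") {
  if (is.character(x)) {
    df <- utils::read.table(x, header = FALSE, col.names = c("chrom", "length"),
                            colClasses = c("character", "numeric"),
                            comment.char = "#")
  } else {
    df <- as.data.frame(x)[, c("chrom", "length")]
  }
  if (anyDuplicated(df$chrom)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(df$chrom[duplicated(df$chrom)]), collapse = ", "),
         call. = FALSE)
  }
  len <- as.numeric(df$length)
  if (any(is.na(len)) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- tibble::tibble(chrom = as.character(df$chrom), length = len)
  attr(out, "assembly_name") <- name
  class(out) <- c("fs_assembly", class(out))
  out
}

#' Total genome length over an assembly or a chromosome subset
#'
#' The sum of chromosome lengths; with the bundled GRCh37 table this is the
#' haploid genome-length denominator G of every genome fraction and
#' outside-region density in the package.
#'
#' @param assembly An `fs_assembly` tibble from [read_chrom_sizes()].
#' @param chroms Optional character vector of chromosome names; default all.
#' @return Total length in base pairs (a double).
#' @export
genome_length <- function(assembly, chroms = NULL) {
  if (is.null(chroms)) return(sum(assembly$length))
  if (length(chroms) == 0) return(0)
  missing <- setdiff(chroms, assembly$chrom)
  if (length(missing) > 0) {
    stop("unknown chromosome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(assembly$length[match(chroms, assembly$chrom)])
}

#' Read a UCSC-style cytogenetic band table
#'
#' @param x Path to a five-column UCSC cytoBand file (chrom, start, end,
#'   band, stain; 0-based half-open, band label without the chromosome
#'   prefix), or a data frame with those columns. The bundled
#'   `cytoband_grch37_subset.txt` is a GRCh37 subset restricted to
#'   non-overlapping bands referenced by the fragile-site catalogue.
#' @return A tibble with columns `chrom`, `start`, `end`, `band`, `stain`.
#' @export
read_cytobands <- function(x) {
  if (is.character(x)) {
    df <- utils::read.table(x, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "band", "stain"),
                            colClasses = c("character", "numeric", "numeric",
                                           "character", "character"),
                            comment.char = "#")
  } else {
    df <- as.data.frame(x)
  }
  out <- tibble::as_tibble(df)
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("cytoband intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  split_chrom <- split(out, out$chrom)
  for (cb in split_chrom) {
    cb <- cb[order(cb$start), ]
    if (nrow(cb) > 1 && any(cb$start[-1] < cb$end[-nrow(cb)])) {
      stop("overlapping bands on ", cb$chrom[1], call. = FALSE)
    }
  }
  out
}

#' Resolve a cytogenetic band spec to a genomic interval
#'
#' Accepts a single band (`"3p14.2"`) or a range over two bands on the same
#' chromosome (`"1q21-1q25"`, en dash tolerated). A band label matches its
#' own row and any finer sub-band rows (`"1q21"` matches `1q21.1`). The
#' result is the smallest interval covering all matched bands, so adding
#' bands to a range can never shrink it.
#'
#' @param spec Band spec text, chromosome prefix included.
#' @param bands A band table from [read_cytobands()].
#' @return A one-row tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
band_to_interval <- function(spec, bands) {
  spec <- gsub("–", "-", trimws(spec))
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(1, 2)) {
    stop("band spec must be a single band or a two-band range: ", spec,
         call. = FALSE)
  }
  match_band <- function(one) {
    m <- regexec("^(chr)?([0-9]{1,2}|[XY])([pq][0-9.]*)$", one)
    g <- regmatches(one, m)[[1]]
    if (length(g) == 0) stop("cannot parse band spec: ", one, call. = FALSE)
    chrom <- paste0("chr", g[3])
    lab <- g[4]
    hit <- bands$chrom == chrom &
      (bands$band == lab | startsWith(bands$band, paste0(lab, ".")))
    if (!any(hit)) stop("unknown band: ", one, call. = FALSE)
    bands[hit, ]
  }
  hits <- dplyr::bind_rows(lapply(parts, match_band))
  if (length(unique(hits$chrom)) != 1) {
    stop("band range spans more than one chromosome: ", spec, call. = FALSE)
  }
  tibble::tibble(chrom = hits$chrom[1], start = min(hits$start),
                 end = max(hits$end))
}
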