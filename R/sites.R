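#' Parse a fragile-site catalogue table
#'
#' Reads a delimited catalogue of fragile sites -- either the cytogenetically
#' banded catalogue (125 sites) or the molecularly mapped catalogue (26
#' sites with BAC/STS-anchored boundaries), both bundled under `extdata` --
#' and normalizes it to 0-based half-open coordinates. Printed tables use
#' 1-based inclusive coordinates with thousands separators; on ingest the
#' separators are stripped and start is decremented by one, so interval
#' length is simply `end - start`.
#'
#' Rows flagged in the source `note` column as numerically ambiguous (the
#' digit grouping of some published rows cannot be resolved to a unique pair
#' of coordinates) are quarantined: they are excluded from the returned site
#' list and reported in the `exceptions` attribute rather than guessed at.
#' A site whose printed start is a telomere anchor or a bare "1" starts at
#' position 0 of its chromosome. Sites printed with two coordinate blocks
#' under one code appear as two rows sharing the same `site_id`.
#'
#' @param x Path to a TSV/CSV file, or a data frame, with columns `fra`,
#'   `chrom`, `start`, `end`, `inducer`, `frequency`, and optionally `band`,
#'   `anchor_from`/`anchor_to`, `cancer_genes`, `mirnas`, `refs`, `note`.
#' @param resolution `"cytogenetic"` or `"molecular"`.
#' @return A tibble of fragile sites (class `fs_sites`) with columns
#'   `site_id`, `chrom`, `start`, `end` (0-based half-open), `band`,
#'   `inducer`, `freq_class`, `resolution`, plus any feature-list columns
#'   present. Quarantined or otherwise noteworthy rows are recorded in
#'   `attr(, "exceptions")`.
#' @examples
#' cfs <- read_fragile_sites(fragsites_extdata("cfs_molecular_table.tsv"),
#'                           resolution = "molecular")
#' dplyr::filter(cfs, site_id == "FRA16D")
#' @export
read_fragile_sites <- function(x, resolution = c("cytogenetic", "molecular")) {
  resolution <- match.arg(resolution)
  if (is.character(x)) {
    sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(x, header = TRUE, sep = sep, quote = "",
                            colClasses = "character", comment.char = "#",
                            fill = TRUE)
  } else {
    df <- as.data.frame(lapply(x, as.character))
  }
  required <- c("fra", "chrom", "start", "end", "inducer", "frequency")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    out <- tibble::tibble(site_id = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          band = character(0), inducer = character(0),
                          freq_class = character(0), resolution = character(0))
    attr(out, "exceptions") <- empty_exceptions()
    attr(out, "quarantined") <- tibble::tibble(fra = character(0))
    class(out) <- c("fs_sites", class(out))
    return(out)
  }

  note <- if ("note" %in% names(df)) df$note else rep("", nrow(df))
  note[is.na(note)] <- ""
  # notes beginning "quarantined:" exclude the row's coordinates from
  # analysis; other notes are informational and only land in the report
  quarantined <- startsWith(note, "quarantined")
  exceptions <- tibble::tibble(site_id = df$fra[nzchar(note)],
                               problem = note[nzchar(note)])

  keep <- df[!quarantined, , drop = FALSE]
  start_raw <- trimws(keep$start)
  telomeric <- is.na(start_raw) | !nzchar(start_raw) |
    tolower(start_raw) == "telomere"
  start1 <- parse_bp(ifelse(telomeric, "1", start_raw))
  end1 <- parse_bp(keep$end)
  if (any(is.na(start1)) || any(is.na(end1))) {
    stop("unparseable coordinate in row(s): ",
         paste(keep$fra[is.na(start1) | is.na(end1)], collapse = ", "),
         call. = FALSE)
  }
  start0 <- start1 - 1
  if (any(end1 <= start0)) {
    stop("end <= start after normalization in row(s): ",
         paste(keep$fra[end1 <= start0], collapse = ", "), call. = FALSE)
  }

  inducer <- normalize_inducer(keep$inducer)
  freq <- tolower(trimws(keep$frequency))
  freq[!nzchar(freq) | is.na(freq)] <- NA_character_
  bad_freq <- !is.na(freq) & !freq %in% c("common", "rare")
  if (any(bad_freq)) {
    stop("unknown frequency label: ",
         paste(unique(keep$frequency[bad_freq]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(freq))) {
    exceptions <- dplyr::bind_rows(exceptions, tibble::tibble(
      site_id = keep$fra[is.na(freq)],
      problem = "frequency class not printed"))
  }

  out <- tibble::tibble(
    site_id = keep$fra,
    chrom = keep$chrom,
    start = start0,
    end = end1,
    band = if ("band" %in% names(keep)) keep$band else NA_character_,
    inducer = inducer,
    freq_class = freq,
    resolution = resolution
  )
  for (col in c("anchor_from", "anchor_to", "cancer_genes", "mirnas", "refs")) {
    if (col %in% names(keep)) out[[col]] <- keep[[col]]
  }
  attr(out, "exceptions") <- exceptions
  # quarantined rows keep their printed feature lists: those are catalogue
  # data even when the row's coordinates cannot be trusted
  qcols <- intersect(c("fra", "cancer_genes", "mirnas", "note"), names(df))
  attr(out, "quarantined") <- tibble::as_tibble(df[quarantined, qcols,
                                                   drop = FALSE])
  class(out) <- c("fs_sites", class(out))
  out
}

empty_exceptions <- function() {
  tibble::tibble(site_id = character(0), problem = character(0))
}

normalize_inducer <- function(x) {
  canon <- c(aphidicolin = "aphidicolin",
             "folic acid" = "folic acid",
             brdu = "BrdU",
             "distamycin a" = "distamycin A",
             "5-azacytidine" = "5-azacytidine",
             "5aza" = "5-azacytidine")
  key <- tolower(trimws(x))
  out <- unname(canon[key])
  if (any(is.na(out))) {
    stop("unknown inducer label: ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Exceptions report of a parsed catalogue
#'
#' @param sites An `fs_sites` tibble.
#' @return A tibble with columns `site_id` and `problem`.
#' @export
site_exceptions <- function(sites) {
  ex <- attr(sites, "exceptions")
  if (is.null(ex)) empty_exceptions() else ex
}

#' Merge fragile sites into a disjoint region set
#'
#' Computes the overlap-deduplicated union of the site intervals per
#' chromosome. Distinct site codes printed with identical coordinates (for
#' example FRA16B and FRA16C) remain distinct named sites but contribute a
#' single interval to the union, so total extents and deduplicated feature
#' counts are never inflated by duplicates.
#'
#' @param sites An `fs_sites` tibble; all rows must share one resolution.
#' @return A tibble (class `fs_merged`) with columns `chrom`, `start`,
#'   `end`, and `site_ids` (list column of contributing site codes), sorted
#'   and pairwise disjoint within each chromosome.
#' @export
merge_sites <- function(sites) {
  res <- unique(sites$resolution)
  if (length(res) > 1) {
    stop("cannot merge sites of mixed resolution classes: ",
         paste(res, collapse = ", "), call. = FALSE)
  }
  if (nrow(sites) == 0) {
    out <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), site_ids = list())
    attr(out, "resolution") <- res
    class(out) <- c("fs_merged", class(out))
    return(out)
  }
  ids <- if ("site_id" %in% names(sites)) sites$site_id else
    as.character(seq_len(nrow(sites)))
  pieces <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    ir <- IRanges::IRanges(start = sites$start[idx] + 1, end = sites$end[idx])
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    tibble::tibble(
      chrom = sites$chrom[idx[1]],
      start = IRanges::start(red) - 1,
      end = IRanges::end(red),
      site_ids = lapply(revmap, function(k) unique(ids[idx][k]))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces), chrom, start)
  attr(out, "resolution") <- res
  class(out) <- c("fs_merged", class(out))
  out
}

#' Total genomic extent of a merged region set
#'
#' @param merged An `fs_merged` tibble from [merge_sites()] (any tibble with
#'   disjoint `start`/`end` columns works).
#' @return Total length in base pairs.
#' @export
total_length <- function(merged) {
  if (nrow(merged) == 0) return(0)
  sum(merged$end - merged$start)
}

#' Genome fraction covered by a region length
#'
#' @param region_length Covered length in base pairs.
#' @param G Genome length denominator in base pairs (see [genome_length()]).
#' @param digits Optional report rounding (half-up); default no rounding.
#' @return Percentage of the genome covered.
#' @examples
#' genome_fraction(835.22e6, 3095677412, digits = 0)  # 27
#' @export
genome_fraction <- function(region_length, G, digits = NULL) {
  if (G <= 0) stop("genome length G must be positive", call. = FALSE)
  if (any(region_length < 0) || any(region_length > G)) {
    stop("region_length must lie in [0, G]", call. = FALSE)
  }
  pct <- 100 * region_length / G
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  pct
}

#' Deduplicated feature lists carried by a catalogue table
#'
#' The printed catalogues carry, per site, the cancer-pathway genes and the
#' miRNA precursors located within that site. This helper flattens those
#' columns into one record per (site, category, feature) and reports the
#' deduplicated totals, the granularity at which the catalogue-level counts
#' (e.g. "110 cancer-related genes within the 125 CFSs") are stated.
#'
#' @param sites An `fs_sites` tibble with `cancer_genes` and/or `mirnas`
#'   columns.
#' @return A list with `records` (tibble: `site_id`, `category`,
#'   `feature_id`) and `n_distinct` (named integer vector per category).
#' @export
site_feature_lists <- function(sites) {
  recs <- list()
  cols <- c(cancer_gene = "cancer_genes", mirna = "mirnas")
  quarantined <- attr(sites, "quarantined")
  for (cat in names(cols)) {
    col <- cols[[cat]]
    if (!col %in% names(sites)) next
    ids <- sites$site_id
    cells <- sites[[col]]
    if (!is.null(quarantined) && col %in% names(quarantined)) {
      # quarantined rows still carry printed feature lists
      ids <- c(ids, quarantined$fra)
      cells <- c(cells, quarantined[[col]])
    }
    recs[[cat]] <- tidyr::unnest(
      tibble::tibble(site_id = ids,
                     category = cat,
                     feature_id = lapply(cells, split_list_cell)),
      "feature_id")
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(site_id = character(0), category = character(0),
                   feature_id = character(0))
  counts <- vapply(split(records$feature_id, records$category),
                   function(v) length(unique(v)), integer(1))
  list(records = records, n_distinct = counts)
}

#' Export sites or merged regions as BED
#'
#' Writes BED6 for site tables (name = site code, score 0, strand ".") or
#' BED4 for merged region sets (name = comma-joined contributing codes),
#' 0-based half-open as BED requires.
#'
#' @param x An `fs_sites` or `fs_merged` tibble.
#' @param path Output file path.
#' @param header Optional comment header lines.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(x, path, header = character(0)) {
  if (inherits(x, "fs_merged")) {
    bed <- data.frame(chrom = x$chrom, start = format_bp(x$start),
                      end = format_bp(x$end),
                      name = vapply(x$site_ids, paste, "", collapse = ","))
  } else {
    bed <- data.frame(chrom = x$chrom, start = format_bp(x$start),
                      end = format_bp(x$end), name = x$site_id,
                      score = 0, strand = ".")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
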