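#' Read miRNA precursor annotations from a miRBase GFF3
#'
#' Keeps one record per precursor (`miRNA_primary_transcript` feature type);
#' mature-miR lines are dropped so a precursor never counts twice. Names are
#' lower-cased to the `hsa-mir-*` convention used by the fragile-site
#' catalogue tables (the hairpin naming in miRBase mixes cases, e.g.
#' `hsa-let-7a-1` vs `hsa-mir-21`).
#'
#' @param gff Path to a GFF3 file (gzip tolerated).
#' @param species_prefix Keep only features whose name starts with this
#'   prefix (default `"hsa"`); set `NULL` to keep all.
#' @return A tibble of feature records: `feature_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `category = "mirna"`, `source`.
#' @export
read_mirna_gff <- function(gff, species_prefix = "hsa") {
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA_primary_transcript"]
  nm <- as.character(gr$Name)
  if (length(gr) > 0 && (is.null(nm) || anyNA(nm))) {
    stop("precursor record(s) missing a Name attribute", call. = FALSE)
  }
  out <- tibble::tibble(
    feature_id = normalize_mir_name(nm),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    category = "mirna",
    source = "mirbase"
  )
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  if (!is.null(species_prefix)) {
    out <- out[startsWith(out$feature_id, paste0(tolower(species_prefix), "-")), ]
  }
  out
}

#' Normalize a miRNA name for matching
#'
#' Case-insensitive and hyphen-normalized, so table typography (`hsa-miR-21`,
#' `hsa mir 21`) matches the catalogue convention `hsa-mir-21`.
#'
#' @param x Character vector of miRNA names.
#' @return Normalized names.
#' @export
normalize_mir_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ _–—]+", "-", x)
  gsub("-+", "-", x)
}

#' Build a gene feature catalogue from a symbol list and an annotation table
#'
#' Each gene is represented by one genomic span (the outermost transcript
#' span per symbol): the analysis counts genes located within fragile
#' regions, not transcripts. Symbols missing from the annotation are
#' reported, never silently dropped.
#'
#' @param symbols Character vector of gene symbols (e.g. the 327 KEGG
#'   "Pathways in cancer" genes).
#' @param annotation Data frame or delimited file with columns `symbol`,
#'   `chrom`, `start`, `end` (1-based inclusive, as annotation exports
#'   print them).
#' @return A tibble of feature records (`category = "cancer_gene"`), with
#'   the unmatched symbols in `attr(, "unmatched")`.
#' @export
read_gene_catalog <- function(symbols, annotation) {
  if (is.character(annotation)) {
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    quote = "", colClasses = "character",
                                    comment.char = "#")
  }
  ann <- tibble::as_tibble(as.data.frame(annotation))
  ann <- ann[ann$symbol %in% symbols, , drop = FALSE]
  conflicting <- unique(ann$symbol[stats::ave(
    as.integer(factor(ann$chrom)), ann$symbol,
    FUN = function(v) length(unique(v))) > 1])
  if (length(conflicting) > 0) {
    stop("conflicting chromosome assignment for symbol(s): ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }
  spans <- dplyr::summarise(
    dplyr::group_by(ann, .data$symbol, .data$chrom),
    start = min(parse_bp(.data$start)) - 1,
    end = max(parse_bp(.data$end)),
    .groups = "drop")
  out <- tibble::tibble(
    feature_id = spans$symbol,
    chrom = spans$chrom,
    start = spans$start,
    end = spans$end,
    strand = "unknown",
    category = "cancer_gene",
    source = "gene_catalog"
  )
  attr(out, "unmatched") <- setdiff(symbols, out$feature_id)
  out
}

#' Read one or more peak files (BED3/BED6/narrowPeak) into a pooled record list
#'
#' Intervals come from columns 1-3; extra columns (narrowPeak scores, summit
#' offsets) are ignored. Each file is tagged with its label (typically the
#' cell line), and per-label counts are retained so genome-wide per-cell-line
#' fractions remain computable after pooling. Pooling never deduplicates
#' identical peaks across labels: a site supported in two cell lines is two
#' records.
#'
#' @param paths Character vector of BED/narrowPeak paths (gzip tolerated).
#' @param labels One label per file.
#' @param category Feature category tag, default `"ctcf_site"`.
#' @return A tibble of feature records with `attr(, "per_label_counts")`.
#' @export
read_peak_sets <- function(paths, labels, category = "ctcf_site") {
  if (length(paths) != length(labels)) {
    stop("need exactly one label per peak file (", length(paths), " files, ",
         length(labels), " labels)", call. = FALSE)
  }
  one <- function(path, label) {
    df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                            comment.char = "#", fill = TRUE,
                            colClasses = "character")
    if (nrow(df) == 0) {
      return(tibble::tibble(feature_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            strand = character(0), category = character(0),
                            source = character(0)))
    }
    start <- parse_bp(df[[2]])
    end <- parse_bp(df[[3]])
    if (any(is.na(start) | is.na(end)) || any(end <= start)) {
      stop("invalid interval (end <= start) in ", path, call. = FALSE)
    }
    name <- if (ncol(df) >= 4 && any(nzchar(df[[4]]))) df[[4]] else
      paste0(label, "_peak", seq_len(nrow(df)))
    strand <- if (ncol(df) >= 6) df[[6]] else rep("unknown", nrow(df))
    strand[!strand %in% c("+", "-")] <- "unknown"
    tibble::tibble(feature_id = paste(label, name, sep = ":"),
                   chrom = df[[1]], start = start, end = end,
                   strand = strand, category = category, source = label)
  }
  out <- dplyr::bind_rows(purrr::map2(paths, labels, one))
  counts <- vapply(labels, function(l) sum(out$source == l), integer(1))
  attr(out, "per_label_counts") <- counts
  out
}

#' Validate feature records against an assembly
#'
#' @param features A feature-record tibble.
#' @param assembly An `fs_assembly` tibble.
#' @return `features`, invisibly, after checking every interval satisfies
#'   `0 <= start < end <= chromosome length`.
#' @export
validate_features <- function(features, assembly) {
  missing <- setdiff(unique(features$chrom), assembly$chrom)
  if (length(missing) > 0) {
    stop("chromosome(s) absent from assembly: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lim <- assembly$length[match(features$chrom, assembly$chrom)]
  bad <- features$start < 0 | features$start >= features$end | features$end > lim
  if (any(bad)) {
    stop(sum(bad), " feature record(s) violate 0 <= start < end <= chrom length",
         call. = FALSE)
  }
  invisible(features)
}
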