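#' Read a piecewise-constant signal track (bedGraph or wiggle)
#'
#' Loads a text signal track into a normalized per-chromosome segment table.
#' Gaps between segments mean "no data" (not zero); overlapping input
#' segments are rejected because a piecewise-constant track is ill-defined
#' under overlap.
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`,
#'   fixedStep or variableStep) file; gzip tolerated.
#' @param label Track label, e.g. `"H3K27ac:K562"`; defaults to the file
#'   name.
#' @param format Override format detection: `"bedGraph"` or `"wig"`.
#' @return A tibble (class `fs_signal_track`) with columns `chrom`, `start`,
#'   `end` (0-based half-open), `value`, sorted, with the label stored in
#'   `attr(, "label")`.
#' @export
read_signal <- function(path, label = NULL, format = NULL) {
  if (is.null(format)) {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(bedgraph|bg)$", base, ignore.case = TRUE))
      "bedGraph" else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  track <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    value = as.numeric(gr$score)
  )
  as_signal_track(track,
                  label = if (is.null(label)) basename(path) else label)
}

#' Construct a signal track from a segment table
#'
#' @param track Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `value` columns.
#' @param label Track label.
#' @return An `fs_signal_track` tibble, validated and sorted.
#' @export
as_signal_track <- function(track, label = "track") {
  out <- tibble::as_tibble(track)[, c("chrom", "start", "end", "value")]
  if (any(out$start < 0)) stop("negative coordinates", call. = FALSE)
  if (any(out$start >= out$end)) stop("segments need start < end", call. = FALSE)
  if (any(!is.finite(out$value))) stop("non-finite signal values", call. = FALSE)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  for (chr in unique(out$chrom)) {
    idx <- out$chrom == chr
    s <- out$start[idx]; e <- out$end[idx]
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      stop("overlapping segments on ", chr, call. = FALSE)
    }
  }
  attr(out, "label") <- label
  class(out) <- c("fs_signal_track", class(out))
  out
}

#' Length-weighted mean signal over an interval
#'
#' The per-region mean a genome-browser summary utility would report:
#' segment values weighted by the number of interval bases they cover. By
#' default uncovered bases are excluded from the weighting; with
#' `gaps_as_zero = TRUE` they enter as zeros (both conventions exist in the
#' wild, so the choice is explicit). An interval with no covered base has no
#' defined mean and raises a condition of class `fragsites_undefined_mean`
#' -- deliberately distinct from a mean of 0.
#'
#' @param track An `fs_signal_track`.
#' @param chrom,start,end Interval (0-based half-open). Alternatively pass a
#'   one-row data frame as `chrom` with those columns.
#' @param gaps_as_zero Treat uncovered bases as signal 0 instead of
#'   excluding them.
#' @return The mean signal (a double).
#' @export
interval_mean <- function(track, chrom, start = NULL, end = NULL,
                          gaps_as_zero = FALSE) {
  if (is.data.frame(chrom)) {
    start <- chrom$start; end <- chrom$end; chrom <- chrom$chrom
  }
  stopifnot(length(chrom) == 1, start < end)
  seg <- track[track$chrom == chrom, ]
  ov_start <- pmax(seg$start, start)
  ov_end <- pmin(seg$end, end)
  w <- pmax(ov_end - ov_start, 0)
  covered <- sum(w)
  if (covered == 0) {
    stop(structure(class = c("fragsites_undefined_mean", "error", "condition"),
                   list(message = paste0("interval ", chrom, ":", start, "-",
                                         end, " has no covered base"),
                        call = sys.call(-1))))
  }
  denom <- if (gaps_as_zero) (end - start) else covered
  sum(seg$value * w) / denom
}

#' Per-site signal delta from the chromosome mean
#'
#' For each fragile site the statistic is the mean signal over the site
#' minus the mean signal over the site's own chromosome:
#' `delta_i = mean(site_i) - mean(chromosome of site_i)`. The chromosome
#' baseline is computed once per (track, chromosome) and reused. Adding a
#' constant to the whole track leaves every delta unchanged.
#'
#' @param track An `fs_signal_track`.
#' @param sites An `fs_sites` tibble (or any tibble with `site_id`, `chrom`,
#'   `start`, `end`).
#' @param assembly Optional `fs_assembly`; required for
#'   `gaps_as_zero = TRUE`, where the chromosome mean needs the true
#'   chromosome length. Otherwise the chromosome mean is taken over the
#'   track's covered bases.
#' @param gaps_as_zero Passed to [interval_mean()].
#' @return A tibble (class `fs_signal_delta`) with columns `site_id`,
#'   `track_label`, `mean_site`, `mean_chrom`, `delta`. Sites on
#'   chromosomes the track does not cover get `NA` deltas with a warning.
#' @export
signal_delta <- function(track, sites, assembly = NULL, gaps_as_zero = FALSE) {
  if (gaps_as_zero && is.null(assembly)) {
    stop("gaps_as_zero = TRUE needs an assembly for chromosome lengths",
         call. = FALSE)
  }
  label <- attr(track, "label")
  if (is.null(label)) label <- "track"
  chrom_mean <- function(chr) {
    seg <- track[track$chrom == chr, ]
    if (nrow(seg) == 0) return(NA_real_)
    if (gaps_as_zero) {
      L <- assembly$length[match(chr, assembly$chrom)]
      sum(seg$value * (seg$end - seg$start)) / L
    } else {
      sum(seg$value * (seg$end - seg$start)) / sum(seg$end - seg$start)
    }
  }
  baselines <- vapply(unique(sites$chrom), chrom_mean, numeric(1))
  mean_site <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    mean_site[i] <- tryCatch(
      interval_mean(track, sites$chrom[i], sites$start[i], sites$end[i],
                    gaps_as_zero = gaps_as_zero),
      fragsites_undefined_mean = function(e) NA_real_)
  }
  mean_chrom <- unname(baselines[sites$chrom])
  if (anyNA(mean_site) || anyNA(mean_chrom)) {
    warning("site(s) on chromosomes not covered by '", label,
            "' have undefined deltas", call. = FALSE)
  }
  out <- tibble::tibble(site_id = sites$site_id, track_label = label,
                        mean_site = mean_site, mean_chrom = mean_chrom,
                        delta = mean_site - mean_chrom)
  class(out) <- c("fs_signal_delta", class(out))
  out
}

#' Per-site delta matrix across several tracks
#'
#' @param tracks List of `fs_signal_track` objects (labels from
#'   `attr(, "label")`).
#' @param sites `fs_sites` tibble.
#' @param ... Passed to [signal_delta()].
#' @return A long tibble of deltas (one row per site x track); reshape with
#'   [tidyr::pivot_wider()] for a sites-by-tracks matrix.
#' @export
delta_matrix <- function(tracks, sites, ...) {
  out <- dplyr::bind_rows(lapply(tracks, signal_delta, sites = sites, ...))
  class(out) <- c("fs_signal_delta", class(out))
  out
}

#' Default cell-line grouping for the seven reference cell lines
#'
#' The grouping used when comparing per-site deltas between cell-type
#' classes: K562 (cancer), GM12878 (lymphoblastoid, grouped with the
#' cancer/embryonic class), H1-hESC (embryonic), NHEK (normal epithelial),
#' and HSMM, HUVEC, NHLF (normal mesenchymal). Editable: pass your own named
#' vector anywhere a grouping is accepted. Whether a lymphoblastoid line
#' belongs with the cancer-like class is an assumption, not a measurement.
#'
#' @return A named character vector mapping cell line to group.
#' @export
default_cell_groups <- function() {
  c(K562 = "cancer_embryonic", GM12878 = "cancer_embryonic",
    `H1-hESC` = "cancer_embryonic", NHEK = "normal_epithelial",
    HSMM = "normal_mesenchymal", HUVEC = "normal_mesenchymal",
    NHLF = "normal_mesenchymal")
}

#' Compare per-site signal deltas between cell-line groups
#'
#' One-way fixed-effects analysis of variance of the deltas across groups,
#' with F and p from the F distribution on (k-1, n-k) degrees of freedom.
#'
#' @param deltas An `fs_signal_delta` tibble (needs `delta` and
#'   `track_label`), or any data frame with those columns. The cell-line
#'   part of `track_label` after a `"mark:cell"` colon, or the whole label,
#'   is matched against `names(grouping)`.
#' @param grouping Named character vector mapping cell line to group; see
#'   [default_cell_groups()].
#' @return An object of class `fs_group_anova`: list with `group_means`,
#'   `statistic` (F), `p.value`, `df`, and the underlying `aov` fit.
#' @export
compare_groups <- function(deltas, grouping = default_cell_groups()) {
  cell <- sub("^[^:]*:", "", deltas$track_label)
  group <- unname(grouping[cell])
  keep <- !is.na(group) & !is.na(deltas$delta)
  df <- data.frame(delta = deltas$delta[keep], group = factor(group[keep]))
  sizes <- table(df$group)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs >= 2 values; short group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  if (stats::var(df$delta) == 0) {
    stop("all deltas identical: F undefined (0/0)", call. = FALSE)
  }
  fit <- stats::aov(delta ~ group, data = df)
  tab <- summary(fit)[[1]]
  structure(list(
    group_means = tapply(df$delta, df$group, mean),
    group_sizes = as.integer(sizes),
    statistic = tab[1, "F value"],
    p.value = tab[1, "Pr(>F)"],
    df = c(tab[1, "Df"], tab[2, "Df"]),
    grouping = grouping,
    fit = fit
  ), class = "fs_group_anova")
}

#' @export
print.fs_group_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of signal deltas: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `fs_group_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per group (mean and size).
#' @method tidy fs_group_anova
#' @export
tidy.fs_group_anova <- function(x, ...) {
  tibble::tibble(group = names(x$group_means),
                 mean_delta = as.numeric(x$group_means),
                 n = x$group_sizes)
}

#' One-row summary of a group comparison
#'
#' @param x An `fs_group_anova` object.
#' @param ... Unused.
#' @return A one-row tibble with F, p and degrees of freedom.
#' @method glance fs_group_anova
#' @export
glance.fs_group_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 df = x$df[1], df.residual = x$df[2])
}

#' Five-number summary with Tukey outlier flagging
#'
#' Min, first quartile, median, third quartile and max of a set of signal
#' deltas, with whiskers at 1.5 x IQR and the values beyond them listed as
#' outliers. The quartile rule is linear interpolation by default
#' ([stats::quantile()] type 7); `rule = "hinges"` uses Tukey hinges
#' ([stats::fivenum()]). The rule used is recorded in the result.
#'
#' @param values Numeric vector (>= 1 value).
#' @param rule `"linear"` or `"hinges"`.
#' @return A list of class `fs_box_summary`: `stats` (named min/q1/median/
#'   q3/max), `whiskers` (lo/hi fences), `outliers`, `rule`, `n`.
#' @export
distribution_summary <- function(values, rule = c("linear", "hinges")) {
  rule <- match.arg(rule)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values", call. = FALSE)
  if (rule == "linear") {
    q <- stats::quantile(values, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  } else {
    q <- stats::fivenum(values)
  }
  iqr <- q[4] - q[2]
  lo <- q[2] - 1.5 * iqr
  hi <- q[4] + 1.5 * iqr
  structure(list(
    stats = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]),
    whiskers = c(lo = lo, hi = hi),
    outliers = sort(values[values < lo | values > hi]),
    rule = rule,
    n = length(values)
  ), class = "fs_box_summary")
}

#' Boxplot of per-site delta distributions
#'
#' @param object An `fs_signal_delta` tibble (typically from
#'   [delta_matrix()] over several cell lines).
#' @param ... Unused.
#' @return A ggplot: one box per site across tracks.
#' @method autoplot fs_signal_delta
#' @export
autoplot.fs_signal_delta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site_id, y = .data$delta)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "signal delta (site mean - chromosome mean)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
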