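#' Simulate a genome with disjoint fragile regions
#'
#' Generates `n_sites` disjoint intervals on a toy multi-chromosome genome
#' so that the realized fragile fraction is within 1 % of the target
#' `fragile_fraction`. Site lengths are equal (the target coverage divided
#' by `n_sites`) and placements are drawn on the integer bp grid, so the
#' output is byte-reproducible given the seed.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp; names
#'   become chromosome names (default `chr1..chrN`).
#' @param fragile_fraction Target fraction of the genome covered, in
#'   `[0, 1)`. `0` yields an empty site list.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return A list: `sites` (an `fs_sites` tibble, ids `SIM1..`), `assembly`
#'   (`fs_assembly`), and `truth` (list with the config echo and the
#'   realized fragile length and fraction).
#' @export
simulate_regions <- function(chrom_lengths, fragile_fraction, n_sites,
                             seed = 1) {
  stopifnot(fragile_fraction >= 0, fragile_fraction < 1, n_sites >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  assembly <- read_chrom_sizes(
    data.frame(chrom = names(chrom_lengths), length = as.numeric(chrom_lengths)),
    name = "synthetic")
  G <- sum(chrom_lengths)
  empty <- read_fragile_sites(
    data.frame(fra = character(0), chrom = character(0), start = character(0),
               end = character(0), inducer = character(0),
               frequency = character(0)), resolution = "molecular")
  if (fragile_fraction == 0 || n_sites == 0) {
    return(list(sites = empty, assembly = assembly,
                truth = list(config = list(chrom_lengths = chrom_lengths,
                                           fragile_fraction = fragile_fraction,
                                           n_sites = n_sites, seed = seed),
                             fragile_length = 0, realized_fraction = 0)))
  }
  site_len <- round(fragile_fraction * G / n_sites)
  if (site_len < 1) stop("infeasible: sites would be empty", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # allot sites to chromosomes proportionally to length, then place each
  # chromosome's sites disjointly via sorted uniform gaps
  probs <- chrom_lengths / G
  alloc <- as.vector(stats::rmultinom(1, n_sites, probs))
  while (any(alloc * site_len > chrom_lengths)) {
    over <- which(alloc * site_len > chrom_lengths)[1]
    room <- which(alloc * site_len + site_len <= chrom_lengths)
    if (length(room) == 0) stop("infeasible fragile_fraction/n_sites combination",
                                call. = FALSE)
    alloc[over] <- alloc[over] - 1
    alloc[room[1]] <- alloc[room[1]] + 1
  }
  rows <- list()
  idx <- 1
  for (ci in seq_along(chrom_lengths)) {
    k <- alloc[ci]
    if (k == 0) next
    L <- chrom_lengths[ci]
    free <- L - k * site_len
    gaps <- sort(sample.int(free + 1, k, replace = TRUE) - 1)
    starts <- gaps + (seq_len(k) - 1) * site_len
    rows[[ci]] <- tibble::tibble(
      fra = paste0("SIM", idx:(idx + k - 1)),
      chrom = names(chrom_lengths)[ci],
      start = format_bp(starts + 1),   # printed convention: 1-based inclusive
      end = format_bp(starts + site_len),
      inducer = "aphidicolin", frequency = "common")
    idx <- idx + k
  }
  sites <- read_fragile_sites(dplyr::bind_rows(rows), resolution = "molecular")
  fragile_length <- total_length(merge_sites(sites))
  list(sites = sites, assembly = assembly,
       truth = list(config = list(chrom_lengths = chrom_lengths,
                                  fragile_fraction = fragile_fraction,
                                  n_sites = n_sites, seed = seed),
                    fragile_length = fragile_length,
                    realized_fraction = fragile_length / G))
}

#' Plant point features with a known inside/outside density ratio
#'
#' Draws a Poisson number of 1 bp features inside the fragile-region set at
#' rate `rho * lambda` per Mb and outside at rate `lambda` per Mb, positions
#' uniform within their stratum on the integer grid. Because features are
#' points, the planted inside/outside counts are exact and the expected
#' relative density increase recovered by [density_enrichment()] is
#' `100 * (rho - 1)`.
#'
#' @param assembly `fs_assembly` tibble.
#' @param merged `fs_merged` region set (the "inside" stratum).
#' @param lambda Outside feature rate per Mb (>= 0).
#' @param rho Enrichment ratio (inside rate = `rho * lambda`).
#' @param seed Integer seed.
#' @param category Category tag for the emitted records.
#' @return A list: `features` (record tibble) and `truth` (planted
#'   parameters, realized `n_in`/`n_out`, and
#'   `expected_relative_increase_pct = 100 * (rho - 1)`).
#' @export
plant_features <- function(assembly, merged, lambda, rho, seed = 1,
                           category = "planted") {
  stopifnot(lambda >= 0, rho >= 0)
  G <- genome_length(assembly)
  L_in <- total_length(merged)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_in <- stats::rpois(1, rho * lambda * L_in / MB)
  n_out <- stats::rpois(1, lambda * (G - L_in) / MB)
  inside <- draw_positions(n_in, stratum_segments(assembly, merged, inside = TRUE))
  outside <- draw_positions(n_out, stratum_segments(assembly, merged, inside = FALSE))
  features <- tibble::tibble(
    feature_id = c(sprintf("in_%d", seq_len(n_in)),
                   sprintf("out_%d", seq_len(n_out))),
    chrom = c(inside$chrom, outside$chrom),
    start = c(inside$pos, outside$pos),
    end = c(inside$pos, outside$pos) + 1,
    strand = "unknown",
    category = category,
    source = "synthetic",
    stratum = rep(c("inside", "outside"), c(n_in, n_out))
  )
  list(features = features,
       truth = list(lambda = lambda, rho = rho, seed = seed,
                    L_in = L_in, G = G, n_in = n_in, n_out = n_out,
                    expected_relative_increase_pct = 100 * (rho - 1)))
}

# disjoint segment table of the inside stratum or its complement
stratum_segments <- function(assembly, merged, inside) {
  if (inside) {
    return(merged[, c("chrom", "start", "end")])
  }
  rows <- list()
  for (i in seq_len(nrow(assembly))) {
    chr <- assembly$chrom[i]
    m <- merged[merged$chrom == chr, ]
    bounds <- c(0, rbind(m$start, m$end), assembly$length[i])
    s <- bounds[seq(1, length(bounds) - 1, by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e > s
    if (any(keep)) rows[[chr]] <- tibble::tibble(chrom = chr, start = s[keep],
                                                 end = e[keep])
  }
  dplyr::bind_rows(rows)
}

# n uniform integer positions over a disjoint segment set
draw_positions <- function(n, segments) {
  if (n == 0 || nrow(segments) == 0) {
    return(tibble::tibble(chrom = character(0), pos = numeric(0)))
  }
  len <- segments$end - segments$start
  cum <- cumsum(len)
  u <- floor(stats::runif(n) * cum[length(cum)])  # 0 .. total-1
  seg <- findInterval(u, c(0, cum))
  offset <- u - c(0, cum)[seg]
  tibble::tibble(chrom = segments$chrom[seg],
                 pos = segments$start[seg] + offset)
}

#' Simulate a binned signal track with a planted per-site shift
#'
#' Emits a piecewise-constant track of `bin`-bp segments with value
#' `mu + delta * [bin midpoint inside a fragile site] + Normal(0, sigma)`.
#' The truth record carries, per site, both the analytic shift
#' `delta * (1 - site_length / chrom_length)` and the exact noise-free delta
#' computed from the realized binning (they coincide when site boundaries
#' align with bins).
#'
#' @param assembly `fs_assembly` tibble.
#' @param sites `fs_sites` tibble.
#' @param mu Baseline signal value.
#' @param delta Signal shift inside sites.
#' @param sigma Noise standard deviation (>= 0).
#' @param bin Bin width in bp; a final partial bin is allowed.
#' @param seed Integer seed.
#' @param label Track label.
#' @return A list: `track` (`fs_signal_track`) and `truth` (config echo plus
#'   per-site `expected_delta` tibble).
#' @export
simulate_track <- function(assembly, sites, mu, delta, sigma, bin, seed = 1,
                           label = "synthetic") {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  segs <- list()
  for (i in seq_len(nrow(assembly))) {
    chr <- assembly$chrom[i]
    L <- assembly$length[i]
    start <- seq(0, L - 1, by = bin)
    end <- pmin(start + bin, L)
    mid <- (start + end) / 2
    in_site <- rep(FALSE, length(start))
    sc <- sites[sites$chrom == chr, ]
    for (j in seq_len(nrow(sc))) {
      in_site <- in_site | (mid >= sc$start[j] & mid < sc$end[j])
    }
    base <- mu + delta * in_site
    segs[[chr]] <- tibble::tibble(
      chrom = chr, start = start, end = end,
      base = base,
      value = base + if (sigma > 0) stats::rnorm(length(start), 0, sigma) else 0)
  }
  all <- dplyr::bind_rows(segs)
  track <- as_signal_track(all[, c("chrom", "start", "end", "value")],
                           label = label)
  clean <- as_signal_track(all[, c("chrom", "start", "end", "base")] |>
                             dplyr::rename(value = "base"),
                           label = paste0(label, "_noiseless"))
  expected <- signal_delta(clean, sites)
  chrom_len <- assembly$length[match(sites$chrom, assembly$chrom)]
  truth <- list(mu = mu, delta = delta, sigma = sigma, bin = bin, seed = seed,
                expected_delta = tibble::tibble(
                  site_id = sites$site_id,
                  analytic = delta * (1 - (sites$end - sites$start) / chrom_len),
                  exact = expected$delta))
  list(track = track, truth = truth)
}

#' Write a synthetic bundle to disk
#'
#' Emits the site BED, feature BED, track bedGraph and a JSON truth file,
#' each with a header recording the seed and coordinate convention, so the
#' other pipeline stages can consume them unchanged.
#'
#' @param regions Result of [simulate_regions()].
#' @param planted Result of [plant_features()] (optional).
#' @param tracked Result of [simulate_track()] (optional).
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in headers.
#' @return Named character vector of the files written.
#' @export
write_synthetic_bundle <- function(regions, planted = NULL, tracked = NULL,
                                   dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(seed = seed)
  files <- c(sites = file.path(dir, "sites.bed"))
  write_sites_bed(regions$sites, files["sites"], header = hdr)
  truth <- list(regions = regions$truth)
  if (!is.null(planted)) {
    files["features"] <- file.path(dir, "features.bed")
    f <- planted$features
    bed <- data.frame(f$chrom, format_bp(f$start), format_bp(f$end),
                      f$feature_id, 0, ".")
    con <- file(files["features"], "wt"); writeLines(hdr, con)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    truth$features <- planted$truth
  }
  if (!is.null(tracked)) {
    files["track"] <- file.path(dir, "track.bedgraph")
    t <- tracked$track
    con <- file(files["track"], "wt"); writeLines(hdr, con)
    utils::write.table(
      data.frame(t$chrom, format_bp(t$start), format_bp(t$end),
                 formatC(t$value, format = "g", digits = 10)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
    truth$track <- tracked$truth
    truth$track$expected_delta <- as.list(truth$track$expected_delta)
  }
  files["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
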