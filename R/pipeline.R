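#' Default run configuration
#'
#' All tunable constants of the pipeline in one inspectable list: the
#' bundled GRCh37 assembly and catalogue tables, the overlap rule, report
#' rounding precisions, the cell-line grouping and the seed. A user config
#' (list or YAML file) is merged over these defaults; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param config Optional list or YAML file path overriding defaults.
#' @return The merged configuration list.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    assembly = fragsites_extdata("grch37.chrom.sizes"),
    sites_cytogenetic = fragsites_extdata("cfs_cytogenetic_table.tsv"),
    sites_molecular = fragsites_extdata("cfs_molecular_table.tsv"),
    feature_files = list(),     # list of list(path=, category=, label=)
    track_files = list(),       # list of list(path=, label=)
    grouping = as.list(default_cell_groups()),
    overlap_rule = "any",
    gaps_as_zero = FALSE,
    n_total = list(cancer_gene = 327, mirna = 1871),
    digits = list(fraction = 1, enrichment = 1, per_kb = 3),
    out_dir = ".",
    seed = 1,
    simulate = NULL             # SyntheticConfig block for run_simulate()
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(config)] <- config
  }
  defaults
}

config_hash <- function(config) {
  # stable short fingerprint of the analysis-relevant configuration;
  # the output directory does not affect results and is excluded
  config <- config[setdiff(names(config), "out_dir")]
  ser <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(ser) * (seq_along(utf8ToInt(ser)) %% 251 + 1)) %% .Machine$integer.max)
}

validate_paths <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(paths)
}

#' Run the catalogue + enrichment stage
#'
#' Parses the configured site tables, merges them per resolution class,
#' computes total extents and genome fractions, counts the catalogue-carried
#' feature lists, assigns any configured feature files to sites, and writes:
#' a per-site association TSV, an enrichment/summary TSV and JSON, and an
#' exceptions TSV (quarantined rows, unmatched symbols). Validation failures
#' abort before any output is written.
#'
#' @param config List or YAML path, see [run_config()].
#' @return Invisibly, a list with the summary tibble, per-site association
#'   table, exceptions, and output paths.
#' @export
run_enrichment <- function(config = NULL) {
  cfg <- run_config(config)
  validate_paths(c(cfg$assembly, cfg$sites_cytogenetic, cfg$sites_molecular,
                   vapply(cfg$feature_files, `[[`, "", "path")))
  assembly <- read_chrom_sizes(cfg$assembly)
  G <- genome_length(assembly)
  hdr <- output_header(seed = cfg$seed, config_hash = config_hash(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  catalogues <- list(
    cytogenetic = read_fragile_sites(cfg$sites_cytogenetic, "cytogenetic"),
    molecular = read_fragile_sites(cfg$sites_molecular, "molecular"))

  summary_rows <- list()
  assoc_rows <- list()
  exceptions <- list()
  for (res in names(catalogues)) {
    sites <- catalogues[[res]]
    merged <- merge_sites(sites)
    L <- total_length(merged)
    raw <- sum(sites$end - sites$start)
    lists <- site_feature_lists(sites)
    assoc_rows[[res]] <- dplyr::mutate(lists$records, resolution = res)
    ex <- site_exceptions(sites)
    if (nrow(ex) > 0) exceptions[[res]] <- dplyr::mutate(ex, resolution = res)
    for (cat in names(lists$n_distinct)) {
      n_in <- lists$n_distinct[[cat]]
      n_tot <- cfg$n_total[[cat]]
      enr <- if (!is.null(n_tot))
        density_enrichment(n_in, n_tot, L, G, category = cat) else NULL
      summary_rows[[paste(res, cat)]] <- tibble::tibble(
        resolution = res, category = cat, n_in = n_in,
        n_total = if (is.null(n_tot)) NA_integer_ else n_tot,
        union_length_bp = L, raw_sum_bp = raw,
        genome_fraction_pct = genome_fraction(L, G),
        pct_of_catalog = if (is.null(n_tot)) NA_real_ else
          fraction_of_total(n_in, n_tot, cfg$digits$fraction),
        relative_increase_pct = if (is.null(enr)) NA_real_ else
          round_half_up(enr$relative_increase_pct, cfg$digits$enrichment))
    }
  }

  # external feature files assigned against the molecular catalogue
  if (length(cfg$feature_files) > 0) {
    sites <- catalogues$molecular
    merged <- merge_sites(sites)
    for (ff in cfg$feature_files) {
      feats <- switch(ff$category,
        mirna = read_mirna_gff(ff$path),
        ctcf_site = read_peak_sets(ff$path, ff$label %||% basename(ff$path)),
        stop("unsupported feature category: ", ff$category, call. = FALSE))
      ov <- assign_features(feats, merged, sites, rule = cfg$overlap_rule,
                            assembly = assembly)
      assoc_rows[[paste0("file:", ff$path)]] <-
        dplyr::mutate(ov$per_site, resolution = "molecular")
      for (cat in names(ov$n_total)) {
        enr <- density_enrichment(ov$n_in[[cat]], ov$n_total[[cat]],
                                  total_length(merged), G, category = cat)
        summary_rows[[paste0("file:", ff$path, ":", cat)]] <- tibble::tibble(
          resolution = "molecular", category = paste0(cat, " (file)"),
          n_in = ov$n_in[[cat]], n_total = ov$n_total[[cat]],
          union_length_bp = total_length(merged),
          raw_sum_bp = sum(sites$end - sites$start),
          genome_fraction_pct = genome_fraction(total_length(merged), G),
          pct_of_catalog = fraction_of_total(ov$n_in[[cat]], ov$n_total[[cat]],
                                             cfg$digits$fraction),
          relative_increase_pct = round_half_up(enr$relative_increase_pct,
                                                cfg$digits$enrichment))
      }
    }
  }

  summary <- dplyr::bind_rows(summary_rows)
  assoc <- dplyr::bind_rows(assoc_rows)
  exceptions <- if (length(exceptions)) dplyr::bind_rows(exceptions) else
    tibble::tibble(site_id = character(0), problem = character(0),
                   resolution = character(0))

  paths <- c(summary_tsv = file.path(cfg$out_dir, "enrichment_summary.tsv"),
             summary_json = file.path(cfg$out_dir, "enrichment_summary.json"),
             association = file.path(cfg$out_dir, "site_associations.tsv"),
             exceptions = file.path(cfg$out_dir, "exceptions.tsv"))
  write_tsv_with_header(summary, paths["summary_tsv"], hdr)
  jsonlite::write_json(summary, paths["summary_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_tsv_with_header(assoc, paths["association"], hdr)
  write_tsv_with_header(exceptions, paths["exceptions"], hdr)
  invisible(list(summary = summary, association = assoc,
                 exceptions = exceptions, paths = paths))
}

#' Run the signal-summary stage
#'
#' Computes the per-site delta (site mean minus chromosome mean) for every
#' configured track over the molecular catalogue (or a sites table given in
#' the config), writes the sites-by-tracks delta TSV, and, when a grouping
#' is configured and feasible, the group-comparison JSON. A track missing a
#' site's chromosome yields an NA cell and a warning, not a failure.
#'
#' @param config List or YAML path, see [run_config()]; `track_files` must
#'   be non-empty.
#' @return Invisibly, a list with the delta tibble, the group comparison (or
#'   `NULL`), and output paths.
#' @export
run_signal <- function(config = NULL) {
  cfg <- run_config(config)
  if (length(cfg$track_files) == 0) {
    stop("no track_files configured", call. = FALSE)
  }
  validate_paths(c(cfg$sites_molecular,
                   vapply(cfg$track_files, `[[`, "", "path")))
  sites <- read_fragile_sites(cfg$sites_molecular, "molecular")
  hdr <- output_header(seed = cfg$seed, config_hash = config_hash(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  tracks <- lapply(cfg$track_files, function(tf) {
    read_signal(tf$path, label = tf$label %||% basename(tf$path))
  })
  deltas <- delta_matrix(tracks, sites, gaps_as_zero = cfg$gaps_as_zero)
  wide <- tidyr::pivot_wider(deltas[, c("site_id", "track_label", "delta")],
                             names_from = "track_label",
                             values_from = "delta")
  comparison <- NULL
  grouping <- unlist(cfg$grouping)
  cells <- sub("^[^:]*:", "", unique(deltas$track_label))
  feasible <- length(unique(stats::na.omit(grouping[cells]))) >= 2 &&
    all(table(grouping[cells][!is.na(grouping[cells])]) >= 2)
  if (feasible) comparison <- compare_groups(deltas, grouping)

  paths <- c(deltas = file.path(cfg$out_dir, "delta_matrix.tsv"))
  write_tsv_with_header(wide, paths["deltas"], hdr)
  if (!is.null(comparison)) {
    paths["comparison"] <- file.path(cfg$out_dir, "group_comparison.json")
    jsonlite::write_json(
      list(group_means = as.list(comparison$group_means),
           F = comparison$statistic, p = comparison$p.value,
           df = comparison$df,
           gap_convention = if (cfg$gaps_as_zero) "gaps_as_zero" else
             "gaps_excluded",
           quantile_rule = "linear"),
      paths["comparison"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(deltas = deltas, wide = wide, comparison = comparison,
                 paths = paths))
}

#' Run the synthetic-data stage
#'
#' Generates a fragile-region set, a planted feature catalogue and a shifted
#' signal track from the `simulate` config block, and writes the bundle
#' (site BED, feature BED, track bedGraph, truth JSON) into the output
#' directory. Identical config and seed give byte-identical bundles.
#'
#' @param config List or YAML path with a `simulate` block: `chrom_lengths`,
#'   `fragile_fraction`, `n_sites`, `lambda`, `rho`, `mu`, `delta`, `sigma`,
#'   `bin`.
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- run_config(config)
  sc <- cfg$simulate
  if (is.null(sc)) stop("no simulate block configured", call. = FALSE)
  sc_defaults <- list(chrom_lengths = c(10e6, 10e6, 10e6),
                      fragile_fraction = 0.27, n_sites = 9,
                      lambda = 60, rho = 1.372,
                      mu = 1, delta = 2, sigma = 0.5, bin = 1000)
  sc_defaults[names(sc)] <- sc
  sc <- sc_defaults
  seed <- cfg$seed
  regions <- simulate_regions(unlist(sc$chrom_lengths), sc$fragile_fraction,
                              sc$n_sites, seed = seed)
  merged <- merge_sites(regions$sites)
  planted <- plant_features(regions$assembly, merged, sc$lambda, sc$rho,
                            seed = seed + 1)
  tracked <- simulate_track(regions$assembly, regions$sites, sc$mu, sc$delta,
                            sc$sigma, sc$bin, seed = seed + 2)
  files <- write_synthetic_bundle(regions, planted, tracked,
                                  dir = cfg$out_dir, seed = seed)
  invisible(list(regions = regions, planted = planted, tracked = tracked,
                 paths = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
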