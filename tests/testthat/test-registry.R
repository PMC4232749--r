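cyto <- read_fragile_sites(fragsites_extdata("cfs_cytogenetic_table.tsv"),
                           "cytogenetic")
mol <- read_fragile_sites(fragsites_extdata("cfs_molecular_table.tsv"),
                          "molecular")

test_that("printed catalogue rows normalize to 0-based half-open coordinates", {
  f16d <- mol[mol$site_id == "FRA16D", ]
  expect_equal(f16d$chrom, "chr16")
  expect_equal(f16d$start, 78420359 - 1)
  expect_equal(f16d$end, 78731553)
  expect_equal(f16d$inducer, "aphidicolin")
  expect_equal(f16d$freq_class, "common")

  f17b <- cyto[cyto$site_id == "FRA17B", ]
  expect_equal(f17b$chrom, "chr17")
  expect_equal(f17b$start, 57600001 - 1)
  expect_equal(f17b$end, 58300000)
  expect_equal(f17b$band, "17q23.1")
})

test_that("empty tables, telomeric starts and quarantined rows are handled", {
  empty <- read_fragile_sites(
    data.frame(fra = character(0), chrom = character(0), start = character(0),
               end = character(0), inducer = character(0),
               frequency = character(0)), "molecular")
  expect_equal(nrow(empty), 0)

  # Telomere anchor becomes position 0
  f7b <- mol[mol$site_id == "FRA7B", ]
  expect_equal(f7b$start, 0)
  expect_equal(f7b$end, 12392296)

  # ambiguously printed FRA19B is quarantined, not guessed
  expect_false("FRA19B" %in% cyto$site_id)
  expect_true("FRA19B" %in% site_exceptions(cyto)$site_id)
  expect_true("FRA19B" %in% attr(cyto, "quarantined")$fra)

  expect_error(read_fragile_sites(
    data.frame(fra = "X", chrom = "chr1", start = "100", end = "50",
               inducer = "Aphidicolin", frequency = "Common"), "molecular"),
    "end <= start")
  expect_error(read_fragile_sites(
    data.frame(fra = "X", chrom = "chr1", start = "1", end = "50",
               inducer = "mystery drug", frequency = "Common"), "molecular"),
    "inducer")
})

test_that("duplicate-coordinate site codes merge to one interval with both ids", {
  pair <- cyto[cyto$site_id %in% c("FRA16B", "FRA16C"), ]
  expect_equal(nrow(pair), 2)
  expect_equal(unique(pair$start), 66700000)
  merged <- merge_sites(pair)
  expect_equal(nrow(merged), 1)
  expect_setequal(merged$site_ids[[1]], c("FRA16B", "FRA16C"))
})

test_that("disjoint sites pass through merging unchanged and mixing resolutions fails", {
  s <- toy_sites(data.frame(fra = c("A", "B"), chrom = "chrA",
                            start = c(1, 501), end = c(100, 600)))
  m <- merge_sites(s)
  expect_equal(nrow(m), 2)
  expect_equal(total_length(m), 100 + 100)
  mixed <- s
  mixed$resolution <- c("molecular", "cytogenetic")
  expect_error(merge_sites(mixed), "mixed resolution")
})

test_that("merging is idempotent and matches the per-base oracle", {
  asm <- toy_assembly(c(chrA = 10000))
  withr::local_seed(42)
  for (i in 1:25) {
    sites <- random_toy_sites(50, asm)
    merged <- merge_sites(sites)
    expect_equal(total_length(merged), oracle_union_length(sites, asm))
    # idempotence: merging the merged set changes nothing
    again <- merge_sites(tibble::tibble(site_id = paste0("M", seq_len(nrow(merged))),
                                        chrom = merged$chrom,
                                        start = merged$start, end = merged$end,
                                        resolution = "molecular"))
    expect_equal(again$start, merged$start)
    expect_equal(again$end, merged$end)
  }
})

test_that("union length is subadditive with equality iff disjoint", {
  a <- toy_sites(data.frame(fra = "A", chrom = "chrA", start = 1, end = 100))
  b_overlap <- toy_sites(data.frame(fra = "B", chrom = "chrA", start = 51,
                                    end = 150))
  b_disjoint <- toy_sites(data.frame(fra = "B", chrom = "chrA", start = 201,
                                     end = 300))
  u_overlap <- total_length(merge_sites(dplyr::bind_rows(a, b_overlap)))
  u_disjoint <- total_length(merge_sites(dplyr::bind_rows(a, b_disjoint)))
  expect_lt(u_overlap,
            total_length(merge_sites(a)) + total_length(merge_sites(b_overlap)))
  expect_equal(u_disjoint,
               total_length(merge_sites(a)) + total_length(merge_sites(b_disjoint)))
})

test_that("genome fractions reproduce the printed haploid-genome percentages", {
  G <- genome_length(read_chrom_sizes(fragsites_extdata("grch37.chrom.sizes")))
  # printed total extents of the two catalogues as inputs
  expect_equal(genome_fraction(835.22e6, G, digits = 0), 27)
  expect_equal(genome_fraction(79.3e6, G, digits = 1), 2.6)
  expect_equal(genome_fraction(0, G), 0)
  expect_error(genome_fraction(10, 0), "positive")
  expect_error(genome_fraction(-1, 10))
})

test_that("the molecular union also recomputes to 2.6 % of the genome", {
  G <- genome_length(read_chrom_sizes(fragsites_extdata("grch37.chrom.sizes")))
  L <- total_length(merge_sites(mol))
  expect_equal(genome_fraction(L, G, digits = 1), 2.6)
})

test_that("catalogue feature lists deduplicate to the published totals", {
  lc <- site_feature_lists(cyto)
  expect_equal(unname(lc$n_distinct["cancer_gene"]), 110L)
  expect_equal(unname(lc$n_distinct["mirna"]), 686L)
  lm <- site_feature_lists(mol)
  expect_equal(unname(lm$n_distinct["cancer_gene"]), 9L)
  expect_equal(unname(lm$n_distinct["mirna"]), 44L)
})

test_that("BED export is 0-based half-open with merged names joined", {
  s <- toy_sites(data.frame(fra = c("A", "B"), chrom = "chrA",
                            start = c(11, 51), end = c(100, 160)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(s, path)
  bed <- read.table(path)
  expect_equal(bed$V2, c(10, 50))
  expect_equal(bed$V3, c(100, 160))
  write_sites_bed(merge_sites(s), path)
  merged_bed <- read.table(path)
  expect_equal(merged_bed$V4, "A,B")
})
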