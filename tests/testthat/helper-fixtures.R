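# toy builders and per-base brute-force oracles shared across the suite

toy_assembly <- function(lengths = c(chrA = 1000, chrB = 500)) {
  read_chrom_sizes(data.frame(chrom = names(lengths),
                              length = as.numeric(lengths)))
}

# a sites tibble straight from printed-style 1-based coordinates
toy_sites <- function(df, resolution = "molecular") {
  df$inducer <- df$inducer %||% "Aphidicolin"
  read_fragile_sites(
    data.frame(fra = df$fra, chrom = df$chrom,
               start = as.character(df$start), end = as.character(df$end),
               inducer = if (is.null(df$inducer)) "Aphidicolin" else df$inducer,
               frequency = "Common"),
    resolution = resolution)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-base boolean-array union oracle on a toy genome
oracle_union_length <- function(sites, assembly) {
  total <- 0
  for (i in seq_len(nrow(assembly))) {
    chr <- assembly$chrom[i]
    mask <- logical(assembly$length[i])
    rows <- sites[sites$chrom == chr, ]
    for (j in seq_len(nrow(rows))) {
      mask[(rows$start[j] + 1):rows$end[j]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# per-base membership oracle: does feature k overlap >=1 covered base
oracle_feature_inside <- function(features, sites, assembly) {
  masks <- lapply(seq_len(nrow(assembly)), function(i) {
    mask <- logical(assembly$length[i])
    rows <- sites[sites$chrom == assembly$chrom[i], ]
    for (j in seq_len(nrow(rows))) {
      mask[(rows$start[j] + 1):rows$end[j]] <- TRUE
    }
    mask
  })
  names(masks) <- assembly$chrom
  vapply(seq_len(nrow(features)), function(k) {
    m <- masks[[features$chrom[k]]]
    any(m[(features$start[k] + 1):features$end[k]])
  }, logical(1))
}

random_toy_sites <- function(n, assembly) {
  chrom <- sample(assembly$chrom, n, replace = TRUE)
  len <- assembly$length[match(chrom, assembly$chrom)]
  start <- floor(runif(n) * (len - 1))
  width <- 1 + floor(runif(n) * pmin(len - start - 1, 200))
  tibble::tibble(site_id = paste0("S", seq_len(n)), chrom = chrom,
                 start = start, end = start + width,
                 resolution = "molecular")
}

mirbase_gff_lines <- function() {
  c("##gff-version 3",
    "chrA\t.\tmiRNA_primary_transcript\t101\t180\t.\t+\t.\tID=MI001;Name=hsa-mir-101-1",
    "chrA\t.\tmiRNA\t110\t131\t.\t+\t.\tID=MIMAT001;Name=hsa-miR-101-5p;Derives_from=MI001",
    "chrA\t.\tmiRNA\t150\t171\t.\t+\t.\tID=MIMAT002;Name=hsa-miR-101-3p;Derives_from=MI001",
    "chrB\t.\tmiRNA_primary_transcript\t51\t120\t.\t-\t.\tID=MI002;Name=hsa-mir-101-2",
    "chrB\t.\tmiRNA\t60\t81\t.\t-\t.\tID=MIMAT003;Name=hsa-miR-101-2-5p;Derives_from=MI002")
}
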