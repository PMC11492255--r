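#' Simulation configuration
#'
#' Defines a diploid assembly with one ZW-mixed chromosome and a set of
#' autosomes, mimicking the structure the coverage scan assumes: PAR1,
#' then a female-specific stratum carrying interleaved W fragments with
#' hemizygous-Z segments between them, then a fully differentiated
#' Z-specific stratum, then PAR2. One autosome carries a ten-gene Hox
#' cluster with configurable inter-gene gaps and strands, plus decoy
#' (non-Hox) homeobox genes elsewhere.
#'
#' Default region boundaries place PAR1 up to 48.3 Mb, the W-bearing
#' female-specific stratum from 48.3 to 62.5 Mb, the Z-specific stratum
#' from 62.5 to 70 Mb, and PAR2 from 70 Mb to the chromosome end. Five W
#' fragments of 2 Mb are planted starting at the stratum boundary,
#' separated by 1 Mb hemizygous-Z segments. Hox inter-gene gaps default to
#' 11.7 Mb between pb and Hox3, 500 kb between abd-A and Abd-B, and 100 kb
#' elsewhere, with ftz on the minus strand and the rest on plus.
#'
#' @param base_depth Mean autosomal per-base depth per sex (diploid copy
#'   number), default 30.
#' @param bin_size Coverage window in bp, default 100000.
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output.
#' @param chr1_length Length of the ZW-mixed chromosome in bp (multiple of
#'   `bin_size`).
#' @param par1_end,fsr_end,zspec_end Region boundaries in bp (multiples of
#'   `bin_size`): PAR1 is `[0, par1_end)`, the W-bearing stratum
#'   `[par1_end, fsr_end)`, the Z-specific stratum `[fsr_end, zspec_end)`,
#'   PAR2 `[zspec_end, chr1_length)`.
#' @param n_w_fragments Number of planted W fragments (0 degenerates the
#'   stratum to hemizygous Z).
#' @param w_fragment_length Length of each W fragment in bp.
#' @param autosome_lengths Numeric vector of autosome lengths in bp
#'   (multiples of `bin_size`); each autosome must exceed 10 Mb so the
#'   chromosome-scaffold filter keeps it.
#' @param hox_autosome Index (into the autosomes) of the chromosome
#'   carrying the Hox cluster.
#' @param hox_start Cluster start on that autosome, bp.
#' @param hox_gene_length Length of each Hox gene, bp.
#' @param hox_gaps Numeric vector of 9 intergenic gaps in bp, anterior to
#'   posterior.
#' @param hox_strands Character vector of 10 strands for the Hox genes.
#' @param n_decoy_homeobox Number of decoy homeobox genes (products mention
#'   "homeobox" but carry no canonical Hox class label).
#' @param expr_baseline Mean expression count of an unbiased gene.
#' @param n_z_candidates Number of Z-specific genes planted with male-biased
#'   expression.
#' @param candidate_fold Male fold factor of the planted Z-specific
#'   candidates.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(base_depth = 30, bin_size = 1e5, seed = 1L,
                       chr1_length = 75e6, par1_end = 48.3e6,
                       fsr_end = 62.5e6, zspec_end = 70e6,
                       n_w_fragments = 5L, w_fragment_length = 2e6,
                       autosome_lengths = c(20e6, 15e6, 12e6),
                       hox_autosome = 1L, hox_start = 2e6,
                       hox_gene_length = 2e4,
                       hox_gaps = c(1e5, 11.7e6, 1e5, 1e5, 1e5, 1e5, 1e5,
                                    1e5, 5e5),
                       hox_strands = c("+", "+", "+", "+", "+", "-", "+",
                                       "+", "+", "+"),
                       n_decoy_homeobox = 20L,
                       expr_baseline = 100, n_z_candidates = 7L,
                       candidate_fold = 4) {
  cfg <- list(base_depth = base_depth, bin_size = bin_size,
              seed = as.integer(seed), chr1_length = chr1_length,
              par1_end = par1_end, fsr_end = fsr_end, zspec_end = zspec_end,
              n_w_fragments = as.integer(n_w_fragments),
              w_fragment_length = w_fragment_length,
              autosome_lengths = autosome_lengths,
              hox_autosome = as.integer(hox_autosome),
              hox_start = hox_start, hox_gene_length = hox_gene_length,
              hox_gaps = hox_gaps, hox_strands = hox_strands,
              n_decoy_homeobox = as.integer(n_decoy_homeobox),
              expr_baseline = expr_baseline,
              n_z_candidates = as.integer(n_z_candidates),
              candidate_fold = candidate_fold)
  stopifnot(cfg$base_depth > 0, cfg$bin_size > 0,
            cfg$chr1_length %% cfg$bin_size == 0,
            all(cfg$autosome_lengths %% cfg$bin_size == 0),
            0 < cfg$par1_end, cfg$par1_end < cfg$fsr_end,
            cfg$fsr_end < cfg$zspec_end, cfg$zspec_end < cfg$chr1_length,
            length(cfg$hox_gaps) == 9L, length(cfg$hox_strands) == 10L,
            cfg$candidate_fold >= 0)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# copy factors (female, male) per planted region label
COPY_MODEL <- list(
  AUTOSOME = c(female = 1, male = 1),
  PAR = c(female = 1, male = 1),
  FSR_W = c(female = 0.5, male = 0),
  FSR_Z = c(female = 0.5, male = 1),
  Z_SPECIFIC = c(female = 0.5, male = 1)
)

#' Per-region copy factors of the simulator
#'
#' Copy factors express the number of template copies per haploid-depth
#' unit in each sex: autosomes and PARs are diploid in both sexes (1, 1);
#' Z-specific and hemizygous-Z sequence has one copy in ZW females against
#' two in ZZ males (0.5, 1); W fragments have one copy in females and none
#' in males (0.5, 0).
#'
#' @return Named list mapping region labels (AUTOSOME, PAR, FSR_W, FSR_Z,
#'   Z_SPECIFIC) to `c(female, male)` copy factors.
#' @export
copy_model <- function() COPY_MODEL

#' Build the planted genome layout
#'
#' Produces the region truth table, an AGP describing the contig
#' composition of every chromosome (each W fragment and each
#' inter-fragment hemizygous-Z segment is its own component, mirroring the
#' contig granularity a scaffolder would leave), and a gene annotation
#' placing genes in every region class: PAR1/PAR2 genes, genes on each W
#' fragment (female-expressed only), hemizygous-Z genes, Z-specific genes
#' (the first `n_z_candidates` planted with male-biased expression),
#' autosomal genes, the ten-gene Hox cluster, and decoy homeobox genes.
#'
#' @param cfg A [sim_config()] list.
#' @return List of class `zw_layout` with elements `regions` (chrom, start,
#'   end, label, component_id; 0-based half-open), `agp`, `genes` (gene
#'   table with planted expression fold columns `fold_female`,
#'   `fold_male`), `chrom_lengths`.
#' @export
build_layout <- function(cfg = sim_config()) {
  bs <- cfg$bin_size
  # --- regions on the ZW-mixed chromosome -------------------------------
  fsr_len <- cfg$fsr_end - cfg$par1_end
  nw <- cfg$n_w_fragments
  if (nw > 0L) {
    if (nw * cfg$w_fragment_length > fsr_len) {
      stop("W fragments do not fit inside the female-specific stratum")
    }
    gap <- if (nw > 1L) {
      floor((fsr_len - nw * cfg$w_fragment_length) / (nw - 1L) / bs) * bs
    } else {
      0
    }
    w_starts <- cfg$par1_end + (seq_len(nw) - 1L) * (cfg$w_fragment_length + gap)
    w_ends <- w_starts + cfg$w_fragment_length
    if (any(w_ends > cfg$fsr_end)) {
      stop("W fragments overlap or extend past the female-specific stratum")
    }
  } else {
    w_starts <- numeric(0)
    w_ends <- numeric(0)
  }
  # interleave FSR_W / FSR_Z segments across the stratum
  bounds <- sort(unique(c(cfg$par1_end, w_starts, w_ends, cfg$fsr_end)))
  seg_start <- head(bounds, -1L)
  seg_end <- tail(bounds, -1L)
  in_w <- vapply(seg_start, function(s) any(w_starts <= s & s < w_ends), NA)
  fsr <- data.frame(start = seg_start, end = seg_end,
                    label = ifelse(in_w, "FSR_W", "FSR_Z"))
  fsr <- fsr[fsr$end > fsr$start, , drop = FALSE]
  chr1 <- rbind(
    data.frame(start = 0, end = cfg$par1_end, label = "PAR"),
    fsr,
    data.frame(start = cfg$fsr_end, end = cfg$zspec_end, label = "Z_SPECIFIC"),
    data.frame(start = cfg$zspec_end, end = cfg$chr1_length, label = "PAR")
  )
  chr1$chrom <- "chr1"
  autos <- data.frame(
    chrom = paste0("chr", seq_along(cfg$autosome_lengths) + 1L),
    start = 0, end = cfg$autosome_lengths, label = "AUTOSOME",
    stringsAsFactors = FALSE
  )
  regions <- rbind(chr1[, c("chrom", "start", "end", "label")],
                   autos[, c("chrom", "start", "end", "label")])
  w_i <- 0L; z_i <- 0L
  regions$component_id <- NA_character_
  for (i in seq_len(nrow(regions))) {
    regions$component_id[i] <- switch(
      regions$label[i],
      FSR_W = { w_i <- w_i + 1L; sprintf("tig_w_%02d", w_i) },
      { z_i <- z_i + 1L; sprintf("tig_z_%02d", z_i) }
    )
  }
  # --- AGP: one sequence component per region row, gapless tiling -------
  agp <- do.call(rbind, lapply(unique(regions$chrom), function(chr) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    data.frame(
      object = chr,
      object_beg = as.integer(r$start + 1),
      object_end = as.integer(r$end),
      part_number = seq_len(nrow(r)),
      component_type = "W",
      component_id = r$component_id,
      component_beg = 1L,
      component_end = as.integer(r$end - r$start),
      orientation = "+",
      gap_length = NA_integer_, gap_type = NA_character_,
      linkage = NA_character_, linkage_evidence = NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(agp) <- NULL
  class(agp) <- c("agp", "data.frame")
  validate_agp(agp)
  # --- genes ------------------------------------------------------------
  genes <- sim_genes(cfg, regions)
  layout <- list(regions = regions, agp = agp, genes = genes,
                 chrom_lengths = setNames(
                   c(cfg$chr1_length, cfg$autosome_lengths),
                   c("chr1", autos$chrom)),
                 cfg = cfg)
  class(layout) <- c("zw_layout", "list")
  layout
}

# place n genes evenly inside [start, end) on chrom; length len bp each
place_genes <- function(chrom, start, end, n, len = 5e3, prefix, product,
                        strand = "+", fold_female = 1, fold_male = 1) {
  if (n == 0L) return(NULL)
  span <- (end - start) / n
  gs <- floor(start + (seq_len(n) - 0.5) * span - len / 2)
  data.frame(
    gene_id = sprintf("%s_%03d", prefix, seq_len(n)),
    chrom = chrom, start = as.integer(gs), end = as.integer(gs + len),
    strand = strand, product = product,
    fold_female = fold_female, fold_male = fold_male,
    stringsAsFactors = FALSE
  )
}

sim_genes <- function(cfg, regions) {
  out <- list()
  par1 <- place_genes("chr1", 0, cfg$par1_end, 10L, prefix = "g_par1",
                      product = "pseudoautosomal protein")
  par2 <- place_genes("chr1", cfg$zspec_end, cfg$chr1_length, 5L,
                      prefix = "g_par2", product = "pseudoautosomal protein")
  wfrag <- regions[regions$label == "FSR_W", , drop = FALSE]
  wg <- lapply(seq_len(nrow(wfrag)), function(i) {
    g <- place_genes("chr1", wfrag$start[i], wfrag$end[i], 3L,
                     prefix = sprintf("g_w%d", i),
                     product = rep_len(c("60 kDa chaperonin, mitochondrial",
                                         "gag-pol polyprotein",
                                         "reverse transcriptase-like protein"),
                                       3L),
                     fold_male = 0)
    g
  })
  zfrag <- regions[regions$label == "FSR_Z", , drop = FALSE]
  zg <- lapply(seq_len(nrow(zfrag)), function(i) {
    place_genes("chr1", zfrag$start[i], zfrag$end[i], 1L,
                prefix = sprintf("g_hz%d", i),
                product = "hemizygous Z protein")
  })
  nz <- 15L
  zs <- place_genes("chr1", cfg$fsr_end, cfg$zspec_end, nz,
                    prefix = "g_zspec", product = "Z-specific protein")
  ncand <- min(cfg$n_z_candidates, nz)
  zs$fold_male[seq_len(ncand)] <- cfg$candidate_fold
  zs$product[seq_len(ncand)] <- "male-biased Z-specific protein"
  auto_chroms <- paste0("chr", seq_along(cfg$autosome_lengths) + 1L)
  ag <- lapply(seq_along(auto_chroms), function(i) {
    place_genes(auto_chroms[i], 0, cfg$autosome_lengths[i], 10L,
                prefix = sprintf("g_a%d", i), product = "autosomal protein")
  })
  # Hox cluster on the designated autosome
  hox_chrom <- auto_chroms[cfg$hox_autosome]
  starts <- cfg$hox_start +
    cumsum(c(0, cfg$hox_gaps + cfg$hox_gene_length))
  hox <- data.frame(
    gene_id = paste0("hox_", gsub("-", "", HOX_CLASSES)),
    chrom = hox_chrom,
    start = as.integer(starts),
    end = as.integer(starts + cfg$hox_gene_length),
    strand = cfg$hox_strands,
    product = paste("Hox cluster protein", HOX_CLASSES),
    fold_female = 1, fold_male = 1,
    stringsAsFactors = FALSE
  )
  if (max(hox$end) > cfg$autosome_lengths[cfg$hox_autosome]) {
    stop("Hox cluster does not fit on its autosome")
  }
  # decoy homeobox genes scattered over the remaining autosomes
  decoy <- if (cfg$n_decoy_homeobox > 0L) {
    dc_chrom <- auto_chroms[if (length(auto_chroms) > 1L)
      ((seq_len(cfg$n_decoy_homeobox) - 1L) %% (length(auto_chroms) - 1L)) + 2L
      else rep(1L, cfg$n_decoy_homeobox)]
    do.call(rbind, lapply(seq_len(cfg$n_decoy_homeobox), function(i) {
      chrom <- dc_chrom[i]
      len <- cfg$autosome_lengths[match(chrom, auto_chroms)]
      s <- floor(len * 0.05 + (i - 1) * floor(len * 0.9 /
                                                cfg$n_decoy_homeobox))
      data.frame(gene_id = sprintf("g_hb_%03d", i), chrom = chrom,
                 start = as.integer(s), end = as.integer(s + 5e3),
                 strand = "+",
                 product = sprintf("homeobox protein HB-%d", i),
                 fold_female = 1, fold_male = 1, stringsAsFactors = FALSE)
    }))
  } else NULL
  genes <- do.call(rbind, c(list(par1), wg, zg, list(zs), list(par2), ag,
                            list(hox), list(decoy)))
  rownames(genes) <- NULL
  genes
}

#' Simulate sexed binned depth
#'
#' For each bin and sex, the covered-base total is drawn
#' Poisson(`base_depth` x copy factor x bin width) and stored as a mean
#' per-base depth (draw / bin width). Copy factors come from
#' [copy_model()]; a bin straddling a region boundary uses the
#' length-weighted sum of the factors of the segments it overlaps. The RNG
#' is seeded from the config, so the same layout and seed give identical
#' output.
#'
#' @param layout A [build_layout()] result.
#' @param cfg The [sim_config()] used to build the layout (defaults to the
#'   one stored in the layout).
#' @return Paired bin table: `chrom`, `start`, `end` (0-based half-open),
#'   `female`, `male`.
#' @export
simulate_depth <- function(layout, cfg = layout$cfg) {
  set.seed(cfg$seed)
  cm <- copy_model()
  bins <- do.call(rbind, lapply(names(layout$chrom_lengths), function(chr) {
    len <- layout$chrom_lengths[[chr]]
    starts <- seq(0, len - 1, by = cfg$bin_size)
    ends <- pmin(starts + cfg$bin_size, len)
    reg <- layout$regions[layout$regions$chrom == chr, , drop = FALSE]
    lambda <- function(sex) {
      vapply(seq_along(starts), function(i) {
        ov <- pmin(ends[i], reg$end) - pmax(starts[i], reg$start)
        ov[ov < 0] <- 0
        sum(ov * vapply(reg$label, function(l) cm[[l]][[sex]], 0)) *
          cfg$base_depth
      }, 0)
    }
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(ends),
               lf = lambda("female"), lm = lambda("male"),
               stringsAsFactors = FALSE)
  }))
  width <- bins$end - bins$start
  bins$female <- rpois(nrow(bins), bins$lf) / width
  bins$male <- rpois(nrow(bins), bins$lm) / width
  bins$lf <- NULL
  bins$lm <- NULL
  rownames(bins) <- NULL
  bins
}

#' Simulate per-gene sexed expression counts
#'
#' Counts are drawn Poisson with mean `expr_baseline x fold` per sex, from
#' the planted `fold_female` / `fold_male` columns of the layout's gene
#' table. Genes on W fragments carry `fold_male = 0`, so their male count
#' is exactly zero.
#'
#' @param genes Gene table with `fold_female` and `fold_male` columns.
#' @param cfg A [sim_config()] list.
#' @return data.frame with `gene_id`, `length` (bp), `female_count`,
#'   `male_count`.
#' @export
simulate_expression <- function(genes, cfg = sim_config()) {
  if (any(genes$fold_female < 0) || any(genes$fold_male < 0)) {
    stop("expression fold factors must be non-negative")
  }
  set.seed(cfg$seed + 1L)
  data.frame(
    gene_id = genes$gene_id,
    length = genes$end - genes$start,
    female_count = rpois(nrow(genes), cfg$expr_baseline * genes$fold_female),
    male_count = rpois(nrow(genes), cfg$expr_baseline * genes$fold_male),
    stringsAsFactors = FALSE
  )
}

#' Run the whole simulator
#'
#' @param cfg A [sim_config()] list.
#' @return List of class `zw_sim` with `layout`, `bins` (sexed binned
#'   depth), `expression`, and `truth` (the planted region table).
#' @export
simulate_zw <- function(cfg = sim_config()) {
  layout <- build_layout(cfg)
  bins <- simulate_depth(layout, cfg)
  expr <- simulate_expression(layout$genes, cfg)
  sim <- list(layout = layout, bins = bins, expression = expr,
              truth = layout$regions, cfg = cfg)
  class(sim) <- c("zw_sim", "list")
  sim
}

#' Write simulator outputs to a directory
#'
#' Writes `female.depth.bed` and `male.depth.bed` (binned BED4),
#' `assembly.agp`, `genes.gff3`, `expression.tsv`, `hox_classes.tsv`
#' (gene_id to Hox class for the planted cluster) and `truth.tsv` (planted
#' region boundaries, labels and component ids).
#'
#' @param sim A [simulate_zw()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$bins
  write_bed(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                       depth = b$female),
            file.path(dir, "female.depth.bed"), name_col = "depth")
  write_bed(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                       depth = b$male),
            file.path(dir, "male.depth.bed"), name_col = "depth")
  write_agp(sim$layout$agp, file.path(dir, "assembly.agp"))
  write_gene_gff3(sim$layout$genes, file.path(dir, "genes.gff3"))
  write.table(sim$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hox <- sim$layout$genes[grepl("^hox_", sim$layout$genes$gene_id), ]
  write.table(data.frame(gene_id = hox$gene_id, hox_class = HOX_CLASSES),
              file.path(dir, "hox_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
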