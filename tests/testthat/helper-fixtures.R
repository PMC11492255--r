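# shared fixtures, all built in code

# a normalized-bin table built directly from f_norm/m_norm values
toy_bins <- function(f_norm, m_norm, chrom = "chr1", bin = 1e5,
                     pseudocount = 0.05) {
  n <- length(f_norm)
  data.frame(
    chrom = chrom,
    start = as.integer((seq_len(n) - 1L) * bin),
    end = as.integer(seq_len(n) * bin),
    female = f_norm, male = m_norm,
    f_norm = f_norm, m_norm = m_norm,
    r = log2_ratio(m_norm, f_norm, pseudocount),
    stringsAsFactors = FALSE
  )
}

# minimal AGP: contig A (Z), 100 bp gap, contig B (W), 100 bp gap,
# contig C (Z); written as a data.frame matching read_agp()'s layout
toy_agp <- function() {
  agp <- data.frame(
    object = "chr1",
    object_beg = c(1L, 1001L, 1101L, 2101L, 2201L),
    object_end = c(1000L, 1100L, 2100L, 2200L, 3200L),
    part_number = 1:5,
    component_type = c("W", "N", "W", "N", "W"),
    component_id = c("tigA", NA, "tigB", NA, "tigC"),
    component_beg = c(1L, NA, 1L, NA, 1L),
    component_end = c(1000L, NA, 1000L, NA, 1000L),
    orientation = c("+", NA, "+", NA, "+"),
    gap_length = c(NA, 100L, NA, 100L, NA),
    gap_type = c(NA, "scaffold", NA, "scaffold", NA),
    linkage = c(NA, "yes", NA, "yes", NA),
    linkage_evidence = c(NA, "paired-ends", NA, "paired-ends", NA),
    stringsAsFactors = FALSE
  )
  class(agp) <- c("agp", "data.frame")
  agp
}

# small, fast simulation shared across tests (default study conditions,
# fixed seed)
sim_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_zw(sim_config(seed = 20240928 %% 1e6))
    cache
  }
})

sim_autosomes <- function(cfg = sim_config()) {
  paste0("chr", seq_along(cfg$autosome_lengths) + 1L)
}

# synthetic reconstruction of the cross-species Hox organizations described
# for arthropods: outgroup (fly + copepod) all genes on the majority strand;
# branchiopods carry Dfd on the opposite strand; within branchiopods the
# phyllopods additionally carry ftz on the opposite strand while anostracans
# keep ftz opposite-of-majority like the outgroup does.
synthetic_arthropod_orgs <- function() {
  build <- function(species, opposite) {
    n <- length(hox_classes())
    tab <- data.frame(
      hox_class = hox_classes(),
      chrom = "chrH",
      start = as.integer(seq(0, by = 2e5, length.out = n)),
      end = as.integer(seq(0, by = 2e5, length.out = n) + 1e5),
      strand = ifelse(hox_classes() %in% opposite, "-", "+"),
      stringsAsFactors = FALSE
    )
    hox_organization(tab, species = species)
  }
  list(
    # outgroup: ftz inverted relative to the cluster majority
    drosophila = build("drosophila", "ftz"),
    copepod = build("copepod", "ftz"),
    # anostracans (Sarsostraca): Dfd also inverted
    artemia_franciscana = build("artemia_franciscana", c("ftz", "Dfd")),
    artemia_sinica = build("artemia_sinica", c("ftz", "Dfd")),
    branchinecta_1 = build("branchinecta_1", c("ftz", "Dfd")),
    branchinecta_2 = build("branchinecta_2", c("ftz", "Dfd")),
    # phyllopods: Dfd inverted, ftz back on the majority strand
    daphnia = build("daphnia", "Dfd"),
    triops = build("triops", "Dfd")
  )
}
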