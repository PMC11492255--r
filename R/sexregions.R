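#' Classification thresholds for the ZW coverage scan
#'
#' The core sex-linkage rule is `|log2(M:F)| > t_sex` with `t_sex = 1`,
#' i.e. a two-fold depth contrast between the sexes. The finer bands
#' operationalize the qualitative region descriptions: a bin is PAR-like
#' when its ratio is within `par_band` of 0, Z-specific-like when the ratio
#' sits in `z_band` (one female copy vs two male copies gives r near 1),
#' and W-like (female-specific) when male depth is essentially absent while
#' female depth is clearly present.
#'
#' @param t_sex Sex-linkage threshold on `|r|` used by
#'   [identify_sex_chromosome()].
#' @param par_band Half-width of the PAR band around r = 0.
#' @param z_band Length-2 numeric, the closed r interval called Z-specific.
#' @param male_absent Normalized male depth below which the male is treated
#'   as having no coverage.
#' @param min_female Minimum normalized female depth for a FEMALE_SPECIFIC
#'   call (half-copy W coverage is ~0.5; this guards against calling noise).
#' @param low_cov Both-sex normalized depth below which a bin is
#'   LOW_COVERAGE.
#' @param smooth_window Odd majority-vote window (bins) for
#'   [smooth_classes()].
#' @param min_run Minimum run length (bins) kept by [segment_regions()].
#' @param w_contig_fraction Minimum class fraction for a contig verdict in
#'   [call_contigs()].
#' @param sex_chrom_fraction Minimum sex-linked bin fraction that flags a
#'   chromosome in [identify_sex_chromosome()].
#' @param pseudocount Pseudocount for the log2 ratio.
#' @return Named list of class `zw_thresholds`.
#' @export
zw_thresholds <- function(t_sex = 1, par_band = 0.35, z_band = c(0.7, 1.5),
                          male_absent = 0.1, min_female = 0.25,
                          low_cov = 0.1, smooth_window = 5L, min_run = 3L,
                          w_contig_fraction = 0.8,
                          sex_chrom_fraction = 0.05, pseudocount = 0.05) {
  th <- list(t_sex = t_sex, par_band = par_band, z_band = z_band,
             male_absent = male_absent, min_female = min_female,
             low_cov = low_cov, smooth_window = as.integer(smooth_window),
             min_run = as.integer(min_run),
             w_contig_fraction = w_contig_fraction,
             sex_chrom_fraction = sex_chrom_fraction,
             pseudocount = pseudocount)
  stopifnot(th$par_band > 0, th$par_band < th$z_band[1L],
            th$z_band[1L] <= 1, 1 <= th$z_band[2L],
            th$smooth_window %% 2L == 1L, th$min_run >= 1L,
            th$w_contig_fraction > 0.5, th$pseudocount > 0)
  class(th) <- c("zw_thresholds", "list")
  th
}

#' Classify normalized bins into coverage classes
#'
#' Rules are applied in a fixed order so that every bin receives exactly
#' one class: LOW_COVERAGE (both normalized depths < `low_cov`), then
#' FEMALE_SPECIFIC (male depth absent, female depth present — the W
#' signature), then Z_SPECIFIC (r in `z_band`; females carry one Z copy
#' against two in males), then PAR (|r| < `par_band`), else UNDETERMINED.
#'
#' @param bins Normalized bin table from [normalize_bins()].
#' @param thresholds A [zw_thresholds()] list.
#' @return `bins` with an added character column `class`.
#' @export
classify_bins <- function(bins, thresholds = zw_thresholds()) {
  th <- thresholds
  stopifnot(all(is.finite(bins$r)))
  cls <- rep("UNDETERMINED", nrow(bins))
  par <- abs(bins$r) < th$par_band
  zsp <- bins$r >= th$z_band[1L] & bins$r <= th$z_band[2L]
  fem <- bins$m_norm < th$male_absent & bins$f_norm >= th$min_female
  low <- bins$f_norm < th$low_cov & bins$m_norm < th$low_cov
  cls[par] <- "PAR"
  cls[zsp] <- "Z_SPECIFIC"
  cls[fem] <- "FEMALE_SPECIFIC"
  cls[low] <- "LOW_COVERAGE"
  bins$class <- cls
  bins
}

#' Majority-vote smoothing of a class sequence
#'
#' Each bin is replaced by the majority class within its centered window;
#' ties keep the bin's original class, and a window of 1 is the identity.
#' Windows are truncated at chromosome ends. Smoothing suppresses isolated
#' misclassified bins before segmentation.
#'
#' @param classes Character vector of classes for one chromosome, in
#'   positional order.
#' @param window Odd window size in bins.
#' @return Character vector of smoothed classes.
#' @export
smooth_classes <- function(classes, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("smoothing window must be odd and >= 1")
  }
  n <- length(classes)
  if (window == 1L || n == 0L) return(classes)
  half <- window %/% 2L
  out <- classes
  for (i in seq_len(n)) {
    win <- classes[max(1L, i - half):min(n, i + half)]
    counts <- table(win)
    top <- counts[counts == max(counts)]
    if (length(top) == 1L) out[i] <- names(top)
    # tie: keep original class
  }
  out
}

#' Segment classified bins into maximal same-class regions
#'
#' Maximal runs of identical class are formed per chromosome. Runs shorter
#' than `min_run` bins are absorbed into the longer flanking run (the left
#' flank on ties) and maximality is re-established, repeating until every
#' remaining run is long enough or a chromosome is a single run. The output
#' regions tile the classified bins exactly.
#'
#' @param bins Classified bin table from [classify_bins()] (optionally
#'   smoothed).
#' @param min_run Minimum run length in bins.
#' @return data.frame of region calls: `chrom`, `start`, `end` (0-based
#'   half-open), `class`, `n_bins`, `mean_r`.
#' @export
segment_regions <- function(bins, min_run = 3L) {
  min_run <- as.integer(min_run)
  out <- lapply(unique(bins$chrom), function(chr) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    cls <- b$class
    repeat {
      runs <- rle(cls)
      if (length(runs$lengths) <= 1L) break
      short <- which(runs$lengths < min_run)
      if (!length(short)) break
      i <- short[1L]
      left_len <- if (i > 1L) runs$lengths[i - 1L] else -1L
      right_len <- if (i < length(runs$lengths)) runs$lengths[i + 1L] else -1L
      absorb_left <- left_len >= right_len  # left flank wins ties
      new_class <- if (absorb_left) runs$values[i - 1L] else runs$values[i + 1L]
      pos <- cumsum(runs$lengths)
      idx <- (pos[i] - runs$lengths[i] + 1L):pos[i]
      cls[idx] <- new_class
    }
    runs <- rle(cls)
    ends_i <- cumsum(runs$lengths)
    starts_i <- ends_i - runs$lengths + 1L
    data.frame(
      chrom = chr,
      start = b$start[starts_i],
      end = b$end[ends_i],
      class = runs$values,
      n_bins = runs$lengths,
      mean_r = vapply(seq_along(runs$lengths),
                      function(k) mean(b$r[starts_i[k]:ends_i[k]]), 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag sex chromosomes by their sex-linked bin fraction
#'
#' A chromosome is flagged when the fraction of its bins that are
#' sex-linked — `|r| > t_sex` or classified FEMALE_SPECIFIC / Z_SPECIFIC —
#' exceeds `sex_chrom_fraction`. No uniqueness is forced: every chromosome
#' over the threshold is flagged, and all fractions are reported.
#'
#' @param bins Classified bin table.
#' @param thresholds A [zw_thresholds()] list.
#' @return data.frame with `chrom`, `n_bins`, `sex_linked_fraction`,
#'   `flagged`, sorted by decreasing fraction.
#' @export
identify_sex_chromosome <- function(bins, thresholds = zw_thresholds()) {
  th <- thresholds
  linked <- abs(bins$r) > th$t_sex |
    bins$class %in% c("FEMALE_SPECIFIC", "Z_SPECIFIC")
  frac <- tapply(linked, bins$chrom, mean)
  n <- tapply(linked, bins$chrom, length)
  rep_tab <- data.frame(chrom = names(frac),
                        n_bins = as.integer(n),
                        sex_linked_fraction = as.numeric(frac),
                        stringsAsFactors = FALSE)
  rep_tab$flagged <- rep_tab$sex_linked_fraction > th$sex_chrom_fraction
  rep_tab <- rep_tab[order(-rep_tab$sex_linked_fraction), , drop = FALSE]
  rownames(rep_tab) <- NULL
  rep_tab
}

#' Call sex linkage of AGP components from classified bins
#'
#' Each bin is assigned to the component containing its midpoint (so bins
#' at component junctions are never double-counted). Per component, the
#' fraction of classified bins in each class is computed; the verdict is W
#' when the FEMALE_SPECIFIC fraction reaches `w_contig_fraction`, Z when
#' the combined PAR + Z_SPECIFIC fraction reaches it, and AMBIGUOUS
#' otherwise. A component overlapped by no classified bin is AMBIGUOUS
#' with a warning.
#'
#' @param bins Classified bin table (chromosome names must match AGP object
#'   names).
#' @param agp AGP table from [read_agp()].
#' @param thresholds A [zw_thresholds()] list.
#' @return data.frame with `component_id`, `object`, `start`, `end`
#'   (0-based object coordinates), `n_bins`, one `frac_*` column per class,
#'   and `verdict` in {W, Z, AMBIGUOUS}.
#' @export
call_contigs <- function(bins, agp, thresholds = zw_thresholds()) {
  th <- thresholds
  comp <- agp_components(agp)
  comp <- comp[comp$object %in% unique(bins$chrom), , drop = FALSE]
  if (!nrow(comp)) stop("no AGP components on the binned chromosomes")
  mid <- (bins$start + bins$end) / 2
  calls <- lapply(seq_len(nrow(comp)), function(i) {
    on_comp <- bins$chrom == comp$object[i] &
      mid >= comp$start[i] & mid < comp$end[i]
    cls <- bins$class[on_comp]
    n <- length(cls)
    frac <- vapply(BIN_CLASSES, function(k) if (n) mean(cls == k) else 0, 0)
    verdict <- if (n == 0L) {
      warning("component ", comp$component_id[i],
              " overlaps no classified bins; verdict AMBIGUOUS")
      "AMBIGUOUS"
    } else if (frac[["FEMALE_SPECIFIC"]] >= th$w_contig_fraction) {
      "W"
    } else if (frac[["PAR"]] + frac[["Z_SPECIFIC"]] >= th$w_contig_fraction) {
      "Z"
    } else {
      "AMBIGUOUS"
    }
    cbind(comp[i, , drop = FALSE],
          data.frame(n_bins = n, t(frac), verdict = verdict,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, calls)
  names(out) <- sub("^(PAR|FEMALE_SPECIFIC|Z_SPECIFIC|UNDETERMINED|LOW_COVERAGE)$",
                    "frac_\\1", names(out))
  rownames(out) <- NULL
  out
}

#' Extract W-verdict components from an AGP object
#'
#' Components called W are removed from their object, gap rows left
#' adjacent to each other by a removal are merged into one (keeping the
#' left gap's length), gaps stranded at object edges are dropped, remaining
#' parts are renumbered and object coordinates recomputed. Total sequence
#' length is conserved between the revised object and the extracted contig
#' list.
#'
#' @param agp AGP table.
#' @param contig_calls Output of [call_contigs()] (or any data.frame with
#'   `component_id` and `verdict`).
#' @return List with `agp` (revised AGP table) and `w_contigs` (data.frame
#'   of removed components with their original 0-based object coordinates
#'   and lengths).
#' @export
extract_w <- function(agp, contig_calls) {
  w_ids <- contig_calls$component_id[contig_calls$verdict == "W"]
  seqrow <- !(agp$component_type %in% c("N", "U"))
  drop_w <- seqrow & agp$component_id %in% w_ids
  if (!any(drop_w)) {
    return(list(agp = agp, w_contigs = data.frame(
      component_id = character(), object = character(),
      start = integer(), end = integer(), length = integer())))
  }
  w_contigs <- data.frame(
    component_id = agp$component_id[drop_w],
    object = agp$object[drop_w],
    start = agp$object_beg[drop_w] - 1L,
    end = agp$object_end[drop_w],
    length = agp$object_end[drop_w] - agp$object_beg[drop_w] + 1L,
    stringsAsFactors = FALSE
  )
  out <- lapply(unique(agp$object), function(obj) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    keep <- !(rows$component_id %in% w_ids &
                !(rows$component_type %in% c("N", "U")))
    rows <- rows[keep, , drop = FALSE]
    if (!nrow(rows) ||
        all(rows$component_type %in% c("N", "U"))) {
      stop("extracting W contigs would leave object ", obj,
           " with no sequence components")
    }
    gap <- rows$component_type %in% c("N", "U")
    # merge adjacent gap rows (keep the left one); a leading gap, or a gap
    # preceded by another gap, is dropped, as are trailing gaps
    drop <- gap & c(TRUE, gap[-length(gap)])
    last <- max(which(!drop))
    while (rows$component_type[last] %in% c("N", "U")) {
      drop[last] <- TRUE
      last <- max(which(!drop))
    }
    rows <- rows[!drop, , drop = FALSE]
    lens <- ifelse(rows$component_type %in% c("N", "U"),
                   rows$gap_length,
                   rows$component_end - rows$component_beg + 1L)
    ends <- cumsum(as.numeric(lens))
    rows$object_beg <- as.integer(ends - lens + 1)
    rows$object_end <- as.integer(ends)
    rows$part_number <- seq_len(nrow(rows))
    rows
  })
  revised <- do.call(rbind, out)
  rownames(revised) <- NULL
  validate_agp(revised)
  class(revised) <- c("agp", "data.frame")
  list(agp = revised, w_contigs = w_contigs)
}

#' Select chromosome-scale scaffolds by length
#'
#' @param lengths Named numeric vector of scaffold lengths in bp.
#' @param min_len Minimum length in bp; scaffolds strictly longer are kept.
#' @return Character vector of scaffold names sorted by decreasing length.
#' @export
filter_chromosome_scaffolds <- function(lengths, min_len = 1e7) {
  stopifnot(min_len > 0)
  keep <- lengths > min_len
  names(sort(lengths[keep], decreasing = TRUE))
}

#' Run the full coverage scan
#'
#' Convenience wrapper chaining [normalize_bins()], [classify_bins()],
#' [smooth_classes()], [segment_regions()], [identify_sex_chromosome()] and
#' (when an AGP is given) [call_contigs()].
#'
#' @param bins Paired sexed bin table (`chrom`, `start`, `end`, `female`,
#'   `male`).
#' @param autosome_ids Chromosomes used for normalization; `NULL` uses all.
#' @param agp Optional AGP table for contig calls.
#' @param thresholds A [zw_thresholds()] list.
#' @param normalize Passed to [normalize_bins()].
#' @return List with `bins` (normalized, classified, smoothed), `regions`,
#'   `chrom_report` and `contig_calls` (NULL without an AGP).
#' @export
scan_sex_regions <- function(bins, autosome_ids = NULL, agp = NULL,
                             thresholds = zw_thresholds(), normalize = TRUE) {
  th <- thresholds
  nb <- normalize_bins(bins, autosome_ids = autosome_ids,
                       pseudocount = th$pseudocount, normalize = normalize)
  cb <- classify_bins(nb, th)
  cb <- cb[order(cb$chrom, cb$start), , drop = FALSE]
  for (chr in unique(cb$chrom)) {
    sel <- cb$chrom == chr
    cb$class[sel] <- smooth_classes(cb$class[sel], th$smooth_window)
  }
  regions <- segment_regions(cb, th$min_run)
  chrom_report <- identify_sex_chromosome(cb, th)
  contig_calls <- if (!is.null(agp)) call_contigs(cb, agp, th) else NULL
  list(bins = cb, regions = regions, chrom_report = chrom_report,
       contig_calls = contig_calls)
}
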