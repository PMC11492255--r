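#' Bin per-base depth into fixed windows
#'
#' Each bin's value is (sum of per-base depths in the bin) / bin width, so
#' positions with no record count as depth 0. The terminal bin of a
#' chromosome may be shorter than `bin_size`; its width is taken from
#' `chrom_lengths` when given, otherwise from the last observed position.
#' Total depth mass (depth x width summed over bins) equals the sum of the
#' input per-base depths.
#'
#' @param depth Per-base depth data.frame from [read_depth()] (`chrom`,
#'   `pos` 1-based, `depth`).
#' @param bin_size Window size in bp (> 0).
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `depth` (mean per-base depth over the bin).
#' @export
bin_depths <- function(depth, bin_size, chrom_lengths = NULL) {
  stopifnot(bin_size > 0)
  steps <- unlist(tapply(depth$pos, depth$chrom, diff), use.names = FALSE)
  if (length(steps) && any(steps <= 0)) {
    stop("per-base depth must be sorted with strictly increasing positions")
  }
  out <- lapply(unique(depth$chrom), function(chr) {
    d <- depth[depth$chrom == chr, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      as.numeric(chrom_lengths[[chr]])
    } else {
      max(d$pos)
    }
    if (any(d$pos > len)) {
      stop("depth position beyond stated length of chromosome ", chr)
    }
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    idx <- findInterval(d$pos - 1L, starts)  # 0-based position -> bin
    sums <- numeric(length(starts))
    agg <- tapply(d$depth, idx, sum)
    sums[as.integer(names(agg))] <- agg
    data.frame(chrom = chr, start = as.integer(starts), end = as.integer(ends),
               depth = sums / (ends - starts), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pair female and male bins into one table
#'
#' @param female,male Binned single-sex depth tables (`chrom`, `start`,
#'   `end`, `depth`), e.g. from [bin_depths()] or [read_depth()] with
#'   binned input. Bins must match exactly.
#' @return data.frame with `chrom`, `start`, `end`, `female`, `male`.
#' @export
pair_sexes <- function(female, male) {
  key_f <- paste(female$chrom, female$start, female$end)
  key_m <- paste(male$chrom, male$start, male$end)
  if (nrow(female) != nrow(male) || !all(key_f == key_m)) {
    stop("female and male bin tables do not describe the same bins")
  }
  data.frame(chrom = female$chrom, start = female$start, end = female$end,
             female = female$depth, male = male$depth,
             stringsAsFactors = FALSE)
}

#' Log2 male:female depth ratio with a pseudocount
#'
#' `r = log2((m + c) / (f + c))`, finite for any non-negative inputs, and
#' antisymmetric under swapping the sexes. The pseudocount keeps bins with
#' zero male depth (W fragments) finite while leaving near-equal bins
#' essentially untouched.
#'
#' @param m_norm,f_norm Normalized (or raw) male and female depths.
#' @param pseudocount Positive constant `c` in normalized-depth units.
#' @return Numeric vector of log2 ratios.
#' @export
log2_ratio <- function(m_norm, f_norm, pseudocount = 0.05) {
  stopifnot(pseudocount > 0 || all(m_norm > 0 & f_norm > 0))
  log2((m_norm + pseudocount) / (f_norm + pseudocount))
}

#' Normalize sexed bin depths by autosomal medians
#'
#' Divides each sex's depths by that sex's median depth over autosomal
#' bins, so the male:female ratio is insensitive to library-yield
#' differences between the two sequencing runs. The median (not the mean)
#' is used for robustness to sex-linked outlier bins. Adds the log2
#' male:female ratio `r` computed with [log2_ratio()].
#'
#' @param bins Paired bin table from [pair_sexes()] or [simulate_depth()].
#' @param autosome_ids Chromosome names treated as autosomal for the
#'   normalization constant. When `NULL`, all chromosomes are used (only
#'   appropriate when sex-linked bins are a small minority).
#' @param pseudocount Pseudocount for [log2_ratio()].
#' @param normalize If `FALSE`, raw depths are carried into `f_norm` /
#'   `m_norm` unchanged and only `r` is added.
#' @return Input with added columns `f_norm`, `m_norm`, `r`, and the two
#'   medians recorded in attributes `female_median` / `male_median`.
#' @export
normalize_bins <- function(bins, autosome_ids = NULL, pseudocount = 0.05,
                           normalize = TRUE) {
  auto <- if (is.null(autosome_ids)) rep(TRUE, nrow(bins)) else
    bins$chrom %in% autosome_ids
  if (!any(auto)) stop("no autosomal bins to normalize against")
  med_f <- median(bins$female[auto])
  med_m <- median(bins$male[auto])
  if (normalize) {
    if (med_f <= 0) stop("female autosomal depth is all zero; cannot normalize")
    if (med_m <= 0) stop("male autosomal depth is all zero; cannot normalize")
    bins$f_norm <- bins$female / med_f
    bins$m_norm <- bins$male / med_m
  } else {
    bins$f_norm <- bins$female
    bins$m_norm <- bins$male
  }
  bins$r <- log2_ratio(bins$m_norm, bins$f_norm, pseudocount)
  attr(bins, "female_median") <- med_f
  attr(bins, "male_median") <- med_m
  bins
}
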