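#' Transcripts per million
#'
#' `tpm_i = 1e6 * (count_i / length_i) / sum_j (count_j / length_j)`.
#' Length-normalizes counts so each sample sums to one million.
#'
#' @param counts Non-negative numeric counts, one per gene.
#' @param gene_lengths Positive gene lengths in bp.
#' @return Numeric TPM vector summing to 1e6.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  stopifnot(length(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / gene_lengths
  total <- sum(rate)
  if (total == 0) stop("all counts are zero; TPM undefined")
  1e6 * rate / total
}

#' Flag sex-biased expression by a fold threshold
#'
#' The fold is the pseudocounted ratio of the larger to the smaller value,
#' `(max + c) / (min + c)`, so it is always >= 1 and finite at zero
#' expression. The bias label goes to the larger side when the fold
#' strictly exceeds `fold_threshold` ("more than `fold_threshold`-fold"),
#' otherwise NONE. Swapping the sexes swaps FEMALE and MALE labels and
#' leaves the fold unchanged.
#'
#' @param expr data.frame with `gene_id`, `female_value`, `male_value`
#'   columns (counts, TPM or depths; column names `female_count` /
#'   `male_count` are also accepted).
#' @param fold_threshold Threshold (> 1), default 2.
#' @param pseudocount Non-negative stabilizer `c`, default 1 (count units).
#' @return `expr` with added `fold` and `bias` (FEMALE / MALE / NONE)
#'   columns.
#' @export
bias_flags <- function(expr, fold_threshold = 2, pseudocount = 1) {
  stopifnot(fold_threshold > 1, pseudocount >= 0)
  f <- expr[["female_value"]] %||% expr[["female_count"]]
  m <- expr[["male_value"]] %||% expr[["male_count"]]
  if (is.null(f) || is.null(m)) {
    stop("expression table needs female_value/male_value ",
         "(or female_count/male_count) columns")
  }
  if (any(f < 0) || any(m < 0)) stop("expression values must be non-negative")
  hi <- pmax(f, m)
  lo <- pmin(f, m)
  fold <- (hi + pseudocount) / (lo + pseudocount)
  bias <- ifelse(fold > fold_threshold,
                 ifelse(f > m, "FEMALE", "MALE"),
                 "NONE")
  expr$fold <- fold
  expr$bias <- bias
  expr
}

#' Candidate sex-determining genes from bias within called regions
#'
#' W candidates are genes overlapping (>= 1 bp) a W-verdict contig or a
#' FEMALE_SPECIFIC region and carrying FEMALE bias; Z candidates are genes
#' overlapping a Z_SPECIFIC region with MALE bias. A gene straddling a
#' boundary is assigned to every region it overlaps and can appear in both
#' lists.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, 0-based
#'   half-open, `product` optional).
#' @param bias ExprBias table from [bias_flags()].
#' @param regions Region calls from [segment_regions()].
#' @param contig_calls Optional contig calls from [call_contigs()]; their
#'   W-verdict spans are treated as female-specific territory.
#' @return data.frame with `candidate_type` (W / Z), `gene_id`, `chrom`,
#'   `start`, `end`, `product`, `fold`, `bias`, `region_start`,
#'   `region_end`, `region_label`.
#' @export
candidates_in_regions <- function(genes, bias, regions, contig_calls = NULL) {
  targets <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    label = regions$class, stringsAsFactors = FALSE
  )
  targets <- targets[targets$label %in% c("FEMALE_SPECIFIC", "Z_SPECIFIC"), ,
                     drop = FALSE]
  if (!is.null(contig_calls)) {
    w <- contig_calls[contig_calls$verdict == "W", , drop = FALSE]
    if (nrow(w)) {
      targets <- rbind(targets, data.frame(
        chrom = w$object, start = w$start, end = w$end,
        label = "W_CONTIG", stringsAsFactors = FALSE))
    }
  }
  empty <- data.frame(candidate_type = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), product = character(),
                      fold = numeric(), bias = character(),
                      region_start = integer(), region_end = integer(),
                      region_label = character(), stringsAsFactors = FALSE)
  if (!nrow(targets) || !nrow(genes)) return(empty)
  g_gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  t_gr <- GenomicRanges::GRanges(targets$chrom,
                                 IRanges::IRanges(targets$start + 1L,
                                                  targets$end))
  hits <- GenomicRanges::findOverlaps(g_gr, t_gr, minoverlap = 1L)
  if (!length(hits)) return(empty)
  gi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  b <- bias[match(genes$gene_id[gi], bias$gene_id), , drop = FALSE]
  out <- data.frame(
    candidate_type = ifelse(targets$label[ti] == "Z_SPECIFIC", "Z", "W"),
    gene_id = genes$gene_id[gi],
    chrom = genes$chrom[gi],
    start = genes$start[gi],
    end = genes$end[gi],
    product = if ("product" %in% names(genes)) genes$product[gi]
      else NA_character_,
    fold = b$fold,
    bias = b$bias,
    region_start = targets$start[ti],
    region_end = targets$end[ti],
    region_label = targets$label[ti],
    stringsAsFactors = FALSE
  )
  keep <- (out$candidate_type == "W" & out$bias %in% "FEMALE") |
    (out$candidate_type == "Z" & out$bias %in% "MALE")
  out <- out[keep & !is.na(out$bias), , drop = FALSE]
  # a gene overlapping both a FEMALE_SPECIFIC region and its own W contig
  # is one W candidate, not two
  out <- out[!duplicated(out[, c("candidate_type", "gene_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
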