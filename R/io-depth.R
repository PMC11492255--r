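#' Read a depth table
#'
#' Two input kinds are supported. `"per-base"` is the 3-column
#' `samtools depth` layout (`chrom`, 1-based position, depth), validated for
#' strictly increasing positions within a chromosome. `"binned"` is BED4
#' (`chrom`, 0-based start, end, mean depth per base) and bypasses binning
#' downstream. `"auto"` sniffs the column count of the first data line.
#'
#' @param path Input path; `#`-prefixed lines are ignored.
#' @param kind One of `"auto"`, `"per-base"`, `"binned"`.
#' @return For per-base input, a data.frame with `chrom`, `pos` (1-based),
#'   `depth`; for binned input, a data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `depth`.
#' @export
read_depth <- function(path, kind = c("auto", "per-base", "binned")) {
  kind <- match.arg(kind)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = NA, stringsAsFactors = FALSE)
  if (kind == "auto") {
    kind <- if (ncol(tab) >= 4L) "binned" else "per-base"
  }
  if (kind == "per-base") {
    if (ncol(tab) < 3L) stop("per-base depth input needs 3 columns")
    out <- data.frame(chrom = as.character(tab[[1L]]),
                      pos = as.integer(tab[[2L]]),
                      depth = as.numeric(tab[[3L]]),
                      stringsAsFactors = FALSE)
    if (any(out$depth < 0)) stop("negative depth value in ", path)
    steps <- unlist(tapply(out$pos, out$chrom, diff), use.names = FALSE)
    if (length(steps) && any(steps <= 0)) {
      stop("positions not strictly increasing within a chromosome in ", path)
    }
    out
  } else {
    if (ncol(tab) < 4L) stop("binned depth input needs 4 columns (BED4)")
    out <- data.frame(chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[2L]]),
                      end = as.integer(tab[[3L]]),
                      depth = as.numeric(tab[[4L]]),
                      stringsAsFactors = FALSE)
    if (any(out$start < 0) || any(out$end <= out$start)) {
      stop("invalid bin interval in ", path)
    }
    if (any(out$depth < 0)) stop("negative depth value in ", path)
    out
  }
}

#' Write intervals as BED
#'
#' Internal intervals are already 0-based half-open, so they are emitted
#' verbatim (BED3, or BED4 when `name_col` is given). A header comment line
#' naming the columns is always written, so an empty region set yields a
#' file with only that comment.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally the
#'   column named by `name_col`.
#' @param path Output path.
#' @param name_col Optional column written as BED column 4 (a class label or
#'   a numeric value such as depth).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path, name_col = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) && (any(regions$start < 0) || any(regions$end < 0))) {
    stop("negative coordinates in BED output")
  }
  cols <- c("chrom", "start", "end", name_col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(regions)) {
    write.table(regions[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED4 region file written by [write_bed()]
#'
#' @param path Input path.
#' @param name Name to give the 4th column (default `"name"`).
#' @return data.frame with `chrom`, `start`, `end` and, if present, the
#'   4th column.
#' @export
read_bed <- function(path, name = "name") {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(tab)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    out[[name]] <- character()
    return(out)
  }
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) out[[name]] <- tab[[4L]]
  out
}

#' Read a gene annotation from GFF3
#'
#' Imports `gene`-type features with rtracklayer and converts them to the
#' package's internal convention (0-based half-open).
#'
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `product`.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(gr$product %||% NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a gene annotation as GFF3
#'
#' Inverse of [read_gene_gff3()]: converts the internal 0-based half-open
#' intervals back to GFF3's 1-based inclusive convention and exports with
#' rtracklayer.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `product`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_gff3 <- function(genes, path) {
  stopifnot(all(genes$end > genes$start), all(genes$strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "zwscan"
  gr$ID <- genes$gene_id
  gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a zwscan configuration file
#'
#' A single YAML key-value file; keys under `thresholds` override
#' [zw_thresholds()] defaults and keys under `sim` override [sim_config()]
#' defaults.
#'
#' @param path YAML path.
#' @return Named list with elements `thresholds` and `sim` (either may be
#'   absent in the file and comes back as an empty list).
#' @export
read_zw_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(thresholds = cfg$thresholds %||% list(),
       sim = cfg$sim %||% list())
}
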