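#' Read an AGP v2.1 file
#'
#' AGP describes how sequence components (contigs) and gaps tile assembled
#' objects (scaffolds/chromosomes). Coordinates are kept as in the format:
#' 1-based inclusive. Rows are returned grouped by object and sorted by
#' part_number, and the tiling of every object is validated: parts must
#' cover the object without overlap or holes, and sequence rows must have
#' matching component and object span lengths.
#'
#' @param path Path to an AGP file; lines starting with `#` are comments.
#' @return A data.frame of class `agp` with columns `object`, `object_beg`,
#'   `object_end`, `part_number`, `component_type`, `component_id`,
#'   `component_beg`, `component_end`, `orientation` (sequence rows; NA on
#'   gap rows) and `gap_length`, `gap_type`, `linkage`, `linkage_evidence`
#'   (gap rows; NA on sequence rows).
#' @seealso [write_agp()], [extract_w()]
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("AGP file ", path, " contains no records")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("AGP line ", which(nf < 8L)[1L], " has fewer than 8 fields")
  }
  fields <- lapply(fields, function(x) c(x, rep(NA_character_, 9L - length(x)))[1:9])
  m <- do.call(rbind, fields)
  gap <- m[, 5L] %in% c("N", "U")
  agp <- data.frame(
    object = m[, 1L],
    object_beg = as.integer(m[, 2L]),
    object_end = as.integer(m[, 3L]),
    part_number = as.integer(m[, 4L]),
    component_type = m[, 5L],
    component_id = ifelse(gap, NA_character_, m[, 6L]),
    component_beg = as.integer(ifelse(gap, NA, suppressWarnings(as.integer(m[, 7L])))),
    component_end = as.integer(ifelse(gap, NA, suppressWarnings(as.integer(m[, 8L])))),
    orientation = ifelse(gap, NA_character_, m[, 9L]),
    gap_length = as.integer(ifelse(gap, suppressWarnings(as.integer(m[, 6L])), NA)),
    gap_type = ifelse(gap, m[, 7L], NA_character_),
    linkage = ifelse(gap, m[, 8L], NA_character_),
    linkage_evidence = ifelse(gap, m[, 9L], NA_character_),
    stringsAsFactors = FALSE
  )
  agp <- agp[order(agp$object, agp$part_number), , drop = FALSE]
  rownames(agp) <- NULL
  validate_agp(agp)
  class(agp) <- c("agp", "data.frame")
  agp
}

#' Validate an AGP table
#'
#' Checks the AGP invariants: `object_end >= object_beg`, parts of one
#' object tile it in part_number order without overlap or holes, and for
#' sequence rows the component span equals the object span.
#'
#' @param agp AGP data.frame as returned by [read_agp()].
#' @return Invisibly, `agp`; errors name the offending object and part.
#' @export
validate_agp <- function(agp) {
  bad <- which(agp$object_end < agp$object_beg)
  if (length(bad)) {
    stop("AGP object ", agp$object[bad[1L]], " part ", agp$part_number[bad[1L]],
         ": object_end < object_beg")
  }
  seqrow <- !(agp$component_type %in% c("N", "U"))
  span_obj <- agp$object_end - agp$object_beg
  span_cmp <- agp$component_end - agp$component_beg
  bad <- which(seqrow & (is.na(span_cmp) | span_cmp != span_obj))
  if (length(bad)) {
    stop("AGP object ", agp$object[bad[1L]], " part ", agp$part_number[bad[1L]],
         ": component span does not match object span")
  }
  bad <- which(!seqrow & (is.na(agp$gap_length) |
                          agp$gap_length != span_obj + 1L))
  if (length(bad)) {
    stop("AGP object ", agp$object[bad[1L]], " part ", agp$part_number[bad[1L]],
         ": gap_length does not match object span")
  }
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    if (rows$object_beg[1L] != 1L) {
      stop("AGP object ", obj, " part ", rows$part_number[1L],
           ": tiling does not start at 1")
    }
    if (nrow(rows) > 1L) {
      gapped <- which(rows$object_beg[-1L] != rows$object_end[-nrow(rows)] + 1L)
      if (length(gapped)) {
        stop("AGP object ", obj, " part ", rows$part_number[gapped[1L] + 1L],
             ": parts overlap or leave a hole in the tiling")
      }
    }
  }
  invisible(agp)
}

#' Write an AGP v2.1 file
#'
#' Inverse of [read_agp()]; a round trip preserves every field the pipeline
#' reads.
#'
#' @param agp AGP data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  gap <- agp$component_type %in% c("N", "U")
  f6 <- ifelse(gap, as.character(agp$gap_length), agp$component_id)
  f7 <- ifelse(gap, agp$gap_type, as.character(agp$component_beg))
  f8 <- ifelse(gap, agp$linkage, as.character(agp$component_end))
  f9 <- ifelse(gap, agp$linkage_evidence, agp$orientation)
  out <- cbind(agp$object, agp$object_beg, agp$object_end, agp$part_number,
               agp$component_type, f6, f7, f8, f9)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# sequence components of one AGP object, converted to 0-based half-open
# object coordinates
agp_components <- function(agp, object = NULL) {
  rows <- agp[!(agp$component_type %in% c("N", "U")), , drop = FALSE]
  if (!is.null(object)) rows <- rows[rows$object %in% object, , drop = FALSE]
  data.frame(
    object = rows$object,
    component_id = rows$component_id,
    start = rows$object_beg - 1L,
    end = rows$object_end,
    orientation = rows$orientation,
    stringsAsFactors = FALSE
  )
}
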