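#' Match genes to canonical Hox classes by product text
#'
#' A convenience class-assignment builder: a gene is assigned the canonical
#' class whose name appears as a whole word in its product description.
#' Decoy homeobox genes whose products mention "homeobox" but carry no
#' canonical class token are not matched. For annotations where name
#' matching is unreliable, supply an externally produced assignment table
#' (e.g. from homeodomain BLAST hits) to [collect_hox()] instead.
#'
#' @param genes Gene table with `gene_id` and `product` columns.
#' @return data.frame with `gene_id`, `hox_class` for matched genes.
#' @export
match_hox_classes <- function(genes) {
  hits <- lapply(HOX_CLASSES, function(cl) {
    pat <- paste0("(^|[^A-Za-z0-9-])", gsub("-", "\\\\-", cl),
                  "($|[^A-Za-z0-9-])")
    sel <- grepl(pat, genes$product)
    if (any(sel)) data.frame(gene_id = genes$gene_id[sel], hox_class = cl,
                             stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), hox_class = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Collect a Hox organization from an annotation
#'
#' Keeps genes with a class assignment, orders them by chromosome and
#' position, records canonical classes absent from the assignment, keeps
#' the first gene (by position) when a class is assigned twice (with a
#' duplicate warning), and warns — without failing — when the assigned
#' genes span multiple chromosomes (a split cluster).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param class_assignment data.frame mapping `gene_id` to `hox_class`,
#'   e.g. from [match_hox_classes()] or an external homeodomain-hit table.
#' @param species Species label stored with the organization.
#' @return Object of class `hox_organization`: list with `species`,
#'   `genes` (ordered data.frame with `hox_class`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`), `missing` (character), `duplicates`
#'   (character), `split` (logical, TRUE when genes lie on more than one
#'   chromosome).
#' @export
collect_hox <- function(genes, class_assignment, species = "species") {
  stopifnot(all(c("gene_id", "hox_class") %in% names(class_assignment)))
  bad <- setdiff(class_assignment$hox_class, HOX_CLASSES)
  if (length(bad)) stop("unknown Hox class: ", paste(bad, collapse = ", "))
  g <- merge(class_assignment, genes, by = "gene_id")
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  dup <- unique(g$hox_class[duplicated(g$hox_class)])
  if (length(dup)) {
    warning("duplicate assignment for Hox class ",
            paste(dup, collapse = ", "), "; keeping the first by position")
    g <- g[!duplicated(g$hox_class), , drop = FALSE]
  }
  split <- length(unique(g$chrom)) > 1L
  if (split) {
    warning("Hox genes of ", species, " lie on multiple chromosomes: ",
            paste(unique(g$chrom), collapse = ", "))
  }
  org <- list(
    species = species,
    genes = g[, c("hox_class", "gene_id", "chrom", "start", "end", "strand")],
    missing = setdiff(HOX_CLASSES, g$hox_class),
    duplicates = dup,
    split = split
  )
  rownames(org$genes) <- NULL
  class(org) <- c("hox_organization", "list")
  org
}

#' Build a Hox organization directly from a per-species gene table
#'
#' For cross-species comparisons the input is often already a curated
#' table of Hox genes; this wraps it as an organization without a separate
#' assignment step.
#'
#' @param tab data.frame with `hox_class`, `chrom`, `start`, `end`,
#'   `strand` (and optionally `gene_id`).
#' @param species Species label.
#' @return A `hox_organization`.
#' @export
hox_organization <- function(tab, species = "species") {
  if (!"gene_id" %in% names(tab)) tab$gene_id <- tab$hox_class
  collect_hox(tab[, c("gene_id", "chrom", "start", "end", "strand")],
              tab[, c("gene_id", "hox_class")], species = species)
}

#' Partition a Hox organization into gap-separated subclusters
#'
#' A cut is placed between consecutive genes whenever the intergenic
#' distance (next start minus previous end; negative for overlapping
#' genes, which never cut) exceeds `gap_threshold`, or when the next gene
#' lies on a different chromosome. The number of subclusters is 1 + the
#' number of cuts.
#'
#' @param org A `hox_organization`.
#' @param gap_threshold Gap size in bp above which a cut is made
#'   (default 1 Mb).
#' @return Integer vector of subcluster indices (1-based, one per gene),
#'   with the list-of-index-ranges partition in attribute `partition`.
#' @export
hox_subclusters <- function(org, gap_threshold = 1e6) {
  stopifnot(inherits(org, "hox_organization"), gap_threshold > 0)
  g <- org$genes
  n <- nrow(g)
  if (n == 0L) return(integer(0))
  cut <- if (n > 1L) {
    gaps <- g$start[-1L] - g$end[-n]
    gaps > gap_threshold | g$chrom[-1L] != g$chrom[-n]
  } else {
    logical(0)
  }
  idx <- cumsum(c(1L, as.integer(cut)))
  attr(idx, "partition") <- split(seq_len(n), idx)
  idx
}

#' Relative-orientation matrix across species
#'
#' For each species, the majority strand over present Hox genes is the
#' reference (ties break to `+`); each gene is labeled `same` or
#' `opposite` relative to it, and absent classes are labeled `absent`.
#' Globally flipping every strand of a species flips its majority too, so
#' the matrix is invariant under such flips.
#'
#' @param organizations List of `hox_organization` objects (names or
#'   `species` fields label the rows).
#' @return Character matrix, species x canonical class, entries in
#'   {same, opposite, absent}.
#' @export
orientation_matrix <- function(organizations) {
  stopifnot(length(organizations) >= 1L)
  rows <- lapply(organizations, function(org) {
    g <- org$genes
    n_plus <- sum(g$strand == "+")
    n_minus <- sum(g$strand == "-")
    majority <- if (n_plus >= n_minus) "+" else "-"
    out <- setNames(rep("absent", length(HOX_CLASSES)), HOX_CLASSES)
    out[g$hox_class] <- ifelse(g$strand == majority, "same", "opposite")
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(organizations, function(o) o$species, "")
  m
}

#' Infer inversion sites between two clades
#'
#' A Hox class is an inversion site between two clades when its relative
#' orientation is uniform within each clade but differs between them.
#' Classes absent from any species of a clade, or with mixed orientation
#' within a clade, are inconclusive; identical uniform orientations are
#' consistent. The report is symmetric in clade order.
#'
#' @param mat Orientation matrix from [orientation_matrix()].
#' @param group_assignment Named character vector mapping species (rownames
#'   of `mat`) to exactly two clade labels.
#' @return data.frame with `hox_class`, one orientation column per clade,
#'   and `status` in {inversion, consistent, inconclusive}.
#' @export
infer_inversions <- function(mat, group_assignment) {
  clades <- unique(group_assignment)
  if (length(clades) != 2L) stop("group assignment must define two clades")
  members <- lapply(clades, function(cl)
    names(group_assignment)[group_assignment == cl])
  if (any(lengths(members) == 0L)) stop("a clade has zero species")
  missing_sp <- setdiff(unlist(members), rownames(mat))
  if (length(missing_sp)) {
    stop("species not in orientation matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  clade_state <- function(cl, hox) {
    vals <- mat[members[[which(clades == cl)]], hox]
    if (any(vals == "absent")) return(NA_character_)
    u <- unique(vals)
    if (length(u) == 1L) u else NA_character_
  }
  out <- do.call(rbind, lapply(colnames(mat), function(hox) {
    s1 <- clade_state(clades[1L], hox)
    s2 <- clade_state(clades[2L], hox)
    status <- if (is.na(s1) || is.na(s2)) {
      "inconclusive"
    } else if (s1 != s2) {
      "inversion"
    } else {
      "consistent"
    }
    d <- data.frame(hox_class = hox, s1 = s1, s2 = s2, status = status,
                    stringsAsFactors = FALSE)
    names(d)[2:3] <- clades
    d
  }))
  rownames(out) <- NULL
  out
}

#' Test synteny conservation across organizations
#'
#' Conserved means every organization presents the same class sequence in
#' the same order with identical relative orientations (absolute
#' coordinates are ignored). When not conserved, the first differing class
#' is reported.
#'
#' @param organizations List of at least two `hox_organization` objects.
#' @return List with `conserved` (logical) and `first_difference`
#'   (class name, or NA when conserved).
#' @export
synteny_conserved <- function(organizations) {
  stopifnot(length(organizations) >= 2L)
  mat <- orientation_matrix(organizations)
  sigs <- lapply(organizations, function(org) org$genes$hox_class)
  ref <- sigs[[1L]]
  for (i in seq_along(organizations)[-1L]) {
    s <- sigs[[i]]
    len <- min(length(ref), length(s))
    mismatch <- which(head(ref, len) != head(s, len))
    if (length(mismatch)) {
      return(list(conserved = FALSE, first_difference = ref[mismatch[1L]]))
    }
    if (length(ref) != length(s)) {
      extra <- if (length(ref) > length(s)) ref[len + 1L] else s[len + 1L]
      return(list(conserved = FALSE, first_difference = extra))
    }
  }
  for (hox in colnames(mat)) {
    if (length(unique(mat[, hox])) > 1L) {
      return(list(conserved = FALSE, first_difference = hox))
    }
  }
  list(conserved = TRUE, first_difference = NA_character_)
}
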