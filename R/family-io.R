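#' Read a segmental-duplication family table
#'
#' Parses a tab-separated duplication table modeled on the UCSC
#' `genomicSuperDups` layout: one row per paralogous locus with its genomic
#' interval (0-based half-open, BED convention), sequence name and family
#' identifier. Records are grouped by family; families with fewer than four
#' members cannot form an unrooted quartet and are flagged ineligible.
#'
#' @param path path to a TSV file with a header row naming at least
#'   `chrom`, `start` (or `chromStart`), `end` (or `chromEnd`), `name`, and
#'   `family` columns; an optional `strand` column defaults to `+`.
#' @return a named list of data frames (one per family) with columns
#'   `family_id`, `seq_name`, `chrom`, `start`, `end`, `strand`; each element
#'   carries a logical attribute `eligible` (`TRUE` iff >= 4 members).
#' @export
load_family_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    stop("family table is missing a required column (one of: ",
         paste(c(...), collapse = ", "), ")")
  }
  rec <- data.frame(
    family_id = as.character(pick("family", "family_id")),
    seq_name  = as.character(pick("name", "seq_name")),
    chrom     = as.character(pick("chrom", "chromosome")),
    start     = as.integer(pick("start", "chromStart")),
    end       = as.integer(pick("end", "chromEnd")),
    stringsAsFactors = FALSE
  )
  rec$strand <- if ("strand" %in% names(tab)) as.character(tab$strand) else "+"
  bad <- which(is.na(rec$start) | is.na(rec$end) | rec$end <= rec$start)
  if (length(bad))
    stop("invalid interval (end <= start or non-numeric) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (!all(rec$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  split_rec <- split(rec, rec$family_id)
  lapply(split_rec, function(fam) {
    key <- paste(fam$chrom, fam$start, fam$end)
    if (anyDuplicated(key))
      stop("duplicate (chrom,start,end) within family ", fam$family_id[1])
    attr(fam, "eligible") <- nrow(fam) >= 4L
    fam
  })
}

#' Proportion of matching positions between two aligned sequences
#'
#' @param a,b equal-length character vectors of residues (or single strings),
#'   assumed gap-free.
#' @return fraction of positions at which `a` and `b` agree, in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (is.character(a) && length(a) == 1L && nchar(a) > 1L) a <- seq_to_chars(a)
  if (is.character(b) && length(b) == 1L && nchar(b) > 1L) b <- seq_to_chars(b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  if (length(a) == 0L) stop("cannot compute identity over zero overlap")
  mean(a == b)
}

#' Preprocessing configuration for paralog alignments
#'
#' Defaults mirror the filtering applied to the human segmental-duplication
#' catalog: sequences below 88% identity to every other member are removed
#' (below that divergence the IGC rate is expected to be negligible), sequences
#' inflating the gapped alignment by more than a quarter are removed, and
#' families are rejected below 10 kb of gapless alignment or four members.
#'
#' @param min_identity drop a sequence iff its maximum pairwise identity to the
#'   other members is below this fraction.
#' @param gap_inflation_factor drop a sequence if removing it shrinks the
#'   family's gap-free column count by more than this fraction, i.e. the
#'   sequence destroys that share of otherwise alignable columns.
#' @param min_length minimum gapless alignment length (bp) to retain a family.
#' @param min_members minimum number of sequences (>= 4 for quartet analysis).
#' @param strip_cpg whether downstream scans should use the CpG-stripped view.
#' @param trim_window terminal trimming drops leading/trailing columns until a
#'   run of this many consecutive gap-free columns is reached.
#' @param identity_on compute pairwise identity over `"ungapped"` columns
#'   (positions where neither sequence has a gap; default) or all `"gapped"`
#'   columns with gap-vs-base counted as mismatch.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_identity = 0.88, gap_inflation_factor = 0.25,
                              min_length = 10000L, min_members = 4L,
                              strip_cpg = FALSE, trim_window = 20L,
                              identity_on = c("ungapped", "gapped")) {
  stopifnot(min_identity > 0, min_identity < 1, min_members >= 4L,
            gap_inflation_factor >= 0, min_length >= 1L)
  structure(list(min_identity = min_identity,
                 gap_inflation_factor = gap_inflation_factor,
                 min_length = as.integer(min_length),
                 min_members = as.integer(min_members),
                 strip_cpg = isTRUE(strip_cpg),
                 trim_window = as.integer(trim_window),
                 identity_on = match.arg(identity_on)),
            class = "preprocess_config")
}

# identity between two gapped rows under the configured column rule
.gapped_identity <- function(a, b, identity_on) {
  if (identity_on == "ungapped") {
    keep <- a != "-" & b != "-"
    if (!any(keep)) return(0)
    mean(a[keep] == b[keep])
  } else {
    mean(a == b & a != "-")
  }
}

# number of columns free of gaps in every row
.ungapped_length <- function(m) {
  if (nrow(m) == 0L) return(0L)
  sum(colSums(m == "-") == 0L)
}

.reject <- function(family_id, reason, detail = NULL) {
  structure(list(family_id = family_id, reason = reason, detail = detail),
            class = "family_rejection")
}

#' @export
print.family_rejection <- function(x, ...) {
  cat("<family_rejection>", x$family_id, "--", x$reason, "\n")
  invisible(x)
}

#' Is this object a rejected family?
#' @param x object returned by [preprocess_alignment()].
#' @return logical.
#' @export
is_rejected <- function(x) inherits(x, "family_rejection")

#' Filter and coordinate-map a raw gapped paralog alignment
#'
#' Applies, in order: (i) terminal trimming of ragged alignment ends; (ii)
#' removal of sequences whose best pairwise identity to any other member falls
#' below `cfg$min_identity`; (iii) iterative worst-first removal of sequences
#' whose gaps destroy more than `cfg$gap_inflation_factor` of the otherwise
#' gap-free columns; (iv) deletion of every remaining gap-containing column;
#' (v) rejection of families below `cfg$min_length` gapless bp or
#' `cfg$min_members` sequences. Surviving columns carry a per-sequence map back
#' to 0-based genomic positions derived from the locus records.
#'
#' @param aln gapped alignment: character matrix (rows = sequences, gap `"-"`)
#'   or named character vector of equal-length gapped strings.
#' @param members data frame of locus records as returned by
#'   [load_family_table()] (one row per sequence, matched by `seq_name`).
#' @param cfg a [preprocess_config()].
#' @return an `aligned_family` object, or a `family_rejection` (see
#'   [is_rejected()]) when the family fails the filters.
#' @export
preprocess_alignment <- function(aln, members, cfg = preprocess_config()) {
  if (!is.matrix(aln)) aln <- strings_to_matrix(aln)
  aln <- toupper(aln)
  fam_id <- as.character(members$family_id[1] %||% "family")
  ok_chars <- c(DNA, "-", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  if (!all(aln %in% ok_chars))
    stop("alignment contains non-IUPAC characters: ",
         paste(unique(aln[!aln %in% ok_chars]), collapse = ","))
  if (is.null(rownames(aln))) rownames(aln) <- members$seq_name
  members <- members[match(rownames(aln), members$seq_name), , drop = FALSE]
  if (anyNA(members$seq_name))
    stop("alignment rows lack matching locus records")
  if (nrow(aln) < 4L) return(.reject(fam_id, "min_members"))

  # residue index of each cell within its (original, gapped) row -- fixed now
  # so genomic coordinates survive all later column deletions
  resi <- t(apply(aln != "-", 1L, cumsum))
  orig_cols <- seq_len(ncol(aln))

  # (i) terminal trim: advance each end to the first clean window
  gapfree <- colSums(aln == "-") == 0L
  w <- min(cfg$trim_window, length(gapfree))
  runlen <- stats::filter(as.numeric(gapfree), rep(1, w), sides = 1)
  hit <- which(!is.na(runlen) & runlen == w)
  if (!length(hit)) return(.reject(fam_id, "min_length",
                                   "no gap-free window after trimming"))
  lo <- min(hit) - w + 1L
  hi <- max(hit)
  keep_cols <- orig_cols >= lo & orig_cols <= hi
  aln <- aln[, keep_cols, drop = FALSE]
  resi <- resi[, keep_cols, drop = FALSE]

  # (ii) identity filter: a sequence needs at least one close partner
  n <- nrow(aln)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idm[i, j] <- idm[j, i] <- .gapped_identity(aln[i, ], aln[j, ], cfg$identity_on)
  }
  diag(idm) <- NA
  best <- apply(idm, 1L, max, na.rm = TRUE)
  keep <- best >= cfg$min_identity
  aln <- aln[keep, , drop = FALSE]
  resi <- resi[keep, , drop = FALSE]
  members <- members[keep, , drop = FALSE]
  if (nrow(aln) == 0L) return(.reject(fam_id, "min_identity", "all sequences removed"))

  # (iii) gap-inflation: greedily drop the single worst offender and recompute
  repeat {
    if (nrow(aln) < 2L) break
    L_with <- .ungapped_length(aln)
    ratio <- vapply(seq_len(nrow(aln)), function(s) {
      L_wo <- .ungapped_length(aln[-s, , drop = FALSE])
      if (L_wo == 0L) 0 else (L_wo - L_with) / L_wo
    }, numeric(1))
    worst <- which.max(ratio)
    if (ratio[worst] <= cfg$gap_inflation_factor) break
    aln <- aln[-worst, , drop = FALSE]
    resi <- resi[-worst, , drop = FALSE]
    members <- members[-worst, , drop = FALSE]
  }

  # (iv) drop all remaining gap columns
  keep_cols <- colSums(aln == "-") == 0L
  aln <- aln[, keep_cols, drop = FALSE]
  resi <- resi[, keep_cols, drop = FALSE]

  # (v) family-level thresholds
  if (nrow(aln) < cfg$min_members) return(.reject(fam_id, "min_members"))
  if (ncol(aln) < cfg$min_length) return(.reject(fam_id, "min_length"))

  new_aligned_family(fam_id, aln, members, resi)
}

# Construct an aligned_family from a gapless matrix plus per-cell residue
# indices into each member's original sequence.
new_aligned_family <- function(family_id, mat, members, resi = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(members))
  if (is.null(resi)) resi <- matrix(rep(seq_len(ncol(mat)), each = nrow(mat)),
                                    nrow = nrow(mat))
  col_map <- matrix(NA_integer_, nrow(mat), ncol(mat),
                    dimnames = list(rownames(mat), NULL))
  for (i in seq_len(nrow(mat))) {
    if (members$strand[i] == "+") {
      col_map[i, ] <- members$start[i] + resi[i, ] - 1L
    } else {
      col_map[i, ] <- members$end[i] - resi[i, ]
    }
  }
  fam <- structure(list(
    family_id = family_id,
    members = members,
    matrix = mat,
    col_map = col_map,
    length = ncol(mat),
    mean_identity = mean_family_identity(mat)
  ), class = "aligned_family")
  fam
}

#' Mean pairwise identity of a gapless alignment matrix
#' @param mat character matrix, rows = sequences.
#' @return mean over all sequence pairs of the fraction of matching columns.
#' @export
mean_family_identity <- function(mat) {
  if (inherits(mat, "aligned_family")) mat <- mat$matrix
  n <- nrow(mat)
  if (n < 2L) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + mean(mat[i, ] == mat[j, ])
  tot / choose(n, 2)
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family> %s: %d sequences x %d bp, mean identity %.3f\n",
              x$family_id, nrow(x$matrix), x$length, x$mean_identity))
  invisible(x)
}

#' Remove hypermutable CpG dinucleotide columns
#'
#' Deletes every alignment column that participates in a `C` immediately
#' followed by `G` on the forward strand in any member (both columns of each
#' dinucleotide are removed, unioned over members). CpG sites mutate at a
#' greatly elevated rate and are the dominant source of coincident parallel
#' substitutions, so reticulate-site analyses are replicated on this view.
#'
#' @param fam an `aligned_family`.
#' @return the `aligned_family` restricted to CpG-free columns, with
#'   coordinate maps updated; attribute `cpg_stripped` set to `TRUE`.
#' @export
strip_cpg <- function(fam) {
  stopifnot(inherits(fam, "aligned_family"))
  m <- fam$matrix
  L <- ncol(m)
  if (L >= 2L) {
    cg <- (m[, -L, drop = FALSE] == "C") & (m[, -1L, drop = FALSE] == "G")
    first <- which(colSums(cg) > 0L)
    drop <- unique(c(first, first + 1L))
  } else drop <- integer(0)
  if (length(drop)) {
    keep <- setdiff(seq_len(L), drop)
    fam$matrix <- m[, keep, drop = FALSE]
    fam$col_map <- fam$col_map[, keep, drop = FALSE]
    fam$length <- length(keep)
    fam$mean_identity <- mean_family_identity(fam$matrix)
  }
  attr(fam, "cpg_stripped") <- TRUE
  fam
}

#' Read a gapped multi-FASTA alignment
#' @param path FASTA file; gap character `-`.
#' @return character matrix (rows = sequences).
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  strings_to_matrix(stats::setNames(toupper(as.character(ss)), names(ss)))
}

#' Write an alignment (or aligned_family) as multi-FASTA
#' @param x character matrix or `aligned_family`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(x, path) {
  if (inherits(x, "aligned_family")) x <- x$matrix
  ss <- Biostrings::BStringSet(matrix_to_strings(x))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
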