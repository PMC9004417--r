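#' Construct a validated allele-count matrix
#'
#' The raw input of the pipeline: one row per clone x site with read counts
#' for the four bases, a flag for a candidate indel within 3 bp, and a
#' per-site quality score. Coordinates are 1-based on a circular reference.
#'
#' @param df data.frame with columns `clone_id`, `population_id`, `site`,
#'   `A`, `C`, `G`, `T`, `indel_within_3bp`, `site_quality`.
#' @param reference_length optional length of the circular reference; when
#'   given, sites outside `[1, reference_length]` are rejected.
#' @return data.frame of class `allele_counts` with an added `coverage`
#'   column (the row sum of the four base counts).
#' @export
allele_counts <- function(df, reference_length = NULL) {
  required <- c("clone_id", "population_id", "site", BASES,
                "indel_within_3bp", "site_quality")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("allele-count table is missing columns: ",
         paste(missing, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$clone_id <- as.character(df$clone_id)
  df$population_id <- as.character(df$population_id)
  df$site <- as.integer(df$site)
  for (b in BASES) df[[b]] <- as.integer(df[[b]])
  df$indel_within_3bp <- as.logical(df$indel_within_3bp)
  df$site_quality <- as.numeric(df$site_quality)

  cnt <- as.matrix(df[BASES])
  bad <- which(rowSums(is.na(cnt)) > 0 | rowSums(cnt < 0) > 0)
  if (length(bad) > 0L)
    stop("negative or missing base counts at row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  if (anyNA(df$site) || any(df$site < 1L))
    stop("sites must be positive 1-based integers; offending row(s): ",
         paste(head(which(is.na(df$site) | df$site < 1L), 5L), collapse = ", "))
  if (!is.null(reference_length) && any(df$site > reference_length))
    stop("site beyond reference length ", reference_length,
         " at row(s) ", paste(head(which(df$site > reference_length), 5L),
                              collapse = ", "))
  if (anyNA(df$site_quality) || any(df$site_quality < 0))
    stop("site_quality must be non-negative")
  key <- paste(df$clone_id, df$site, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (clone, site) record at row(s) ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "))

  df$coverage <- as.integer(rowSums(cnt))
  attr(df, "reference_length") <- reference_length
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Read an allele-count table from a tab-separated file
#'
#' Expects a header line `clone_id population_id site A C G T
#' indel_within_3bp site_quality`. Rows are validated and `coverage` is
#' computed; malformed rows raise an error naming the offending row.
#'
#' @inheritParams allele_counts
#' @param path path to the TSV file.
#' @return an [allele_counts()] data.frame.
#' @export
read_allele_counts <- function(path, reference_length = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  allele_counts(df, reference_length = reference_length)
}

#' Write an allele-count table as TSV
#' @param x an [allele_counts()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(x, path) {
  cols <- c("clone_id", "population_id", "site", BASES,
            "indel_within_3bp", "site_quality")
  write.table(as.data.frame(x)[cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interval mask on the circular reference
#'
#' Intervals are 1-based and inclusive; a feature that wraps the origin is
#' represented as two intervals. Used to drop Numt-contaminated regions and
#' the D-loop before downstream analyses.
#'
#' @param start,end integer vectors of interval bounds (inclusive).
#' @param label one of `"numt"`, `"dloop"`, `"other"` (recycled).
#' @return data.frame of class `interval_mask`.
#' @export
interval_mask <- function(start, end, label = "other") {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (length(start) > 0 && (any(start < 1L) || any(end < start)))
    stop("mask intervals must satisfy 1 <= start <= end")
  label <- rep_len(as.character(label), length(start))
  if (!all(label %in% c("numt", "dloop", "other")))
    stop("mask label must be numt, dloop or other")
  out <- data.frame(start = start, end = end, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("interval_mask", "data.frame")
  out
}

#' Read a BED mask and convert to 1-based inclusive coordinates
#'
#' BED is 0-based, half-open; internally the package uses 1-based inclusive
#' positions, so an interval `(chromStart, chromEnd)` becomes
#' `[chromStart + 1, chromEnd]`.
#'
#' @param path path to a BED file (first three columns used; an optional
#'   fourth column is taken as the mask label).
#' @return an [interval_mask()].
#' @export
read_mask_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns")
  label <- if (ncol(bed) >= 4L) bed[[4L]] else "other"
  label[!label %in% c("numt", "dloop", "other")] <- "other"
  interval_mask(as.integer(bed[[2L]]) + 1L, as.integer(bed[[3L]]), label)
}

#' Remove allele-count records whose site falls in a mask
#'
#' All records with `site` inside any mask interval are dropped; all other
#' records are untouched. Masking is idempotent.
#'
#' @param x an [allele_counts()] data.frame.
#' @param mask an [interval_mask()].
#' @return the masked `allele_counts`.
#' @export
apply_site_mask <- function(x, mask) {
  stopifnot(inherits(x, "allele_counts"), inherits(mask, "interval_mask"))
  L <- attr(x, "reference_length")
  if (!is.null(L) && nrow(mask) > 0 && any(mask$end > L))
    stop("mask interval beyond reference length ", L)
  if (nrow(mask) == 0L || nrow(x) == 0L) return(x)
  drop <- sites_in_mask(x$site, mask)
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_length") <- L
  class(out) <- class(x)
  out
}

#' Which sites fall inside a mask?
#' @param sites integer vector of 1-based positions.
#' @param mask an [interval_mask()].
#' @return logical vector parallel to `sites`.
#' @export
sites_in_mask <- function(sites, mask) {
  inside <- rep(FALSE, length(sites))
  for (k in seq_len(nrow(mask)))
    inside <- inside | (sites >= mask$start[k] & sites <= mask$end[k])
  inside
}

#' Gene annotation on the circular reference
#'
#' Coding intervals with strand, reading-frame offset and NCBI genetic-code
#' id (5 = invertebrate mitochondrial). The coding span after removing the
#' frame offset must be divisible by 3.
#'
#' @param df data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `frame`, `code`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  required <- c("gene_id", "start", "end", "strand", "frame", "code")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[required]
  df$gene_id <- as.character(df$gene_id)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  df$frame <- as.integer(df$frame)
  df$code <- as.character(df$code)
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("annotation intervals must satisfy 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be + or -")
  span <- df$end - df$start + 1L - df$frame
  bad <- which(span %% 3L != 0L)
  if (length(bad) > 0L)
    stop("coding span not divisible by 3 for gene(s): ",
         paste(df$gene_id[bad], collapse = ", "))
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read gene annotation from TSV or GFF3 CDS lines
#'
#' A tab-separated table with header `gene_id start end strand frame code`
#' is read directly; a GFF3 file is recognized by its `##gff` pragma or
#' nine-column layout, and its `CDS` features are used (`ID`/`gene_id`
#' attribute, `phase` column as the frame, `transl_table` attribute as the
#' code, defaulting to 5).
#'
#' @param path input path.
#' @return a [gene_annotation()].
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##gff", first) ||
      length(strsplit(first, "\t", fixed = TRUE)[[1L]]) == 9L) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) == 9L]
    f <- f[vapply(f, function(x) x[3L] == "CDS", TRUE)]
    if (length(f) == 0L) stop("no CDS features in GFF3 file")
    attr_get <- function(a, key, default) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))[[1L]]
      if (length(m) == 2L) m[2L] else default
    }
    df <- data.frame(
      gene_id = vapply(f, function(x)
        attr_get(x[9L], "ID", attr_get(x[9L], "gene_id", x[1L])), ""),
      start = vapply(f, function(x) as.integer(x[4L]), 1L),
      end = vapply(f, function(x) as.integer(x[5L]), 1L),
      strand = vapply(f, function(x) x[7L], ""),
      frame = vapply(f, function(x)
        if (x[8L] %in% c(".", "")) 0L else as.integer(x[8L]), 1L),
      code = vapply(f, function(x) attr_get(x[9L], "transl_table", "5"), ""),
      stringsAsFactors = FALSE)
    gene_annotation(df)
  } else {
    gene_annotation(read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
  }
}

#' Write gene annotation as TSV
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(as.data.frame(ann), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A set of aligned full-length haplotype sequences
#'
#' Sequences are equal-length strings over `{A,C,G,T,N}` (N marks ambiguous
#' or low-depth positions and is excluded from all pairwise statistics).
#' Each sequence carries a clone id, a population id and a role among
#' `major`, `minor`, `consensus`.
#'
#' @param sequences character vector of equal-length base strings.
#' @param clone_id,population_id,role label vectors parallel to `sequences`.
#' @return list of class `haplotype_set` with elements `seq`, `info`
#'   (data.frame of labels) and `L` (reference length).
#' @export
haplotype_set <- function(sequences, clone_id, population_id,
                          role = "consensus") {
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  clone_id <- rep_len(as.character(clone_id), n)
  population_id <- rep_len(as.character(population_id), n)
  role <- rep_len(as.character(role), n)
  if (!all(role %in% c("major", "minor", "consensus")))
    stop("role must be major, minor or consensus")
  lens <- nchar(sequences)
  if (n > 0L && length(unique(lens)) != 1L)
    stop("all haplotype sequences must have the same length")
  if (n > 0L && grepl("[^ACGTN]", paste(sequences, collapse = "")))
    stop("haplotype alphabet restricted to A, C, G, T, N")
  structure(list(
    seq = sequences,
    info = data.frame(clone_id = clone_id, population_id = population_id,
                      role = role, stringsAsFactors = FALSE),
    L = if (n > 0L) lens[1L] else 0L),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$seq), "sequence(s) of length", x$L, "\n")
  if (length(x$seq) > 0L) print(head(x$info))
  invisible(x)
}

#' @export
length.haplotype_set <- function(x) length(x$seq)

#' Subset a haplotype set
#' @param x a [haplotype_set()].
#' @param i index vector (logical or integer over sequences).
#' @param ... unused.
#' @return a `haplotype_set`.
#' @export
`[.haplotype_set` <- function(x, i, ...) {
  haplotype_set(x$seq[i], x$info$clone_id[i], x$info$population_id[i],
                x$info$role[i])
}

#' Read haplotypes from FASTA
#'
#' Headers are expected to carry `clone|population|role` tokens; missing
#' tokens default to the full header as clone id, population `"NA"` and role
#' `"consensus"`.
#'
#' @param path FASTA path.
#' @return a [haplotype_set()].
#' @export
read_haplotypes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  toks <- strsplit(names(ss), "|", fixed = TRUE)
  getter <- function(k, default) vapply(toks, function(t)
    if (length(t) >= k) t[k] else default, "")
  haplotype_set(as.character(ss),
                clone_id = getter(1L, "hap"),
                population_id = ifelse(nzchar(getter(2L, "")),
                                       getter(2L, ""), "NA"),
                role = ifelse(nzchar(getter(3L, "")),
                              getter(3L, ""), "consensus"))
}

#' Write haplotypes as FASTA with `clone|population|role` headers
#' @param haps a [haplotype_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haps, path) {
  ss <- Biostrings::DNAStringSet(haps$seq)
  names(ss) <- paste(haps$info$clone_id, haps$info$population_id,
                     haps$info$role, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
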