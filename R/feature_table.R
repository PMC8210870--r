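#' Construct a genus-level count table with sample metadata
#'
#' Bundles a samples x taxa matrix of non-negative integer counts with the
#' per-sample metadata required by the downstream era analysis. Taxon labels
#' are genus names, or family/order fallbacks prefixed `f__` / `o__` when the
#' genus is inconclusive; they are treated as opaque strings.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   rownames (sample ids) and colnames (taxon labels).
#' @param metadata data.frame with columns `sample_id`, `patient_id`, `era`
#'   (exactly `"pre"` or `"covid"`), `admission_day`, `collection_day`
#'   (integers; day 0 is the first day of chemotherapy). One row per sample.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `metadata` (data.frame aligned to the matrix rows).
#' @export
count_table <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  req <- c("sample_id", "patient_id", "era", "admission_day", "collection_day")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  absent <- setdiff(rownames(counts), metadata$sample_id)
  if (length(absent))
    stop("no metadata for sample(s): ", paste(absent, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$era %in% c("pre", "covid")))
    stop("era must be exactly 'pre' or 'covid'")
  if (any(metadata$collection_day < metadata$admission_day))
    stop("collection day before admission day for sample(s): ",
         paste(metadata$sample_id[metadata$collection_day < metadata$admission_day],
               collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (%d pre, %d covid)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$metadata$era == "pre"), sum(x$metadata$era == "covid")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table and its sample metadata from TSV files
#'
#' The count TSV may be taxon-major (BIOM-style export: first header field
#' `#OTU ID`, taxa in rows, samples in columns) or sample-major (first column
#' `sample_id`, taxa in columns); the orientation is auto-detected from the
#' header sentinel. The metadata TSV must contain the columns
#' `sample_id, patient_id, era, admission_day, collection_day`.
#'
#' @param table_path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return A [count_table].
#' @export
read_count_table <- function(table_path, metadata_path) {
  header <- strsplit(readLines(table_path, n = 1), "\t", fixed = TRUE)[[1]]
  tab <- utils::read.delim(table_path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (grepl("OTU ID", header[1], fixed = TRUE) || header[1] == "taxon") {
    rownames(m) <- tab[[1]]
    m <- t(m)                       # -> samples x taxa
  } else {
    rownames(m) <- tab[[1]]
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  count_table(m, meta)
}

#' Write a count table to TSV files
#'
#' Writes the counts in the taxon-major BIOM-style dialect (`#OTU ID` header)
#' read back by [read_count_table()], and the metadata alongside.
#'
#' @param x a [count_table].
#' @param table_path,metadata_path output paths.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, table_path, metadata_path) {
  tm <- t(x$counts)
  df <- data.frame(`#OTU ID` = rownames(tm), tm, check.names = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Filter low-depth samples and rare taxa
#'
#' Samples with fewer than `min_sample_reads` total reads are removed first;
#' then taxa whose total count across the retained samples is strictly below
#' `min_taxon_frac` of the retained grand total are removed. A taxon sitting
#' exactly at the threshold is kept (strict `<`). Set `samples_first = FALSE`
#' to apply the taxon filter before the sample filter as a sensitivity check.
#'
#' @param x a [count_table].
#' @param min_sample_reads minimum per-sample read total (default 500).
#' @param min_taxon_frac minimum taxon frequency as a fraction of all reads
#'   (default 1e-4, i.e. 0.01%).
#' @param samples_first apply the sample filter before the taxon filter
#'   (default TRUE).
#' @return The filtered [count_table].
#' @export
filter_table <- function(x, min_sample_reads = 500, min_taxon_frac = 1e-4,
                         samples_first = TRUE) {
  stopifnot(inherits(x, "count_table"))
  drop_samples <- function(m) m[rowSums(m) >= min_sample_reads, , drop = FALSE]
  drop_taxa <- function(m) {
    thr <- min_taxon_frac * sum(m)
    m[, colSums(m) >= thr, drop = FALSE]   # strict "<" removal: keep ties
  }
  m <- x$counts
  m <- if (samples_first) drop_taxa(drop_samples(m)) else drop_samples(drop_taxa(m))
  if (nrow(m) == 0) stop("all samples removed by filtering")
  meta <- x$metadata[match(rownames(m), x$metadata$sample_id), , drop = FALSE]
  count_table(m, meta)
}

#' Centered log-ratio transform of a count table
#'
#' Per sample, with pseudocounted counts c, computes
#' `x_i = log(c_i + pseudocount) - mean_j log(c_j + pseudocount)`, so every
#' row sums to zero. The clr scale is where all abundance statistics in this
#' package operate.
#'
#' @param x a [count_table] (non-empty).
#' @param pseudocount value added to every count before taking logs
#'   (default 1). Must be positive if any count is zero.
#' @return A `clr_matrix`: a numeric samples x taxa matrix with attributes
#'   `pseudocount` and `metadata` (the source table's metadata).
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "count_table"))
  if (nrow(x$counts) == 0 || ncol(x$counts) == 0) stop("empty count table")
  if (pseudocount <= 0 && any(x$counts == 0))
    stop("pseudocount must be > 0 when zero counts are present")
  lg <- log(x$counts + pseudocount)
  m <- lg - rowMeans(lg)
  structure(m, pseudocount = pseudocount, metadata = x$metadata,
            class = c("clr_matrix", class(m)))
}

#' Aitchison distance between samples
#'
#' The Aitchison distance is the Euclidean distance between clr-transformed
#' compositions.
#'
#' @param m a clr matrix (samples x taxa), at least 2 rows.
#' @return A [stats::dist] object.
#' @export
aitchison_distance <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 samples")
  stats::dist(unclass(m), method = "euclidean")
}
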