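#' OTU count table with per-sample metadata
#'
#' A `count_table` bundles an OTU x sample matrix of read counts with the
#' sample metadata the downstream analyses need: which subject (mother-child
#' dyad) the sample belongs to, which compartment it was taken from
#' (`vaginal`, `feces` or `airway`) and at which timepoint (`w24`, `w36`,
#' `birth` for vaginal samples, `week1` for the child compartments).
#'
#' @param counts numeric matrix, OTUs in rows, samples in columns. All
#'   entries must be nonnegative integers. Row and column names are used as
#'   OTU and sample ids and must be unique.
#' @param metadata data.frame with one row per sample and at least the
#'   columns `sample_id`, `subject_id`, `compartment`, `timepoint`.
#'   Additional columns (e.g. `delivery_mode`) are carried along untouched.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix) and `metadata` (data.frame aligned to the
#'   columns of `counts`).
#' @export
count_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have OTU row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate OTU id: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop("duplicate sample id: ", dup)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative and non-missing")
  }
  if (any(counts != round(counts))) {
    bad <- rownames(counts)[which(rowSums(counts != round(counts)) > 0)][1L]
    stop("non-integer count in OTU: ", bad)
  }
  storage.mode(counts) <- "double"
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "compartment", "timepoint")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         metadata$sample_id[duplicated(metadata$sample_id)][1L])
  }
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent)) {
    stop("sample missing from metadata: ", absent[1L])
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (any(is.na(metadata[req]))) stop("incomplete metadata")
  bad_comp <- setdiff(unique(metadata$compartment), c("vaginal", "feces", "airway"))
  if (length(bad_comp)) stop("unknown compartment: ", bad_comp[1L])
  bad_tp <- setdiff(unique(metadata$timepoint), c("w24", "w36", "birth", "week1"))
  if (length(bad_tp)) stop("unknown timepoint: ", bad_tp[1L])
  vag <- metadata$compartment == "vaginal"
  if (any(vag & !metadata$timepoint %in% c("w24", "w36", "birth")) ||
      any(!vag & metadata$timepoint != "week1")) {
    stop("compartment/timepoint mismatch: vaginal samples must be w24/w36/birth, ",
         "child compartments week1")
  }
  structure(list(counts = counts, metadata = metadata), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$metadata$compartment, x$metadata$timepoint)
  print(tab)
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' OTU and sample accessors
#'
#' @param x a `count_table` or `composition_table`.
#' @return character vectors of ids, or numeric sample depths.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname otu_ids
#' @export
sample_depths <- function(x) colSums(x$counts)

#' Subset samples of a count table
#'
#' @param x a `count_table`.
#' @param samples character vector of sample ids (order respected) or a
#'   logical/integer index over samples.
#' @param drop_empty_otus drop OTUs with zero counts in the retained samples.
#' @return a `count_table` restricted to the requested samples.
#' @export
subset_samples <- function(x, samples, drop_empty_otus = FALSE) {
  if (is.character(samples)) {
    miss <- setdiff(samples, sample_ids(x))
    if (length(miss)) stop("unknown sample id: ", miss[1L])
    idx <- match(samples, sample_ids(x))
  } else {
    idx <- seq_len(ncol(x$counts))[samples]
  }
  counts <- x$counts[, idx, drop = FALSE]
  md <- x$metadata[idx, , drop = FALSE]
  rownames(md) <- NULL
  if (drop_empty_otus) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  out <- list(counts = counts, metadata = md)
  class(out) <- class(x)
  out
}

#' Read an OTU count table and its sample metadata
#'
#' The TSV dialect is the usual QIIME-style flat table: first header field
#' `#OTU_ID`, remaining header fields sample ids, one row per OTU. Metadata
#' is a companion TSV with columns `sample_id`, `subject_id`, `compartment`,
#' `timepoint`. A BIOM file (JSON or HDF5) can be read instead through the
#' biomformat package.
#'
#' @param path path to the count TSV (or BIOM file).
#' @param metadata_path path to the metadata TSV.
#' @param format `"tsv"` or `"biom"`.
#' @return a validated [count_table()].
#' @export
read_count_table <- function(path, metadata_path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
  }
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  count_table(counts, metadata)
}

#' Write a count table (and metadata) as TSV
#'
#' @param x a `count_table` or `composition_table`.
#' @param path output path for the count TSV.
#' @param metadata_path optional output path for the metadata TSV.
#' @export
write_count_table <- function(x, path, metadata_path = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#OTU_ID", colnames(x$counts)), collapse = "\t"), con)
  utils::write.table(x$counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  if (!is.null(metadata_path)) {
    write_tsv_lf(x$metadata, metadata_path)
  }
  invisible(x)
}

# TSV writer with LF endings and no quoting, used by all exporters
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' @param path TSV with columns `otu_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`. Empty strings or NA mark unassigned ranks.
#' @return data.frame of class `taxonomy`.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxonomy(tax)
}

#' Construct/validate a taxonomy table
#'
#' @param tax data.frame with `otu_id` plus the six ranks kingdom..genus.
#' @return the validated data.frame, class `taxonomy`.
#' @export
taxonomy <- function(tax) {
  req <- c("otu_id", tax_ranks())
  miss <- setdiff(req, names(tax))
  if (length(miss)) stop("taxonomy missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$otu_id)) stop("duplicate otu_id in taxonomy")
  for (r in tax_ranks()) {
    v <- as.character(tax[[r]])
    v[is.na(v)] <- ""
    tax[[r]] <- v
  }
  class(tax) <- c("taxonomy", "data.frame")
  tax
}

tax_ranks <- function() c("kingdom", "phylum", "class", "order", "family", "genus")
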