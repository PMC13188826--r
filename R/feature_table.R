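#' Construct a feature table
#'
#' A feature table is the package's basic container: a numeric matrix of
#' non-negative abundances with features (species, OTUs or metabolites) in
#' rows and samples in columns, tagged with the omics layer it came from.
#'
#' @param mat Numeric matrix, features x samples, non-negative, with unique
#'   row and column names.
#' @param layer Layer tag, one of `"MG"` (metagenome), `"MT"`
#'   (metatranscriptome), `"16S"` or `"metabolome"`.
#' @return A `feature_table`: the matrix with a `layer` attribute.
#' @examples
#' ft <- feature_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("sp1", "sp2"), c("s1", "s2", "s3"))), layer = "MG")
#' @export
feature_table <- function(mat, layer = c("MG", "MT", "16S", "metabolome")) {
  layer <- match.arg(layer)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("feature table requires feature (row) and sample (column) names")
  if (anyDuplicated(rownames(mat)))
    stop("duplicated feature id: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicated sample id: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (anyNA(mat)) stop("feature table contains missing values")
  if (any(mat < 0)) stop("feature table contains negative values")
  structure(mat, layer = layer, class = c("feature_table", "matrix", "array"))
}

#' Read a feature table from TSV or BIOM
#'
#' TSV layout: first column = feature id, remaining columns = samples.
#' BIOM files (classic JSON or HDF5, format 1.0/2.1) are read through the
#' biomformat package when available.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`.
#' @param layer Layer tag recorded on the returned table.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"), layer = "MG") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("parse error in ", path, ": need id column plus samples")
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop("parse error in ", path, ": non-numeric sample column '",
           names(df)[-1][bad], "'")
    }
    rownames(mat) <- ids
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    mat <- as.matrix(biomformat::biom_data(b))
  }
  feature_table(mat, layer = layer)
}

#' Write a feature table as TSV
#'
#' @param x A [feature_table()] or plain matrix.
#' @param path Output path.
#' @param id_col Name of the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expected columns: `sample_id`, `group`, and optionally the phenotypes
#' `BW` (body weight, g) and `AFW` (abdominal fat weight, g).  When both
#' phenotypes are present the abdominal fat percentage `AFP = AFW / BW` is
#' computed and appended.
#'
#' @param path TSV path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (all(c("BW", "AFW") %in% names(df))) df$AFP <- df$AFW / df$BW
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  cat("features:", paste(utils::head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) "..." else "", "\n")
  cat("samples: ", paste(utils::head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) "..." else "", "\n")
  invisible(x)
}
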