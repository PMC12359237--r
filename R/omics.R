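#' Assemble a multi-omics dataset for flux prediction
#'
#' Samples-by-features container pairing omics measurements (transcripts,
#' proteins and measured input exchange fluxes, concatenated early into a
#' single feature matrix) with per-sample reference fluxes and the measured
#' input fluxes used as mechanistic upper bounds.
#'
#' @param features numeric matrix, samples x din, with column names;
#'   expression in arbitrary units, fluxes in mmol·gDW^-1·h^-1.
#' @param targets numeric matrix, samples x k, reference fluxes with target
#'   labels as column names.
#' @param vin numeric matrix, samples x nin, measured input exchange fluxes
#'   (e.g. glucose and oxygen uptake); may have zero columns.
#' @param metadata optional data.frame of per-sample annotations (strain
#'   label, knockout target, dilution rate, ...).
#' @return object of class `omics_dataset`.
#' @export
omics_dataset <- function(features, targets, vin = NULL, metadata = NULL) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (is.null(vin)) vin <- matrix(0, nrow(features), 0)
  vin <- as.matrix(vin)
  if (is.null(colnames(features))) stop("features must have column names")
  if (is.null(colnames(targets))) stop("targets must have column names")
  if (nrow(targets) != nrow(features) || nrow(vin) != nrow(features))
    stop("features, targets and vin must have the same number of samples")
  if (anyNA(features) || anyNA(targets) || anyNA(vin))
    stop("missing values are not allowed")
  overlap <- intersect(colnames(features), colnames(targets))
  if (length(overlap))
    stop("feature and target labels must be disjoint: ",
         paste(overlap, collapse = ", "))
  if (is.null(rownames(features)))
    rownames(features) <- paste0("sample_", seq_len(nrow(features)))
  rownames(targets) <- rownames(features)
  if (ncol(vin)) rownames(vin) <- rownames(features)
  if (is.null(metadata))
    metadata <- data.frame(sample = rownames(features), stringsAsFactors = FALSE)
  structure(list(features = features, targets = targets, vin = vin,
                 metadata = metadata),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("Multi-omics dataset:", nrow(x$features), "samples x",
      ncol(x$features), "features;", ncol(x$targets), "reference fluxes;",
      ncol(x$vin), "measured input fluxes\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) c(nrow(x$features), ncol(x$features))

# row subset preserving structure
.subset_samples <- function(dataset, idx) {
  omics_dataset(dataset$features[idx, , drop = FALSE],
                dataset$targets[idx, , drop = FALSE],
                dataset$vin[idx, , drop = FALSE],
                dataset$metadata[idx, , drop = FALSE])
}

#' Write an omics dataset as three CSV tables
#'
#' Emits `<prefix>_features.csv`, `<prefix>_targets.csv` and
#' `<prefix>_vin.csv` (plus `<prefix>_metadata.csv`), each with the sample
#' id as first column, the layout [read_omics_tables()] expects.
#' @param dataset an `omics_dataset`.
#' @param prefix path prefix for the output files.
#' @return the file paths, invisibly.
#' @export
write_omics_tables <- function(dataset, prefix) {
  out <- character(0)
  tabs <- list(features = dataset$features, targets = dataset$targets,
               vin = dataset$vin)
  for (nm in names(tabs)) {
    f <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(data.frame(sample = rownames(dataset$features),
                                tabs[[nm]], check.names = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    out <- c(out, f)
  }
  f <- paste0(prefix, "_metadata.csv")
  utils::write.csv(dataset$metadata, f, row.names = FALSE, quote = FALSE)
  invisible(c(out, f))
}

#' Read an omics dataset from feature/target/input CSV tables
#'
#' Joins the tables on their first (sample id) column and validates
#' completeness: every sample must appear in every table and no cell may
#' be missing.
#'
#' @param features_csv,targets_csv CSV paths (first column: sample id).
#' @param vin_csv optional CSV of measured input exchange fluxes.
#' @param metadata_csv optional CSV of sample annotations.
#' @return an `omics_dataset`.
#' @export
read_omics_tables <- function(features_csv, targets_csv, vin_csv = NULL,
                              metadata_csv = NULL) {
  rd <- function(f) {
    d <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    storage.mode(m) <- "double"
    m
  }
  X <- rd(features_csv)
  Y <- rd(targets_csv)
  ids <- rownames(X)
  check_ids <- function(m, what) {
    miss <- c(setdiff(ids, rownames(m)), setdiff(rownames(m), ids))
    if (length(miss))
      stop("sample ids of ", what, " do not match the feature table: ",
           paste(unique(miss), collapse = ", "))
    m[ids, , drop = FALSE]
  }
  Y <- check_ids(Y, "targets")
  Vin <- if (!is.null(vin_csv)) check_ids(rd(vin_csv), "vin") else NULL
  meta <- NULL
  if (!is.null(metadata_csv)) {
    meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
    if (nrow(meta) != length(ids)) stop("metadata row count mismatch")
  }
  if (anyNA(X) || anyNA(Y) || (!is.null(Vin) && anyNA(Vin)))
    stop("missing cells in input tables")
  omics_dataset(X, Y, Vin, meta)
}
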