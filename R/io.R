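## Delimited-text readers/writers for omics, survival and clinical tables,
## plus cohort alignment.  Xena-style matrices ship features as rows, so
## that orientation is the default.

.missingMarkers <- c("NA", "NaN", "nan", "", "null", "NULL", "N/A")

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = .missingMarkers,
                   comment.char = "")
  if (!nrow(df) || ncol(df) < 2L)
    stop("no data rows/columns in ", path)
  df
}

#' Read a delimited omics matrix
#'
#' Reads a TSV/CSV matrix with one header row and one leading ID column into
#' an [OmicsLayer-class] in canonical samples x features orientation.  The
#' default orientation follows the UCSC Xena convention of features as rows.
#' Duplicate feature IDs are de-duplicated deterministically (first
#' occurrence kept, the rest dropped with a warning); duplicate sample IDs
#' are an error because they would make the survival join ambiguous.
#' Missing-value markers `NA`, `NaN`, `null` and the empty string are read
#' as missing; any other non-numeric cell is a hard error naming the cell.
#'
#' @param path path to a TSV (default) or CSV (by `.csv` extension) file.
#' @param layerKind omics modality, see [OmicsLayer()].
#' @param orientation `"features_as_rows"` (Xena convention, default) or
#'   `"samples_as_rows"`.
#' @return An [OmicsLayer-class]; entries may be `NA` until
#'   [dropMissing()] is applied.
#' @export
readOmicsMatrix <- function(path, layerKind = "other",
                            orientation = c("features_as_rows",
                                            "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- .readTable(path)
  ids <- as.character(df[[1L]])
  hdr <- names(df)[-1L]          # before subsetting, which uniquifies
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("unparseable numeric cell at row '%s', column '%s' in %s",
                     ids[bad[1L]], names(body)[j], path))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, hdr)
  if (orientation == "features_as_rows") m <- t(m)
  ## now samples x features
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample IDs in ", path,
         ": survival joins would be ambiguous")
  dup <- duplicated(colnames(m))
  if (any(dup)) {
    warning(sprintf("%d duplicate feature ID(s) dropped (kept first): %s",
                    sum(dup),
                    paste(head(unique(colnames(m)[dup]), 5L),
                          collapse = ", ")))
    m <- m[, !dup, drop = FALSE]
  }
  OmicsLayer(m, layerKind)
}

#' Write an omics layer to delimited text
#'
#' Inverse of [readOmicsMatrix()]: round-tripping reproduces values to
#' better than 1e-12 (full double precision is written).
#'
#' @param layer an [OmicsLayer-class].
#' @param path output path; `.csv` extension selects comma separation.
#' @param orientation see [readOmicsMatrix()].
#' @param idColumn name for the leading ID column.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(layer, path,
                             orientation = c("features_as_rows",
                                             "samples_as_rows"),
                             idColumn = "id") {
  orientation <- match.arg(orientation)
  m <- as.matrix(layer)
  if (orientation == "features_as_rows") m <- t(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(idColumn, colnames(m))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `sample`, `time` (follow-up, days) and `event`
#' (1 = death observed, 0 = censored).  Rows with missing time or event are
#' kept here and removed by [alignCohort()].
#'
#' @param path TSV/CSV path.
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
readSurvivalTable <- function(path) {
  df <- .readTable(path)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns sample, time, event")
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample[!is.na(df$sample)]))
    stop("duplicate sample IDs in survival table")
  df[, need]
}

#' Read a clinical covariate table
#'
#' `sample` plus arbitrary categorical columns; missing markers become
#' `NA`, never silently coerced to a level.
#'
#' @param path TSV/CSV path.
#' @return data.frame with character covariate columns.
#' @export
readClinicalTable <- function(path) {
  df <- .readTable(path)
  if (!"sample" %in% names(df))
    stop("clinical table must have a 'sample' column")
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample IDs in clinical table")
  for (j in setdiff(names(df), "sample"))
    df[[j]] <- as.character(df[[j]])
  df
}

#' Drop features with missing values
#'
#' Removes every feature column that contains at least one undefined entry;
#' the sample set is unchanged.  Mirrors the preprocessing rule of removing
#' biological features with missing values layer-wise.
#'
#' @param layer an [OmicsLayer-class].
#' @return An [OmicsLayer-class] with complete columns only.
#' @export
dropMissing <- function(layer) {
  stopifnot(is(layer, "OmicsLayer"))
  m <- as.matrix(layer)
  keep <- colSums(!is.finite(m)) == 0L
  if (!any(keep))
    stop("all features contain missing values; layer '",
         layerKind(layer), "' is unusable")
  OmicsLayer(m[, keep, drop = FALSE], layerKind(layer))
}

#' Align omics layers, survival and clinical tables into one cohort
#'
#' Restricts all tables to the intersection of their sample sets, removes
#' samples with missing survival time or event, and canonicalizes the
#' sample order lexicographically so that downstream seeded computations
#' are reproducible regardless of input file order.  Aligning an already
#' aligned cohort is the identity.
#'
#' @param layers named list of [OmicsLayer-class] objects (names default to
#'   the layer kinds).
#' @param survival data.frame with columns `sample`, `time`, `event`.
#' @param clinical optional data.frame keyed by `sample`.
#' @return A [MultiOmicsCohort-class].
#' @export
alignCohort <- function(layers, survival, clinical = NULL) {
  if (is(layers, "OmicsLayer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, is, TRUE, class2 = "OmicsLayer")))
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    nm <- vapply(layers, layerKind, "")
    names(layers) <- make.unique(nm)
  }
  survival$sample <- as.character(survival$sample)
  surv <- survival[!is.na(survival$sample) & is.finite(survival$time) &
                     survival$event %in% c(0, 1), , drop = FALSE]
  common <- Reduce(intersect, c(lapply(layers, sampleIDs),
                                list(surv$sample)))
  if (!length(common)) {
    counts <- vapply(layers, function(l) length(sampleIDs(l)), 0L)
    stop("no samples shared by all layers and the survival table (",
         paste(sprintf("%s: %d", names(layers), counts), collapse = ", "),
         ", survival: ", nrow(surv), ")")
  }
  common <- sort(common)
  layers <- lapply(layers, function(l)
    OmicsLayer(as.matrix(l)[common, , drop = FALSE], layerKind(l)))
  surv <- surv[match(common, surv$sample), c("sample", "time", "event")]
  rownames(surv) <- NULL
  if (is.null(clinical)) {
    clin <- data.frame(sample = common, stringsAsFactors = FALSE)
  } else {
    clinical$sample <- as.character(clinical$sample)
    clin <- clinical[match(common, clinical$sample), , drop = FALSE]
    clin$sample <- common   # samples absent from the clinical file -> all-NA
    rownames(clin) <- NULL
  }
  new("MultiOmicsCohort", layers = layers, survival = surv, clinical = clin)
}

#' Fraction of censored samples in a cohort
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @return Proportion of samples with `event == 0`, in `[0, 1]`.
#' @export
empiricalCensoringRate <- function(cohort) {
  ev <- survivalData(cohort)$event
  mean(ev == 0)
}
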