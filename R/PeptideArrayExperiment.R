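#' Container for immunosignature peptide-array intensities
#'
#' \code{PeptideArrayExperiment} extends
#' \linkS4class{SummarizedExperiment} to hold a raw fluorescence
#' (RFU) matrix from an immunosignature experiment, with peptides as rows
#' (features) and serum samples as columns. Per-sample disease-group
#' labels live in \code{colData(x)$group}; per-peptide annotation
#' (\code{sequence}, \code{empty_spot}) lives in \code{rowData}. After
#' \code{\link{medianNormalizeLog10}} the object carries a second assay,
#' \code{"lognorm"}, with the per-sample scaling constants in
#' \code{colData(x)$norm_constant}.
#'
#' Scanner intensities are 16-bit, so raw values are expected in
#' [0, 65500]; validity requires finite, nonnegative values, unique
#' sample and peptide identifiers, and at least 2 samples and 3 peptides.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("PeptideArrayExperiment", contains = "SummarizedExperiment")

setValidity("PeptideArrayExperiment", function(object) {
  msg <- character()
  if (!"rfu" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rfu' is required")
  v <- SummarizedExperiment::assay(object, "rfu")
  if (ncol(v) < 2L) msg <- c(msg, "at least 2 samples are required")
  if (nrow(v) < 3L) msg <- c(msg, "at least 3 peptides are required")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "peptide ids must be present and unique")
  if (!all(is.finite(v))) msg <- c(msg, "all intensities must be finite")
  else if (any(v < 0)) msg <- c(msg, "intensities must be nonnegative")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (!"empty_spot" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain an 'empty_spot' column")
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideArrayExperiment
#'
#' @param values numeric matrix of raw fluorescence, samples x peptides
#'   (the orientation GenePix-derived tables use); it is stored
#'   transposed, peptides x samples, following the Bioconductor
#'   features-as-rows convention. Row names are sample ids, column names
#'   peptide ids.
#' @param groups character/factor of per-sample group labels (recycled
#'   \code{"unspecified"} if missing), or a named vector indexed by
#'   sample id.
#' @param sequences optional character vector of peptide sequences.
#' @param emptySpot optional logical vector flagging empty (no-peptide)
#'   spots used to gauge background; default all \code{FALSE}.
#' @return A validated \linkS4class{PeptideArrayExperiment}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
#' pae <- PeptideArrayExperiment(m, groups = c("normal", "single_tumor"))
#' @export
PeptideArrayExperiment <- function(values, groups = NULL, sequences = NULL,
                                   emptySpot = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("intensity values must be numeric")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (is.null(groups)) groups <- rep("unspecified", nrow(values))
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(values), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[rownames(values)]
  }
  if (length(groups) != nrow(values))
    stop("'groups' must have one label per sample")
  if (is.null(emptySpot)) emptySpot <- rep(FALSE, ncol(values))
  if (length(emptySpot) != ncol(values))
    stop("'emptySpot' must have one flag per peptide")
  if (is.null(sequences)) sequences <- rep(NA_character_, ncol(values))
  rd <- S4Vectors::DataFrame(sequence = as.character(sequences),
                             empty_spot = as.logical(emptySpot),
                             row.names = colnames(values))
  cd <- S4Vectors::DataFrame(group = as.character(groups),
                             row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rfu = t(values)), rowData = rd, colData = cd)
  methods::new("PeptideArrayExperiment", se)
}

setMethod("show", "PeptideArrayExperiment", function(object) {
  cat("PeptideArrayExperiment:", nrow(object), "peptides x",
      ncol(object), "samples\n")
  cat("  groups:",
      paste(sprintf("%s (%d)", names(table(groupLabels(object))),
                    table(groupLabels(object))), collapse = ", "), "\n")
  cat("  empty spots:", sum(emptySpots(object)), "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' Accessors for PeptideArrayExperiment components
#'
#' \code{rfu} returns the raw intensity matrix (peptides x samples);
#' \code{groupLabels} the per-sample disease group; \code{emptySpots} the
#' per-peptide empty-spot flag; \code{peptideSequences} the sequences;
#' \code{normalizedValues} the log10 median-normalized assay (error if
#' \code{\link{medianNormalizeLog10}} has not been run);
#' \code{normConstants} the per-sample scaling constants.
#'
#' @param x a \linkS4class{PeptideArrayExperiment}.
#' @return Matrix or vector as described.
#' @export
rfu <- function(x) SummarizedExperiment::assay(x, "rfu")

#' @rdname rfu
#' @export
groupLabels <- function(x) SummarizedExperiment::colData(x)$group

#' @rdname rfu
#' @export
emptySpots <- function(x) SummarizedExperiment::rowData(x)$empty_spot

#' @rdname rfu
#' @export
peptideSequences <- function(x) SummarizedExperiment::rowData(x)$sequence

#' @rdname rfu
#' @export
normalizedValues <- function(x) {
  if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
    stop("no 'lognorm' assay; run medianNormalizeLog10() first")
  SummarizedExperiment::assay(x, "lognorm")
}

#' @rdname rfu
#' @export
normConstants <- function(x) SummarizedExperiment::colData(x)$norm_constant

#' @rdname rfu
#' @export
isNormalized <- function(x)
  "lognorm" %in% SummarizedExperiment::assayNames(x)

.resolveLabelMap <- function(labelMap) {
  if (is.null(labelMap)) return(NULL)
  if (is.character(labelMap) && length(labelMap) == 1L && file.exists(labelMap)) {
    tab <- read.delim(labelMap, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("label map file must have two columns: sample id, group")
    # tolerate a header row
    if (any(tolower(tab[1, ]) %in% c("sample", "sample_id", "group")))
      tab <- tab[-1, , drop = FALSE]
    return(setNames(as.character(tab[[2]]), as.character(tab[[1]])))
  }
  if (is.null(names(labelMap)))
    stop("label map must be a named vector (sample -> group) or a TSV path")
  labelMap
}

.checkIntensityTable <- function(values, what = "intensity table") {
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: non-numeric/non-finite intensity at sample '%s', peptide '%s'",
                 what, rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s: negative intensity at sample '%s', peptide '%s'",
                 what, rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  invisible(TRUE)
}

#' Read an immunosignature intensity table
#'
#' Reads raw fluorescence data from a delimited table (samples as rows,
#' first column the sample id, peptides as the remaining columns) or from
#' GenePix-results (GPR) files, one array per file. The GPR dialect
#' skips the ATF-style header block and requires the columns
#' \code{Block}, \code{Row}, \code{Column}, \code{Name}, \code{ID} plus
#' one signal column (default \code{"F635 Median"}, the median
#' non-background-subtracted spot intensity).
#'
#' @param path file path (tsv/csv) or character vector of GPR files, one
#'   per sample.
#' @param format one of \code{"tsv"}, \code{"csv"}, \code{"gpr"}.
#' @param labelMap named character vector mapping sample id to group, or
#'   the path of a two-column TSV; unlabeled samples get
#'   \code{"unspecified"}.
#' @param emptySpotToken peptide name marking empty spots
#'   (case-insensitive exact match; default \code{"empty"}).
#' @param signalColumn GPR column holding the spot signal.
#' @return A \linkS4class{PeptideArrayExperiment}.
#' @export
readIntensityTable <- function(path, format = c("tsv", "csv", "gpr"),
                               labelMap = NULL, emptySpotToken = "empty",
                               signalColumn = "F635 Median") {
  format <- match.arg(format)
  labelMap <- .resolveLabelMap(labelMap)
  if (format == "gpr") {
    arrays <- lapply(path, .readGPRFile, signalColumn = signalColumn)
    ids <- lapply(arrays, function(a) a$id)
    if (length(unique(lapply(ids, paste, collapse = "\r"))) != 1L)
      stop("GPR files disagree on peptide identities")
    sampleIds <- sub("\\.[^.]*$", "", basename(path))
    if (anyDuplicated(sampleIds))
      stop("duplicate sample ids derived from GPR file names")
    values <- do.call(rbind, lapply(arrays, function(a) a$signal))
    dimnames(values) <- list(sampleIds, arrays[[1]]$id)
    spotNames <- arrays[[1]]$name
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- read.delim(path, sep = sep, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("intensity table needs >= 2 columns")
    sampleIds <- as.character(tab[[1]])
    if (anyDuplicated(sampleIds))
      stop("duplicate sample id in intensity table: ",
           sampleIds[duplicated(sampleIds)][1])
    pepIds <- colnames(tab)[-1]
    if (anyDuplicated(pepIds))
      stop("duplicate peptide id in intensity table: ",
           pepIds[duplicated(pepIds)][1])
    values <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(values) <- "double")
    dimnames(values) <- list(sampleIds, pepIds)
    spotNames <- pepIds
  }
  .checkIntensityTable(values)
  empty <- tolower(spotNames) == tolower(emptySpotToken)
  groups <- rep("unspecified", nrow(values))
  if (!is.null(labelMap)) {
    hit <- rownames(values) %in% names(labelMap)
    groups[hit] <- unname(labelMap[rownames(values)[hit]])
  }
  PeptideArrayExperiment(values, groups = groups, emptySpot = empty)
}

# Parse one GPR file: ATF header, then a tab-delimited spot table.
.readGPRFile <- function(file, signalColumn = "F635 Median") {
  if (!file.exists(file)) stop("GPR file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  need <- c("Block", "Row", "Column", "Name", "ID")
  headerAt <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(gsub('"', "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (all(need %in% f)) { headerAt <- i; break }
  }
  if (is.na(headerAt))
    stop("GPR header with Block/Row/Column/Name/ID not found in ", file)
  tab <- read.delim(text = paste(lines[headerAt:length(lines)],
                                 collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!signalColumn %in% colnames(tab))
    stop(sprintf("signal column '%s' not found in %s", signalColumn, file))
  id <- as.character(tab$ID)
  if (anyDuplicated(id))
    stop("duplicate peptide id in ", file, ": ", id[duplicated(id)][1])
  sig <- suppressWarnings(as.numeric(tab[[signalColumn]]))
  list(id = id, name = as.character(tab$Name), signal = sig)
}

#' Write an intensity or normalized table to TSV
#'
#' Writes samples as rows (first column \code{sample}), peptides as
#' columns, matching the layout \code{\link{readIntensityTable}} reads.
#'
#' @param x a \linkS4class{PeptideArrayExperiment}.
#' @param path output file.
#' @param assay which assay to write (\code{"rfu"} or \code{"lognorm"}).
#' @return Invisibly, \code{path}.
#' @export
writeIntensityTable <- function(x, path, assay = "rfu") {
  v <- t(SummarizedExperiment::assay(x, assay))
  out <- data.frame(sample = rownames(v), v, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-slide median normalization on the log10 scale
#'
#' Each array (sample) is rescaled so that its median intensity equals
#' the grand median of per-sample medians, keeping values on the RFU
#' scale, and the rescaled values are log10 transformed. This adjusts
#' for global intensity bias between slides; no background subtraction
#' is performed (empty-spot background on these arrays is low and
#' consistent, and subtraction degrades reproducibility).
#'
#' Zeros cannot be log-transformed: entries equal to 0 are replaced by
#' \code{zeroOffset} RFU before scaling. With raw background typically
#' 150-300 RFU zeros are rare; set \code{zeroOffset = 0} to turn the
#' guard into an error.
#'
#' @param x a \linkS4class{PeptideArrayExperiment} with raw intensities.
#' @param zeroOffset RFU value substituted for exact zeros (default 1).
#' @return The object with an added \code{"lognorm"} assay and
#'   \code{colData(x)$norm_constant} (the per-sample multiplicative
#'   constants: dividing \code{10^lognorm} by the constant recovers the
#'   raw scale).
#' @export
medianNormalizeLog10 <- function(x, zeroOffset = 1) {
  v <- rfu(x)
  if (any(v == 0)) {
    if (zeroOffset <= 0)
      stop("zero intensities present and zeroOffset <= 0; cannot log-transform")
    v[v == 0] <- zeroOffset
  }
  meds <- apply(v, 2L, median)
  if (any(meds == 0))
    stop("sample(s) with zero median intensity cannot be scaled: ",
         paste(colnames(v)[meds == 0], collapse = ", "))
  grand <- median(meds)
  const <- grand / meds
  scaled <- sweep(v, 2L, const, `*`)
  SummarizedExperiment::assay(x, "lognorm") <- log10(scaled)
  SummarizedExperiment::colData(x)$norm_constant <- const
  methods::validObject(x)
  x
}

#' Descriptive statistics of raw fluorescence by disease group
#'
#' Summarizes the raw RFU distribution of each group, pooling every spot
#' of every sample in the group (the scale on which scanner saturation
#' and immune-activity differences such as floor suppression or ceiling
#' utilization are visible).
#'
#' @param x a \linkS4class{PeptideArrayExperiment}.
#' @return A data.frame with one row per group (in order of first
#'   appearance): \code{group}, \code{mean}, \code{minimum},
#'   \code{maximum}, \code{std_deviation}, \code{variance}, \code{range}.
#' @export
describeGroups <- function(x) {
  g <- groupLabels(x)
  v <- rfu(x)
  lev <- unique(g)
  rows <- lapply(lev, function(lv) {
    vals <- as.vector(v[, g == lv, drop = FALSE])
    if (!length(vals)) stop("empty group: ", lv)
    data.frame(group = lv, mean = mean(vals), minimum = min(vals),
               maximum = max(vals), std_deviation = sd(vals),
               variance = var(vals), range = max(vals) - min(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
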