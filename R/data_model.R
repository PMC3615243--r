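#' Default 47-region atlas
#'
#' Reads the bundled NeuroQ-style atlas: 22 left/right cortical and
#' subcortical pairs plus three midline structures, 47 region names in
#' total.  Temporal, frontal, language and subcortical regions carry
#' their standard names; the remaining pairs are documented placeholders.
#' Any text file with one ROI name per line (lines starting with `#`
#' ignored) can be used instead.
#'
#' @param path optional path to an alternative atlas file.
#' @return character vector of unique ROI names.
#' @export
default_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atlas_default.txt", package = "tlecad")
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines)) stop("atlas contains duplicate ROI names")
  lines
}

#' Construct a cohort object
#'
#' A cohort bundles per-patient ROI metabolism, diagnosis, optional
#' clinical covariates (age in years, sex, duration of disease in years,
#' seizure frequency in events/month) and optional manual-analysis (MA)
#' reads for iPET and sMRI.  Unavailable reads are `NA` (distinct from
#' `"negative"`).
#'
#' @param id character vector of unique patient ids.
#' @param diagnosis character/factor with levels `NES`, `LTLE`, `RTLE`.
#' @param roi numeric matrix, one row per patient, columns named by the
#'   atlas; all values must be finite and positive (regional radioactivity
#'   normalized by whole-brain radioactivity).
#' @param clinical data.frame with columns `age`, `sex`, `duration`,
#'   `frequency` (may contain `NA`), or `NULL`.
#' @param reads data.frame with columns `ipet`, `smri` holding values in
#'   `negative`, `left_abnormal`, `right_abnormal`, `bilateral_abnormal`
#'   or `NA` (report unavailable), or `NULL`.
#' @param atlas character vector of ROI names (defaults to the column
#'   names of `roi`).
#' @return an object of class `cad_cohort` with element `counts` giving
#'   the per-class tally.
#' @export
new_cohort <- function(id, diagnosis, roi, clinical = NULL, reads = NULL,
                       atlas = colnames(roi)) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate patient id: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  n <- length(id)
  diagnosis <- as.character(diagnosis)
  bad <- setdiff(unique(diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad)) stop("unknown diagnosis label: ", paste(bad, collapse = ", "))
  diagnosis <- factor(diagnosis, levels = DIAGNOSIS_LEVELS)
  roi <- as.matrix(roi)
  storage.mode(roi) <- "double"
  if (nrow(roi) != n) stop("roi row count does not match id length")
  if (is.null(atlas)) stop("roi must have column names (the atlas)")
  if (!identical(colnames(roi), atlas)) roi <- roi[, atlas, drop = FALSE]
  if (anyDuplicated(atlas)) stop("atlas names must be unique")
  bad_row <- which(!apply(roi, 1L, function(v) all(is.finite(v) & v > 0)))
  if (length(bad_row))
    stop("non-positive or non-finite ROI value for patient ",
         paste(id[bad_row], collapse = ", "))
  if (is.null(clinical))
    clinical <- data.frame(age = rep(NA_real_, n), sex = factor(rep(NA, n), levels = SEX_LEVELS),
                           duration = NA_real_, frequency = NA_real_)
  clinical <- data.frame(age = as.numeric(clinical$age),
                         sex = factor(as.character(clinical$sex), levels = SEX_LEVELS),
                         duration = as.numeric(clinical$duration),
                         frequency = as.numeric(clinical$frequency))
  if (nrow(clinical) != n) stop("clinical row count mismatch")
  with(clinical, {
    if (any(age <= 0, na.rm = TRUE)) stop("age must be > 0")
    if (any(duration < 0, na.rm = TRUE)) stop("duration must be >= 0")
    if (any(frequency < 0, na.rm = TRUE)) stop("frequency must be >= 0")
  })
  if (is.null(reads))
    reads <- data.frame(ipet = factor(rep(NA, n), levels = MA_CALLS),
                        smri = factor(rep(NA, n), levels = MA_CALLS))
  reads <- data.frame(ipet = factor(as.character(reads$ipet), levels = MA_CALLS),
                      smri = factor(as.character(reads$smri), levels = MA_CALLS))
  if (nrow(reads) != n) stop("reads row count mismatch")
  rownames(roi) <- id
  out <- structure(list(id = id, diagnosis = diagnosis, roi = roi,
                        clinical = clinical, reads = reads, atlas = atlas,
                        counts = table(diagnosis)),
                   class = "cad_cohort")
  out
}

#' @export
print.cad_cohort <- function(x, ...) {
  cat("cad_cohort:", length(x$id), "patients,", length(x$atlas), "ROIs\n")
  print(x$counts)
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `cad_cohort`.
#' @return integer.
#' @export
cohort_size <- function(cohort) length(cohort$id)

#' Subset a cohort by patient index or id
#' @param cohort a `cad_cohort`.
#' @param i integer/logical index or character ids.
#' @return a `cad_cohort`.
#' @export
cohort_subset <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$id)
  new_cohort(cohort$id[i], as.character(cohort$diagnosis[i]),
             cohort$roi[i, , drop = FALSE],
             cohort$clinical[i, , drop = FALSE],
             cohort$reads[i, , drop = FALSE],
             atlas = cohort$atlas)
}

#' Read a cohort from a delimited feature table
#'
#' Expects a UTF-8 CSV (or TSV, by extension or `sep`) with a header and
#' one row per patient: columns `id`, `diagnosis`, one column per atlas
#' ROI, and optional `age`, `sex`, `duration`, `frequency`, `ipet`,
#' `smri` columns.  Empty cells in optional columns become `NA`.
#'
#' @param path file path.
#' @param atlas ROI names expected in the header (default bundled atlas).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return a `cad_cohort`.
#' @export
load_cohort <- function(path, atlas = default_atlas(), sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          encoding = "UTF-8", na.strings = c("NA", ""))
  for (col in c("id", "diagnosis")) if (!col %in% names(df))
    stop("missing required column: ", col)
  missing_roi <- setdiff(atlas, names(df))
  if (length(missing_roi))
    stop("missing ROI column: ", paste(missing_roi, collapse = ", "))
  roi <- as.matrix(df[, atlas, drop = FALSE])
  suppressWarnings(storage.mode(roi) <- "double")
  nonnum <- which(apply(roi, 1L, function(v) any(is.na(v))))
  if (length(nonnum))
    stop("non-numeric or missing ROI value for patient ",
         paste(df$id[nonnum], collapse = ", "))
  clinical <- if (all(c("age", "sex", "duration", "frequency") %in% names(df)))
    df[c("age", "sex", "duration", "frequency")] else NULL
  reads <- if (all(c("ipet", "smri") %in% names(df))) df[c("ipet", "smri")] else NULL
  new_cohort(df$id, df$diagnosis, roi, clinical, reads, atlas = atlas)
}

#' Write a cohort to a delimited feature table
#'
#' Inverse of [load_cohort()]: numeric fields are written with 17
#' significant digits so that a write/load round trip reproduces every
#' value exactly.
#'
#' @param cohort a `cad_cohort`.
#' @param path output file path (`.tsv` extension selects tab separation).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  roi_chr <- apply(cohort$roi, 2L, num)
  if (is.null(dim(roi_chr))) roi_chr <- matrix(roi_chr, nrow = 1,
                                               dimnames = list(NULL, colnames(cohort$roi)))
  df <- data.frame(id = cohort$id, diagnosis = as.character(cohort$diagnosis),
                   roi_chr, check.names = FALSE, stringsAsFactors = FALSE)
  df$age <- num(cohort$clinical$age)
  df$sex <- as.character(cohort$clinical$sex)
  df$duration <- num(cohort$clinical$duration)
  df$frequency <- num(cohort$clinical$frequency)
  df$ipet <- as.character(cohort$reads$ipet)
  df$smri <- as.character(cohort$reads$smri)
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

ma_abnormal <- function(call) {
  ifelse(is.na(call), NA_real_, as.numeric(call != "negative"))
}

ma_side <- function(call, side) {
  hit <- c(left = "left_abnormal", right = "right_abnormal")[[side]]
  ifelse(is.na(call), NA_real_,
         as.numeric(call == hit | call == "bilateral_abnormal"))
}

#' Assemble the classification feature matrix
#'
#' Base columns are the 47 ROI metabolism values.  With
#' `include_clinical`, age, sex (female = 1), duration and seizure
#' frequency are appended; with `include_ma`, one abnormal-vs-negative
#' indicator per modality (iPET, sMRI), or — with `trinary_ma_split` —
#' two indicators per modality flagging a reported left and/or right
#' abnormality (a bilateral read sets both).  Rows with any missing
#' included feature are dropped; row order is preserved.
#'
#' @param cohort a `cad_cohort`.
#' @param include_clinical append clinical covariates.
#' @param include_ma append manual-analysis indicators.
#' @param trinary_ma_split use the left/right split MA encoding
#'   (trinary task).
#' @return a `cad_features` object: list with numeric matrix `x`
#'   (rownames = patient id), factor `labels`, character `id`, and
#'   `dropped` (ids excluded for missing data).
#' @export
assemble_features <- function(cohort, include_clinical = FALSE,
                              include_ma = FALSE, trinary_ma_split = FALSE) {
  if (cohort_size(cohort) == 0L) stop("empty cohort")
  x <- cohort$roi
  if (include_clinical) {
    cl <- cbind(age = cohort$clinical$age,
                sex = as.numeric(cohort$clinical$sex == "female"),
                duration = cohort$clinical$duration,
                frequency = cohort$clinical$frequency)
    x <- cbind(x, cl)
  }
  if (include_ma) {
    ma <- if (trinary_ma_split)
      cbind(ipet_left = ma_side(cohort$reads$ipet, "left"),
            ipet_right = ma_side(cohort$reads$ipet, "right"),
            smri_left = ma_side(cohort$reads$smri, "left"),
            smri_right = ma_side(cohort$reads$smri, "right"))
    else
      cbind(ipet = ma_abnormal(cohort$reads$ipet),
            smri = ma_abnormal(cohort$reads$smri))
    x <- cbind(x, ma)
  }
  if (anyDuplicated(colnames(x))) stop("duplicate feature column names")
  keep <- !apply(x, 1L, anyNA)
  if (!any(keep))
    stop("all ", length(keep), " rows dropped for missing included features")
  structure(list(x = x[keep, , drop = FALSE],
                 labels = droplevels(cohort$diagnosis[keep]),
                 id = cohort$id[keep],
                 dropped = cohort$id[!keep]),
            class = "cad_features")
}

#' @export
print.cad_features <- function(x, ...) {
  cat("cad_features:", nrow(x$x), "patients x", ncol(x$x), "features;",
      length(x$dropped), "dropped\n")
  invisible(x)
}
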