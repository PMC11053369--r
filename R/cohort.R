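#' @useDynLib mirvote, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef glm median pbinom phyper pnorm predict pt qnorm
#'   quantile rbinom rlnorm rnorm runif sd setNames uniroot var optim
#'   binomial as.formula complete.cases
#' @importFrom utils read.delim write.table head
#' @importFrom graphics abline axis legend lines par plot points
"_PACKAGE"

# Column layout of a clinical table (CSV header order).
.clinical_cols <- c(
  "sample_id", "event", "time_months", "age_years", "tumor_size_mm",
  "er_status", "pr_status", "grade", "tumor_type", "year_of_surgery",
  "pair_id"
)

# Events are metastases within 10 years of diagnosis; later times for
# event = 1 violate the case definition.
.case_horizon_months <- 120

#' Validate an expression matrix
#'
#' Checks the invariants of the log-scale expression container: unique
#' feature and sample identifiers, all values finite, at least 2 features
#' and 4 samples.
#'
#' @param x numeric matrix, features x samples, with rownames (miRNA mature
#'   names) and colnames (sample identifiers).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry feature rownames and sample colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate feature_id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (nrow(x) < 2 || ncol(x) < 4)
    stop("expression matrix needs at least 2 features and 4 samples")
  invisible(x)
}

#' Read a miRNA expression matrix from TSV
#'
#' Expects a tab-separated file whose first column (`feature_id`) holds the
#' miRNA mature names and whose remaining columns are samples. Values are
#' assumed to be already-normalized log-scale intensities; the package never
#' re-normalizes arrays (standardization happens per CV fold, from training
#' data only).
#'
#' @param path path to the TSV file.
#' @return numeric matrix, features x samples, row/column order as in the
#'   file.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!ncol(df) >= 2 || names(df)[1] != "feature_id")
    stop("expression file must have header 'feature_id<TAB>sample1<TAB>...'")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric expression value at row %d (feature '%s'), column '%s'",
      bad[1], ids[bad[1]], colnames(num)[bad[2]]))
  }
  rownames(num) <- ids
  validate_expression(num)
  num
}

#' Write a miRNA expression matrix to TSV
#'
#' @param x numeric features x samples matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a clinical table
#'
#' Enforces the case definition (an event is a regional or distant
#' metastasis within 10 years, so `event == 1` requires
#' `time_months <= 120`), positive times, and binary events.
#'
#' @param clinical data.frame with the columns of [read_clinical()].
#' @return the normalized data.frame (categorical fields as lowercase
#'   character tokens).
#' @export
validate_clinical <- function(clinical) {
  missing_cols <- setdiff(.clinical_cols, names(clinical))
  if (length(missing_cols))
    stop("clinical table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  cl <- clinical[, .clinical_cols]
  cl$sample_id <- as.character(cl$sample_id)
  if (anyDuplicated(cl$sample_id))
    stop("duplicate sample_id in clinical table: ",
         cl$sample_id[duplicated(cl$sample_id)][1])
  cl$event <- as.integer(cl$event)
  if (!all(cl$event %in% c(0L, 1L)))
    stop("event must be 0 or 1")
  cl$time_months <- as.numeric(cl$time_months)
  if (any(!is.finite(cl$time_months)) || any(cl$time_months <= 0))
    stop("time_months must be positive and finite")
  late <- cl$event == 1L & cl$time_months > .case_horizon_months
  if (any(late))
    stop(sprintf(paste0(
      "sample '%s': event = 1 with time_months = %g violates the case ",
      "definition (metastasis within 10 years, i.e. <= %d months)"),
      cl$sample_id[which(late)[1]], cl$time_months[which(late)[1]],
      .case_horizon_months))
  cl$age_years <- as.numeric(cl$age_years)
  cl$tumor_size_mm <- as.numeric(cl$tumor_size_mm)
  for (col in c("er_status", "pr_status", "grade", "tumor_type")) {
    cl[[col]] <- tolower(trimws(as.character(cl[[col]])))
  }
  if (!all(cl$er_status %in% c("pos", "neg", "na")))
    stop("er_status must be one of pos/neg/na")
  if (!all(cl$pr_status %in% c("pos", "neg", "na")))
    stop("pr_status must be one of pos/neg/na")
  if (!all(cl$grade %in% c("1", "2", "3", "na")))
    stop("grade must be one of 1/2/3/na")
  cl$year_of_surgery <- as.integer(cl$year_of_surgery)
  cl$pair_id <- as.character(cl$pair_id)
  cl
}

#' Read a clinical annotation table from CSV
#'
#' Expected header:
#' `sample_id,event,time_months,age_years,tumor_size_mm,er_status,pr_status,grade,tumor_type,year_of_surgery,pair_id`.
#' The token `na` marks missing ER/PR status or grade. `event` is 1 for
#' patients with regional/distant metastasis within 10 years; `time_months`
#' is time to metastasis for cases and follow-up for recurrence-free
#' patients.
#'
#' @param path path to the CSV file.
#' @return data.frame of typed clinical records.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = ",", check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  validate_clinical(df)
}

#' Write a clinical annotation table to CSV
#'
#' @param clinical data.frame as returned by [read_clinical()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  cl <- validate_clinical(clinical)
  write.table(cl, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a paired case-control cohort
#'
#' Binds the expression matrix, the clinical table and (optionally) the
#' case-control pairing into the cohort object all downstream stages
#' consume. With pairing present, every sample must belong to exactly one
#' pair and each pair must hold exactly one case (`event == 1`) and one
#' control. Without pairing, the cohort is legal but leave-one-pair-out
#' cross-validation will refuse it.
#'
#' @param expression numeric features x samples matrix (see
#'   [validate_expression()]).
#' @param clinical clinical data.frame (see [validate_clinical()]).
#' @param pairs optional two-column data.frame or matrix
#'   (`case`, `control`) of sample identifiers.
#' @return an object of class `mirvote_cohort`: a list with elements
#'   `expression`, `clinical`, `pairs`.
#' @export
assemble_cohort <- function(expression, clinical, pairs = NULL) {
  validate_expression(expression)
  cl <- validate_clinical(clinical)
  # order-independence: clinical rows are keyed to expression column order
  if (!setequal(colnames(expression), cl$sample_id))
    stop("sample ids of expression and clinical tables do not coincide; ",
         "missing from clinical: ",
         paste(head(setdiff(colnames(expression), cl$sample_id)),
               collapse = ", "))
  cl <- cl[match(colnames(expression), cl$sample_id), ]
  rownames(cl) <- NULL
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) != 2)
      stop("pairs must have two columns: case, control")
    names(pairs) <- c("case", "control")
    pairs$case <- as.character(pairs$case)
    pairs$control <- as.character(pairs$control)
    ids <- c(pairs$case, pairs$control)
    if (anyDuplicated(ids))
      stop("sample '", ids[duplicated(ids)][1],
           "' appears in more than one pair")
    if (!setequal(ids, cl$sample_id))
      stop("pairing must cover every cohort sample exactly once")
    ev <- setNames(cl$event, cl$sample_id)
    bad <- ev[pairs$case] != 1L | ev[pairs$control] != 0L
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "pair ('%s', '%s') must hold exactly one case and one control",
        pairs$case[i], pairs$control[i]))
    }
    rownames(pairs) <- NULL
  }
  structure(list(expression = expression, clinical = cl, pairs = pairs),
            class = "mirvote_cohort")
}

#' @export
print.mirvote_cohort <- function(x, ...) {
  cat(sprintf("mirvote cohort: %d miRNAs x %d samples (%d cases, %d controls)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event == 1L), sum(x$clinical$event == 0L)))
  if (is.null(x$pairs)) {
    cat("  pairing: absent (LOPO-CV unavailable; see match_pairs())\n")
  } else {
    cat(sprintf("  pairing: %d matched case-control pairs\n", nrow(x$pairs)))
  }
  invisible(x)
}

#' Read a vote table from TSV
#'
#' @param path path to a TSV written by [write_votes()].
#' @return data.frame with columns `sample_id`, the seven method columns,
#'   `votes`, `risk_group`.
#' @export
read_votes <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample_id", mirvote_methods(), "votes", "risk_group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("vote file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  chk <- rowSums(df[, mirvote_methods(), drop = FALSE])
  if (!all(chk == df$votes))
    stop("votes column does not equal the sum of per-method votes")
  df
}

#' Write a vote table to TSV
#'
#' Columns: `sample_id`, one 0/1 column per method (RSVM, RF, NB, LSVM,
#' COX-RS, KNN, LR), the vote sum, and the assigned risk group.
#'
#' @param votes data.frame as produced by [aggregate_votes()]; a
#'   `risk_group` column is added (as `NA`) when absent.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_votes <- function(votes, path) {
  if (!"risk_group" %in% names(votes)) votes$risk_group <- NA_character_
  keep <- c("sample_id", intersect(mirvote_methods(), names(votes)),
            "votes", "risk_group")
  write.table(votes[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
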