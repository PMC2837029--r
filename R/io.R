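# delimiter from extension unless given: .tsv/.txt -> tab, else comma
read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# numbers serialized at 17 significant digits so a write/read round trip
# is lossless for doubles
fmt17 <- function(x) {
  if (is.double(x)) formatC(x, digits = 17, format = "g") else x
}

#' Load an aligned clinical + molecular dataset from delimited text
#'
#' Reads the clinical table (sample-ID column first, header row) and the
#' molecular matrix, aligns them on the intersection of their sample IDs
#' (clinical file order wins), and validates the result. Rows with missing
#' values in the outcome, the clinical covariates or the molecular block
#' are dropped with a message naming the dropped IDs. Non-numeric clinical
#' columns are dummy-encoded (reference = first sorted level).
#'
#' @param clinical_path path to the clinical CSV/TSV (first column: sample
#'   IDs).
#' @param molecular_path path to the molecular CSV/TSV.
#' @param outcome name of the outcome column in the clinical file, or a
#'   path to a separate two-column (ID, outcome) file.
#' @param orientation `"samples_by_features"` (molecular file rows are
#'   samples) or `"features_by_samples"` (rows are features, columns are
#'   samples — the conventional expression-matrix layout; the matrix is
#'   transposed on load).
#' @param sep field delimiter; inferred from the extension when `NULL`
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A `boost_dataset` (see [simulate_dataset()]), plus
#'   `outcome_levels` recording the label coding.
#' @export
load_dataset <- function(clinical_path, molecular_path, outcome,
                         orientation = c("samples_by_features",
                                         "features_by_samples"),
                         sep = NULL) {
  orientation <- match.arg(orientation)

  clin <- read_delim_auto(clinical_path, sep)
  if (ncol(clin) < 2) stop("clinical file needs an ID column plus data")
  clin_ids <- as.character(clin[[1L]])
  if (anyDuplicated(clin_ids))
    stop("duplicate sample IDs in clinical file: ",
         clin_ids[duplicated(clin_ids)][1L])
  clin <- clin[, -1L, drop = FALSE]

  if (outcome %in% names(clin)) {
    y_raw <- clin[[outcome]]
    clin <- clin[, setdiff(names(clin), outcome), drop = FALSE]
  } else if (file.exists(outcome)) {
    ytab <- read_delim_auto(outcome, sep)
    if (ncol(ytab) < 2) stop("outcome file needs ID and outcome columns")
    idx <- match(clin_ids, as.character(ytab[[1L]]))
    y_raw <- ytab[[2L]][idx]
  } else {
    stop("outcome \"", outcome,
         "\" is neither a clinical column nor a readable file")
  }

  mol <- read_delim_auto(molecular_path, sep)
  if (orientation == "samples_by_features") {
    mol_ids <- as.character(mol[[1L]])
    Xfull <- mol[, -1L, drop = FALSE]
    feature_ids <- names(Xfull)
  } else {
    feature_ids <- as.character(mol[[1L]])
    Xfull <- as.data.frame(t(mol[, -1L, drop = FALSE]))
    names(Xfull) <- feature_ids
    mol_ids <- colnames(mol)[-1L]
  }
  if (anyDuplicated(mol_ids))
    stop("duplicate sample IDs in molecular file: ",
         mol_ids[duplicated(mol_ids)][1L])
  for (j in seq_along(Xfull)) {
    if (!is.numeric(Xfull[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(Xfull[[j]]))) &
                   !is.na(Xfull[[j]]))[1L]
      stop("non-numeric molecular value in column \"", feature_ids[j],
           "\", row ", if (is.na(bad)) "?" else bad)
    }
  }

  ids <- clin_ids[clin_ids %in% mol_ids]   # clinical order wins
  if (length(ids) == 0L)
    stop("no common sample IDs between clinical and molecular files")
  ci <- match(ids, clin_ids)
  mi <- match(ids, mol_ids)
  X <- as.matrix(Xfull)[mi, , drop = FALSE]
  storage.mode(X) <- "double"
  clin <- clin[ci, , drop = FALSE]
  y_raw <- y_raw[ci]

  keep <- !is.na(y_raw) &
    (ncol(clin) == 0 | stats::complete.cases(clin)) &
    stats::complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) dropped for missing values: ",
            paste(ids[!keep], collapse = ", "))
    ids <- ids[keep]
    clin <- clin[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
    y_raw <- y_raw[keep]
  }
  if (length(ids) < 4L) stop("fewer than 4 complete samples remain")

  Z <- if (ncol(clin) > 0) encode_covariates(clin)
       else matrix(numeric(0), length(ids), 0)
  rownames(X) <- ids
  out <- encode_outcome(y_raw)

  structure(list(Z = Z, X = X, y = out$y, sample_ids = ids,
                 feature_ids = colnames(X), covariate_ids = colnames(Z),
                 outcome_levels = out$levels, setting = NULL),
            class = "boost_dataset")
}

#' Write a dataset as the CSV pair the loader reads
#'
#' Writes `clinical.csv` (sample ID, outcome, clinical covariates) and
#' `molecular.csv` (sample ID, features) into `dir`. Doubles are written
#' with 17 significant digits, so a [load_dataset()] round trip is
#' lossless and downstream p-values are bit-identical to the in-memory
#' pipeline.
#'
#' @param dataset a `boost_dataset`.
#' @param dir output directory (created if absent).
#' @param sep field delimiter, default comma.
#' @return invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, dir, sep = ",") {
  stopifnot(inherits(dataset, "boost_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "clinical.csv")
  mp <- file.path(dir, "molecular.csv")

  clin <- data.frame(sample_id = dataset$sample_ids,
                     outcome = dataset$y, check.names = FALSE)
  if (ncol(dataset$Z) > 0)
    clin <- cbind(clin, as.data.frame(apply(dataset$Z, 2, fmt17,
                                            simplify = FALSE)))
  write.table(clin, cp, sep = sep, row.names = FALSE, quote = FALSE)

  mol <- data.frame(sample_id = dataset$sample_ids, check.names = FALSE)
  mol <- cbind(mol, as.data.frame(apply(dataset$X, 2, fmt17,
                                        simplify = FALSE)))
  write.table(mol, mp, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(clinical = cp, molecular = mp))
}

#' Serialize a test result to JSON
#'
#' Writes everything needed to re-run the test exactly: p-value, observed
#' and permuted statistics, the permutation resolution, mstop bookkeeping,
#' seed, configuration and clinical coefficients.
#'
#' @param test a [global_boost_test()] result.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_test_report <- function(test, path) {
  stopifnot(inherits(test, "boost_perm_test"))
  rep <- list(
    p_value = test$p_value,
    resolution = test$resolution,
    ell_observed = test$ell_observed,
    ell_perm = test$ell_perm,
    mstop_mode = test$mstop_mode,
    mstop_used = unname(test$mstop_used),
    B = test$B, seed = test$seed, nu = test$nu,
    center = test$center, standardize = test$standardize,
    offset_mode = test$offset$mode,
    offset_coefficients = as.list(test$offset$coefficients),
    n = test$n, p = test$p,
    package_version = as.character(packageVersion("offsetboost")))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
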