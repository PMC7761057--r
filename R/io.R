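#' Read a wide metabolite abundance table
#'
#' Reads a samples-by-metabolites numeric table from CSV or TSV. The first
#' column must hold sample identifiers and the header row metabolite
#' identifiers. Empty cells and the spellings `NA`, `NaN`, `nan`
#' (case-insensitive) are read as missing; every other cell must parse as a
#' finite number. Missing cells are never zero-filled.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param transpose Set `TRUE` for metabolites-in-rows exports (first column
#'   metabolite ids, header sample ids); the returned matrix is always
#'   samples-in-rows.
#' @return A numeric matrix with unique `rownames` (samples) and `colnames`
#'   (metabolites); missing cells are `NA`.
#' @seealso [write_metabolite_table()], [read_annotations()]
#' @export
read_metabolite_table <- function(path, dialect = c("csv", "tsv"),
                                  transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (ncol(raw) < 1L) stop("no columns found in ", path)
  row_ids <- as.character(raw[[1L]])
  col_ids <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  norm <- tolower(trimws(cells))
  is_missing <- norm == "" | norm == "na" | norm == "nan"
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!is_missing & (is.na(values) | !is.finite(values)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric or non-finite cell at row '", row_ids[bad[1L, 1L]],
         "', column '", col_ids[bad[1L, 2L]], "': \"",
         cells[bad[1L, , drop = FALSE]], "\"")
  }
  values[is_missing] <- NA_real_
  dimnames(values) <- list(row_ids, col_ids)
  if (transpose) values <- t(values)
  validate_metabolite_table(values)
}

#' Validate a metabolite table
#'
#' Checks the container invariants: a numeric matrix, unique sample and
#' metabolite identifiers, and all present values finite.
#'
#' @param table Numeric matrix, samples in rows.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_metabolite_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("metabolite table must be a numeric matrix (samples x metabolites)")
  sid <- rownames(table)
  mid <- colnames(table)
  if (is.null(mid)) stop("metabolite table lacks metabolite ids (colnames)")
  if (nrow(table) > 0L && is.null(sid))
    stop("metabolite table lacks sample ids (rownames)")
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(mid))
    stop("duplicate metabolite ids: ",
         paste(unique(mid[duplicated(mid)]), collapse = ", "))
  if (any(!is.finite(table) & !is.na(table)))
    stop("metabolite table contains non-finite values")
  table
}

#' Write a metabolite table
#'
#' Inverse of [read_metabolite_table()]: missing cells are written as empty
#' strings, values at full `as.character` precision (15 significant digits),
#' so a write-then-read round trip preserves the missingness mask exactly and
#' values to at least 12 significant digits.
#'
#' @param table Numeric matrix, samples in rows.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_metabolite_table(table)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(sample_id = rownames(table) %||% character(0),
                   table, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, na = "", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", quote = 1L,
                     fileEncoding = "UTF-8")
  invisible(path)
}

ANNOT_CLASSES <- c("endogenous", "unannotated", "xenobiotic")

#' Read a metabolite annotation table
#'
#' Requires columns `metabolite_id` and `class`; `class` values must be (case
#' insensitively) `endogenous`, `unannotated` or `xenobiotic` and are
#' normalised to lowercase. Optional `super_pathway` / `sub_pathway` columns
#' are carried through.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param data_ids Optional character vector of metabolite ids that must all
#'   be covered; an uncovered id is a coverage error naming the offenders.
#' @return A `data.frame` with columns `metabolite_id`, `class`,
#'   `super_pathway`, `sub_pathway`.
#' @export
read_annotations <- function(path, dialect = c("csv", "tsv"), data_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, na.strings = NULL)
  req <- c("metabolite_id", "class")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("annotation file lacks required column(s): ", paste(miss, collapse = ", "))
  ann <- data.frame(metabolite_id = df$metabolite_id,
                    class = tolower(trimws(df$class)),
                    super_pathway = if ("super_pathway" %in% colnames(df))
                      df$super_pathway else NA_character_,
                    sub_pathway = if ("sub_pathway" %in% colnames(df))
                      df$sub_pathway else NA_character_,
                    stringsAsFactors = FALSE)
  validate_annotations(ann, data_ids)
}

#' Validate an annotation table
#'
#' @param annotations A data frame as returned by [read_annotations()].
#' @param data_ids Optional metabolite ids that must be covered.
#' @return The validated annotation data frame.
#' @export
validate_annotations <- function(annotations, data_ids = NULL) {
  if (anyDuplicated(annotations$metabolite_id))
    stop("duplicate metabolite_id in annotations: ",
         paste(unique(annotations$metabolite_id[
           duplicated(annotations$metabolite_id)]), collapse = ", "))
  unknown <- setdiff(unique(annotations$class), ANNOT_CLASSES)
  if (length(unknown))
    stop("unknown metabolite class value(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(ANNOT_CLASSES, collapse = ", "), ")")
  if (!is.null(data_ids)) {
    uncovered <- setdiff(data_ids, annotations$metabolite_id)
    if (length(uncovered))
      stop("metabolite(s) present in data but absent from annotations: ",
           paste(uncovered, collapse = ", "))
  }
  annotations
}

#' Read a covariate table (sample_id, age, sex, BMI)
#'
#' @param path Path to a CSV/TSV file with a `sample_id` column plus numeric
#'   `age`, `sex` (0/1) and `BMI` columns (case-insensitive names).
#' @param dialect `"csv"` or `"tsv"`.
#' @return A data frame with columns `sample_id`, `age`, `sex`, `BMI`.
#' @export
read_covariates <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"", stringsAsFactors = FALSE)
  nm <- tolower(colnames(df))
  for (want in c("sample_id", "age", "sex", "bmi")) {
    if (!want %in% nm) stop("covariate file lacks column '", want, "'")
  }
  out <- data.frame(sample_id = as.character(df[[which(nm == "sample_id")[1L]]]),
                    age = as.numeric(df[[which(nm == "age")[1L]]]),
                    sex = as.numeric(df[[which(nm == "sex")[1L]]]),
                    BMI = as.numeric(df[[which(nm == "bmi")[1L]]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out)) stop("covariate table must be complete (no missing values)")
  out
}

#' Run configuration with the workflow defaults
#'
#' Defaults reproduce the reference configuration: 10 auxiliary metabolites,
#' m = 5 imputations, k = 10 neighbours, 5 PMM donors, 5 chained-equation
#' sweeps, and a 90% high-missingness cutoff.
#'
#' @param method `"mice_pmm"` or `"knn_obs_sel"`.
#' @param n_aux Maximum number of auxiliary metabolites per target.
#' @param m Number of imputed datasets (MICE only).
#' @param knn_k Number of nearest donor samples (kNN only).
#' @param donors Number of PMM donors d.
#' @param chained_iterations Chained-equation sweeps per imputation chain.
#' @param high_missing_cutoff Missing fraction at or above which a
#'   non-xenobiotic metabolite is reclassified and zero-imputed; in (0, 1].
#' @param min_pairwise_overlap Minimum pairwise-complete sample count for a
#'   correlation to be considered defined.
#' @param seed Integer RNG seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(method = c("mice_pmm", "knn_obs_sel"), n_aux = 10L,
                       m = 5L, knn_k = 10L, donors = 5L,
                       chained_iterations = 5L, high_missing_cutoff = 0.90,
                       min_pairwise_overlap = 5L, seed = 1L) {
  method <- match.arg(method)
  chk_pos_int <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != as.integer(x))
      stop("'", nm, "' must be a positive integer")
    as.integer(x)
  }
  if (!is.numeric(high_missing_cutoff) || high_missing_cutoff <= 0 ||
      high_missing_cutoff > 1)
    stop("'high_missing_cutoff' must lie in (0, 1]")
  structure(list(method = method,
                 n_aux = chk_pos_int(n_aux, "n_aux"),
                 m = chk_pos_int(m, "m"),
                 knn_k = chk_pos_int(knn_k, "knn_k"),
                 donors = chk_pos_int(donors, "donors"),
                 chained_iterations = chk_pos_int(chained_iterations,
                                                  "chained_iterations"),
                 high_missing_cutoff = high_missing_cutoff,
                 min_pairwise_overlap = chk_pos_int(min_pairwise_overlap,
                                                    "min_pairwise_overlap"),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), names(formals(run_config)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

#' Write completed datasets and a provenance sidecar
#'
#' Writes one CSV per completed dataset (`<prefix>_imp1.csv` ..
#' `<prefix>_impm.csv`) plus `<prefix>_provenance.txt`, a flat key: value
#' text file recording method, seed, parameters, and the id lists of the
#' imputation plan (zero-imputed, reclassified, excluded targets).
#'
#' @param result An `"imputation_result"` (from [impute_metabolites()],
#'   [mice_pmm()] or [knn_obs_sel_impute()] wrapped via the pipeline).
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix, default `"imputed"`.
#' @return Character vector of the files written (data files then sidecar).
#' @export
write_completed_datasets <- function(result, out_dir, prefix = "imputed") {
  if (!inherits(result, "imputation_result"))
    stop("'result' must be an imputation_result")
  if (length(result$completed) < 1L)
    stop("result holds no completed tables")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- character(0)
  for (i in seq_along(result$completed)) {
    p <- file.path(out_dir, sprintf("%s_imp%d.csv", prefix, i))
    write_metabolite_table(result$completed[[i]], p)
    paths <- c(paths, p)
  }
  side <- file.path(out_dir, paste0(prefix, "_provenance.txt"))
  extra <- result$params %||% list()
  extra <- extra[setdiff(names(extra), c("method", "m", "seed"))]
  kv <- c(method = result$method,
          m = length(result$completed),
          seed = result$seed %||% "NA",
          unlist(lapply(extra, format)),
          zero_impute_ids = paste(result$plan$zero_impute_ids %||% character(0),
                                  collapse = ","),
          reclassified_ids = paste(result$plan$reclassified_ids %||% character(0),
                                   collapse = ","),
          excluded_targets = paste(result$excluded %||% character(0),
                                   collapse = ","),
          knn_fallback_count = result$fallback_count %||% 0L)
  writeLines(paste0(names(kv), ": ", as.character(kv)), side, useBytes = TRUE)
  c(paths, side)
}
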