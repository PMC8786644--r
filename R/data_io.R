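#' Read a patient-by-gene expression matrix from TSV
#'
#' The expected layout is a tab-separated file whose header row names the
#' genes and whose first column holds patient identifiers; all remaining
#' cells are nonnegative FPKM-like expression values. Values are consumed
#' as-is (no log transform).
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix with patients in rows (rownames = patient ids)
#'   and genes in columns (colnames = gene ids).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression file must have a patient id column and >= 1 gene column: ", path)
  }
  patient_ids <- as.character(df[[1L]])
  gene_ids <- colnames(df)[-1L]
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stop("duplicated gene id(s) in header: ", paste(dup_g, collapse = ", "))
  dup_p <- unique(patient_ids[duplicated(patient_ids)])
  if (length(dup_p)) stop("duplicated patient id(s): ", paste(dup_p, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric cell in gene column '", gene_ids[j], "' (row ",
           if (is.na(bad)) "?" else bad, ")")
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  dimnames(m) <- list(patient_ids, gene_ids)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing cell at patient '", patient_ids[idx[1L]], "', gene '",
         gene_ids[idx[2L]], "'")
  }
  validate_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips numeric content exactly
#' (full double precision).
#'
#' @param expression Numeric patients-by-genes matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expression, path) {
  validate_expression(expression)
  df <- data.frame(patient_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(expression) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stop("expression must be a numeric matrix")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("expression must carry patient ids as rownames and gene ids as colnames")
  }
  if (anyDuplicated(rownames(expression))) stop("duplicated patient ids")
  if (anyDuplicated(colnames(expression))) stop("duplicated gene ids")
  if (anyNA(expression)) stop("expression contains missing values")
  invisible(expression)
}

clinical_columns <- c("patient_id", "cohort", "age", "gender", "event", "time")

#' Read and validate a clinical survival table
#'
#' Reads a tab-separated clinical table with columns `patient_id`, `cohort`,
#' `age`, `gender`, `event` and `time`. Rows with missing key fields,
#' nonpositive survival time, nonpositive age, or an event flag outside
#' \{0, 1\} are excluded rather than failing the whole read; the excluded rows
#' are returned in the `"rejected"` attribute (a data frame of
#' `patient_id`, `reason`) and optionally written to `reject_log`.
#'
#' @param path Path to a tab-separated clinical file.
#' @param reject_log Optional path; when given, the rejection log is written
#'   there as TSV.
#' @return A data frame of valid records in file order, with attribute
#'   `"rejected"`.
#' @export
read_clinical_table <- function(path, reject_log = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(clinical_columns, colnames(df))
  if (length(missing_cols)) {
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[clinical_columns]
  df$age <- suppressWarnings(as.numeric(df$age))
  df$event <- suppressWarnings(as.numeric(df$event))
  df$time <- suppressWarnings(as.numeric(df$time))
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(is.na(df$patient_id) | is.na(df$cohort) | is.na(df$gender),
                 "missing field")
  reason <- flag(is.na(df$age), "missing or non-numeric age")
  reason <- flag(is.na(df$event), "missing or non-numeric event")
  reason <- flag(is.na(df$time), "missing or non-numeric time")
  reason <- flag(!is.na(df$age) & df$age <= 0, "nonpositive age")
  reason <- flag(!is.na(df$event) & !df$event %in% c(0, 1), "event not in {0,1}")
  reason <- flag(!is.na(df$time) & df$time <= 0, "nonpositive time")
  keep <- is.na(reason)
  rejected <- data.frame(patient_id = as.character(df$patient_id[!keep]),
                         reason = reason[!keep], stringsAsFactors = FALSE)
  records <- df[keep, , drop = FALSE]
  rownames(records) <- NULL
  if (!is.null(reject_log)) {
    utils::write.table(rejected, reject_log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  attr(records, "rejected") <- rejected
  records
}

#' Construct a single-cohort dataset
#'
#' Pairs an expression matrix with clinical records for one cohort; patients
#' are aligned (same set, same order) between the two.
#'
#' @param expression Numeric patients-by-genes matrix.
#' @param clinical Data frame of validated survival records for the same
#'   patients.
#' @param cohort Cohort label.
#' @return A `cohort_dataset` object (list with `expression`, `clinical`,
#'   `cohort`).
#' @export
cohort_dataset <- function(expression, clinical, cohort) {
  validate_expression(expression)
  if (!setequal(rownames(expression), clinical$patient_id)) {
    stop("patient sets of expression and clinical differ for cohort ", cohort)
  }
  clinical <- clinical[match(rownames(expression), clinical$patient_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(expression = expression, clinical = clinical,
                 cohort = as.character(cohort)),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s: %d patients x %d genes, %d uncensored\n",
              x$cohort, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event == 1)))
  invisible(x)
}

#' Partition cohorts into trainable and held-out sets
#'
#' Splits the clinical table by cohort, aligns each cohort with the shared
#' expression matrix, and partitions cohorts by the number of uncensored
#' (event = 1) patients: cohorts with at least `min_uncensored` uncensored
#' patients are trainable, the rest are held out for prediction only.
#'
#' @param expression Expression matrix covering every clinical patient.
#' @param clinical Validated clinical data frame (see
#'   [read_clinical_table()]).
#' @param min_uncensored Minimum number of uncensored patients a cohort needs
#'   to be trainable (default 20).
#' @return List with elements `trainable` and `heldout`, each a named list of
#'   `cohort_dataset` objects.
#' @export
assemble_cohorts <- function(expression, clinical, min_uncensored = 20L) {
  validate_expression(expression)
  absent <- setdiff(clinical$patient_id, rownames(expression))
  if (length(absent)) {
    stop("clinical patient(s) absent from expression: ",
         paste(absent, collapse = ", "))
  }
  out <- list(trainable = list(), heldout = list())
  for (co in unique(clinical$cohort)) {
    cl <- clinical[clinical$cohort == co, , drop = FALSE]
    ds <- cohort_dataset(expression[cl$patient_id, , drop = FALSE], cl, co)
    side <- if (sum(cl$event == 1) >= min_uncensored) "trainable" else "heldout"
    out[[side]][[co]] <- ds
  }
  out
}

#' Read an undirected PPI edge list
#'
#' Reads a two-column tab-separated edge list (`gene_a<TAB>gene_b`); lines
#' starting with `#` are ignored. Self-loops and parallel edges are dropped so
#' the returned graph is simple.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::graph] with gene ids as vertex names.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("edge list rows must have two columns")
  em <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::simplify(g)
}

#' Write a graph as a two-column edge list
#'
#' @param network An undirected [igraph::graph] with named vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- igraph::as_edgelist(network)
  writeLines(c("# gene_a\tgene_b", paste(em[, 1L], em[, 2L], sep = "\t")), path)
  invisible(path)
}

#' Write a gene weight table to TSV
#'
#' @param weights Named nonnegative numeric vector (gene -> summed gain).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_weights <- function(weights, path) {
  stopifnot(is.numeric(weights), !is.null(names(weights)), all(weights >= 0))
  df <- data.frame(gene = names(weights), weight = as.numeric(weights),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene weight table from TSV
#'
#' @param path Path written by [write_gene_weights()].
#' @return Named numeric vector of weights.
#' @export
read_gene_weights <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$weight, df$gene)
}
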