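# Readers and writers for the tabular interchange formats: tab-delimited
# expression matrices (gene IDs in the first column, sample IDs in the
# header) and CSV clinical tables.

#' Read a tab-delimited expression matrix
#'
#' First column gene IDs, header row sample IDs, real-valued cells.
#' Duplicate gene IDs are collapsed by keeping the row with the highest mean
#' (reported via a message); ragged rows, non-numeric cells and duplicate
#' sample IDs are errors naming the offending line.
#'
#' @param path File path.
#' @param platform Platform tag to attach.
#' @return A validated genes x samples matrix.
#' @export
read_expression_matrix <- function(path, platform = "") {
  fields <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(fields)) != 1)
    stop2("ragged row at line ", which(fields != fields[1])[1], " of ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("expected gene IDs plus >= 1 sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(colnames(df)[-1]))
    stop2("duplicate sample ID in header: ",
          colnames(df)[-1][duplicated(colnames(df)[-1])][1])
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop2("non-numeric cell in column '", colnames(df)[j], "' at line ",
            bad + 1, " of ", path)
    }
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(ids)) {
    means <- rowMeans(m)
    keep <- !logical(nrow(m))
    for (id in unique(ids[duplicated(ids)])) {
      rows <- which(ids == id)
      keep[setdiff(rows, rows[which.max(means[rows])])] <- FALSE
    }
    message(sum(!keep), " duplicate gene row(s) collapsed by max-mean")
    m <- m[keep, , drop = FALSE]
  }
  expression_matrix(m, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x samples matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  check_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with columns `sample_id`, `response` (CR, PR, SD or PD), `os_months`,
#' `event` (death or censored) and optional covariates (`age`, `stage`,
#' `debulking`, `race`).  CR is classified responder; PR, SD and PD
#' non-responder.  Unknown response codes and negative survival times are
#' errors.
#'
#' @param path File path.
#' @return A data.frame with a derived `response_class` column.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "response", "os_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("clinical table lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop2("duplicate sample_id in ", path)
  df$response_class <- map_response_codes(df$response)
  if (any(df$os_months < 0))
    stop2("negative os_months at line ",
          which(df$os_months < 0)[1] + 1, " of ", path)
  bad <- setdiff(unique(df$event), c("death", "censored"))
  if (length(bad)) stop2("unknown event code(s): ", paste(bad, collapse = ", "))
  df
}

#' Write a clinical table as CSV
#'
#' @param clinical Clinical data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(clinical[, setdiff(names(clinical), "response_class")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
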