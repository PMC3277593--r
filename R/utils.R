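# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Deterministically derive a sub-stage seed from a master seed and a tag,
# kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

stop2 <- function(...) stop(..., call. = FALSE)

# Validate a genes x samples expression matrix (numeric, finite, unique ids).
check_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(arg, " must be a numeric genes x samples matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2(arg, " must carry gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(x))) stop2(arg, ": duplicate gene IDs")
  if (anyDuplicated(colnames(x))) stop2(arg, ": duplicate sample IDs")
  if (anyNA(x) || any(!is.finite(x))) stop2(arg, ": non-finite values present")
  invisible(x)
}

#' Construct an expression matrix
#'
#' Light wrapper that validates a genes x samples numeric matrix (unique gene
#' and sample identifiers, no missing values) and attaches a free-text
#' platform tag.  All pipeline stages accept plain matrices of this shape.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set.
#' @param platform Free-text platform tag (e.g. an array name).
#' @return The validated matrix with a `"platform"` attribute.
#' @export
expression_matrix <- function(values, platform = "") {
  check_expression_matrix(values, "values")
  attr(values, "platform") <- as.character(platform)
  values
}

# Normalize sensitivity labels into a named factor with levels
# c("sensitive", "resistant").  Accepts the data.frame emitted by
# select_extreme_lines() or a named character/factor vector.
as_sensitivity_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "label") %in% names(labels)))
    out <- as.character(labels$label)
    names(out) <- as.character(labels$sample_id)
  } else {
    if (is.null(names(labels))) stop2("labels must be named by sample ID")
    out <- stats::setNames(as.character(labels), names(labels))
  }
  bad <- setdiff(unique(out), c("sensitive", "resistant"))
  if (length(bad)) stop2("unknown sensitivity label(s): ", paste(bad, collapse = ", "))
  factor(out, levels = c("sensitive", "resistant"))
}

# Normalize a clinical response into a named factor with levels
# c("responder", "non_responder").  Accepts a clinical table (data.frame with
# sample_id and response/response_class columns) or a named vector.
as_response <- function(response) {
  if (is.data.frame(response)) {
    stopifnot("sample_id" %in% names(response))
    ids <- as.character(response$sample_id)
    if ("response_class" %in% names(response)) {
      cls <- as.character(response$response_class)
    } else if ("response" %in% names(response)) {
      cls <- map_response_codes(as.character(response$response))
    } else {
      stop2("clinical table needs a response or response_class column")
    }
    names(cls) <- ids
  } else {
    cls <- as.character(response)
    if (is.null(names(cls))) names(cls) <- names(response)
    if (any(cls %in% c("CR", "PR", "PD", "SD"))) cls <- map_response_codes(cls)
  }
  bad <- setdiff(unique(cls), c("responder", "non_responder"))
  if (length(bad)) stop2("unknown response class(es): ", paste(bad, collapse = ", "))
  factor(cls, levels = c("responder", "non_responder"))
}

# CR counts as responder; PR, SD and PD as non-responder.
map_response_codes <- function(codes) {
  out <- ifelse(codes == "CR", "responder",
    ifelse(codes %in% c("PR", "PD", "SD"), "non_responder", NA_character_))
  if (anyNA(out)) {
    bad <- unique(codes[is.na(out)])
    stop2("unknown response code(s): ", paste(bad, collapse = ", "),
          " (expected CR, PR, SD or PD)")
  }
  names(out) <- names(codes)
  out
}

# Align a score vector (data.frame sample_id/raw/z or named numeric) with a
# response classification; returns list(score, response) on common samples.
align_scores_response <- function(scores, response, use = c("z", "raw")) {
  use <- match.arg(use)
  if (is.data.frame(scores)) {
    x <- scores[[use]]
    names(x) <- as.character(scores$sample_id)
  } else {
    x <- scores
    if (is.null(names(x))) stop2("scores must be named by sample ID")
  }
  y <- as_response(response)
  common <- intersect(names(x), names(y))
  if (!length(common)) stop2("no samples shared between scores and response")
  list(score = unname(x[common]), response = unname(y[common]),
       sample_id = common)
}
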