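# Internal helpers shared across modules: integer apportionment and TSV I/O
# for expression matrices.

#' Largest-remainder apportionment of counts
#'
#' Splits `n` items into integer class counts proportional to `proportions`,
#' assigning floor counts first and distributing the remainder to the classes
#' with the largest fractional parts (ties resolved by class order). Used by
#' the synthetic-data generators so planted class sizes are reproducible
#' integers that always sum to `n`.
#'
#' @param n Total number of items (non-negative integer).
#' @param proportions Named non-negative numeric vector summing to 1.
#' @return Named integer vector of counts summing to `n`.
#' @examples
#' apportion_counts(10, c(A = 0.55, B = 0.45))
#' @export
apportion_counts <- function(n, proportions) {
  stopifnot(length(n) == 1L, n >= 0, is.numeric(proportions),
            all(proportions >= 0), !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(proportions)), ")")
  }
  raw <- n * proportions
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    frac <- raw - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  setNames(as.integer(base), names(proportions))
}

#' Write an expression dataset as TSV
#'
#' Writes the value matrix with the gene identifier in the first column
#' (`gene_id`) and one column per tissue/stage. If the dataset carries
#' presence/absence calls, a sibling file `<stem>.calls.tsv` is written in the
#' same shape.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output TSV path. The calls sibling replaces a trailing
#'   `.tsv` with `.calls.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$calls)) {
    cdf <- data.frame(gene_id = rownames(dataset$calls),
                      dataset$calls, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(cdf, calls_path(path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

calls_path <- function(path) sub("\\.tsv$", ".calls.tsv", path)

#' Read an expression dataset from TSV
#'
#' Expects the layout written by [write_expression_tsv()]: first column
#' `gene_id`, remaining columns numeric. For array datasets a sibling
#' `<stem>.calls.tsv` with "P"/"A" strings is read when present (or from
#' `calls`, when given explicitly).
#'
#' @param path Values TSV path.
#' @param calls Optional path of the calls matrix; defaults to the
#'   `<stem>.calls.tsv` sibling if it exists.
#' @param kind `"array"` or `"est_counts"`.
#' @param name Dataset name; defaults to the file stem.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, calls = NULL,
                                kind = c("array", "est_counts"),
                                name = NULL) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- sub("\\.tsv$", "", basename(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  storage.mode(values) <- "double"
  call_mat <- NULL
  if (kind == "array") {
    if (is.null(calls) && file.exists(calls_path(path))) calls <- calls_path(path)
    if (!is.null(calls)) {
      cdf <- read.delim(calls, check.names = FALSE, stringsAsFactors = FALSE)
      call_mat <- as.matrix(cdf[, -1, drop = FALSE])
      rownames(call_mat) <- as.character(cdf[[1]])
    }
  }
  expression_dataset(name, values, calls = call_mat, kind = kind)
}

# md5 of a canonical JSON rendering of an R object (via a temp file, since
# base R only fingerprints files)
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
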