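# Five-level tissue-specificity rating from per-dataset z-scores, and the
# cross-dataset ballot that aggregates the per-voter levels.

#' Expression levels in ascending order of tissue specificity
#'
#' `A` (absent), `P` (present), `HP` (highly present), `MS` (multi-tissue
#' specific) and `SP` (specific). The ballot can additionally yield
#' `"UNCLASSIFIED"` when no level reaches the minimum vote count; that value
#' sits outside the specificity order.
#'
#' @format Character vector of length 5.
#' @export
E3_LEVELS <- c("A", "P", "HP", "MS", "SP")

#' Construct an expression dataset (one voter)
#'
#' A genes-by-tissues non-negative value matrix with optional parallel
#' presence/absence calls (MAS5-style "P"/"A" strings). EST-count voters carry
#' integer counts and no call matrix; presence is defined downstream as
#' count > 0.
#'
#' @param name Dataset identifier.
#' @param values Numeric matrix, genes in rows (rownames = gene ids), tissues
#'   in columns (colnames = tissue names). Must be non-negative.
#' @param calls Optional character matrix over `"P"`/`"A"` with the same
#'   dimnames as `values`. Only allowed for `kind = "array"`.
#' @param kind `"array"` (intensity values, optional calls) or `"est_counts"`
#'   (integer counts, no calls).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(name, values, calls = NULL,
                               kind = c("array", "est_counts")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("values must carry gene ids as rownames")
  }
  if (is.null(colnames(values))) stop("values must carry tissue names as colnames")
  if (anyDuplicated(colnames(values))) stop("duplicate tissue names")
  if (nrow(values) > 0 && anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (kind == "est_counts") {
    if (!is.null(calls)) stop("est_counts datasets carry no P/A calls")
    if (any(values != round(values))) stop("est_counts values must be integers")
  }
  if (!is.null(calls)) {
    if (!identical(dim(calls), dim(values)) ||
        !identical(dimnames(calls), dimnames(values))) {
      stop("calls must have identical shape and axes to values")
    }
    if (!all(calls %in% c("P", "A"))) stop("calls must be 'P' or 'A'")
  }
  structure(list(name = name, values = values, calls = calls, kind = kind),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> %d genes x %d tissues (%s%s)\n",
              x$name, nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$calls)) "" else ", with P/A calls"))
  invisible(x)
}

#' Rating configuration
#'
#' Thresholds for the z-score-based levels and the ballot. The defaults
#' (`z1 = 1`, `z2 = 1.96`, `z3 = 2.58`) are the standard-normal quantiles
#' within which roughly 68%, 95% and 99% of tissue z-scores are expected to
#' fall if a gene's per-tissue expression were normally distributed.
#'
#' @param z1,z2,z3 Increasing positive thresholds: a gene is HP in tissue t if
#'   `z_t >= z1`, MS if `z_t >= z2`, and SP if `z_t >= z3` while every other
#'   tissue has `z <= z2`.
#' @param min_votes Minimum number of concordant voters required before the
#'   ballot assigns a level (default 2).
#' @param sd_mode `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n) standard deviation in the z-score.
#' @return Object of class `rating_config`.
#' @export
rating_config <- function(z1 = 1, z2 = 1.96, z3 = 2.58, min_votes = 2,
                          sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (!(z1 > 0 && z1 < z2 && z2 < z3)) stop("need 0 < z1 < z2 < z3")
  if (min_votes < 1) stop("min_votes must be >= 1")
  structure(list(z1 = z1, z2 = z2, z3 = z3, min_votes = as.integer(min_votes),
                 sd_mode = sd_mode),
            class = "rating_config")
}

#' Per-tissue z-scores of one gene within one dataset
#'
#' Standardizes a gene's expression vector across the tissues of a single
#' dataset: `z_t = (x_t - mean) / s`, where the mean and standard deviation
#' are taken over all tissues of that gene. A constant vector (sd = 0) yields
#' all-zero z-scores.
#'
#' @param x Numeric vector of per-tissue expression values (length >= 2).
#' @param sd_mode `"sample"` (n-1) or `"population"` (n) divisor.
#' @return Numeric vector of z-scores, same length/names as `x`.
#' @examples
#' zscores(c(100, rep(1, 9)))  # one-hot high: z = (n-1)/sqrt(n) = 2.846
#' @export
zscores <- function(x, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (length(x) < 2) stop("need at least 2 tissues to compute z-scores")
  m <- mean(x)
  s <- if (sd_mode == "sample") sd(x) else sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) return(setNames(rep(0, length(x)), names(x)))
  (x - m) / s
}

# row-wise z-scores of a genes x tissues matrix; rows with sd 0 become 0
zscore_rows <- function(values, sd_mode = "sample") {
  n <- ncol(values)
  m <- rowMeans(values)
  cv <- values - m
  ss <- rowSums(cv^2)
  s <- sqrt(ss / if (sd_mode == "sample") n - 1 else n)
  z <- cv / s
  z[s == 0 | !is.finite(s), ] <- 0
  z
}

# warn when the one-hot upper bound on the sample z-score, (n-1)/sqrt(n),
# cannot reach z3: SP is then unattainable for this tissue count
check_sp_attainable <- function(n_tissues, config) {
  bound <- (n_tissues - 1) / sqrt(n_tissues)
  if (config$sd_mode == "population") bound <- sqrt(n_tissues - 1)
  if (bound < config$z3) {
    warning(sprintf(paste0(
      "with %d tissues the maximum attainable z-score is %.3f < z3 = %.2f; ",
      "level SP can never be assigned"), n_tissues, bound, config$z3),
      call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' Rate every gene/tissue of one dataset on the five-level scale
#'
#' For each gene the per-tissue z-scores are computed within the dataset, and
#' each tissue is assigned the most specific satisfied level:
#' * `A` if the presence call is "A" (for EST-count voters: count = 0) —
#'   the call overrides any z-score;
#' * `SP` if `z_t >= z3` and `z_i <= z2` for every other tissue;
#' * `MS` if `z_t >= z2`;
#' * `HP` if `z_t >= z1`;
#' * `P` otherwise.
#'
#' Array datasets without a call matrix are treated as all-present. EST-count
#' voters are normalized to counts per million within each tissue column
#' before the z-scores are taken, and presence is count > 0.
#'
#' @param dataset An [expression_dataset()].
#' @param config A [rating_config()].
#' @return Character matrix (genes x tissues) over [E3_LEVELS].
#' @export
rate_one_dataset <- function(dataset, config = rating_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  values <- dataset$values
  if (ncol(values) < 2) stop("need at least 2 tissues")
  check_sp_attainable(ncol(values), config)
  if (nrow(values) == 0) {
    return(matrix(character(), 0, ncol(values),
                  dimnames = list(NULL, colnames(values))))
  }
  if (dataset$kind == "est_counts") {
    present <- values > 0
    cs <- colSums(values)
    cs[cs == 0] <- 1
    zin <- sweep(values, 2, cs, "/") * 1e6
  } else {
    present <- if (is.null(dataset$calls)) {
      matrix(TRUE, nrow(values), ncol(values))
    } else dataset$calls == "P"
    zin <- values
  }
  z <- zscore_rows(zin, config$sd_mode)
  lev <- matrix("P", nrow(values), ncol(values), dimnames = dimnames(values))
  lev[z >= config$z1] <- "HP"
  lev[z >= config$z2] <- "MS"
  # SP: z_t >= z3 and no other tissue exceeds z2. Since z_t itself exceeds
  # z2, the row must contain exactly one tissue with z > z2.
  sp <- (z >= config$z3) & (rowSums(z > config$z2) == 1)
  lev[sp] <- "SP"
  lev[!present] <- "A"
  lev
}

#' Cross-dataset ballot over per-voter levels
#'
#' Each dataset votes one level; abstentions (`NA`) are discarded. The level
#' supported by the highest number of votes wins, provided that count reaches
#' `min_votes`; ties at the maximum resolve to the least specific tied level
#' (so two MS votes against two SP votes yield MS). If no level reaches
#' `min_votes` the result is `"UNCLASSIFIED"`.
#'
#' @param votes Character vector over [E3_LEVELS], with `NA` for abstaining
#'   voters. At least one voter must not abstain.
#' @param config A [rating_config()] (only `min_votes` is used).
#' @return A single level, or `"UNCLASSIFIED"`.
#' @examples
#' ballot(c("SP", "SP", "MS", "MS", "P"))  # tie at 2 -> less specific: MS
#' @export
ballot <- function(votes, config = rating_config()) {
  v <- votes[!is.na(votes)]
  if (length(v) == 0) stop("all voters abstain")
  bad <- setdiff(unique(v), E3_LEVELS)
  if (length(bad)) stop("unknown levels in votes: ", paste(bad, collapse = ", "))
  counts <- table(factor(v, levels = E3_LEVELS))
  mx <- max(counts)
  if (mx < config$min_votes) return("UNCLASSIFIED")
  # E3_LEVELS is ordered least -> most specific, so the first maximal
  # entry is the least specific tied level
  names(counts)[counts == mx][1]
}

#' Rate all datasets and aggregate by ballot
#'
#' Applies [rate_one_dataset()] to every voter, then runs the per-gene,
#' per-tissue [ballot()] over the union of genes. A gene missing from a
#' dataset abstains in that dataset; a gene rated in fewer than `min_votes`
#' datasets therefore ends up `"UNCLASSIFIED"`.
#'
#' @param datasets List of [expression_dataset()] objects (>= 2) sharing a
#'   gene-id namespace and an identical tissue set.
#' @param config A [rating_config()].
#' @return Object of class `rating_matrix`: a list with `per_dataset` (one
#'   level matrix per voter, `NA` = abstain), `final` (balloted levels),
#'   `genes`, `tissues` and `config`.
#' @export
rate_all <- function(datasets, config = rating_config()) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  tissues <- colnames(datasets[[1]]$values)
  for (d in datasets) {
    if (!setequal(colnames(d$values), tissues)) {
      stop("all datasets must cover the same tissues (dataset '", d$name,
           "' differs)")
    }
  }
  gene_sets <- lapply(datasets, function(d) rownames(d$values))
  genes <- Reduce(union, gene_sets)
  if (length(genes) == 0) stop("datasets contain no genes")
  in_k <- Reduce(`+`, lapply(gene_sets, function(g) genes %in% g))
  if (!any(in_k >= 2)) {
    stop("no overlapping genes across datasets (", length(genes),
         " genes, none shared by >= 2 voters)")
  }
  per_dataset <- lapply(datasets, function(d) {
    rated <- rate_one_dataset(d, config)
    full <- matrix(NA_character_, length(genes), length(tissues),
                   dimnames = list(genes, tissues))
    full[rownames(rated), tissues] <- rated[, tissues, drop = FALSE]
    full
  })
  names(per_dataset) <- vapply(datasets, `[[`, "", "name")
  # vectorized ballot: per-level vote counts, then assign least-specific
  # maximal level meeting min_votes
  counts <- lapply(E3_LEVELS, function(lv) {
    Reduce(`+`, lapply(per_dataset, function(m) (!is.na(m)) & m == lv))
  })
  names(counts) <- E3_LEVELS
  maxc <- Reduce(pmax, counts)
  final <- matrix("UNCLASSIFIED", length(genes), length(tissues),
                  dimnames = list(genes, tissues))
  undecided <- matrix(TRUE, length(genes), length(tissues))
  for (lv in E3_LEVELS) {
    hit <- undecided & counts[[lv]] == maxc & maxc >= config$min_votes
    final[hit] <- lv
    undecided <- undecided & !hit
  }
  structure(list(per_dataset = per_dataset, final = final,
                 genes = genes, tissues = tissues, config = config),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d genes x %d tissues, %d voters\n",
              length(x$genes), length(x$tissues), length(x$per_dataset)))
  print(table(factor(x$final, levels = c(E3_LEVELS, "UNCLASSIFIED"))))
  invisible(x)
}

#' Cross-tabulate catalogue families against final expression levels
#'
#' Counts catalogue genes per (family, balloted level) for one tissue, with
#' row and column totals. Catalogue genes absent from the rating matrix are
#' counted as `"UNCLASSIFIED"`.
#'
#' @param catalog An `e3_catalog` from [classify_families()].
#' @param ratings A `rating_matrix` from [rate_all()].
#' @param tissue Tissue name (must be a column of the rating matrix).
#' @return Integer matrix: families (plus `Total`) x levels `SP, MS, HP, P,
#'   A, UNCLASSIFIED` (plus `Total`).
#' @export
level_cross_tab <- function(catalog, ratings, tissue) {
  stopifnot(inherits(catalog, "e3_catalog"), inherits(ratings, "rating_matrix"))
  if (!tissue %in% ratings$tissues) stop("unknown tissue: ", tissue)
  fams <- c("RING", "HECT", "U-box")
  levs <- c("SP", "MS", "HP", "P", "A", "UNCLASSIFIED")
  lev <- rep("UNCLASSIFIED", nrow(catalog))
  hit <- catalog$gene_id %in% rownames(ratings$final)
  lev[hit] <- ratings$final[catalog$gene_id[hit], tissue]
  tab <- table(factor(catalog$family, levels = fams),
               factor(lev, levels = levs))
  tab <- unclass(tab)
  tab <- rbind(tab, Total = colSums(tab))
  tab <- cbind(tab, Total = rowSums(tab))
  storage.mode(tab) <- "integer"
  tab
}
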