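# Developmental expression onset during spermatogenesis: a 3-fold
# differential-expression filter, a half-max onset rule replacing visual
# heat-map inspection, phase grouping (MI/ME/PM) and a cross-dataset vote.

#' Stage groups in phase order
#'
#' `MI` (high from the mitotic stage), `ME` (expression rises at meiosis),
#' `PM` (rises post-meiotically), plus `NONE` for genes that fail the
#' fold-change filter or the vote.
#'
#' @format Character vector of length 4.
#' @export
STAGE_GROUPS <- c("MI", "ME", "PM", "NONE")

STAGE_PHASES <- c("mitotic", "meiotic", "post-meiotic")
PHASE_TO_GROUP <- c(mitotic = "MI", meiotic = "ME", `post-meiotic` = "PM")

#' Construct a staged developmental dataset
#'
#' An ordered genes-by-stages value matrix where every stage carries a
#' spermatogenic phase tag, and phase tags are non-decreasing along the stage
#' axis (mitotic stages first, then meiotic, then post-meiotic).
#'
#' @param name Dataset identifier.
#' @param values Non-negative numeric matrix, genes in rows, ordered stages
#'   in columns.
#' @param phases Character vector, one of `"mitotic"`, `"meiotic"`,
#'   `"post-meiotic"` per stage column.
#' @return Object of class `stage_dataset`.
#' @export
stage_dataset <- function(name, values, phases) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (ncol(values) < 2) stop("need at least 2 stages")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(phases) != ncol(values)) stop("one phase tag per stage required")
  if (!all(phases %in% STAGE_PHASES)) {
    stop("phases must be one of: ", paste(STAGE_PHASES, collapse = ", "))
  }
  ord <- match(phases, STAGE_PHASES)
  if (is.unsorted(ord)) {
    stop("phase tags must be non-decreasing along the stage order")
  }
  structure(list(name = name, values = values, phases = phases),
            class = "stage_dataset")
}

#' Stage-grouping configuration
#'
#' @param fold_threshold Minimum max/min fold change for a gene to count as
#'   differentially expressed across the time course (default 3).
#' @param floor Pseudo-intensity added to numerator and denominator before
#'   the ratio, guarding against near-zero array values (default 1).
#' @param min_votes Datasets that must agree before a group is assigned
#'   (default 2).
#' @return Object of class `stage_config`.
#' @export
stage_config <- function(fold_threshold = 3, floor = 1, min_votes = 2) {
  if (fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (floor <= 0) stop("floor must be positive")
  structure(list(fold_threshold = fold_threshold, floor = floor,
                 min_votes = as.integer(min_votes)),
            class = "stage_config")
}

#' Differential-expression fold filter
#'
#' A profile passes when `(max + floor) / (min + floor) >= fold_threshold`,
#' i.e. the gene is at least `fold_threshold`-fold differentially expressed
#' at one or more stages.
#'
#' @param profile Non-negative numeric vector over ordered stages (length
#'   >= 2).
#' @param config A [stage_config()].
#' @return Logical scalar.
#' @examples
#' fold_filter(c(10, 35, 40, 38))  # 41/11 = 3.73 -> TRUE
#' @export
fold_filter <- function(profile, config = stage_config()) {
  if (length(profile) < 2) stop("profile needs at least 2 stages")
  if (any(profile < 0)) stop("negative expression values")
  (max(profile) + config$floor) / (min(profile) + config$floor) >=
    config$fold_threshold
}

#' Onset stage of an expression rise
#'
#' Returns the index (1-based) of the first stage whose value reaches the
#' half-max level `min + 0.5 * (max - min)`. Index 1 means the gene is high
#' from the first stage on.
#'
#' @param profile Numeric vector over ordered stages.
#' @param config A [stage_config()] (unused by the default half-max rule,
#'   kept for interface stability).
#' @return Integer stage index.
#' @examples
#' onset_stage(c(5, 50, 60, 55))  # half-max 32.5, first crossed at stage 2
#' @export
onset_stage <- function(profile, config = stage_config()) {
  half <- min(profile) + 0.5 * (max(profile) - min(profile))
  unname(which(profile >= half)[1])
}

#' Assign one gene to a spermatogenic stage group
#'
#' `NONE` if the profile fails [fold_filter()]; otherwise the group given by
#' the phase of the onset stage: mitotic -> MI, meiotic -> ME, post-meiotic
#' -> PM.
#'
#' @param profile Numeric vector over ordered stages.
#' @param phases Phase tag per stage (see [stage_dataset()]).
#' @param config A [stage_config()].
#' @return One of [STAGE_GROUPS].
#' @export
assign_group <- function(profile, phases, config = stage_config()) {
  stopifnot(length(phases) == length(profile))
  if (!fold_filter(profile, config)) return("NONE")
  unname(PHASE_TO_GROUP[phases[onset_stage(profile, config)]])
}

# vectorized assign_group over a stage_dataset
assign_groups_dataset <- function(dataset, config = stage_config()) {
  stopifnot(inherits(dataset, "stage_dataset"))
  v <- dataset$values
  if (nrow(v) == 0) return(setNames(character(), character()))
  mx <- apply(v, 1, max)
  mn <- apply(v, 1, min)
  pass <- (mx + config$floor) / (mn + config$floor) >= config$fold_threshold
  half <- mn + 0.5 * (mx - mn)
  onset <- max.col(v >= half, ties.method = "first")
  grp <- unname(PHASE_TO_GROUP[dataset$phases[onset]])
  grp[!pass] <- "NONE"
  setNames(grp, rownames(v))
}

#' Vote a final stage group across datasets
#'
#' Each dataset casts one group vote per gene; `NONE` is an explicit vote
#' (a gene differentially expressed in only one dataset cannot be grouped),
#' `NA` is an abstention. A group among MI/ME/PM wins when it holds the
#' maximal vote count and that count reaches `min_votes`; otherwise the
#' result is `NONE`. Ties at the maximum resolve to the earliest phase
#' (MI < ME < PM).
#'
#' @param votes Character vector over [STAGE_GROUPS] (with `NA` = abstain).
#' @param config A [stage_config()].
#' @return One of `"MI"`, `"ME"`, `"PM"`, `"NONE"`.
#' @examples
#' group_ballot(c("ME", "ME", "PM"))  # ME
#' group_ballot(c("MI", "ME", "PM"))  # no group reaches 2 votes -> NONE
#' @export
group_ballot <- function(votes, config = stage_config()) {
  v <- votes[!is.na(votes)]
  if (length(v) < config$min_votes) {
    stop("need at least ", config$min_votes, " voting datasets")
  }
  bad <- setdiff(unique(v), STAGE_GROUPS)
  if (length(bad)) stop("unknown groups in votes: ", paste(bad, collapse = ", "))
  counts <- table(factor(v, levels = c("MI", "ME", "PM")))
  mx <- max(counts)
  if (mx < config$min_votes) return("NONE")
  names(counts)[counts == mx][1]  # ties -> earliest phase
}

#' Assign and vote stage groups across datasets
#'
#' Runs the per-dataset assignment on every voter, then [group_ballot()] per
#' gene over the union of genes. Genes missing from a dataset abstain there;
#' genes voted on by fewer than `min_votes` datasets are `NONE`.
#'
#' @param datasets List of [stage_dataset()] objects (>= 2).
#' @param config A [stage_config()].
#' @return Object of class `stage_groups`: list with `per_dataset` (named
#'   group vectors), `final` (named vector of balloted groups) and `config`.
#' @export
stage_all <- function(datasets, config = stage_config()) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  per_dataset <- lapply(datasets, assign_groups_dataset, config = config)
  names(per_dataset) <- vapply(datasets, `[[`, "", "name")
  genes <- Reduce(union, lapply(per_dataset, names))
  votes <- vapply(per_dataset, function(g) unname(g[genes]), character(length(genes)))
  if (length(genes) == 1) votes <- matrix(votes, nrow = 1)
  final <- setNames(rep("NONE", length(genes)), genes)
  n_votes <- rowSums(!is.na(votes))
  ok <- n_votes >= config$min_votes
  final[ok] <- apply(votes[ok, , drop = FALSE], 1, group_ballot, config = config)
  structure(list(per_dataset = per_dataset, final = final, config = config),
            class = "stage_groups")
}

#' Map days-postpartum time points to spermatogenic phases
#'
#' Whole-testis developmental series sample successive germ-cell types as the
#' first wave of spermatogenesis advances; day breakpoints stand in for the
#' first appearance of meiotic and post-meiotic cells.
#'
#' @param days Numeric vector of days postpartum.
#' @param mitotic_max Last day still counted as mitotic (default 8, when the
#'   testis contains spermatogonia but no spermatocytes).
#' @param meiotic_max Last day counted as meiotic (default 17, pachytene
#'   spermatocytes present, spermatids not yet).
#' @return Character vector of phase tags.
#' @export
dpp_phases <- function(days, mitotic_max = 8, meiotic_max = 17) {
  ifelse(days <= mitotic_max, "mitotic",
         ifelse(days <= meiotic_max, "meiotic", "post-meiotic"))
}

#' Cross-tabulate stage groups against testis expression levels
#'
#' Counts genes per (stage group, balloted expression level) for one tissue,
#' over the levels SP, MS, HP and P, with totals — the intersection of the
#' developmental grouping with the tissue-specificity classes.
#'
#' @param groups A `stage_groups` object from [stage_all()], or a named
#'   character vector of final groups.
#' @param ratings A `rating_matrix` from [rate_all()].
#' @param tissue Tissue name.
#' @return Integer matrix: groups MI/ME/PM (plus `Total`) x levels
#'   SP/MS/HP/P (plus `Total`).
#' @export
stage_cross_tab <- function(groups, ratings, tissue) {
  if (inherits(groups, "stage_groups")) groups <- groups$final
  stopifnot(inherits(ratings, "rating_matrix"))
  if (!tissue %in% ratings$tissues) stop("unknown tissue: ", tissue)
  levs <- c("SP", "MS", "HP", "P")
  genes <- intersect(names(groups), rownames(ratings$final))
  grp <- groups[genes]
  lev <- ratings$final[genes, tissue]
  keep <- grp %in% c("MI", "ME", "PM") & lev %in% levs
  tab <- table(factor(grp[keep], levels = c("MI", "ME", "PM")),
               factor(lev[keep], levels = levs))
  tab <- unclass(tab)
  tab <- rbind(tab, Total = colSums(tab))
  tab <- cbind(tab, Total = rowSums(tab))
  storage.mode(tab) <- "integer"
  tab
}
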