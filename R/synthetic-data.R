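# Synthetic-data generators: multi-tissue expression panels with planted
# specificity classes and noisy P/A calls, a Poisson EST-count voter, staged
# developmental time courses with planted onset groups, and toy domain /
# ortholog-group fixtures. All randomness flows from a single integer seed,
# with one derived stream per generated dataset.

#' Configuration of a synthetic multi-tissue expression panel
#'
#' Defines the conditions under which the tissue-panel voters are generated:
#' gene count, tissue set, the mixture of planted specificity classes, the
#' log2-scale baseline distribution, planted fold elevations, measurement
#' noise and presence-call error. Values are generated on log2 scale and
#' exponentiated to MAS5-style intensity scale.
#'
#' Classes are planted per the target tissue: `A` genes sit at `absent_level`
#' everywhere and are called absent; `P` genes are flat at their baseline;
#' `SP` genes are elevated `sp_fold`-fold in the target tissue only; `MS` and
#' `HP` genes additionally elevate a companion tissue, with the companion
#' fraction solved so that the target tissue's noise-free z-score lands in
#' the middle of the MS band (between `z2` and `z3`) or the HP band (between
#' `z1` and `z2`) respectively.
#'
#' @param n_genes Number of genes.
#' @param tissues Ordered tissue names (>= 9, no duplicates, containing
#'   `target_tissue`); default 10 tissues including "testis".
#' @param target_tissue Tissue in which specificity classes are planted.
#' @param class_proportions Named fractions over `A, P, HP, MS, SP` summing
#'   to 1 (largest-remainder apportionment to integer counts); the default
#'   approximates the class mix observed for E3 genes in the mouse testis.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log2 intensity
#'   distribution.
#' @param noise_log_sd Per-measurement log2-scale noise standard deviation.
#' @param sp_fold Fold elevation of the target tissue for SP genes (>= 8).
#' @param ms_fold,hp_fold Fold elevations used for the MS / HP geometries.
#' @param absent_level Log2 intensity of absent genes.
#' @param call_threshold Intensity below which the P/A call is "A".
#' @param call_flip_rate Probability of flipping each P/A call.
#' @param n_datasets Number of array voters (default 4; the EST voter from
#'   [generate_est_voter()] is the customary fifth).
#' @param est_depth Mean EST count at baseline intensity for the EST voter.
#' @param seed Integer seed; identical configs give byte-identical data.
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(n_genes = 2000,
                         tissues = c("testis", "brain", "heart", "kidney",
                                     "liver", "lung", "muscle", "ovary",
                                     "spleen", "thymus"),
                         target_tissue = "testis",
                         class_proportions = c(A = 0.15, P = 0.65, HP = 0.10,
                                               MS = 0.02, SP = 0.08),
                         baseline_log_mean = 7, baseline_log_sd = 1,
                         noise_log_sd = 0.2,
                         sp_fold = 16, ms_fold = 8, hp_fold = 8,
                         absent_level = 2, call_threshold = 16,
                         call_flip_rate = 0.02,
                         n_datasets = 4, est_depth = 20, seed = 1) {
  if (length(tissues) < 2) stop("need at least 2 tissues")
  if (anyDuplicated(tissues)) stop("tissues contains duplicates")
  if (!target_tissue %in% tissues) stop("target tissue not among tissues")
  cp <- class_proportions[c("A", "P", "HP", "MS", "SP")]
  if (anyNA(cp)) stop("class_proportions must name A, P, HP, MS, SP")
  if (abs(sum(cp) - 1) > 1e-9) stop("class_proportions must sum to 1")
  if (sp_fold < 8) stop("sp_fold must be >= 8")
  if (call_flip_rate < 0 || call_flip_rate > 1) stop("call_flip_rate in [0,1]")
  if (any(cp[c("HP", "MS", "SP")] > 0) && length(tissues) < 9) {
    stop("planting HP/MS/SP classes requires at least 9 tissues")
  }
  structure(list(n_genes = as.integer(n_genes), tissues = tissues,
                 target_tissue = target_tissue, class_proportions = cp,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_log_sd = noise_log_sd,
                 sp_fold = sp_fold, ms_fold = ms_fold, hp_fold = hp_fold,
                 absent_level = absent_level,
                 call_threshold = call_threshold,
                 call_flip_rate = call_flip_rate,
                 n_datasets = as.integer(n_datasets),
                 est_depth = est_depth, seed = as.integer(seed)),
            class = "panel_config")
}

# z-score of element idx in the pattern (1, beta x k, 0 x (n-1-k))
pattern_z <- function(beta, n, k, idx) {
  x <- c(1, rep(beta, k), rep(0, n - 1 - k))
  ((x - mean(x)) / sd(x))[idx]
}

# Companion geometry for a planted class. target_z is where the target
# tissue's noise-free z-score should land. For MS the target is the maximum
# and k companions at fraction beta pull its z down from (n-1)/sqrt(n); k is
# the smallest companion count that brings target_z within reach. For HP one
# full-height companion dominates and the target sits at fraction beta.
solve_ms_geometry <- function(n, target_z) {
  if (pattern_z(0, n, 1, 1) <= target_z) {
    stop(sprintf("MS geometry infeasible: max z %.3f <= target %.3f for %d tissues",
                 pattern_z(0, n, 1, 1), target_z, n))
  }
  for (k in seq_len(n - 2)) {
    if (pattern_z(1, n, k, 1) <= target_z) {
      beta <- uniroot(function(b) pattern_z(b, n, k, 1) - target_z,
                      c(1e-9, 1), tol = 1e-12)$root
      return(list(k = k, beta = beta))
    }
  }
  stop("MS geometry infeasible for ", n, " tissues")
}

solve_hp_geometry <- function(n, target_z) {
  if (pattern_z(1, n, 1, 2) < target_z) {
    stop(sprintf("HP geometry infeasible: two-tissue z %.3f < target %.3f for %d tissues",
                 pattern_z(1, n, 1, 2), target_z, n))
  }
  beta <- uniroot(function(b) pattern_z(b, n, 1, 2) - target_z,
                  c(1e-9, 1), tol = 1e-12)$root
  list(k = 1L, beta = beta)
}

# deterministic noise-free blueprint shared by the array and EST generators:
# planted classes, baselines and the intensity pattern matrix
panel_blueprint <- function(config, thresholds = rating_config()) {
  n <- config$n_genes
  tissues <- config$tissues
  nt <- length(tissues)
  ti <- match(config$target_tissue, tissues)
  set.seed(config$seed)
  counts <- apportion_counts(n, config$class_proportions)
  classes <- if (n > 0) sample(rep(names(counts), counts)) else character()
  genes <- sprintf("g%05d", seq_len(n))
  b <- rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  # planted present genes must sit above the detection threshold, or the
  # planted class would contradict its own P/A call; truncate the baseline
  # distribution at twice the call threshold
  b <- pmax(b, log2(config$call_threshold) + 1)
  pattern <- matrix(2^b, n, nt, dimnames = list(genes, tissues))
  is_a <- classes == "A"
  pattern[is_a, ] <- 2^config$absent_level
  sp <- which(classes == "SP")
  pattern[sp, ti] <- 2^b[sp] * config$sp_fold
  ms <- which(classes == "MS")
  if (length(ms)) {
    geo <- solve_ms_geometry(nt, (thresholds$z2 + thresholds$z3) / 2)
    for (g in ms) {
      delta <- (config$ms_fold - 1) * 2^b[g]
      comp <- sample(setdiff(seq_len(nt), ti), geo$k)
      pattern[g, ti] <- 2^b[g] + delta
      pattern[g, comp] <- 2^b[g] + geo$beta * delta
    }
  }
  hp <- which(classes == "HP")
  if (length(hp)) {
    geo <- solve_hp_geometry(nt, (thresholds$z1 + thresholds$z2) / 2)
    for (g in hp) {
      delta <- (config$hp_fold - 1) * 2^b[g]
      comp <- sample(setdiff(seq_len(nt), ti), geo$k)
      pattern[g, ti] <- 2^b[g] + geo$beta * delta
      pattern[g, comp] <- 2^b[g] + delta
    }
  }
  list(genes = genes, classes = setNames(classes, genes), pattern = pattern,
       target_index = ti)
}

# derived per-dataset seed, kept within 32-bit integer range
derive_seed <- function(seed, i) (seed %% 2000000000L) + i

truth_frame <- function(labels, axis) {
  data.frame(gene_id = names(labels), axis = axis,
             label = unname(labels), stringsAsFactors = FALSE)
}

#' Generate array-style tissue-panel voters with planted truth
#'
#' Produces `n_datasets` microarray-like expression datasets (intensity
#' values plus P/A calls) sharing one gene namespace and one planted truth:
#' each gene carries one specificity class in the target tissue. With
#' `noise_log_sd = 0` and `call_flip_rate = 0` the single-dataset rater
#' recovers every planted label exactly (provided the tissue count makes the
#' label attainable).
#'
#' @param config A [panel_config()].
#' @return List with `datasets` (list of [expression_dataset()]) and `truth`
#'   (data frame `gene_id`, `axis = "specificity"`, `label`).
#' @export
generate_tissue_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  bp <- panel_blueprint(config)
  n <- config$n_genes
  nt <- length(config$tissues)
  datasets <- lapply(seq_len(config$n_datasets), function(i) {
    set.seed(derive_seed(config$seed, i))
    noise <- matrix(rnorm(n * nt, 0, config$noise_log_sd), n, nt)
    values <- bp$pattern * 2^noise
    calls <- matrix(ifelse(values >= config$call_threshold, "P", "A"), n, nt,
                    dimnames = dimnames(values))
    if (config$call_flip_rate > 0 && n > 0) {
      flip <- matrix(runif(n * nt) < config$call_flip_rate, n, nt)
      calls[flip] <- ifelse(calls[flip] == "P", "A", "P")
    }
    expression_dataset(sprintf("array%d", i), values, calls, "array")
  })
  list(datasets = datasets, truth = truth_frame(bp$classes, "specificity"))
}

#' Generate the EST-count voter
#'
#' Draws a genes-by-tissues matrix of non-negative integer counts, Poisson
#' with rates proportional to the same planted intensity pattern as the array
#' voters (`est_depth` expected counts at baseline intensity). No call matrix
#' is attached; presence is defined downstream as count > 0.
#'
#' @param config A [panel_config()] (the same one used for the array panel,
#'   so the planted truth is shared).
#' @return An [expression_dataset()] of kind `est_counts`.
#' @export
generate_est_voter <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  bp <- panel_blueprint(config)
  lambda <- config$est_depth * bp$pattern / 2^config$baseline_log_mean
  set.seed(derive_seed(config$seed, 1000003L))
  counts <- matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda),
                   dimnames = dimnames(lambda))
  storage.mode(counts) <- "double"
  expression_dataset("est", counts, NULL, "est_counts")
}

#' Generate the full five-voter panel
#'
#' Convenience wrapper combining [generate_tissue_panel()]'s array voters
#' with the [generate_est_voter()] as the final voter.
#'
#' @param config A [panel_config()].
#' @return List with `datasets` (arrays then EST) and `truth`.
#' @export
generate_panel_voters <- function(config) {
  panel <- generate_tissue_panel(config)
  panel$datasets <- c(panel$datasets, list(generate_est_voter(config)))
  panel
}

#' Configuration of a synthetic spermatogenesis time course
#'
#' @param n_genes Number of genes.
#' @param stages Named character vector: ordered stage names mapped to phase
#'   tags (`mitotic`, `meiotic`, `post-meiotic`, non-decreasing). Default:
#'   the four spermatogenic cell types SG-A, pacSC, rST, eST.
#' @param group_proportions Named fractions over `MI, ME, PM, NONE` summing
#'   to 1.
#' @param onset_fold Fold elevation of the high over the low plateau
#'   (>= 3, so planted grouped genes always pass the 3-fold filter).
#' @param noise_log_sd Per-measurement log2 noise standard deviation.
#' @param baseline_log_mean,baseline_log_sd Low-plateau log2 intensity
#'   distribution.
#' @param n_datasets Number of voters (default 3).
#' @param seed Integer seed.
#' @return Object of class `course_config`.
#' @export
course_config <- function(n_genes = 2000,
                          stages = c("SG-A" = "mitotic", "pacSC" = "meiotic",
                                     "rST" = "post-meiotic",
                                     "eST" = "post-meiotic"),
                          group_proportions = c(MI = 0.05, ME = 0.06,
                                                PM = 0.015, NONE = 0.875),
                          onset_fold = 8, noise_log_sd = 0.2,
                          baseline_log_mean = 6, baseline_log_sd = 0.5,
                          n_datasets = 3, seed = 1) {
  if (length(stages) < 2) stop("need at least 2 stages")
  if (!all(stages %in% STAGE_PHASES)) {
    stop("stage phases must be mitotic/meiotic/post-meiotic")
  }
  if (is.unsorted(match(stages, STAGE_PHASES))) {
    stop("phases must be non-decreasing along the stage order")
  }
  if (onset_fold < 3) {
    stop("onset_fold must be >= 3 (planted groups must pass the 3-fold filter)")
  }
  gp <- group_proportions[c("MI", "ME", "PM", "NONE")]
  if (anyNA(gp)) stop("group_proportions must name MI, ME, PM, NONE")
  if (abs(sum(gp) - 1) > 1e-9) stop("group_proportions must sum to 1")
  for (g in c("MI", "ME", "PM")) {
    phase <- c(MI = "mitotic", ME = "meiotic", PM = "post-meiotic")[g]
    if (gp[g] > 0 && !phase %in% stages) {
      stop("cannot plant ", g, " genes: no ", phase, " stage configured")
    }
  }
  structure(list(n_genes = as.integer(n_genes), stages = stages,
                 group_proportions = gp, onset_fold = onset_fold,
                 noise_log_sd = noise_log_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 n_datasets = as.integer(n_datasets), seed = as.integer(seed)),
            class = "course_config")
}

#' Generate staged developmental datasets with planted onset groups
#'
#' Planted `MI` genes are high at the mitotic stage(s) and low afterwards;
#' `ME` genes rise `onset_fold`-fold at the first meiotic stage; `PM` genes
#' rise at the first post-meiotic stage; `NONE` genes stay flat. With zero
#' noise, [stage_all()] recovers every planted group.
#'
#' @param config A [course_config()].
#' @return List with `datasets` (list of [stage_dataset()]) and `truth`
#'   (data frame `gene_id`, `axis = "stage_group"`, `label`).
#' @export
generate_stage_course <- function(config) {
  stopifnot(inherits(config, "course_config"))
  n <- config$n_genes
  phases <- unname(config$stages)
  ns <- length(phases)
  # distinct stream offset so a shared seed does not couple the planted
  # course groups to the planted panel classes
  set.seed(derive_seed(config$seed, 2000003L))
  counts <- apportion_counts(n, config$group_proportions)
  classes <- if (n > 0) sample(rep(names(counts), counts)) else character()
  genes <- sprintf("g%05d", seq_len(n))
  low <- 2^rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  high_mask <- matrix(FALSE, n, ns)
  high_mask[classes == "MI", ] <- rep(phases == "mitotic", each = sum(classes == "MI"))
  first_meiotic <- match("meiotic", phases)
  if (!is.na(first_meiotic)) {
    high_mask[classes == "ME", ] <-
      rep(seq_len(ns) >= first_meiotic, each = sum(classes == "ME"))
  }
  first_pm <- match("post-meiotic", phases)
  if (!is.na(first_pm)) {
    high_mask[classes == "PM", ] <-
      rep(seq_len(ns) >= first_pm, each = sum(classes == "PM"))
  }
  pattern <- matrix(low, n, ns, dimnames = list(genes, names(config$stages)))
  pattern[high_mask] <- (matrix(low, n, ns) * config$onset_fold)[high_mask]
  datasets <- lapply(seq_len(config$n_datasets), function(i) {
    set.seed(derive_seed(config$seed, 2000003L + i))
    noise <- matrix(rnorm(n * ns, 0, config$noise_log_sd), n, ns)
    stage_dataset(sprintf("course%d", i), pattern * 2^noise, phases)
  })
  list(datasets = datasets, truth = truth_frame(setNames(classes, genes),
                                                "stage_group"))
}

#' Write a synthetic HMMER domtblout fixture
#'
#' Emits one well-formed per-domain tabular line per planted hit, with a
#' comment header, so the file round-trips through [parse_domtblout()].
#'
#' @param families Either a named character vector `gene id -> domain name`
#'   (one hit per gene at `evalue`; the protein id equals the gene id), or a
#'   data frame with columns `protein_id`, `gene_id`, `domain`, `evalue` for
#'   multi-hit fixtures. Domains must be among `zf-C3HC4`, `HECT`, `U-box`.
#' @param path Output file path.
#' @param evalue Default full-sequence E-value for the vector form.
#' @return `path` invisibly, with a `protein_to_gene` attribute carrying the
#'   mapping implied by the fixture.
#' @export
write_domain_fixture <- function(families, path, evalue = 1e-8) {
  if (is.data.frame(families)) {
    df <- families
    stopifnot(all(c("protein_id", "gene_id", "domain", "evalue") %in% names(df)))
  } else {
    ids <- if (length(families)) names(families) else character()
    df <- data.frame(protein_id = ids, gene_id = ids,
                     domain = unname(families),
                     evalue = rep_len(evalue, length(families)),
                     stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(df$domain), names(E3_FAMILY_ALIASES))
  if (length(bad)) stop("unknown family name(s): ", paste(bad, collapse = ", "))
  accs <- c("zf-C3HC4" = "PF00097.21", "HECT" = "PF00632.21",
            "U-box" = "PF04564.11")
  lines <- c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  if (nrow(df) > 0) {
    body <- sprintf(
      "%-20s -            500 %-20s %-10s    50 %9.2g   55.0   0.1   1   1 %9.2g %9.2g   54.0   0.1     1    50    10    60     8    62 0.95 synthetic fixture",
      df$protein_id, df$domain, accs[df$domain], df$evalue,
      df$evalue / 10, df$evalue)
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(structure(path,
                      protein_to_gene = setNames(df$gene_id, df$protein_id)))
}

#' Write a synthetic ortholog-group fixture
#'
#' Emits the 4-column tab-delimited dialect (`group_id`, `taxon_id`,
#' `gene_id`, `gene_symbol`, no header) read by [parse_homologene()].
#'
#' @param groups Data frame with columns `group_id`, `taxon_id`, `gene_id`
#'   and optionally `symbol` (defaults to the gene id). Duplicate
#'   (group, taxon, gene) rows are an error.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_homology_fixture <- function(groups, path) {
  stopifnot(is.data.frame(groups),
            all(c("group_id", "taxon_id", "gene_id") %in% names(groups)))
  key <- paste(groups$group_id, groups$taxon_id, groups$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (group, taxon, gene) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  symbol <- if ("symbol" %in% names(groups)) groups$symbol else groups$gene_id
  out <- data.frame(groups$group_id, groups$taxon_id, groups$gene_id, symbol)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write truth labels as TSV
#'
#' @param truth Data frame (`gene_id`, `axis`, `label`) from a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
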