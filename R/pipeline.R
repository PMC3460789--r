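# Pipeline orchestration: mine -> homology -> rate -> stage -> report from
# a single configuration, emitting a bundle of TSV/JSON artifacts plus a run
# manifest. Any prefix of the stage chain can be run by omitting later
# sections from the configuration.

#' Summarize testis expression classes from a cross-tab
#'
#' From a family-by-level cross-tab (see [level_cross_tab()]) computes the
#' headline counts: genes expressed at all (`P + HP + MS + SP`) and genes
#' highly or specifically expressed (`HP + MS + SP`).
#'
#' @param cross_tab Matrix from [level_cross_tab()] (with or without the
#'   `Total` margins).
#' @return Named list with `expressed` and `high_or_specific`.
#' @examples
#' # the worked example: P=267, HP=39, MS=2, SP=32 -> 340 expressed, 73 high
#' tab <- rbind(RING = c(SP = 32, MS = 2, HP = 39, P = 267, A = 58,
#'                       UNCLASSIFIED = 0))
#' summarize_testis_classes(tab)
#' @export
summarize_testis_classes <- function(cross_tab) {
  totals <- if ("Total" %in% rownames(cross_tab)) {
    cross_tab["Total", ]
  } else {
    colSums(cross_tab)
  }
  need <- c("SP", "MS", "HP", "P")
  if (!all(need %in% names(totals))) {
    stop("cross_tab must carry columns SP, MS, HP, P")
  }
  list(expressed = unname(sum(totals[need])),
       high_or_specific = unname(sum(totals[c("SP", "MS", "HP")])))
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$output_dir)) stop("config must name an output_dir")
  config
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

load_rate_datasets <- function(entries) {
  lapply(entries, function(e) {
    kind <- if (is.null(e$kind)) "array" else e$kind
    if (kind == "array" && !is.null(e$calls) && !file.exists(e$calls)) {
      stop("calls file missing for array dataset '",
           if (is.null(e$name)) e$values else e$name, "': ", e$calls)
    }
    read_expression_tsv(e$values, calls = e$calls, kind = kind, name = e$name)
  })
}

#' Run the full mining and expression-characterization pipeline
#'
#' Executes the configured stages in order — domain mining, cross-species
#' homology, tissue rating, stage grouping — and writes the report bundle:
#' catalogue TSV, homology summary JSON, ratings TSV, a family-by-level
#' cross-tab for the focal tissue, per-tissue level counts (long TSV), stage
#' groups TSV, a group-by-level cross-tab, Venn counts and a run manifest
#' with a configuration hash. The run is deterministic given inputs and
#' configuration.
#'
#' @param config A configuration list, or the path of a YAML file holding
#'   one. Recognised sections (each optional; later stages may depend on
#'   earlier ones):
#'   \describe{
#'     \item{`output_dir`}{Directory for the bundle (required).}
#'     \item{`mine`}{`domtbl`, optional `gene_map` (2-column TSV
#'       protein/gene; identity if omitted), `e_max` (default 0.1),
#'       `species`.}
#'     \item{`homology`}{`table` (4-column dialect; `format: ncbi` for the
#'       6-column layout), `set_b` (one-column TSV of the second species'
#'       genes), `taxon_a`, `taxon_b`, optional `set_a` (defaults to the
#'       mined catalogue), optional `p0` for the enrichment test.}
#'     \item{`rate`}{`datasets` (list of `values`/`calls`/`kind`/`name`),
#'       `tissue`, optional `z1`/`z2`/`z3`/`min_votes`/`sd_mode`.}
#'     \item{`stage`}{`datasets` (list of `values`/`phases`/`name`; `phases`
#'       is a comma-free YAML list of phase tags), optional
#'       `fold_threshold`/`floor`/`min_votes`.}
#'   }
#' @return Object of class `report_bundle`: list of in-memory results
#'   (`catalog`, `homology`, `ratings`, `level_tab`, `groups`, `stage_tab`,
#'   `summary`, `manifest`) with files written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bundle <- list()

  if (!is.null(config$mine)) {
    bundle$catalog <- pipeline_stage("mine", {
      m <- config$mine
      hits <- parse_domtblout(m$domtbl)
      e_max <- if (is.null(m$e_max)) 0.1 else m$e_max
      hits <- filter_hits(hits, e_max)
      p2g <- if (is.null(m$gene_map)) {
        prot <- unique(hits$target_protein_id)
        setNames(prot, prot)
      } else {
        gm <- read.delim(m$gene_map, header = TRUE, stringsAsFactors = FALSE)
        setNames(as.character(gm[[2]]), as.character(gm[[1]]))
      }
      cat_ <- classify_families(hits, p2g,
                                species = if (is.null(m$species)) "unspecified" else m$species)
      write_catalog_tsv(cat_, file.path(out, "catalog.tsv"))
      cat_
    })
  }

  if (!is.null(config$homology)) {
    bundle$homology <- pipeline_stage("homology", {
      h <- config$homology
      fmt <- if (is.null(h$format)) "fixture" else h$format
      tab <- parse_homologene(h$table, format = fmt)
      set_a <- if (!is.null(h$set_a)) {
        read.delim(h$set_a, header = FALSE, stringsAsFactors = FALSE)[[1]]
      } else if (!is.null(bundle$catalog)) {
        bundle$catalog$gene_id
      } else stop("no set_a given and no catalogue mined")
      set_b <- read.delim(h$set_b, header = FALSE, stringsAsFactors = FALSE)[[1]]
      summ <- map_homologs(set_a, h$taxon_a, set_b, h$taxon_b, tab)
      res <- unclass(summ)
      if (!is.null(h$p0)) {
        res$p_value <- enrichment_test(summ$n_shared, summ$union, h$p0)
        res$p0 <- h$p0
      }
      jsonlite::write_json(res, file.path(out, "homology.json"),
                           auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(list(set_a = summ$n_a, set_b = summ$n_b,
                                intersection = summ$n_shared),
                           file.path(out, "venn.json"), auto_unbox = TRUE)
      res
    })
  }

  if (!is.null(config$rate)) {
    bundle$ratings <- pipeline_stage("rate", {
      r <- config$rate
      datasets <- load_rate_datasets(r$datasets)
      rc <- rating_config(
        z1 = if (is.null(r$z1)) 1 else r$z1,
        z2 = if (is.null(r$z2)) 1.96 else r$z2,
        z3 = if (is.null(r$z3)) 2.58 else r$z3,
        min_votes = if (is.null(r$min_votes)) 2 else r$min_votes,
        sd_mode = if (is.null(r$sd_mode)) "sample" else r$sd_mode)
      ratings <- rate_all(datasets, rc)
      write_ratings_tsv(ratings, file.path(out, "ratings.tsv"))
      write_tissue_profile_tsv(ratings, file.path(out, "tissue_profile.tsv"))
      ratings
    })
    if (!is.null(bundle$catalog) && !is.null(config$rate$tissue)) {
      bundle$level_tab <- level_cross_tab(bundle$catalog, bundle$ratings,
                                          config$rate$tissue)
      write_cross_tab_tsv(bundle$level_tab, file.path(out, "level_cross_tab.tsv"))
      bundle$summary <- summarize_testis_classes(bundle$level_tab)
    }
  }

  if (!is.null(config$stage)) {
    bundle$groups <- pipeline_stage("stage", {
      s <- config$stage
      datasets <- lapply(s$datasets, function(e) {
        ds <- read_expression_tsv(e$values, kind = "array", name = e$name)
        stage_dataset(ds$name, ds$values, unlist(e$phases))
      })
      sc <- stage_config(
        fold_threshold = if (is.null(s$fold_threshold)) 3 else s$fold_threshold,
        floor = if (is.null(s$floor)) 1 else s$floor,
        min_votes = if (is.null(s$min_votes)) 2 else s$min_votes)
      groups <- stage_all(datasets, sc)
      write_groups_tsv(groups, file.path(out, "groups.tsv"))
      groups
    })
    if (!is.null(bundle$ratings) && !is.null(config$rate$tissue)) {
      bundle$stage_tab <- stage_cross_tab(bundle$groups, bundle$ratings,
                                          config$rate$tissue)
      write_cross_tab_tsv(bundle$stage_tab, file.path(out, "stage_cross_tab.tsv"))
    }
  }

  manifest <- list(package = "e3miner",
                   version = as.character(packageVersion("e3miner")),
                   config_md5 = object_md5(config),
                   seed = config$seed,
                   stages_run = names(bundle))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bundle$manifest <- manifest
  structure(bundle, class = "report_bundle")
}

# per-gene, per-tissue ratings: per-dataset votes pipe-joined plus the final
# balloted level
write_ratings_tsv <- function(ratings, path) {
  genes <- rep(ratings$genes, times = length(ratings$tissues))
  tissues <- rep(ratings$tissues, each = length(ratings$genes))
  votes <- do.call(paste, c(lapply(ratings$per_dataset, function(m) {
    v <- as.vector(m)
    v[is.na(v)] <- "."
    v
  }), sep = "|"))
  df <- data.frame(gene_id = genes, tissue = tissues, votes = votes,
                   final = as.vector(ratings$final), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-tissue counts of final SP/HP/P-etc. levels: the comparative
# tissue-profile report in long format
write_tissue_profile_tsv <- function(ratings, path) {
  long <- expand.grid(tissue = ratings$tissues,
                      level = c(E3_LEVELS, "UNCLASSIFIED"),
                      stringsAsFactors = FALSE)
  long$count <- mapply(function(t, l) sum(ratings$final[, t] == l),
                       long$tissue, long$level)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_groups_tsv <- function(groups, path) {
  genes <- names(groups$final)
  votes <- do.call(paste, c(lapply(groups$per_dataset, function(g) {
    v <- unname(g[genes])
    v[is.na(v)] <- "."
    v
  }), sep = "|"))
  df <- data.frame(gene_id = genes, votes = votes,
                   final = unname(groups$final), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cross_tab_tsv <- function(tab, path) {
  df <- data.frame(row = rownames(tab), tab, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
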