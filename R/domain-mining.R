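# Catalogue construction from profile-HMM domain search output: parse the
# HMMER per-domain tabular ("domtblout") format, filter by full-sequence
# E-value, and classify genes into the RING / HECT / U-box families.

# Pfam model name -> family label. zf-C3HC4 is the canonical RING-finger
# model; extra aliases can be supplied by the caller.
E3_FAMILY_ALIASES <- c("zf-C3HC4" = "RING", "HECT" = "HECT", "U-box" = "U-box")

#' Families recognised in the E3 catalogue
#' @format Character vector of length 3.
#' @export
E3_FAMILIES <- c("RING", "HECT", "U-box")

#' Parse HMMER per-domain tabular output
#'
#' Reads the whitespace-aligned "domtblout" dialect: '#' lines are comments,
#' every data line has at least 22 fields in the standard column order
#' (target name, target accession, tlen, query name, query accession, qlen,
#' full-sequence E-value/score/bias, domain index, per-domain c-Evalue and
#' i-Evalue, scores, hmm/ali/env coordinates, acc). Unknown query domains are
#' retained with their name passed through.
#'
#' @param path Path to a domtblout file (or a connection readable by
#'   [readLines()]).
#' @return A `data.frame` of class `domain_hits` with columns
#'   `target_protein_id`, `query_domain`, `full_seq_evalue`,
#'   `domain_i_evalue`, `bit_score`, `envelope_from`, `envelope_to`.
#' @export
parse_domtblout <- function(path) {
  if (is.character(path) && !file.exists(path)) {
    stop("no such file: ", path)
  }
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 22) {
      stop(sprintf("line %d: expected >= 22 whitespace-separated fields, got %d",
                   i, length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields[c(7, 13, 14, 20, 21)]))
    if (anyNA(num)) {
      stop(sprintf("line %d: non-numeric E-value/score/coordinate field", i))
    }
    rows[[k]] <- data.frame(
      target_protein_id = fields[1],
      query_domain = fields[4],
      full_seq_evalue = num[1],
      domain_i_evalue = num[2],
      bit_score = num[3],
      envelope_from = as.integer(num[4]),
      envelope_to = as.integer(num[5]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    target_protein_id = character(), query_domain = character(),
    full_seq_evalue = numeric(), domain_i_evalue = numeric(),
    bit_score = numeric(), envelope_from = integer(),
    envelope_to = integer(), stringsAsFactors = FALSE)
  if (any(out$full_seq_evalue < 0) || any(out$domain_i_evalue < 0)) {
    stop("negative E-values in input")
  }
  if (any(out$envelope_from > out$envelope_to) || any(out$envelope_from < 1)) {
    stop("invalid envelope coordinates (need 1 <= from <= to)")
  }
  class(out) <- c("domain_hits", "data.frame")
  out
}

#' Filter domain hits by full-sequence E-value
#'
#' Retains hits whose full-sequence E-value is no more than `e_max`
#' (boundary inclusive), preserving input order.
#'
#' @param hits A `domain_hits` data frame from [parse_domtblout()].
#' @param e_max Maximum E-value, default 0.1.
#' @return The retained hits, same class.
#' @export
filter_hits <- function(hits, e_max = 0.1) {
  stopifnot(is.data.frame(hits), e_max > 0)
  out <- hits[hits$full_seq_evalue <= e_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify genes into an exclusive E3 family catalogue
#'
#' Collapses protein-level hits to genes: a gene enters the catalogue iff at
#' least one of its proteins carries a retained hit in a recognised family.
#' Each gene is assigned exactly one family — that of the hit with the lowest
#' full-sequence E-value across all its proteins, with ties broken by the
#' fixed precedence RING > HECT > U-box. Hits on domains outside the alias
#' table are ignored.
#'
#' @param hits A `domain_hits` data frame (usually after [filter_hits()]).
#' @param protein_to_gene Named character vector (`protein id -> gene id`) or
#'   a two-column data frame (`protein_id`, `gene_id`). Every hit protein
#'   must be mapped; unmapped proteins raise an error listing the orphans.
#' @param species Taxon label stored in the catalogue (provenance only).
#' @param aliases Named vector mapping query-domain names to families; the
#'   default maps `zf-C3HC4` to RING and keeps HECT and U-box.
#' @return Object of class `e3_catalog`: a data frame with columns `gene_id`,
#'   `family`, `best_evalue`, plus `species` and `provenance` attributes.
#' @export
classify_families <- function(hits, protein_to_gene, species = "unspecified",
                              aliases = E3_FAMILY_ALIASES) {
  stopifnot(is.data.frame(hits))
  if (is.data.frame(protein_to_gene)) {
    protein_to_gene <- setNames(as.character(protein_to_gene[[2]]),
                                as.character(protein_to_gene[[1]]))
  }
  fam <- unname(aliases[hits$query_domain])
  known <- !is.na(fam)
  hits <- hits[known, , drop = FALSE]
  fam <- fam[known]
  if (nrow(hits) > 0) {
    orphans <- setdiff(unique(hits$target_protein_id), names(protein_to_gene))
    if (length(orphans)) {
      stop("proteins with no gene mapping: ", paste(orphans, collapse = ", "))
    }
  }
  gene <- unname(protein_to_gene[hits$target_protein_id])
  ord <- order(hits$full_seq_evalue,
               match(fam, E3_FAMILIES))  # ties: RING > HECT > U-box
  first <- !duplicated(gene[ord])
  entries <- data.frame(gene_id = gene[ord][first],
                        family = fam[ord][first],
                        best_evalue = hits$full_seq_evalue[ord][first],
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$gene_id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, species = species,
            provenance = list(n_hits = nrow(hits)),
            class = c("e3_catalog", "data.frame"))
}

#' Tally membrane-associated catalogue genes
#'
#' Given a user-supplied annotation table, counts catalogue genes carrying a
#' predicted signal peptide and a transmembrane domain. Genes absent from the
#' annotation count as neither; annotated genes outside the catalogue are
#' ignored.
#'
#' @param catalog An `e3_catalog`.
#' @param annotation Data frame with columns `gene_id`,
#'   `has_signal_peptide`, `has_tmd` (logical).
#' @return Named list with counts `signal_peptide`, `tmd` and `either`.
#' @export
annotate_membrane <- function(catalog, annotation) {
  stopifnot(inherits(catalog, "e3_catalog"), is.data.frame(annotation))
  if (nrow(annotation) == 0) {
    return(list(signal_peptide = 0L, tmd = 0L, either = 0L))
  }
  ann <- annotation[annotation$gene_id %in% catalog$gene_id, , drop = FALSE]
  sp <- as.logical(ann$has_signal_peptide)
  tmd <- as.logical(ann$has_tmd)
  list(signal_peptide = sum(sp, na.rm = TRUE),
       tmd = sum(tmd, na.rm = TRUE),
       either = sum(sp | tmd, na.rm = TRUE))
}

#' Write a catalogue as TSV
#'
#' @param catalog An `e3_catalog`.
#' @param path Output path (columns `gene_id`, `family`, `best_evalue`).
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
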