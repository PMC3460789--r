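# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# a domain_hits data frame built directly (bypassing the parser)
make_hits <- function(protein, domain, evalue) {
  k <- length(protein)
  structure(data.frame(target_protein_id = protein, query_domain = domain,
                       full_seq_evalue = evalue, domain_i_evalue = evalue,
                       bit_score = rep(50, k), envelope_from = rep(1L, k),
                       envelope_to = rep(50L, k), stringsAsFactors = FALSE),
            class = c("domain_hits", "data.frame"))
}

# identity protein -> gene map
identity_map <- function(ids) stats::setNames(ids, ids)

# a one-gene array dataset over n tissues with explicit values/calls
one_gene_dataset <- function(values, calls = NULL, tissues = NULL,
                             name = "d1") {
  n <- length(values)
  if (is.null(tissues)) tissues <- paste0("t", seq_len(n))
  m <- matrix(values, 1, n, dimnames = list("g1", tissues))
  cm <- if (!is.null(calls)) {
    matrix(calls, 1, n, dimnames = list("g1", tissues))
  }
  expression_dataset(name, m, cm, "array")
}

# ortholog-group fixture planting a given (n_a, n_b, n_shared) structure:
# n_shared two-species groups plus single-species groups for the remainder
planted_homology <- function(n_a, n_b, n_shared,
                             taxon_a = "10090", taxon_b = "9606") {
  genes_a <- sprintf("m%04d", seq_len(n_a))
  genes_b <- sprintf("h%04d", seq_len(n_b))
  shared <- data.frame(
    group_id = rep(sprintf("G%04d", seq_len(n_shared)), 2),
    taxon_id = rep(c(taxon_a, taxon_b), each = n_shared),
    gene_id = c(genes_a[seq_len(n_shared)], genes_b[seq_len(n_shared)]),
    stringsAsFactors = FALSE)
  only_a <- data.frame(
    group_id = sprintf("GA%04d", seq_len(n_a - n_shared)),
    taxon_id = taxon_a, gene_id = genes_a[-seq_len(n_shared)],
    stringsAsFactors = FALSE)
  only_b <- data.frame(
    group_id = sprintf("GB%04d", seq_len(n_b - n_shared)),
    taxon_id = taxon_b, gene_id = genes_b[-seq_len(n_shared)],
    stringsAsFactors = FALSE)
  list(groups = rbind(shared, only_a, only_b),
       set_a = genes_a, set_b = genes_b)
}

# literal re-application of the stated ballot rules, used as the exhaustive
# oracle: tally non-abstaining votes per level, require the top tally to
# reach two voters, break ties toward lower specificity rank
ballot_oracle <- function(votes, min_votes = 2) {
  order_ <- c("A", "P", "HP", "MS", "SP")
  v <- votes[votes != "abstain"]
  tallies <- vapply(order_, function(l) sum(v == l), integer(1))
  top <- max(tallies)
  if (top < min_votes) return("UNCLASSIFIED")
  tied <- order_[tallies == top]
  tied[which.min(match(tied, order_))]
}
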