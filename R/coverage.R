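#' Per-element disease-gene overlap scores (SPG / SNG-style)
#'
#' For every element of a collection (pathway map or network), the summation
#' over all diseases of the number of genes shared between the element and
#' the disease's gene set:
#' \deqn{SPG_i = \sum_j | P_i \cap Dg_j |.}
#'
#' @param collection a [gene_set_collection()].
#' @param universe a [study_universe()] supplying the disease records.
#' @param gene_mode `"integrated"` (OMIM union GWAS) or `"omim"`.
#' @return named integer vector, one entry per element of `collection`.
#' @export
spg_scores <- function(collection, universe,
                       gene_mode = c("integrated", "omim")) {
  gene_mode <- match.arg(gene_mode)
  # multiplicity of each gene across disease gene sets; SPG_i is then the
  # sum of multiplicities over the element's genes
  gene_mult <- table(unlist(lapply(universe$diseases, function(d) {
    if (gene_mode == "omim") d$omim_genes else union(d$omim_genes, d$risk_genes)
  }), use.names = FALSE))
  score_by_multiplicity(collection, gene_mult)
}

#' Per-element drug-target overlap scores (SPT / SNT-style)
#'
#' For every element, the summation over all diseases of the number of genes
#' shared between the element and the disease's pooled drug-target set
#' `T_j` (the union of the targets of the disease's drugs in the given
#' phase): \deqn{SPT_i = \sum_j | P_i \cap T_j |.}
#' A gene targeted by several drugs of one disease counts once for that
#' disease (the union is taken before the intersection).
#'
#' @inheritParams spg_scores
#' @param phase drug-development phase defining `T_j`.
#' @return named integer vector, one entry per element.
#' @export
spt_scores <- function(collection, universe, phase = "all") {
  check_phase(phase)
  js <- names(universe$diseases)
  gene_mult <- table(unlist(lapply(js, function(j)
    union_drug_targets(universe, j, phase)), use.names = FALSE))
  score_by_multiplicity(collection, gene_mult)
}

score_by_multiplicity <- function(collection, gene_mult) {
  stopifnot(inherits(collection, "gene_set_collection"))
  out <- vapply(unclass(collection), function(genes) {
    as.numeric(sum(gene_mult[match(genes, names(gene_mult))], na.rm = TRUE))
  }, numeric(1))
  storage.mode(out) <- "integer"
  out
}

#' Per-element count of diseases pairing genes and targets (S_i)
#'
#' For every element, the number of diseases whose gene set *and* whose
#' pooled drug-target set both overlap the element:
#' \deqn{S_i = \sum_j \alpha_{ij}, \quad \alpha_{ij} = 1 \iff
#'   |P_i \cap Dg_j| > 0 \ \mathrm{and}\ |P_i \cap T_j| > 0.}
#' An element with positive `S_i` holds a disease-gene/drug-target pair of
#' the *same* disease, the strictest of the four co-occurrence notions.
#'
#' @inheritParams spt_scores
#' @param gene_mode `"integrated"` or `"omim"`.
#' @return named integer vector, one entry per element; each value is at
#'   most the number of diseases.
#' @export
same_disease_scores <- function(collection, universe,
                                gene_mode = c("integrated", "omim"),
                                phase = "all") {
  gene_mode <- match.arg(gene_mode)
  check_phase(phase)
  idx <- invert_collection(collection)
  s <- structure(integer(length(collection)), names = names(collection))
  for (j in names(universe$diseases)) {
    dg <- disease_genes(universe, j, gene_mode)
    tj <- union_drug_targets(universe, j, phase)
    hit_g <- unique(unlist(idx[intersect(dg, names(idx))], use.names = FALSE))
    hit_t <- unique(unlist(idx[intersect(tj, names(idx))], use.names = FALSE))
    both <- intersect(hit_g, hit_t)
    s[both] <- s[both] + 1L
  }
  s
}

#' Coverage counts of one gene-set universe
#'
#' The four headline counts for a universe of `n` elements (353 pathway maps
#' or 1260 networks in the original study): the number of elements
#' containing at least one disease gene (`with_genes`, PG/NG), at least one
#' drug target (`with_targets`, PT/NT), both (`with_both`, PGT/NGT), and a
#' disease-gene/drug-target pair of the same disease
#' (`with_same_disease_pair`, PGT_s/NGT_s). Each count is the number of
#' strictly positive entries of the corresponding per-element score vector,
#' and the chain
#' `with_same_disease_pair <= with_both <= min(with_genes, with_targets) <= n`
#' always holds. Elements whose genes appear in no disease or drug list
#' still count toward `element_count`.
#'
#' @inheritParams same_disease_scores
#' @return object of class `coverage_counts`: list with `universe_kind`,
#'   `element_count`, score vectors `spg`, `spt`, `same_disease`, and
#'   `counts` (the four counts above).
#' @export
coverage_counts <- function(collection, universe,
                            gene_mode = c("integrated", "omim"),
                            phase = "all") {
  gene_mode <- match.arg(gene_mode)
  spg <- spg_scores(collection, universe, gene_mode)
  spt <- spt_scores(collection, universe, phase)
  s <- same_disease_scores(collection, universe, gene_mode, phase)
  structure(list(
    universe_kind = collection_kind(collection),
    element_count = length(collection),
    spg = spg, spt = spt, same_disease = s,
    counts = list(with_genes = sum(spg > 0L),
                  with_targets = sum(spt > 0L),
                  with_both = sum(spg > 0L & spt > 0L),
                  with_same_disease_pair = sum(s > 0L))
  ), class = "coverage_counts")
}

#' @export
print.coverage_counts <- function(x, ...) {
  cat(sprintf(paste0("<coverage_counts> %s universe, n=%d: genes %d, ",
                     "targets %d, both %d, same-disease pair %d\n"),
              x$universe_kind, x$element_count, x$counts$with_genes,
              x$counts$with_targets, x$counts$with_both,
              x$counts$with_same_disease_pair))
  invisible(x)
}

#' Contingency comparison of the pathway-map and network universes
#'
#' Tests whether the distribution of elements over coverage categories
#' depends on the universe kind. The raw coverage counts overlap (an
#' element with both genes and targets is also counted among
#' `with_genes`), so they are first decomposed into mutually exclusive
#' cells. Two layouts are offered:
#' \describe{
#'   \item{`"four_category"`}{per universe: genes only, targets only, both
#'     (including same-disease pairs), neither — a 2 x 4 table.}
#'   \item{`"two_by_two"`}{elements with both genes and targets vs the
#'     rest — a 2 x 2 table.}
#' }
#'
#' @param pathway_counts,network_counts [coverage_counts()] objects computed
#'   on the same diseases and drugs.
#' @param layout contingency layout, see above.
#' @param correct apply the Yates continuity correction (2 x 2 only);
#'   default off.
#' @return list with the contingency `table`, and `statistic`, `dof`,
#'   `p_value` from [chi_square_independence()].
#' @export
compare_universes <- function(pathway_counts, network_counts,
                              layout = c("four_category", "two_by_two"),
                              correct = FALSE) {
  layout <- match.arg(layout)
  stopifnot(inherits(pathway_counts, "coverage_counts"),
            inherits(network_counts, "coverage_counts"))
  row_of <- function(cc) {
    ct <- cc$counts
    if (layout == "four_category") {
      c(genes_only = ct$with_genes - ct$with_both,
        targets_only = ct$with_targets - ct$with_both,
        both = ct$with_both,
        neither = cc$element_count - ct$with_genes - ct$with_targets +
          ct$with_both)
    } else {
      c(both = ct$with_both, rest = cc$element_count - ct$with_both)
    }
  }
  tab <- rbind(pathway = row_of(pathway_counts),
               network = row_of(network_counts))
  res <- chi_square_independence(tab, correct = correct)
  c(list(table = tab), res)
}
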