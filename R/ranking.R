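#' Per-group network scores for disease genes (SNG)
#'
#' For each network, the summation over the diseases of one group of the
#' number of genes shared between the network and the disease's gene set:
#' \deqn{SNG_i = \sum_{j \in group} | N_i \cap Dg_j |.}
#' A disease carrying several group labels contributes to every group it
#' belongs to.
#'
#' @param universe a [study_universe()].
#' @param group disease-group label.
#' @param gene_mode `"integrated"` or `"omim"`.
#' @return named integer vector over all networks (zeros included; use
#'   [top_k()] to rank the populated ones).
#' @export
sng_scores <- function(universe, group, gene_mode = c("integrated", "omim")) {
  gene_mode <- match.arg(gene_mode)
  js <- group_disease_numbers(universe, group)
  gene_mult <- table(unlist(lapply(as.character(js), function(j)
    disease_genes(universe, j, gene_mode)), use.names = FALSE))
  score_by_multiplicity(universe$networks, gene_mult)
}

#' Number of a disease's drugs targeting one network (beta)
#'
#' The number of drugs developed for disease `j` (in the given phase) whose
#' target set meets the network's share of the disease's pooled targets:
#' \deqn{\beta_{ij} = |\{ Dr_k \in Dd_j : T_{kj} \cap (N_i \cap T_j) \neq
#' \emptyset \}|} — equivalently, the number of the disease's drugs with at
#' least one target inside network `i`. Drugs with no targets are never
#' counted.
#'
#' @param universe a [study_universe()].
#' @param network_id network element ID.
#' @param j disease number.
#' @param phase drug-development phase.
#' @return integer count, between 0 and the number of the disease's drugs.
#' @export
beta_count <- function(universe, network_id, j, phase = "all") {
  check_phase(phase)
  net <- universe$networks[[network_id]]
  if (is.null(net)) stop("unknown network: ", network_id)
  rec <- get_disease(universe, j)
  tj <- union_drug_targets(universe, j, phase)
  window <- intersect(net, tj)
  sum(vapply(universe$drugs[rec$drugs_by_phase[[phase]]],
             function(tk) length(intersect(tk, window)) > 0L, logical(1)))
}

#' Per-group network scores for drug targeting (SND)
#'
#' For each network, the summation over the diseases of one group of the
#' number of that disease's drugs targeting the network:
#' \deqn{SND_i = \sum_{j \in group} \beta_{ij}.}
#' The sum runs over drug–disease pairs: a drug developed for two diseases
#' of the group counts once per disease. `dedup = TRUE` instead counts
#' distinct drugs per network across the group (sensitivity analysis).
#'
#' @inheritParams sng_scores
#' @param phase drug-development phase.
#' @param dedup count distinct drugs instead of drug–disease pairs.
#' @return named integer vector over all networks.
#' @export
snd_scores <- function(universe, group, phase = "all", dedup = FALSE) {
  check_phase(phase)
  js <- group_disease_numbers(universe, group)
  idx <- invert_collection(universe$networks)
  score <- structure(integer(length(universe$networks)),
                     names = names(universe$networks))
  seen <- list()  # dedup mode: networks already credited to each drug
  for (j in js) {
    rec <- get_disease(universe, j)
    for (drug in rec$drugs_by_phase[[phase]]) {
      hits <- unique(unlist(idx[intersect(universe$drugs[[drug]], names(idx))],
                            use.names = FALSE))
      if (dedup) {
        hits <- setdiff(hits, seen[[drug]])
        seen[[drug]] <- c(seen[[drug]], hits)
      }
      score[hits] <- score[hits] + 1L
    }
  }
  score
}

#' Top-ranked networks by score
#'
#' Ranks score entries in descending order, breaking ties lexicographically
#' by element ID. Zero-score entries are never ranked. By default all
#' entries tied with the k-th score are returned (the list may exceed `k`);
#' `strict = TRUE` truncates to exactly `k` rows.
#'
#' @param scores named numeric vector (e.g. from [sng_scores()] or
#'   [snd_scores()]).
#' @param k number of ranks requested; must be >= 1.
#' @param strict truncate ties at rank `k`.
#' @return data.frame with columns `rank`, `id`, `score`.
#' @export
top_k <- function(scores, k = 3, strict = FALSE) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("`k` must be >= 1")
  scores <- scores[scores > 0]
  if (length(scores) == 0L) {
    return(data.frame(rank = integer(), id = character(), score = numeric()))
  }
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  cutoff <- scores[min(k, length(scores))]
  keep <- if (strict) seq_len(min(k, length(scores)))
          else which(scores >= cutoff)
  data.frame(rank = rank(-scores[keep], ties.method = "min"),
             id = names(scores)[keep], score = unname(scores[keep]),
             row.names = NULL)
}

#' Full ranking table of one disease group
#'
#' Combines the group's disease-gene scores (SNG), drug-targeting scores
#' (SND) with the underlying per-disease beta counts, and the group's
#' "Total SUM" — the summed number of drugs per disease that target any
#' network at all (the group aggregate of [disease_network_sets()]'s
#' `drugs_on_any_network`).
#'
#' @inheritParams snd_scores
#' @param gene_mode `"integrated"` or `"omim"`.
#' @return object of class `group_score_table`: list with `group`, `sng`,
#'   `snd`, `beta` (networks x diseases integer matrix, populated rows
#'   only), `total_sum`.
#' @export
group_score_table <- function(universe, group,
                              gene_mode = c("integrated", "omim"),
                              phase = "all") {
  gene_mode <- match.arg(gene_mode)
  check_phase(phase)
  js <- group_disease_numbers(universe, group)
  snd <- snd_scores(universe, group, phase)
  keep <- names(snd)[snd > 0]
  beta <- matrix(0L, nrow = length(keep), ncol = length(js),
                 dimnames = list(keep, as.character(js)))
  for (i in keep) {
    for (j in js) beta[i, as.character(j)] <- beta_count(universe, i, j, phase)
  }
  total_sum <- sum(vapply(as.character(js), function(j)
    length(disease_network_sets(universe, j, gene_mode,
                                phase)$drugs_on_any_network), integer(1)))
  structure(list(group = group,
                 sng = sng_scores(universe, group, gene_mode),
                 snd = snd, beta = beta, total_sum = total_sum),
            class = "group_score_table")
}

#' @export
print.group_score_table <- function(x, ...) {
  cat(sprintf("<group_score_table> group %s: %d gene-scored, %d drug-scored networks, total SUM %d\n",
              x$group, sum(x$sng > 0), sum(x$snd > 0), x$total_sum))
  invisible(x)
}
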