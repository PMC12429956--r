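#' Drug target-category labels
#'
#' The priority-ordered classification of a drug's targets relative to one
#' disease's genes and the network universe:
#' \describe{
#'   \item{`disease_gene`}{at least one target is itself a disease (risk)
#'     gene;}
#'   \item{`related_network_partner`}{no target is a disease gene, but some
#'     target lies in a network that contains a disease gene;}
#'   \item{`other_network`}{targets lie only in networks without disease
#'     genes;}
#'   \item{`no_network`}{no target lies in any network (includes
#'     target-free drugs).}
#' }
#'
#' @format character vector of the four labels, in priority order.
#' @export
drug_categories <- c("disease_gene", "related_network_partner",
                     "other_network", "no_network")

#' Disease-related networks (NC_j)
#'
#' The networks holding both the disease's genes and the targets of the
#' disease's drugs:
#' \deqn{NC_j = \{ N_i : N_i \cap Dg_j \neq \emptyset \ \mathrm{and}\
#'   N_i \cap T_j \neq \emptyset \}.}
#'
#' @param universe a [study_universe()].
#' @param j disease number.
#' @param gene_mode `"integrated"` or `"omim"`.
#' @param phase drug-development phase defining `T_j`.
#' @return character vector of network IDs (sorted).
#' @export
related_networks <- function(universe, j,
                             gene_mode = c("integrated", "omim"),
                             phase = "all") {
  gene_mode <- match.arg(gene_mode)
  check_phase(phase)
  idx <- invert_collection(universe$networks)
  dg <- disease_genes(universe, j, gene_mode)
  tj <- union_drug_targets(universe, j, phase)
  hit_g <- as.character(unlist(idx[intersect(dg, names(idx))],
                               use.names = FALSE))
  hit_t <- as.character(unlist(idx[intersect(tj, names(idx))],
                               use.names = FALSE))
  sort(intersect(unique(hit_g), unique(hit_t)))
}

#' Drug sets of one disease on the network universe
#'
#' Collects, for one disease and phase, the full stage-3 decomposition:
#' \describe{
#'   \item{`related_networks`}{`NC_j`, see [related_networks()];}
#'   \item{`drugs_on_related`}{per related network `N_i`, the set
#'     `DNC_ij` of the disease's drugs with a target inside `N_i`;}
#'   \item{`drugs_on_related_union`}{`DNGT_j_s`, the union of the
#'     `DNC_ij` — the disease's drugs targeting networks that contain
#'     disease genes;}
#'   \item{`drugs_on_any_network`}{`DNA_j`, the disease's drugs with a
#'     target anywhere in the pooled gene content of all networks.}
#' }
#' The chain `drugs_on_related_union` \eqn{\subseteq}
#' `drugs_on_any_network` \eqn{\subseteq} the disease's phase drug set
#' always holds.
#'
#' @inheritParams related_networks
#' @return object of class `disease_network_sets`.
#' @export
disease_network_sets <- function(universe, j,
                                 gene_mode = c("integrated", "omim"),
                                 phase = "all") {
  gene_mode <- match.arg(gene_mode)
  check_phase(phase)
  rec <- get_disease(universe, j)
  drugs <- rec$drugs_by_phase[[phase]]
  tj <- union_drug_targets(universe, j, phase)
  nc <- related_networks(universe, j, gene_mode, phase)
  dnc <- lapply(nc, function(i) {
    window <- intersect(universe$networks[[i]], tj)
    drugs[vapply(universe$drugs[drugs],
                 function(tk) length(intersect(tk, window)) > 0L, logical(1))]
  })
  names(dnc) <- nc
  na_genes <- collection_genes(universe$networks)
  dna <- drugs[vapply(universe$drugs[drugs],
                      function(tk) length(intersect(tk, na_genes)) > 0L,
                      logical(1))]
  structure(list(disease_number = rec$disease_number, phase = phase,
                 gene_mode = gene_mode,
                 related_networks = nc,
                 drugs_on_related = dnc,
                 drugs_on_related_union =
                   sort(unique(as.character(unlist(dnc, use.names = FALSE)))),
                 drugs_on_any_network = sort(dna)),
            class = "disease_network_sets")
}

#' @export
print.disease_network_sets <- function(x, ...) {
  cat(sprintf(paste0("<disease_network_sets> disease %d (%s, %s): %d related",
                     " networks, %d drugs on related, %d on any network\n"),
              x$disease_number, x$phase, x$gene_mode,
              length(x$related_networks), length(x$drugs_on_related_union),
              length(x$drugs_on_any_network)))
  invisible(x)
}

#' Classify one drug's targets for a disease
#'
#' Assigns the priority-ordered label of [drug_categories]: `disease_gene`
#' if any target is a disease (risk) gene; otherwise
#' `related_network_partner` if any target lies in a network containing a
#' disease gene; otherwise `other_network` if any target lies in any
#' network; otherwise `no_network`.
#'
#' @param universe a [study_universe()].
#' @param j disease number.
#' @param drug_id drug ID (must exist in the universe's drug table).
#' @param gene_mode `"integrated"` or `"omim"`.
#' @return one of the [drug_categories] labels.
#' @export
categorize_drug <- function(universe, j, drug_id,
                            gene_mode = c("integrated", "omim")) {
  gene_mode <- match.arg(gene_mode)
  if (!drug_id %in% names(universe$drugs)) stop("unknown drug: ", drug_id)
  unname(categorize_drugs_impl(universe, j, drug_id, gene_mode,
                               invert_collection(universe$networks)))
}

# vectorized over drug IDs with a precomputed gene -> network index
categorize_drugs_impl <- function(universe, j, drug_ids, gene_mode, idx) {
  dg <- disease_genes(universe, j, gene_mode)
  gene_nets <- unique(unlist(idx[intersect(dg, names(idx))],
                             use.names = FALSE))
  vapply(drug_ids, function(drug_id) {
    targets <- universe$drugs[[drug_id]]
    if (length(intersect(targets, dg))) return("disease_gene")
    hit_nets <- unique(unlist(idx[intersect(targets, names(idx))],
                              use.names = FALSE))
    if (length(intersect(hit_nets, gene_nets))) {
      return("related_network_partner")
    }
    if (length(hit_nets)) return("other_network")
    "no_network"
  }, character(1))
}

#' Phase-wise target-category rate table
#'
#' For each requested disease and each drug-development phase, counts the
#' disease's drugs per target category and converts them to percentages.
#' With the default denominator `"dna"` only drugs targeting at least one
#' network (`DNA_j`) enter the table, split over the three in-network
#' categories; drugs outside every network are reported separately in the
#' `no_network_count` attribute-free column of the summary (they change no
#' percentage). With `denominator = "all_drugs"` the whole phase drug set
#' is the denominator and `no_network` becomes a fourth category. Within
#' each (disease, phase) the percentages sum to 100.
#'
#' @param universe a [study_universe()].
#' @param disease_numbers integer vector of disease numbers.
#' @param gene_mode `"integrated"` or `"omim"`.
#' @param denominator `"dna"` (drugs targeting any network) or
#'   `"all_drugs"`.
#' @return object of class `rate_table`: a data.frame with columns
#'   `disease`, `phase`, `category`, `count`, `percent`, plus attributes
#'   `denominators` (per disease x phase) and `no_network` (per disease x
#'   phase count of out-of-network drugs, `"dna"` mode only).
#' @export
rate_table <- function(universe, disease_numbers,
                       gene_mode = c("integrated", "omim"),
                       denominator = c("dna", "all_drugs")) {
  gene_mode <- match.arg(gene_mode)
  denominator <- match.arg(denominator)
  if (length(disease_numbers) < 1L) stop("need at least one disease")
  cats <- if (denominator == "dna") drug_categories[1:3] else drug_categories
  idx <- invert_collection(universe$networks)
  rows <- list()
  denoms <- list()
  no_net <- list()
  for (j in disease_numbers) {
    rec <- get_disease(universe, j)
    for (ph in drug_phases) {
      drugs <- rec$drugs_by_phase[[ph]]
      labs <- categorize_drugs_impl(universe, j, drugs, gene_mode, idx)
      if (denominator == "dna") {
        dna <- disease_network_sets(universe, j, gene_mode,
                                    ph)$drugs_on_any_network
        if (length(dna) == 0L) {
          stop("disease ", j, ", phase '", ph,
               "': no drug targets any network; rate undefined")
        }
        no_net[[paste(j, ph)]] <- length(drugs) - length(dna)
        labs <- labs[drugs %in% dna]
        denom <- length(dna)
      } else {
        if (length(drugs) == 0L) {
          stop("disease ", j, ", phase '", ph, "': no drugs; rate undefined")
        }
        denom <- length(drugs)
      }
      denoms[[paste(j, ph)]] <- denom
      counts <- vapply(cats, function(cc) sum(labs == cc), integer(1))
      rows[[paste(j, ph)]] <- data.frame(
        disease = j, phase = ph, category = cats,
        count = unname(counts), percent = unname(100 * counts / denom),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$phase <- factor(out$phase, levels = drug_phases)
  out$category <- factor(out$category, levels = cats)
  structure(out, denominators = denoms,
            no_network = if (denominator == "dna") no_net,
            gene_mode = gene_mode, denominator = denominator,
            class = c("rate_table", "data.frame"))
}

#' Fold change of a category rate across the development pipeline
#'
#' The ratio of a target category's percentage among approved drugs to its
#' percentage among all drugs — the pipeline's enrichment of that category.
#' For instance a category at 2.0% of all drugs and 8.2% of approved drugs
#' has a fold change of 4.1. A zero baseline yields `NaN` (flagged, not an
#' error).
#'
#' @param rates a [rate_table()].
#' @param j disease number present in the table.
#' @param category one of the table's category labels.
#' @return numeric ratio; `NaN` when the all-drugs percentage is zero.
#' @export
pipeline_fold_change <- function(rates, j, category) {
  stopifnot(inherits(rates, "rate_table"))
  pick <- function(ph) {
    r <- rates$percent[rates$disease == j & rates$phase == ph &
                         rates$category == category]
    if (length(r) != 1L) {
      stop("no unique cell for disease ", j, ", phase '", ph,
           "', category '", category, "'")
    }
    r
  }
  p_all <- pick("all")
  p_app <- pick("approved")
  if (p_all == 0) return(NaN)
  p_app / p_all
}
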