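#' Configuration for the synthetic annotation universe
#'
#' Defines the shape of a generated study universe. Structural defaults
#' follow the scale of the real annotation snapshot the pipeline was
#' designed around: 1260 networks of 2-10 genes nested inside 353 larger,
#' overlapping pathway maps, 15 disease groups, about 22 diseases per group
#' and 12273 drugs. The generative assumptions are:
#'
#' * networks are random gene segments; each pathway map is the union of
#'   several sampled networks plus extra genes, so every network is
#'   contained in at least one pathway map;
#' * each disease group owns a designated pool of networks; a disease's
#'   Mendelian genes are drawn from its group's pool genes with probability
#'   `group_enrichment` (gamma) and uniformly otherwise — gamma is the knob
#'   that makes disease-gene networks group-characteristic;
#' * GWAS risk genes are drawn half from the pool and half uniformly, so
#'   the `"integrated"` and `"omim"` gene modes differ measurably;
#' * drugs receive uniform random targets; each disease samples its drug
#'   list; clinical-trial membership is an independent coin with rate
#'   `phase_rates["clinical"]`; approval is a coin whose *odds* are
#'   multiplied by `approval_odds_multiplier` (rho) when the drug targets a
#'   network containing the disease's genes — rho is the knob that creates
#'   the genetic-support approval enrichment the rate analysis measures.
#'
#' @param n_genes number of genes in the universe.
#' @param n_networks,network_size_range number and gene-size range of
#'   network elements.
#' @param n_pathways,networks_per_pathway_range,extra_genes_per_pathway
#'   pathway-map construction parameters.
#' @param n_groups number of disease groups (labels taken from
#'   [disease_group_codes] when `n_groups <= 15`).
#' @param pool_networks_per_group networks designated to each group's pool
#'   (pools are disjoint).
#' @param diseases_per_group,disease_genes_per_disease,gwas_genes_per_disease
#'   disease-table parameters (gene counts are numbers of draws; the stored
#'   sets deduplicate).
#' @param group_enrichment gamma in `[0, 1]`, see above.
#' @param n_drugs,targets_per_drug_range,drugs_per_disease_range drug-table
#'   parameters.
#' @param phase_rates named numeric: fraction of a disease's drugs reaching
#'   `clinical` and baseline approval probability `approved`, both in
#'   (0, 1].
#' @param approval_odds_multiplier rho > 0, see above.
#' @param multi_group_prob probability that a disease carries a second
#'   group label (0 by default so the generated ground truth is
#'   unambiguous).
#' @param seed integer seed; every draw flows from it.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 8000,
                         n_networks = 1260,
                         network_size_range = c(2, 10),
                         n_pathways = 353,
                         networks_per_pathway_range = c(2, 8),
                         extra_genes_per_pathway = 40,
                         n_groups = 15,
                         pool_networks_per_group = 10,
                         diseases_per_group = 22,
                         disease_genes_per_disease = 6,
                         gwas_genes_per_disease = 30,
                         group_enrichment = 0.8,
                         n_drugs = 12273,
                         targets_per_drug_range = c(1, 3),
                         drugs_per_disease_range = c(10, 60),
                         phase_rates = c(clinical = 0.6, approved = 0.2),
                         approval_odds_multiplier = 4,
                         multi_group_prob = 0,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_networks = as.integer(n_networks),
              network_size_range = as.integer(network_size_range),
              n_pathways = as.integer(n_pathways),
              networks_per_pathway_range =
                as.integer(networks_per_pathway_range),
              extra_genes_per_pathway = as.integer(extra_genes_per_pathway),
              n_groups = as.integer(n_groups),
              pool_networks_per_group = as.integer(pool_networks_per_group),
              diseases_per_group = as.integer(diseases_per_group),
              disease_genes_per_disease =
                as.integer(disease_genes_per_disease),
              gwas_genes_per_disease = as.integer(gwas_genes_per_disease),
              group_enrichment = as.numeric(group_enrichment),
              n_drugs = as.integer(n_drugs),
              targets_per_drug_range = as.integer(targets_per_drug_range),
              drugs_per_disease_range = as.integer(drugs_per_disease_range),
              phase_rates = phase_rates,
              approval_odds_multiplier =
                as.numeric(approval_odds_multiplier),
              multi_group_prob = as.numeric(multi_group_prob),
              seed = as.integer(seed))
  counts <- c("n_genes", "n_networks", "n_pathways", "n_groups",
              "pool_networks_per_group", "diseases_per_group",
              "disease_genes_per_disease", "n_drugs")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("`", nm, "` must be a positive integer")
    }
  }
  for (nm in c("network_size_range", "networks_per_pathway_range",
               "targets_per_drug_range", "drugs_per_disease_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || anyNA(r) || r[1] < 1L || r[2] < r[1]) {
      stop("`", nm, "` must be an increasing pair of positive integers")
    }
  }
  if (cfg$gwas_genes_per_disease < 0L || cfg$extra_genes_per_pathway < 0L) {
    stop("gene counts must be non-negative")
  }
  if (cfg$group_enrichment < 0 || cfg$group_enrichment > 1) {
    stop("`group_enrichment` (gamma) must lie in [0, 1]")
  }
  if (cfg$approval_odds_multiplier <= 0) {
    stop("`approval_odds_multiplier` (rho) must be > 0")
  }
  pr <- cfg$phase_rates
  if (!all(c("clinical", "approved") %in% names(pr)) ||
      any(pr[c("clinical", "approved")] <= 0) ||
      any(pr[c("clinical", "approved")] > 1)) {
    stop("`phase_rates` must give clinical and approved fractions in (0, 1]")
  }
  if (cfg$network_size_range[2] > cfg$n_genes) {
    stop("network size range exceeds the gene universe")
  }
  if (cfg$networks_per_pathway_range[2] > cfg$n_networks) {
    stop("networks per pathway exceed the number of networks")
  }
  if (cfg$n_groups * cfg$pool_networks_per_group > cfg$n_networks) {
    stop("designated pools require n_groups * pool_networks_per_group <= n_networks")
  }
  if (cfg$drugs_per_disease_range[2] > cfg$n_drugs) {
    stop("drugs per disease exceed the drug universe")
  }
  structure(cfg, class = "synth_config")
}

rbern <- function(n, p) stats::runif(n) < p

#' Generate a synthetic study universe with known ground truth
#'
#' Draws a complete [study_universe()] under the generative model described
#' in [synth_config()], fully reproducible from `config$seed`, and returns
#' it together with a ground-truth record: the per-group designated network
#' pools, the per-(disease, drug) genetic-support flag used to bias
#' approval odds, and the realized support rate among in-network drug
#' pairs (the quantity [expected_fold()] needs).
#'
#' The generated universe always passes [assemble_universe()] validation.
#'
#' @param config a [synth_config()].
#' @return list with elements `universe` (a `study_universe`) and `truth`
#'   (list: `pools`, `pairs` data.frame with columns `disease`, `drug`,
#'   `supported`, `in_network`, `clinical`, `approved`, `support_rate`,
#'   `gamma`, `rho`).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))

  net_sizes <- sample(seq(cfg$network_size_range[1],
                          cfg$network_size_range[2]),
                      cfg$n_networks, replace = TRUE)
  networks <- lapply(net_sizes, function(s) sample(genes, s))
  names(networks) <- sprintf("N%05d", seq_len(cfg$n_networks))

  npp <- sample(seq(cfg$networks_per_pathway_range[1],
                    cfg$networks_per_pathway_range[2]),
                cfg$n_pathways, replace = TRUE)
  pathway_nets <- lapply(npp, function(k) sample(names(networks), k))
  # guarantee every network is nested in at least one pathway map
  uncovered <- setdiff(names(networks),
                       unique(unlist(pathway_nets, use.names = FALSE)))
  if (length(uncovered)) {
    host <- sample.int(cfg$n_pathways, length(uncovered), replace = TRUE)
    for (i in seq_along(uncovered)) {
      pathway_nets[[host[i]]] <- c(pathway_nets[[host[i]]], uncovered[i])
    }
  }
  pathways <- lapply(pathway_nets, function(ids) {
    unique(c(unlist(networks[ids], use.names = FALSE),
             if (cfg$extra_genes_per_pathway > 0)
               sample(genes, cfg$extra_genes_per_pathway)))
  })
  names(pathways) <- sprintf("P%04d", seq_len(cfg$n_pathways))

  groups <- if (cfg$n_groups <= length(disease_group_codes)) {
    disease_group_codes[seq_len(cfg$n_groups)]
  } else {
    sprintf("G%02d", seq_len(cfg$n_groups))
  }
  pool_ids <- sample(names(networks),
                     cfg$n_groups * cfg$pool_networks_per_group)
  pools <- split(pool_ids, rep(groups, each = cfg$pool_networks_per_group))
  pools <- pools[groups]
  pool_genes <- lapply(pools, function(ids)
    unique(unlist(networks[ids], use.names = FALSE)))

  drug_sizes <- sample(seq(cfg$targets_per_drug_range[1],
                           cfg$targets_per_drug_range[2]),
                       cfg$n_drugs, replace = TRUE)
  drugs <- lapply(drug_sizes, function(s) sample(genes, s))
  names(drugs) <- sprintf("D%05d", seq_len(cfg$n_drugs))

  gene2net <- invert_collection(
    gene_set_collection(networks, kind = "network"))
  na_genes <- unique(unlist(networks, use.names = FALSE))
  drug_in_na <- vapply(drugs, function(tk)
    any(tk %in% na_genes), logical(1))

  draw_genes <- function(n, pool, p_pool) {
    if (n == 0L) return(character())
    from_pool <- rbern(n, p_pool) & length(pool) > 0
    unique(c(if (any(from_pool)) sample(pool, sum(from_pool), replace = TRUE),
             if (any(!from_pool)) sample(genes, sum(!from_pool),
                                         replace = TRUE)))
  }

  p_clin <- cfg$phase_rates[["clinical"]]
  p_app <- cfg$phase_rates[["approved"]]
  odds <- p_app / (1 - p_app)
  p_app_supported <- if (p_app >= 1) 1 else {
    (cfg$approval_odds_multiplier * odds) /
      (1 + cfg$approval_odds_multiplier * odds)
  }

  diseases <- list()
  pair_rows <- list()
  j <- 0L
  for (gi in seq_along(groups)) {
    for (d in seq_len(cfg$diseases_per_group)) {
      j <- j + 1L
      glab <- groups[gi]
      if (cfg$multi_group_prob > 0 && cfg$n_groups > 1L &&
          rbern(1L, cfg$multi_group_prob)) {
        glab <- c(glab, sample(setdiff(groups, glab), 1L))
      }
      omim <- draw_genes(cfg$disease_genes_per_disease, pool_genes[[gi]],
                         cfg$group_enrichment)
      risk <- draw_genes(cfg$gwas_genes_per_disease, pool_genes[[gi]], 0.5)
      dg <- union(omim, risk)
      # genes of every network containing a disease gene: the support set
      gene_nets <- unique(unlist(gene2net[intersect(dg, names(gene2net))],
                                 use.names = FALSE))
      support_genes <- unique(unlist(networks[gene_nets], use.names = FALSE))

      n_dd <- sample(seq(cfg$drugs_per_disease_range[1],
                         cfg$drugs_per_disease_range[2]), 1L)
      dd <- sample(names(drugs), n_dd)
      supported <- vapply(drugs[dd], function(tk)
        any(tk %in% support_genes), logical(1))
      clinical <- rbern(n_dd, p_clin)
      approved <- rbern(n_dd, ifelse(supported, p_app_supported, p_app))
      diseases[[as.character(j)]] <- disease_record(
        j, name = sprintf("synthetic disease %d", j), groups = glab,
        omim_genes = omim, risk_genes = risk,
        drugs_by_phase = list(all = dd, clinical = dd[clinical],
                              approved = dd[approved]))
      pair_rows[[j]] <- data.frame(
        disease = j, drug = dd, supported = unname(supported),
        in_network = unname(drug_in_na[dd]), clinical = clinical,
        approved = approved, row.names = NULL)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  support_rate <- mean(pairs$supported[pairs$in_network])

  universe <- assemble_universe(
    gene_set_collection(pathways, kind = "pathway"),
    gene_set_collection(networks, kind = "network"),
    drugs, diseases)
  list(universe = universe,
       truth = list(pools = pools, pairs = pairs,
                    support_rate = support_rate,
                    gamma = cfg$group_enrichment,
                    rho = cfg$approval_odds_multiplier,
                    config = cfg))
}

#' Expected pipeline fold change under the generator's odds model
#'
#' Closed-form expectation of the approved-vs-all rate ratio for the
#' genetically supported category. Writing `q` for the support rate among
#' in-network drug pairs at the all-drugs stage, `p0` for the baseline
#' approval probability and `p1` for the rho-boosted one
#' (`odds(p1) = rho * odds(p0)`), the approved-stage support rate is
#' `q p1 / (q p1 + (1 - q) p0)` and the fold change is
#' \deqn{fold = \frac{p_1}{q p_1 + (1-q) p_0}.}
#' At `rho = 1` the fold is exactly 1 for any `q`; as rho grows the fold
#' saturates at `1 / (q + (1 - q) p0)`, below the absolute `1/q` ceiling
#' reached only when the baseline approval rate also vanishes.
#'
#' @param config a [synth_config()].
#' @param support_rate realized support rate `q` among in-network drug
#'   pairs (from `generate_universe()$truth$support_rate`). May be omitted
#'   when `rho = 1`, where the fold is 1 identically.
#' @return numeric expected fold change.
#' @export
expected_fold <- function(config, support_rate = NULL) {
  stopifnot(inherits(config, "synth_config"))
  rho <- config$approval_odds_multiplier
  if (is.null(support_rate)) {
    if (rho == 1) return(1)
    stop("`support_rate` is required when rho != 1 ",
         "(pass generate_universe()$truth$support_rate)")
  }
  stopifnot(support_rate > 0, support_rate <= 1)
  p0 <- config$phase_rates[["approved"]]
  odds <- p0 / (1 - p0)
  p1 <- if (p0 >= 1) 1 else (rho * odds) / (1 + rho * odds)
  unname(p1 / (support_rate * p1 + (1 - support_rate) * p0))
}

#' Pooled genetic-support rate and pipeline fold change
#'
#' Measures, across a set of diseases and one phase, the pooled rate of
#' drugs targeting networks that contain disease genes (the
#' `drugs_on_related_union` sets) among drugs targeting any network (the
#' `drugs_on_any_network` denominators). `pooled_pipeline_fold()` is the
#' ratio of that rate among approved drugs to the rate among all drugs —
#' the measured counterpart of [expected_fold()].
#'
#' @param universe a [study_universe()].
#' @param disease_numbers diseases to pool over (default: all).
#' @param gene_mode `"integrated"` or `"omim"`.
#' @param phase drug-development phase.
#' @return `pooled_support_rate()`: list with `n_supported`, `n_in_network`,
#'   `rate`. `pooled_pipeline_fold()`: numeric fold (NaN if a stage has no
#'   in-network drugs or zero support at the all stage).
#' @export
pooled_support_rate <- function(universe, disease_numbers = NULL,
                                gene_mode = c("integrated", "omim"),
                                phase = "all") {
  gene_mode <- match.arg(gene_mode)
  if (is.null(disease_numbers)) {
    disease_numbers <- as.integer(names(universe$diseases))
  }
  n_sup <- 0L
  n_dna <- 0L
  for (j in disease_numbers) {
    sets <- disease_network_sets(universe, j, gene_mode, phase)
    n_sup <- n_sup + length(sets$drugs_on_related_union)
    n_dna <- n_dna + length(sets$drugs_on_any_network)
  }
  list(n_supported = n_sup, n_in_network = n_dna,
       rate = if (n_dna > 0) n_sup / n_dna else NaN)
}

#' @rdname pooled_support_rate
#' @export
pooled_pipeline_fold <- function(universe, disease_numbers = NULL,
                                 gene_mode = c("integrated", "omim")) {
  gene_mode <- match.arg(gene_mode)
  r_all <- pooled_support_rate(universe, disease_numbers, gene_mode, "all")
  r_app <- pooled_support_rate(universe, disease_numbers, gene_mode,
                               "approved")
  if (!is.finite(r_all$rate) || r_all$rate == 0 || !is.finite(r_app$rate)) {
    return(NaN)
  }
  r_app$rate / r_all$rate
}
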