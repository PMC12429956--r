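# Hand-built toy universes and naive enumeration oracles used to validate
# every score/count family by exhaustive loops over elements x diseases.

toy_universe <- function(pathways, networks, drugs, diseases) {
  # diseases: list of list(j, groups, omim, risk, all, clinical, approved)
  recs <- list()
  for (d in diseases) {
    recs[[as.character(d$j)]] <- disease_record(
      d$j, name = paste0("disease ", d$j),
      groups = d$groups %||% character(),
      omim_genes = d$omim %||% character(),
      risk_genes = d$risk %||% character(),
      drugs_by_phase = list(all = d$all %||% character(),
                            clinical = d$clinical %||% character(),
                            approved = d$approved %||% character()))
  }
  assemble_universe(gene_set_collection(pathways, "pathway"),
                    gene_set_collection(networks, "network"),
                    drugs, recs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dg_of <- function(u, j, gene_mode) {
  r <- u$diseases[[as.character(j)]]
  if (gene_mode == "omim") r$omim_genes else union(r$omim_genes, r$risk_genes)
}

tj_of <- function(u, j, phase) {
  r <- u$diseases[[as.character(j)]]
  unique(unlist(u$drugs[r$drugs_by_phase[[phase]]], use.names = FALSE))
}

oracle_spg <- function(collection, u, gene_mode = "integrated") {
  vapply(names(collection), function(i) {
    sum(vapply(names(u$diseases), function(j)
      length(intersect(collection[[i]], dg_of(u, j, gene_mode))), integer(1)))
  }, integer(1))
}

oracle_spt <- function(collection, u, phase = "all") {
  vapply(names(collection), function(i) {
    sum(vapply(names(u$diseases), function(j)
      length(intersect(collection[[i]], tj_of(u, j, phase))), integer(1)))
  }, integer(1))
}

oracle_same_disease <- function(collection, u, gene_mode = "integrated",
                                phase = "all") {
  vapply(names(collection), function(i) {
    sum(vapply(names(u$diseases), function(j) {
      length(intersect(collection[[i]], dg_of(u, j, gene_mode))) > 0 &&
        length(intersect(collection[[i]], tj_of(u, j, phase))) > 0
    }, logical(1)))
  }, integer(1))
}

oracle_sng <- function(u, group, gene_mode = "integrated") {
  js <- Filter(function(j) group %in% u$diseases[[j]]$groups,
               names(u$diseases))
  vapply(names(u$networks), function(i) {
    sum(vapply(js, function(j)
      length(intersect(u$networks[[i]], dg_of(u, j, gene_mode))), integer(1)))
  }, integer(1))
}

oracle_beta <- function(u, i, j, phase = "all") {
  tj <- tj_of(u, j, phase)
  window <- intersect(u$networks[[i]], tj)
  dd <- u$diseases[[as.character(j)]]$drugs_by_phase[[phase]]
  sum(vapply(dd, function(k)
    length(intersect(u$drugs[[k]], window)) > 0, logical(1)))
}

oracle_snd <- function(u, group, phase = "all") {
  js <- Filter(function(j) group %in% u$diseases[[j]]$groups,
               names(u$diseases))
  vapply(names(u$networks), function(i) {
    sum(vapply(js, function(j) oracle_beta(u, i, j, phase), integer(1)))
  }, integer(1))
}

oracle_related_networks <- function(u, j, gene_mode = "integrated",
                                    phase = "all") {
  dg <- dg_of(u, j, gene_mode)
  tj <- tj_of(u, j, phase)
  sort(Filter(function(i) {
    length(intersect(u$networks[[i]], dg)) > 0 &&
      length(intersect(u$networks[[i]], tj)) > 0
  }, names(u$networks)))
}

oracle_dngt <- function(u, j, gene_mode = "integrated", phase = "all") {
  nc <- oracle_related_networks(u, j, gene_mode, phase)
  tj <- tj_of(u, j, phase)
  dd <- u$diseases[[as.character(j)]]$drugs_by_phase[[phase]]
  sort(unique(as.character(unlist(lapply(nc, function(i) {
    window <- intersect(u$networks[[i]], tj)
    dd[vapply(dd, function(k)
      length(intersect(u$drugs[[k]], window)) > 0, logical(1))]
  }), use.names = FALSE))))
}

oracle_dna <- function(u, j, phase = "all") {
  na_genes <- unique(unlist(unclass(u$networks), use.names = FALSE))
  dd <- u$diseases[[as.character(j)]]$drugs_by_phase[[phase]]
  sort(dd[vapply(dd, function(k)
    length(intersect(u$drugs[[k]], na_genes)) > 0, logical(1))])
}

oracle_categorize <- function(u, j, drug_id, gene_mode = "integrated") {
  targets <- u$drugs[[drug_id]]
  dg <- dg_of(u, j, gene_mode)
  if (length(intersect(targets, dg)) > 0) return("disease_gene")
  gene_nets <- Filter(function(i)
    length(intersect(u$networks[[i]], dg)) > 0, names(u$networks))
  in_gene_net <- any(vapply(gene_nets, function(i)
    length(intersect(u$networks[[i]], targets)) > 0, logical(1)))
  if (in_gene_net) return("related_network_partner")
  in_any <- any(vapply(names(u$networks), function(i)
    length(intersect(u$networks[[i]], targets)) > 0, logical(1)))
  if (in_any) return("other_network")
  "no_network"
}

# small random universe within the validation-study size caps
small_config <- function(seed, ...) {
  defaults <- list(n_genes = 120, n_networks = 30,
                   network_size_range = c(2, 6), n_pathways = 10,
                   networks_per_pathway_range = c(2, 4),
                   extra_genes_per_pathway = 3, n_groups = 3,
                   pool_networks_per_group = 4, diseases_per_group = 4,
                   disease_genes_per_disease = 4,
                   gwas_genes_per_disease = 4, group_enrichment = 0.8,
                   n_drugs = 80, targets_per_drug_range = c(1, 3),
                   drugs_per_disease_range = c(5, 15),
                   phase_rates = c(clinical = 0.6, approved = 0.25),
                   approval_odds_multiplier = 2, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# shared reference example: one disease's genes, a related and an
# unrelated network, drugs covering all four target categories
example_universe <- function() {
  toy_universe(
    pathways = list(P1 = c("g1", "g2", "g3", "g4", "g9")),
    networks = list(N1 = c("g1", "g2"), N2 = c("g3", "g4")),
    drugs = list(a = "g1", b = "g2", c = "g3", d = "g9", e = character()),
    diseases = list(list(j = 1, groups = "Imm", omim = "g1",
                         all = c("a", "b", "c", "d", "e"),
                         clinical = c("a", "b"), approved = "a")))
}

fake_rate_table <- function(df) {
  structure(df, class = c("rate_table", "data.frame"))
}
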