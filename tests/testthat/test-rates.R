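# Expected values computed with the enumeration oracles in helper-oracles.R.

test_that("related_networks needs gene and target in the same network", {
  u <- toy_universe(
    pathways = list(P1 = c("g1", "g2", "g3")),
    networks = list(N1 = c("g1", "g2"), N2 = "g3"),
    drugs = list(a = "g2"),
    diseases = list(list(j = 1, omim = "g1", all = "a")))
  expect_identical(related_networks(u, 1), "N1")

  # disease gene and drug target split across networks -> no related network
  u2 <- toy_universe(
    pathways = list(P1 = c("g1", "g3")),
    networks = list(N1 = "g1", N2 = "g3"),
    drugs = list(a = "g3"),
    diseases = list(list(j = 1, omim = "g1", all = "a"),
                    list(j = 2, all = "a")))
  expect_identical(related_networks(u2, 1), character(0))
  # no disease genes -> empty
  expect_identical(related_networks(u2, 2), character(0))
})

test_that("disease_network_sets builds the DNC/DNGT/DNA chain", {
  u <- example_universe()
  sets <- disease_network_sets(u, 1)
  expect_identical(sets$related_networks, "N1")
  expect_setequal(sets$drugs_on_related$N1, c("a", "b"))
  expect_identical(sets$drugs_on_related_union, c("a", "b"))
  expect_setequal(sets$drugs_on_any_network, c("a", "b", "c"))
  # chain: DNGT_s subset of DNA subset of the phase drug set
  expect_true(all(sets$drugs_on_related_union %in%
                    sets$drugs_on_any_network))
  expect_true(all(sets$drugs_on_any_network %in%
                    u$diseases[["1"]]$drugs_by_phase$all))
})

test_that("set chains and oracle agreement hold on random universes", {
  for (seed in 1:12) {
    u <- generate_universe(small_config(seed + 300))$universe
    for (j in as.integer(names(u$diseases))[1:4]) {
      for (ph in c("all", "approved")) {
        sets <- disease_network_sets(u, j, phase = ph)
        expect_identical(sets$related_networks,
                         oracle_related_networks(u, j, phase = ph))
        expect_identical(sets$drugs_on_related_union,
                         oracle_dngt(u, j, phase = ph))
        expect_identical(sort(sets$drugs_on_any_network),
                         oracle_dna(u, j, ph))
        expect_true(all(sets$drugs_on_related_union %in%
                          sets$drugs_on_any_network))
        expect_true(all(sets$drugs_on_any_network %in%
                          u$diseases[[as.character(j)]]$drugs_by_phase[[ph]]))
      }
      # risk genes only ever add related networks and supported drugs
      omim <- disease_network_sets(u, j, gene_mode = "omim")
      intg <- disease_network_sets(u, j, gene_mode = "integrated")
      expect_true(all(omim$related_networks %in% intg$related_networks))
      expect_gte(length(intg$drugs_on_related_union),
                 length(omim$drugs_on_related_union))
    }
  }
})

test_that("categorize_drug applies the priority order over the four cases", {
  u <- toy_universe(
    pathways = list(P1 = c("g1", "g2", "g3", "g4", "g9")),
    networks = list(N1 = c("g1", "g2"), N2 = c("g3", "g4")),
    drugs = list(dg = "g1", partner = "g2", other = "g3", none = "g9",
                 mixed = c("g1", "g3"), empty = character()),
    diseases = list(list(j = 1, omim = "g1",
                         all = c("dg", "partner", "other", "none",
                                 "mixed", "empty"))))
  expect_identical(categorize_drug(u, 1, "dg"), "disease_gene")
  expect_identical(categorize_drug(u, 1, "partner"), "related_network_partner")
  expect_identical(categorize_drug(u, 1, "other"), "other_network")
  expect_identical(categorize_drug(u, 1, "none"), "no_network")
  # a disease-gene target wins over an other-network target
  expect_identical(categorize_drug(u, 1, "mixed"), "disease_gene")
  expect_identical(categorize_drug(u, 1, "empty"), "no_network")
  expect_error(categorize_drug(u, 1, "zzz"), "unknown drug")
  for (d in names(u$drugs)) {
    expect_identical(categorize_drug(u, 1, d), oracle_categorize(u, 1, d))
  }
})

test_that("categorization partitions the phase drug set on random universes", {
  for (seed in 1:8) {
    u <- generate_universe(small_config(seed + 400))$universe
    j <- as.integer(names(u$diseases))[2]
    for (ph in drug_phases) {
      dd <- u$diseases[[as.character(j)]]$drugs_by_phase[[ph]]
      labs <- vapply(dd, function(d) categorize_drug(u, j, d), character(1))
      expect_identical(unname(labs),
                       unname(vapply(dd, function(d)
                         oracle_categorize(u, j, d), character(1))))
      expect_identical(length(labs), length(dd))
      expect_true(all(labs %in% drug_categories))
    }
  }
})

test_that("rate_table percentages sum to 100 and counts to the denominator", {
  gu <- generate_universe(small_config(91, drugs_per_disease_range = c(15, 30)))
  u <- gu$universe
  js <- as.integer(names(u$diseases))[1:5]
  rt <- rate_table(u, js)
  denoms <- attr(rt, "denominators")
  for (j in js) {
    for (ph in drug_phases) {
      cell <- rt[rt$disease == j & rt$phase == ph, ]
      expect_equal(sum(cell$percent), 100, tolerance = 1e-9)
      expect_identical(sum(cell$count), denoms[[paste(j, ph)]])
    }
  }
  # all-drugs denominator variant includes no_network as a fourth category
  rt4 <- rate_table(u, js, denominator = "all_drugs")
  expect_true("no_network" %in% levels(rt4$category))
  for (j in js) {
    cell <- rt4[rt4$disease == j & rt4$phase == "all", ]
    expect_equal(sum(cell$percent), 100, tolerance = 1e-9)
    expect_identical(sum(cell$count),
                     length(u$diseases[[as.character(j)]]$drugs_by_phase$all))
  }
})

test_that("rate_table arithmetic matches a hand-counted example", {
  # one disease: 4 in-network drugs categorized (1, 2, 1) -> (25, 50, 25)
  u <- toy_universe(
    pathways = list(P1 = c("g1", "g2", "g3", "g4", "g9")),
    networks = list(N1 = c("g1", "g2"), N2 = c("g3", "g4")),
    drugs = list(d1 = "g1", d2 = "g2", d3 = "g2", d4 = "g3",
                 d5 = "g9"),
    diseases = list(list(j = 1, omim = "g1",
                         all = c("d1", "d2", "d3", "d4", "d5"),
                         clinical = c("d1", "d2", "d3", "d4"),
                         approved = c("d1", "d4"))))
  rt <- rate_table(u, 1)
  cell <- rt[rt$phase == "all", ]
  expect_identical(cell$count, c(1L, 2L, 1L))
  expect_equal(cell$percent, c(25, 50, 25))
  # removing the out-of-network drug d5 changes no percentage
  u2 <- toy_universe(
    pathways = list(P1 = c("g1", "g2", "g3", "g4", "g9")),
    networks = list(N1 = c("g1", "g2"), N2 = c("g3", "g4")),
    drugs = list(d1 = "g1", d2 = "g2", d3 = "g2", d4 = "g3"),
    diseases = list(list(j = 1, omim = "g1",
                         all = c("d1", "d2", "d3", "d4"),
                         clinical = c("d1", "d2", "d3", "d4"),
                         approved = c("d1", "d4"))))
  rt2 <- rate_table(u2, 1)
  expect_equal(rt2$percent, rt$percent)
})

test_that("rate_table errors when a cell has no in-network drugs", {
  u <- toy_universe(
    pathways = list(P1 = c("g1", "g9")),
    networks = list(N1 = "g1"),
    drugs = list(d1 = "g9"),
    diseases = list(list(j = 1, omim = "g1", all = "d1", approved = "d1")))
  expect_error(rate_table(u, 1), "no drug targets any network")
})

test_that("pipeline_fold_change divides approved by all-stage percentages", {
  rt <- fake_rate_table(data.frame(
    disease = 1,
    phase = rep(c("all", "clinical", "approved"), each = 2),
    category = rep(c("related_network_partner", "other_network"), 3),
    percent = c(2.0, 98.0, 3.0, 97.0, 8.2, 91.8)))
  # the classic genetic-support illustration: 2.0% -> 8.2% is a 4.1 fold
  expect_equal(pipeline_fold_change(rt, 1, "related_network_partner"), 4.1)
  expect_equal(pipeline_fold_change(rt, 1, "other_network"), 91.8 / 98)

  flat <- fake_rate_table(data.frame(
    disease = 1, phase = c("all", "approved"), category = "x",
    percent = c(5, 5)))
  expect_equal(pipeline_fold_change(flat, 1, "x"), 1)

  zero <- fake_rate_table(data.frame(
    disease = 1, phase = c("all", "approved"), category = "x",
    percent = c(0, 5)))
  expect_true(is.nan(pipeline_fold_change(zero, 1, "x")))
})
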