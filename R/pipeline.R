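#' Write a study universe to a directory of plain-text tables
#'
#' Serializes a universe to the exact TSV dialects the readers consume:
#' `pathways.tsv` and `networks.tsv` (two-column link files),
#' `diseases.tsv`, `drugs.tsv` (drug/target pairs, `-` marking target-free
#' drugs), `gene_lists.tsv` and `trial_links.tsv`. Reading the directory
#' back with [load_universe_dir()] reproduces the universe, so the
#' synthetic path exercises the real parsers.
#'
#' @param universe a [study_universe()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "study_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_link_file(universe$pathways, file.path(dir, "pathways.tsv"))
  write_link_file(universe$networks, file.path(dir, "networks.tsv"))

  ds <- universe$diseases
  dtab <- data.frame(
    disease_number = vapply(ds, `[[`, integer(1), "disease_number"),
    name = vapply(ds, `[[`, character(1), "name"),
    groups = vapply(ds, function(d) paste(sort(d$groups), collapse = ";"),
                    character(1)),
    row.names = NULL)
  write_tsv(dtab, file.path(dir, "diseases.tsv"))

  drug_ids <- sort(names(universe$drugs))
  dr <- do.call(rbind, lapply(drug_ids, function(id) {
    tg <- sort(universe$drugs[[id]])
    if (length(tg) == 0L) tg <- "-"
    data.frame(drug_id = id, gene_id = tg, row.names = NULL)
  }))
  write_tsv(dr, file.path(dir, "drugs.tsv"))

  gl <- do.call(rbind, lapply(ds, function(d) {
    rbind(
      if (length(d$omim_genes))
        data.frame(disease_number = d$disease_number,
                   gene_id = sort(d$omim_genes), source = "omim"),
      if (length(d$risk_genes))
        data.frame(disease_number = d$disease_number,
                   gene_id = sort(d$risk_genes), source = "gwas"))
  }))
  if (is.null(gl)) {
    gl <- data.frame(disease_number = integer(), gene_id = character(),
                     source = character())
  }
  write_tsv(gl, file.path(dir, "gene_lists.tsv"))

  tl <- do.call(rbind, lapply(ds, function(d) {
    do.call(rbind, lapply(drug_phases, function(ph) {
      ids <- sort(d$drugs_by_phase[[ph]])
      if (length(ids) == 0L) return(NULL)
      data.frame(disease_number = d$disease_number, drug_id = ids,
                 phase = ph)
    }))
  }))
  if (is.null(tl)) {
    tl <- data.frame(disease_number = integer(), drug_id = character(),
                     phase = character())
  }
  write_tsv(tl, file.path(dir, "trial_links.tsv"))
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Load a study universe from a directory of plain-text tables
#'
#' Counterpart of [write_universe()]: reads the six TSV tables and
#' assembles a validated [study_universe()].
#'
#' @param dir directory holding the tables.
#' @param group_vocabulary allowed group labels, see
#'   [read_disease_table()].
#' @return a `study_universe`.
#' @export
load_universe_dir <- function(dir, group_vocabulary = disease_group_codes) {
  need <- c("pathways.tsv", "networks.tsv", "diseases.tsv", "drugs.tsv",
            "gene_lists.tsv", "trial_links.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("input directory '", dir, "' is missing: ",
         paste(missing, collapse = ", "))
  }
  assemble_universe(
    pathways = read_link_file(file.path(dir, "pathways.tsv"), "pathway"),
    networks = read_link_file(file.path(dir, "networks.tsv"), "network"),
    drugs = read_drug_table(file.path(dir, "drugs.tsv")),
    diseases = read_disease_table(file.path(dir, "diseases.tsv"),
                                  group_vocabulary),
    gene_lists = read_gene_lists(file.path(dir, "gene_lists.tsv")),
    trial_links = read_trial_links(file.path(dir, "trial_links.tsv")))
}

#' Select focal diseases by drug count
#'
#' Deterministic focal-disease selection: rank diseases by the number of
#' drugs in `phase` (ties broken by ascending disease number), keep the top
#' `n_top`, then optionally drop the `exclude_fewest_approved` diseases
#' with the fewest approved drugs and the `exclude_fewest_risk` diseases
#' with the fewest GWAS risk genes (same tie rule). The study design this
#' mirrors picked the 9 diseases with the most drugs in clinical trials and
#' excluded one by fewest approved drugs and two by fewest GWAS data,
#' leaving six.
#'
#' @param universe a [study_universe()].
#' @param n_top how many diseases to shortlist.
#' @param phase phase whose drug counts rank the diseases.
#' @param exclude_fewest_approved,exclude_fewest_risk how many shortlisted
#'   diseases to drop again.
#' @return integer vector of disease numbers, ordered by descending drug
#'   count.
#' @export
select_diseases <- function(universe, n_top = 9, phase = "clinical",
                            exclude_fewest_approved = 1,
                            exclude_fewest_risk = 2) {
  check_phase(phase)
  ds <- universe$diseases
  if (length(ds) < n_top) {
    stop("universe has ", length(ds), " diseases; cannot shortlist ", n_top)
  }
  nums <- vapply(ds, `[[`, integer(1), "disease_number")
  n_drugs <- vapply(ds, function(d) length(d$drugs_by_phase[[phase]]),
                    integer(1))
  ord <- order(-n_drugs, nums)
  picked <- nums[ord][seq_len(n_top)]
  drop_fewest <- function(picked, key, m) {
    if (m <= 0) return(picked)
    if (m >= length(picked)) stop("exclusion rules would drop every disease")
    vals <- vapply(as.character(picked), key, numeric(1))
    drop <- picked[order(vals, picked)][seq_len(m)]
    setdiff(picked, drop)
  }
  picked <- drop_fewest(picked, function(j)
    length(ds[[j]]$drugs_by_phase$approved), exclude_fewest_approved)
  picked <- drop_fewest(picked, function(j)
    length(ds[[j]]$risk_genes), exclude_fewest_risk)
  unname(picked[order(match(picked, nums[ord]))])
}

#' Run the full analysis pipeline on an input directory
#'
#' End-to-end driver reproducing the three stages on any universe
#' directory (real or written by [write_universe()]): (1) coverage counts
#' on both universes and their contingency comparison; (2) per-group
#' network rankings by disease-gene score and by drug-targeting score;
#' (3) focal-disease rate table with three-way ANOVA, Tukey HSD contrasts
#' and per-disease pipeline fold changes. All tables are written as TSV,
#' summaries as JSON, plus a `manifest.json` with input checksums, the
#' seed and the run parameters; reruns on identical inputs are
#' byte-identical.
#'
#' @param input_dir directory of input tables, see [load_universe_dir()].
#' @param output_dir where to write results (created if absent).
#' @param gene_mode `"integrated"` or `"omim"`.
#' @param phase phase used for the coverage and ranking stages.
#' @param top_k ranks reported per group.
#' @param layout contingency layout for [compare_universes()]. The default
#'   four-category table degenerates (zero "neither" column) when every
#'   pathway map is saturated with disease genes and targets, as happens at
#'   full annotation scale; use `"two_by_two"` there.
#' @param diseases focal disease numbers for the rate stage, or `NULL` to
#'   apply [select_diseases()] with its defaults.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents the provenance of generated inputs).
#' @return invisibly, a list with the in-memory results (`coverage`,
#'   `comparison`, `rankings`, `rates`, `anova`, `tukey`, `folds`,
#'   `manifest`).
#' @export
run_all <- function(input_dir, output_dir,
                    gene_mode = c("integrated", "omim"), phase = "all",
                    top_k = 3, diseases = NULL, seed = NULL,
                    layout = c("four_category", "two_by_two")) {
  gene_mode <- match.arg(gene_mode)
  layout <- match.arg(layout)
  check_phase(phase)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  universe <- load_universe_dir(input_dir)

  # stage 1: coverage of both universes
  cov_p <- coverage_counts(universe$pathways, universe, gene_mode, phase)
  cov_n <- coverage_counts(universe$networks, universe, gene_mode, phase)
  for (cc in list(cov_p, cov_n)) {
    write_tsv(data.frame(element = names(cc$spg), spg = unname(cc$spg),
                         spt = unname(cc$spt),
                         same_disease = unname(cc$same_disease)),
              file.path(output_dir,
                        sprintf("coverage_%s.tsv", cc$universe_kind)))
  }
  # universes so saturated that a contingency category empties make the
  # chi-square undefined; record that instead of failing the whole run
  comparison <- tryCatch(
    compare_universes(cov_p, cov_n, layout = layout),
    error = function(e) list(table = NULL, statistic = NULL, dof = NULL,
                             p_value = NULL,
                             degenerate = conditionMessage(e)))
  write_json_file(list(
    pathway = c(list(element_count = cov_p$element_count), cov_p$counts),
    network = c(list(element_count = cov_n$element_count), cov_n$counts),
    chi_square = list(statistic = comparison$statistic,
                      dof = comparison$dof, p_value = comparison$p_value,
                      table = comparison$table,
                      degenerate = comparison$degenerate)),
    file.path(output_dir, "coverage_summary.json"))

  # stage 2: per-group rankings
  rankings <- list()
  for (grp in universe_groups(universe)) {
    sng <- sng_scores(universe, grp, gene_mode)
    snd <- snd_scores(universe, grp, phase)
    rk_g <- top_k(sng, top_k)
    rk_d <- top_k(snd, top_k)
    rk_g$by <- if (nrow(rk_g)) "genes" else character()
    rk_d$by <- if (nrow(rk_d)) "drugs" else character()
    rk <- rbind(rk_g, rk_d)
    rk <- data.frame(group = rep(grp, nrow(rk)), rk, row.names = NULL)
    rankings[[grp]] <- rk
  }
  write_tsv(do.call(rbind, c(rankings, list(make.row.names = FALSE))),
            file.path(output_dir, "group_rankings.tsv"))

  # stage 3: focal-disease rates and factorial statistics. The ANOVA runs
  # on whole-drug-set percentages restricted to the three in-network
  # categories: with the DNA denominator the three percentages sum to 100
  # within every (disease, phase), which forces the DISEASE and PHASE main
  # effects to be structurally zero.
  if (is.null(diseases)) diseases <- select_diseases(universe)
  rates <- rate_table(universe, diseases, gene_mode)
  write_tsv(as.data.frame(rates), file.path(output_dir, "rate_table.tsv"))
  rates_all <- rate_table(universe, diseases, gene_mode,
                          denominator = "all_drugs")
  anova <- three_way_anova(
    rates_all[rates_all$category != "no_network", ])
  write_tsv(anova$table, file.path(output_dir, "anova.tsv"))
  tukey <- anova_tukey(anova, "PHASE")
  write_tsv(tukey, file.path(output_dir, "tukey_phase.tsv"))
  folds <- vapply(diseases, function(j)
    pipeline_fold_change(rates, j, "related_network_partner"), numeric(1))
  write_tsv(data.frame(disease = diseases, category =
                         "related_network_partner", fold = folds),
            file.path(output_dir, "fold_changes.tsv"))

  files <- sort(list.files(input_dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  manifest <- list(
    inputs = as.list(sums),
    parameters = list(gene_mode = gene_mode, phase = phase, top_k = top_k,
                      diseases = diseases),
    seed = seed)
  write_json_file(manifest, file.path(output_dir, "manifest.json"))
  invisible(list(universe = universe,
                 coverage = list(pathway = cov_p, network = cov_n),
                 comparison = comparison, rankings = rankings,
                 rates = rates, anova = anova, tukey = tukey,
                 folds = folds, manifest = manifest))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "string")
}
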