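#' Disease-group vocabulary
#'
#' The default 15-label vocabulary for disease groups, after the standard
#' categorization of designated rare and intractable diseases: neuromuscular,
#' endocrine, metabolic, immune, cardiovascular, hematologic, skin and
#' connective tissue, bone and joint, eye, gastrointestinal, kidney and
#' urinary, respiratory, chromosomal/gene abnormalities, hearing and balance,
#' and ear/nose/throat diseases.
#'
#' @format character vector of 15 three-letter codes.
#' @export
disease_group_codes <- c("Neu", "Endo", "Met", "Imm", "Card", "Hem", "Skin",
                         "Bone", "Eye", "Gast", "Kid", "Resp", "Chr", "Hear",
                         "Ear")

#' Drug-development phase labels
#'
#' The three nested drug sets compared by the rate analysis: all drugs ever
#' developed for a disease, the subset in clinical trials, and the subset
#' approved. Clinical and approved drugs are always contained in "all";
#' approved drugs need not all appear in "clinical" (approvals can predate
#' the trial registries a database covers).
#'
#' @format character vector `c("all", "clinical", "approved")`.
#' @export
drug_phases <- c("all", "clinical", "approved")

check_phase <- function(phase) {
  if (length(phase) != 1L || !phase %in% drug_phases) {
    stop("unknown phase '", paste(phase, collapse = ","),
         "'; must be one of: ", paste(drug_phases, collapse = ", "))
  }
  phase
}

#' Disease record
#'
#' One designated disease: its number `j`, name, group labels, Mendelian
#' (OMIM-derived) disease genes, GWAS-derived risk genes, and the per-phase
#' drug sets.
#'
#' @param disease_number integer disease number `j`.
#' @param name disease name.
#' @param groups character vector of group labels (may be empty).
#' @param omim_genes,risk_genes character vectors of gene IDs.
#' @param drugs_by_phase named list with entries `all`, `clinical`,
#'   `approved`, each a character vector of drug IDs. `clinical` and
#'   `approved` must be subsets of `all`; `approved` need not be a subset of
#'   `clinical`.
#' @return object of class `disease_record`.
#' @export
disease_record <- function(disease_number, name = "", groups = character(),
                           omim_genes = character(), risk_genes = character(),
                           drugs_by_phase = list(all = character(),
                                                 clinical = character(),
                                                 approved = character())) {
  disease_number <- as.integer(disease_number)
  stopifnot(length(disease_number) == 1L, !is.na(disease_number))
  missing_phase <- setdiff(drug_phases, names(drugs_by_phase))
  for (ph in missing_phase) drugs_by_phase[[ph]] <- character()
  drugs_by_phase <- lapply(drugs_by_phase[drug_phases],
                           function(d) unique(as.character(d)))
  for (ph in c("clinical", "approved")) {
    extra <- setdiff(drugs_by_phase[[ph]], drugs_by_phase$all)
    if (length(extra)) {
      stop("disease ", disease_number, ": ", ph,
           " drugs not contained in the 'all' phase: ",
           paste(extra, collapse = ", "))
    }
  }
  structure(list(disease_number = disease_number,
                 name = as.character(name),
                 groups = unique(as.character(groups)),
                 omim_genes = unique(as.character(omim_genes)),
                 risk_genes = unique(as.character(risk_genes)),
                 drugs_by_phase = drugs_by_phase),
            class = "disease_record")
}

#' @export
print.disease_record <- function(x, ...) {
  cat(sprintf("<disease_record> #%d '%s' [%s] %d OMIM + %d risk genes; drugs all/clinical/approved = %d/%d/%d\n",
              x$disease_number, x$name, paste(x$groups, collapse = ";"),
              length(x$omim_genes), length(x$risk_genes),
              length(x$drugs_by_phase$all), length(x$drugs_by_phase$clinical),
              length(x$drugs_by_phase$approved)))
  invisible(x)
}

#' Disease genes of a record under a gene mode
#'
#' `"omim"` returns the Mendelian gene list alone; `"integrated"` (the
#' default throughout the package) returns the union of Mendelian genes and
#' GWAS risk genes.
#'
#' @param universe a [study_universe()].
#' @param j disease number.
#' @param gene_mode `"integrated"` or `"omim"`.
#' @return character vector of gene IDs.
#' @export
disease_genes <- function(universe, j, gene_mode = c("integrated", "omim")) {
  gene_mode <- match.arg(gene_mode)
  rec <- get_disease(universe, j)
  if (gene_mode == "omim") rec$omim_genes
  else union(rec$omim_genes, rec$risk_genes)
}

get_disease <- function(universe, j) {
  rec <- universe$diseases[[as.character(j)]]
  if (is.null(rec)) stop("unknown disease number: ", j)
  rec
}

#' Read the disease table
#'
#' TSV with columns `disease_number`, `name`, `groups` (semicolon-separated
#' group labels; may be empty). Unknown group labels are rejected unless the
#' vocabulary is overridden.
#'
#' @param path file path.
#' @param group_vocabulary allowed group labels; defaults to
#'   [disease_group_codes].
#' @return named list of [disease_record()]s (gene and drug slots empty),
#'   keyed by disease number.
#' @export
read_disease_table <- function(path, group_vocabulary = disease_group_codes) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#", quote = "")
  need <- c("disease_number", "name", "groups")
  if (!all(need %in% names(tab))) {
    stop("disease table must have columns: ", paste(need, collapse = ", "))
  }
  nums <- suppressWarnings(as.integer(tab$disease_number))
  if (anyNA(nums)) stop("non-integer disease_number in '", path, "'")
  if (anyDuplicated(nums)) {
    stop("duplicate disease_number: ",
         paste(unique(nums[duplicated(nums)]), collapse = ", "))
  }
  recs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    groups <- strsplit(tab$groups[i], ";", fixed = TRUE)[[1]]
    groups <- groups[nzchar(groups)]
    unknown <- setdiff(groups, group_vocabulary)
    if (length(unknown)) {
      stop("disease ", nums[i], ": unknown group label(s) ",
           paste(unknown, collapse = ", "),
           " (override `group_vocabulary` to accept them)")
    }
    if (length(groups) == 0L) {
      warning("disease ", nums[i], " has no group label")
    }
    recs[[i]] <- disease_record(nums[i], tab$name[i], groups)
  }
  names(recs) <- as.character(nums)
  recs
}

#' Read a drug-target table
#'
#' TSV with columns `drug_id`, `gene_id`, one target pair per line. A
#' `gene_id` of `"-"` declares a drug with no targets (so that target-free
#' drugs can still be referenced by trial links).
#'
#' @param path file path.
#' @return named list: drug ID -> character vector of target gene IDs.
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#", quote = "")
  if (!all(c("drug_id", "gene_id") %in% names(tab))) {
    stop("drug table must have columns drug_id, gene_id")
  }
  targets <- lapply(split(tab$gene_id, tab$drug_id),
                    function(g) setdiff(unique(g), "-"))
  targets[order(names(targets))]
}

#' Read per-disease gene lists
#'
#' TSV with columns `disease_number`, `gene_id`, `source` where source is
#' `"omim"` (Mendelian disease genes) or `"gwas"` (risk genes).
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_gene_lists <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#", quote = "")
  if (!all(c("disease_number", "gene_id", "source") %in% names(tab))) {
    stop("gene list must have columns disease_number, gene_id, source")
  }
  bad <- setdiff(unique(tab$source), c("omim", "gwas"))
  if (length(bad)) stop("unknown gene source(s): ", paste(bad, collapse = ", "))
  tab$disease_number <- as.integer(tab$disease_number)
  tab
}

#' Read disease-drug trial links
#'
#' TSV with columns `disease_number`, `drug_id`, `phase` (one of `all`,
#' `clinical`, `approved`). A drug listed for a disease under `clinical` or
#' `approved` is automatically a member of that disease's `all` set.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_trial_links <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#", quote = "")
  if (!all(c("disease_number", "drug_id", "phase") %in% names(tab))) {
    stop("trial links must have columns disease_number, drug_id, phase")
  }
  bad <- setdiff(unique(tab$phase), drug_phases)
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  tab$disease_number <- as.integer(tab$disease_number)
  tab
}

#' Assemble and validate a study universe
#'
#' Cross-links all component tables into a single validated container: the
#' pathway and network collections, the drug-target map, and the disease
#' records carrying their gene lists and phase-wise drug sets. Every
#' referenced drug must exist in the drug table; disease genes absent from
#' every pathway and network are retained in the gene universe but counted
#' in the validation report (they can never contribute to an overlap score).
#'
#' @param pathways,networks [gene_set_collection()]s.
#' @param drugs named list: drug ID -> character vector of target gene IDs.
#' @param diseases named list of [disease_record()]s keyed by disease number.
#' @param gene_lists data.frame as from [read_gene_lists()], or `NULL`.
#' @param trial_links data.frame as from [read_trial_links()], or `NULL`.
#' @return object of class `study_universe` with fields `pathways`,
#'   `networks`, `drugs`, `diseases`, `gene_universe` and a `validation`
#'   report (orphan gene count and IDs, element counts).
#' @export
assemble_universe <- function(pathways, networks, drugs, diseases,
                              gene_lists = NULL, trial_links = NULL) {
  stopifnot(inherits(pathways, "gene_set_collection"),
            inherits(networks, "gene_set_collection"))
  if (collection_kind(pathways) != "pathway" ||
      collection_kind(networks) != "network") {
    stop("`pathways` must have kind 'pathway' and `networks` kind 'network'")
  }
  drugs <- lapply(drugs, function(g) unique(as.character(g)))
  diseases <- diseases[order(as.integer(names(diseases)))]

  if (!is.null(gene_lists)) {
    by_dis <- split(gene_lists, gene_lists$disease_number)
    for (key in names(by_dis)) {
      if (is.null(diseases[[key]])) {
        stop("gene list references unknown disease number: ", key)
      }
      gl <- by_dis[[key]]
      diseases[[key]]$omim_genes <-
        unique(c(diseases[[key]]$omim_genes, gl$gene_id[gl$source == "omim"]))
      diseases[[key]]$risk_genes <-
        unique(c(diseases[[key]]$risk_genes, gl$gene_id[gl$source == "gwas"]))
    }
  }
  if (!is.null(trial_links)) {
    unknown_dis <- setdiff(unique(trial_links$disease_number),
                           as.integer(names(diseases)))
    unknown_drug <- setdiff(unique(trial_links$drug_id), names(drugs))
    if (length(unknown_dis) || length(unknown_drug)) {
      stop("trial links reference unknown ",
           if (length(unknown_dis)) paste0("disease(s) ",
             paste(unknown_dis, collapse = ", ")) else "",
           if (length(unknown_dis) && length(unknown_drug)) " and " else "",
           if (length(unknown_drug)) paste0("drug(s) ",
             paste(unknown_drug, collapse = ", ")) else "")
    }
    by_dis <- split(trial_links, trial_links$disease_number)
    for (key in names(by_dis)) {
      tl <- by_dis[[key]]
      dp <- diseases[[key]]$drugs_by_phase
      for (ph in drug_phases) {
        dp[[ph]] <- unique(c(dp[[ph]], tl$drug_id[tl$phase == ph]))
      }
      # phase nesting: clinical and approved imply membership in all
      dp$all <- unique(c(dp$all, dp$clinical, dp$approved))
      diseases[[key]]$drugs_by_phase <- dp
    }
  }
  # re-validate records (phase nesting) after augmentation
  diseases <- lapply(diseases, function(d) {
    disease_record(d$disease_number, d$name, d$groups, d$omim_genes,
                   d$risk_genes, d$drugs_by_phase)
  })

  for (d in diseases) {
    missing <- setdiff(d$drugs_by_phase$all, names(drugs))
    if (length(missing)) {
      stop("disease ", d$disease_number,
           " references drug(s) absent from the drug table: ",
           paste(missing, collapse = ", "))
    }
  }

  annotated <- union(collection_genes(pathways), collection_genes(networks))
  disease_gene_pool <- unique(unlist(lapply(diseases, function(d)
    c(d$omim_genes, d$risk_genes)), use.names = FALSE))
  orphans <- setdiff(disease_gene_pool, annotated)
  gene_universe <- unique(c(annotated, disease_gene_pool,
                            unlist(drugs, use.names = FALSE)))

  validation <- list(
    n_pathways = length(pathways),
    n_networks = length(networks),
    n_drugs = length(drugs),
    n_diseases = length(diseases),
    n_genes = length(gene_universe),
    orphan_disease_genes = sort(orphans),
    n_orphan_disease_genes = length(orphans)
  )
  structure(list(pathways = pathways, networks = networks, drugs = drugs,
                 diseases = diseases, gene_universe = gene_universe,
                 validation = validation),
            class = "study_universe")
}

#' @export
print.study_universe <- function(x, ...) {
  v <- x$validation
  cat(sprintf(paste0("<study_universe> %d pathway maps, %d networks, ",
                     "%d diseases, %d drugs, %d genes (%d orphan disease genes)\n"),
              v$n_pathways, v$n_networks, v$n_diseases, v$n_drugs, v$n_genes,
              v$n_orphan_disease_genes))
  invisible(x)
}

#' Disease groups present in a universe
#' @param universe a [study_universe()].
#' @return sorted character vector of group labels in use.
#' @export
universe_groups <- function(universe) {
  sort(unique(unlist(lapply(universe$diseases, `[[`, "groups"),
                     use.names = FALSE)))
}

group_disease_numbers <- function(universe, group) {
  in_group <- vapply(universe$diseases,
                     function(d) group %in% d$groups, logical(1))
  if (!any(in_group)) stop("unknown or empty disease group: ", group)
  vapply(universe$diseases[in_group], `[[`, integer(1), "disease_number")
}

#' Union of a disease's drug targets in a phase
#'
#' The pooled target set `T_j`: the union over all drugs developed for
#' disease `j` (in the given phase) of each drug's target genes.
#'
#' @param universe a [study_universe()].
#' @param j disease number.
#' @param phase one of `"all"`, `"clinical"`, `"approved"`.
#' @return character vector of gene IDs (empty if the disease has no drugs
#'   in that phase).
#' @export
union_drug_targets <- function(universe, j, phase = "all") {
  check_phase(phase)
  rec <- get_disease(universe, j)
  ids <- rec$drugs_by_phase[[phase]]
  unique(as.character(unlist(universe$drugs[ids], use.names = FALSE)))
}
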