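# End-to-end orchestration: configuration with every census threshold,
# staged execution with per-stage outputs, an effective-config dump, a run
# log of record counts, and a MANIFEST whose hashes certify byte-identical
# reruns.

#' Pipeline configuration
#'
#' All census thresholds in one place. Defaults are the published census
#' settings: Cas10 length/E-value screen (500 aa, 1e-20), dereplication at
#' identity 0.9 / word size 5, cyclase cutoff 1e-3, HD cutoff 1e-1 with the
#' literal motif in the first 50 residues and the 10-40 extraction window,
#' the cyclase -50/+100 window, the +/-4 kb neighbourhood, the 1e-7
#' candidate E-value floor, and candidate clustering at 0.4 / word size 2.
#' The effector search cutoff and the identity floors of the in-package
#' similarity screens are package defaults (documented assumptions).
#'
#' @param ... overrides for any threshold.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cas10_len = 500,
    cas10_evalue = 1e-20,
    derep_identity = 0.9,
    derep_word = 5,
    cyclase_evalue = 1e-3,
    cyclase_window = c(50, 100),
    hd_evalue = 1e-1,
    hd_first_n = 50,
    hd_extract = c(10, 40),
    neighborhood_flank = 4000,
    effector_evalue = 1e-3,
    candidate_evalue_floor = 1e-7,
    candidate_identity = 0.4,
    candidate_word = 2,
    cross_locus_identity = 0.3,
    ancillary_identity = 0.3,
    calibration_shuffles = 200,
    calibration_length = 400,
    calibration_seed = 7L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

# Build and calibrate one profile per seed alignment; group them by role.
build_profile_library <- function(seed_alignments, config) {
  profiles <- imap(seed_alignments, function(aln, fam) {
    p <- build_profile(aln, name = fam, family = fam)
    calibrate_profile(p, n_shuffles = config$calibration_shuffles,
                      length = max(config$calibration_length, p$length),
                      seed = derive_seed(config$calibration_seed, fam))
  })
  known <- intersect(names(profiles), known_families())
  cand <- intersect(names(profiles), candidate_families())
  anc <- intersect(names(profiles), ancillary_families())
  list(cas10 = profiles[intersect(names(profiles), "Cas10")],
       cyclase = profiles[intersect(names(profiles), "Cas10_cyclase")],
       hd = profiles[["Cas10_HD"]],
       effectors = map(setNames(known, known), ~ list(profiles[[.x]])),
       candidates = map(setNames(cand, cand), ~ list(profiles[[.x]])),
       all = profiles)
}

#' Assemble the census table
#'
#' One row per locus surviving the hybrid filter and carrying a
#' representative Cas10, with the Cas10 domain calls, the typed effector
#' families, candidate clusters, activator set, and the per-genome type III
#' locus count.
#'
#' @param loci filtered locus tibble (with `cas10_id`).
#' @param cas10s Cas10 record tibble (cyclase/HD calls).
#' @param effector_hits typed effector hits with `locus_id`.
#' @param candidates candidate records with `locus_id` (may be empty).
#' @return the census tibble.
#' @export
build_census <- function(loci, cas10s, effector_hits,
                         candidates = tibble(locus_id = character(0),
                                             cluster = integer(0))) {
  amap <- activator_map()
  census <- loci |>
    left_join(cas10s |>
                select("protein_id", "has_cyclase", "has_hd"),
              by = c(cas10_id = "protein_id")) |>
    mutate(families = map(.data$locus_id, function(l) {
      sort(unique(effector_hits$family[effector_hits$locus_id == l]))
    }),
    candidates = map(.data$locus_id, function(l) {
      sort(unique(candidates$protein_id[candidates$locus_id == l]))
    }),
    activators = map(.data$families, function(fs) {
      sort(unique(amap$activator[amap$family %in% fs]))
    })) |>
    group_by(.data$genome_id) |>
    mutate(n_type3_loci_in_genome = n()) |>
    ungroup() |>
    select("locus_id", "genome_id", "subtype", "has_cyclase", "has_hd",
           "families", "candidates", "activators",
           "n_type3_loci_in_genome")
  census
}

#' Run the census pipeline end to end
#'
#' Stage order: ingest, profile building and calibration, Cas10 census,
#' hybrid-locus filtering, effector typing, candidate discovery, CorA
#' analysis, statistics, reports. Every stage writes its TSV/JSON under
#' `out_dir`; an effective-config YAML and a run log of per-stage record
#' counts are always written, and a MANIFEST (relative path, md5, row
#' count) certifies the run: reruns with identical inputs, config and seed
#' are byte-identical.
#'
#' @param proteins tibble from [read_protein_fasta()] joined with
#'   coordinates, or a `dataset` from [generate_dataset()] via the
#'   `dataset` argument.
#' @param annotations tibble from [read_annotation_table()].
#' @param seed_alignments named list of aligned seed rows (see
#'   [make_seed_alignments()]).
#' @param out_dir output directory, created if needed; `NULL` skips all
#'   file output.
#' @param config a [pipeline_config()].
#' @param dataset optional dataset list (overrides the first three
#'   arguments).
#' @return invisibly, a list with every stage result (`profiles`,
#'   `cas10s`, `loci`, `effector_hits`, `cross_hits`, `candidates`,
#'   `cora`, `census`, `counts`, `cooccurrence`, `upset`, `glm`,
#'   `manifest`).
#' @export
run_pipeline <- function(proteins = NULL, annotations = NULL,
                         seed_alignments = NULL, out_dir = NULL,
                         config = pipeline_config(), dataset = NULL) {
  if (!is.null(dataset)) {
    proteins <- dataset$proteins
    annotations <- dataset$annotations
    seed_alignments <- dataset$seed_alignments
  }
  log_rows <- list()
  note <- function(stage, n) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(stage = stage, records = n)
    message(sprintf("[%s] %d records", stage, n))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # ingest ------------------------------------------------------------
  stage("ingest", {
    stopifnot(is.data.frame(proteins), is.data.frame(annotations),
              is.list(seed_alignments))
  })
  note("ingest", nrow(proteins))

  # profiles -----------------------------------------------------------
  lib <- stage("profiles", build_profile_library(seed_alignments, config))
  note("profiles", length(lib$all))

  # cas10 census --------------------------------------------------------
  cas10s <- stage("cas10_census", {
    found <- find_cas10(proteins, lib$cas10, min_len = config$min_cas10_len,
                        cutoff = config$cas10_evalue)
    recs <- found |>
      left_join(proteins |> select("protein_id", "sequence"),
                by = "protein_id") |>
      left_join(annotations |> select("protein_id", "locus_id"),
                by = "protein_id")
    recs <- dereplicate_cas10(recs, config$derep_identity, config$derep_word)
    recs <- detect_cyclase(recs, lib$cyclase, cutoff = config$cyclase_evalue)
    detect_hd(recs, lib$hd, cutoff = config$hd_evalue,
              first_n = config$hd_first_n)
  })
  note("cas10_census", nrow(cas10s))

  # hybrid filter --------------------------------------------------------
  loci <- stage("hybrid_filter", {
    # n_cas10 counted from detected Cas10s, not annotation labels
    lt <- build_locus_table(annotations) |>
      mutate(n_cas10 = map_int(.data$member_proteins,
                               ~ sum(.x %in% cas10s$protein_id)))
    lt <- filter_hybrid_loci(lt)
    reps <- cas10s |> filter(.data$cluster_rep)
    lt |>
      mutate(cas10_id = map_chr(.data$member_proteins, function(m) {
        hit <- intersect(m, reps$protein_id)
        if (length(hit)) hit[1] else NA_character_
      })) |>
      filter(!is.na(.data$cas10_id))
  })
  note("hybrid_filter", nrow(loci))

  # effector typing -------------------------------------------------------
  neighborhoods <- map(seq_len(nrow(loci)),
                       ~ locus_neighborhood(loci[.x, ], proteins,
                                            flank = config$neighborhood_flank))
  nb_db <- length(unique(unlist(map(neighborhoods, "protein_id"))))
  typing <- stage("effector_typing", {
    hits <- map2(neighborhoods, loci$locus_id, function(nb, l) {
      if (nrow(nb) == 0) return(NULL)
      h <- type_effectors(nb, lib$effectors, cutoff = config$effector_evalue,
                          db_size = max(nb_db, 1))
      if (nrow(h)) mutate(h, locus_id = l) else NULL
    })
    raw <- map2(neighborhoods, loci$locus_id, function(nb, l) {
      if (nrow(nb) == 0) return(NULL)
      r <- effector_raw_hits(nb, lib$effectors, cutoff = config$effector_evalue,
                             db_size = max(nb_db, 1))
      if (nrow(r)) mutate(r, locus_id = l) else NULL
    })
    list(hits = bind_rows(hits), raw = bind_rows(raw))
  })
  effector_hits <- typing$hits
  cross_hits <- detect_cross_hits(typing$raw)
  note("effector_typing", nrow(effector_hits))

  # candidate discovery ----------------------------------------------------
  cand <- stage("candidate_discovery", {
    flagged <- flag_candidates(annotations, effector_hits,
                               evalue_floor = config$candidate_evalue_floor)
    # exclude detected Cas10s (well-annotated, never candidates)
    flagged <- flagged |> filter(!.data$protein_id %in% cas10s$protein_id)
    clustered <- cluster_candidates(flagged, config$candidate_identity,
                                    config$candidate_word)
    reps <- clustered |> filter(.data$is_representative)
    loci_proteins <- annotations |>
      filter(!is.na(.data$locus_id)) |>
      select("protein_id", "locus_id", "sequence", "annotation_label")
    xl <- cross_locus_search(reps |> select("protein_id", "sequence"),
                             loci_proteins,
                             identity_min = config$cross_locus_identity,
                             exclude_ids = clustered$protein_id)
    list(clustered = clustered, occurrences = xl$occurrences,
         guilt_by_association = xl$guilt_by_association)
  })
  note("candidate_discovery", nrow(cand$clustered))

  # CorA analysis ----------------------------------------------------------
  cora <- stage("cora_analysis", {
    cora_loci <- unique(effector_hits$locus_id[effector_hits$family == "CorA"])
    anc_refs <- map(setNames(ancillary_families(), ancillary_families()),
                    ~ seed_alignments[[.x]] %||% character(0))
    anc_refs <- keep(anc_refs, ~ length(.x) > 0)
    presence <- bind_rows(map(cora_loci, function(l) {
      lp <- annotations |> filter(.data$locus_id == l) |>
        select("protein_id", "locus_id", "sequence")
      nbp <- locus_neighborhood(loci[loci$locus_id == l, ], proteins,
                                flank = config$neighborhood_flank) |>
        transmute(.data$protein_id, locus_id = l, .data$sequence)
      detect_cora_ancillary(bind_rows(lp, nbp) |> distinct(),
                            anc_refs,
                            identity_min = config$ancillary_identity)
    }))
    cora_prot <- effector_hits |> filter(.data$family == "CorA")
    tree <- NULL
    if (nrow(cora_prot) >= 3) {
      seqs <- proteins |> filter(.data$protein_id %in% cora_prot$protein_id)
      tree <- build_tree(tibble(id = seqs$protein_id, sequence = seqs$sequence))
    }
    list(ancillary = presence, newick = tree)
  })
  note("cora_analysis", nrow(cora$ancillary %||% tibble()))

  # statistics ---------------------------------------------------------------
  statres <- stage("statistics", {
    census <- build_census(loci, cas10s, effector_hits,
                           cand$clustered %||% tibble(locus_id = character(0)))
    counts <- count_families(census)
    cooc <- cooccurrence_matrix(census)
    ups <- upset_configurations(census)
    glm_res <- tryCatch(interlocus_association(census),
                        error = function(e) conditionMessage(e))
    list(census = census, counts = counts, cooccurrence = cooc, upset = ups,
         glm = glm_res)
  })
  note("statistics", nrow(statres$census))

  # reports -------------------------------------------------------------------
  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- stage("reports", {
      write_outputs(out_dir, config, cas10s, loci, effector_hits, cross_hits,
                    cand, cora, statres, log_rows)
    })
    note("reports", nrow(manifest))
  }

  invisible(list(profiles = lib, cas10s = cas10s, loci = loci,
                 effector_hits = effector_hits, cross_hits = cross_hits,
                 candidates = cand, cora = cora, census = statres$census,
                 counts = statres$counts, cooccurrence = statres$cooccurrence,
                 upset = statres$upset, glm = statres$glm,
                 manifest = manifest))
}

# Write every stage artifact plus config dump, run log and MANIFEST.
write_outputs <- function(out_dir, config, cas10s, loci, effector_hits,
                          cross_hits, cand, cora, statres, log_rows) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
    name
  }
  files <- character(0)
  files <- c(files, w(cas10s |> select(-"sequence"), "cas10_census.tsv"))
  files <- c(files, w(loci |>
                        mutate(member_proteins = map_chr(.data$member_proteins,
                                                         paste, collapse = ",")),
                      "loci.tsv"))
  files <- c(files, w(effector_hits, "effector_hits.tsv"))
  files <- c(files, w(cross_hits, "cross_hits.tsv"))
  files <- c(files, w(cand$clustered, "candidates.tsv"))
  files <- c(files, w(cand$occurrences |>
                        mutate(matched_loci = map_chr(.data$matched_loci,
                                                      paste, collapse = ",")),
                      "candidate_occurrences.tsv"))
  files <- c(files, w(cand$guilt_by_association, "guilt_by_association.tsv"))
  if (!is.null(cora$ancillary) && nrow(cora$ancillary)) {
    files <- c(files, w(cora$ancillary, "cora_ancillary.tsv"))
  }
  if (!is.null(cora$newick)) {
    writeLines(cora$newick, file.path(out_dir, "cora_tree.nwk"))
    files <- c(files, "cora_tree.nwk")
  }
  census_paths <- write_census(statres$census,
                               file.path(out_dir, "census.tsv"))
  files <- c(files, "census.tsv", "census.json")
  files <- c(files, w(statres$counts, "family_counts.tsv"))
  edges <- as_tibble(as.data.frame(as.table(statres$cooccurrence$matrix),
                                   stringsAsFactors = FALSE)) |>
    setNames(c("family1", "family2", "count")) |>
    filter(.data$family1 < .data$family2, .data$count > 0)
  files <- c(files, w(edges, "cooccurrence_edges.tsv"))
  files <- c(files, w(statres$upset |> select(-"subtype_breakdown"),
                      "upset_configurations.tsv"))
  glm_out <- if (inherits(statres$glm, "census_glm")) {
    statres$glm[c("coefficient", "std_error", "z", "p_value", "odds_ratio",
                  "or_lacking", "n", "note")]
  } else {
    list(error = statres$glm)
  }
  jsonlite::write_json(glm_out, file.path(out_dir, "glm.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "glm.json")
  yaml::write_yaml(unclass(config), file.path(out_dir, "effective_config.yaml"))
  files <- c(files, "effective_config.yaml")
  files <- c(files, w(bind_rows(log_rows), "run_log.tsv"))
  manifest <- tibble(path = sort(files)) |>
    mutate(md5 = unname(tools::md5sum(file.path(out_dir, .data$path))))
  readr::write_tsv(manifest, file.path(out_dir, "MANIFEST.tsv"),
                   progress = FALSE)
  manifest
}
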