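# Synthetic genomes with planted ground truth. The generator emulates the
# statistical structure the census assumes -- genomes with 1-3 type III
# loci, Cas10s with planted cyclase-motif variants and HD motifs, effector
# genes carrying family signatures within the locus neighbourhood, candidate
# families in effector-less loci, and a controllable locus-level association
# between effector absence and multi-locus genomes -- so every stage is
# testable with no download. Family signatures are synthetic sequence
# blocks, not real family sequences: the artifact tests logic, not biology;
# real seed alignments are a drop-in replacement.

#' Synthetic dataset configuration
#'
#' Defaults are the study conditions every test and the acceptance analysis
#' run under. Probabilities that mirror published census fractions (cyclase
#' 0.92, HD 0.39, effector-family weights) are set to those fractions;
#' remaining rates are fixed at values typical for prokaryotic multi-locus
#' genomes (see the methods vignette).
#'
#' @param n_genomes number of genomes to emit.
#' @param p_multi_locus probability a genome carries 2-3 type III loci.
#' @param p_cyclase probability a Cas10 carries an intact cyclase motif.
#' @param p_hd probability a Cas10 carries an HD motif.
#' @param motif_variant_weights named weights over the ten cyclase motif
#'   variants.
#' @param subtype_weights named weights over type III subtypes.
#' @param presence_intercept logit-scale intercept of effector presence.
#' @param planted_log_or log odds-ratio of effector presence against the
#'   multi-locus indicator (negative: effector-lacking loci are enriched in
#'   multi-locus genomes).
#' @param p_cooccur probability an effector-positive locus carries a second
#'   family.
#' @param p_candidate probability an effector-less locus carries a candidate
#'   family gene.
#' @param p_ancillary probability a CorA locus carries each ancillary
#'   family.
#' @param p_hybrid probability a locus is annotated as a III/non-III hybrid
#'   (single Cas10).
#' @param p_non_iii probability of an extra non-type-III locus in a genome.
#' @param p_two_cas10 probability of an extra hybrid locus with two Cas10
#'   genes (removed by the hybrid filter).
#' @param noise per-residue substitution probability applied to emitted
#'   proteins (signature motifs protected when `protect_motifs`).
#' @param protect_motifs spare literal cyclase/HD motif positions from
#'   noise.
#' @param seed_divergence per-residue substitution rate within seed
#'   alignments and planted candidate/ancillary copies.
#' @param seed master RNG seed; fixed seed implies byte-identical output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genomes = 200,
                         p_multi_locus = 0.2,
                         p_cyclase = 0.92,
                         p_hd = 0.39,
                         motif_variant_weights = c(
                           GGDD = 0.82, AGDD = 0.02, GGED = 0.02, GGDE = 0.02,
                           SGDD = 0.02, DGDD = 0.02, AGDE = 0.02, EGDD = 0.02,
                           KGDD = 0.02, GEDD = 0.02),
                         subtype_weights = c(
                           `III-A` = 0.35, `III-B` = 0.30, `III-C` = 0.05,
                           `III-D` = 0.20, `III-E` = 0.05, `III-F` = 0.05),
                         presence_intercept = 2.5,
                         planted_log_or = -log(2.57),
                         p_cooccur = 0.2,
                         p_candidate = 0.4,
                         p_ancillary = 0.8,
                         p_hybrid = 0.04,
                         p_non_iii = 0.04,
                         p_two_cas10 = 0.02,
                         noise = 0,
                         protect_motifs = TRUE,
                         seed_divergence = 0.05,
                         seed = 42L) {
  stopifnot(p_multi_locus >= 0, p_multi_locus <= 1,
            p_cyclase >= 0, p_cyclase <= 1, p_hd >= 0, p_hd <= 1,
            noise >= 0, noise < 1)
  if (p_multi_locus == 0 && planted_log_or != 0) {
    abort("infeasible config: planted_log_or != 0 requires p_multi_locus > 0")
  }
  if (!setequal(names(motif_variant_weights), motif_variants())) {
    abort("motif_variant_weights must cover exactly the ten motif variants")
  }
  structure(as.list(environment()), class = "synth_config")
}

# Effector family menu: synthetic signature geometry plus sampling weights
# proportional to the published family counts.
effector_menu <- function() {
  counts <- c(Csx1 = 411, `Can1-2` = 143, Cami1 = 135, Csm6 = 55, CorA = 53,
              Cam1 = 52, NucC = 35, CalpL = 17, Csx23 = 4, `SAVED-CHAT` = 3)
  tibble(family = names(counts), weight = as.numeric(counts / sum(counts)),
         sig_len = 35L, typical_length = 360L)
}

candidate_families <- function() c("TIR-SAVED", "Cam2", "Cam3", "Csm6-2")
ancillary_families <- function() c("NrN", "DEDD", "SAM-lyase")

# Deterministic synthetic signature/reference sequences per family.
family_signature <- function(family, seed, len = 35L) {
  withr::with_seed(derive_seed(seed, paste0("sig:", family)), {
    s <- random_protein(len)
    if (family == "Cam1") {
      # membrane effector: a 21-residue hydrophobic TM stretch in-signature
      str_sub(s, 1, 21) <- paste(sample(c("L", "I", "V", "F"), 21,
                                        replace = TRUE), collapse = "")
    }
    s
  })
}

# Full-length reference proteins for candidate and ancillary families
# (cross-locus and ancillary screens use global identity, so homologs are
# full-length mutated copies of these).
family_reference <- function(family, seed, len = 280L) {
  withr::with_seed(derive_seed(seed, paste0("ref:", family)),
                   random_protein(len))
}

# Conserved Cas10 blocks: the recognition signature, the cyclase context
# (motif slot at 0-based offset 50) and the HD block occupying residues
# 10-40 with HD at residues 13-14.
cas10_blocks <- function(seed) {
  list(signature = family_signature("Cas10", seed, 60L),
       cyclase_context = withr::with_seed(
         derive_seed(seed, "cyclase_context"), random_protein(154L)),
       hd_block = withr::with_seed(derive_seed(seed, "hd_block"), {
         b <- random_protein(31L)
         str_sub(b, 4, 5) <- "HD"
         b
       }))
}

place_motif <- function(context, motif) {
  str_sub(context, 51, 54) <- motif
  context
}

#' Seed alignments for every profile family
#'
#' Emits, per family (Cas10, the cyclase context, the HD block, the ten
#' effectors, the four candidate families and the three CorA ancillary
#' families), six mutated copies of the family signature region as an
#' equal-length, gap-free alignment -- sufficient input for
#' [build_profile()]. Cyclase rows sample motif variants by their configured
#' weights with motif positions protected from divergence.
#'
#' @param config a [synth_config()].
#' @param n_seed sequences per alignment.
#' @return named list of character vectors (aligned rows).
#' @export
make_seed_alignments <- function(config, n_seed = 6L) {
  blocks <- cas10_blocks(config$seed)
  menu <- effector_menu()
  out <- list()
  withr::with_seed(derive_seed(config$seed, "seed_alignments"), {
    mut_copies <- function(base, protect = integer(0)) {
      vapply(seq_len(n_seed),
             function(i) mutate_sequence(base, config$seed_divergence, protect),
             character(1))
    }
    out[["Cas10"]] <- mut_copies(blocks$signature)
    out[["Cas10_cyclase"]] <- vapply(seq_len(n_seed), function(i) {
      motif <- sample(names(config$motif_variant_weights), 1,
                      prob = config$motif_variant_weights)
      mutate_sequence(place_motif(blocks$cyclase_context, motif),
                      config$seed_divergence, protect = 51:54)
    }, character(1))
    out[["Cas10_HD"]] <- mut_copies(blocks$hd_block, protect = 4:5)
    for (fam in menu$family) {
      out[[fam]] <- mut_copies(family_signature(fam, config$seed))
    }
    for (fam in candidate_families()) {
      out[[fam]] <- mut_copies(family_reference(fam, config$seed))
    }
    for (fam in ancillary_families()) {
      out[[fam]] <- mut_copies(family_reference(fam, config$seed, len = 250L))
    }
  })
  out
}

# Locus-level census structure: genomes, locus counts, subtypes, effector
# presence drawn from the planted logistic model, family draws, candidate
# placement, and Cas10 domain truth. No sequences; generate_dataset() builds
# them on top, and the statistical property tests use this layer directly.

#' Simulate the locus-level census structure
#'
#' Draws, per genome, the locus count (multi-locus with `p_multi_locus`),
#' and per locus the subtype, effector presence from the planted logistic
#' model (`presence_intercept + planted_log_or * multi`), the family set,
#' candidate-family placement in effector-less loci, and Cas10 cyclase/HD
#' truth.
#'
#' @param config a [synth_config()].
#' @return tibble with one row per locus and the planted truth columns.
#' @export
simulate_census <- function(config) {
  withr::with_seed(derive_seed(config$seed, "census"), {
    menu <- effector_menu()
    multi <- runif(config$n_genomes) < config$p_multi_locus
    n_loci <- ifelse(multi, sample(2:3, config$n_genomes, replace = TRUE,
                                   prob = c(0.75, 0.25)), 1L)
    gidx <- rep(seq_len(config$n_genomes), n_loci)
    lidx <- unlist(lapply(n_loci, seq_len))
    n <- length(gidx)
    present <- runif(n) < plogis(config$presence_intercept +
                                   config$planted_log_or * multi[gidx])
    hybrid <- runif(n) < config$p_hybrid
    subtype <- sample(names(config$subtype_weights), n, replace = TRUE,
                      prob = config$subtype_weights)
    second <- runif(n) < config$p_cooccur
    fams <- lapply(seq_len(n), function(i) {
      if (!present[i]) return(character(0))
      sort(sample(menu$family, if (second[i]) 2L else 1L, prob = menu$weight))
    })
    with_cand <- !present & runif(n) < config$p_candidate
    cands <- lapply(seq_len(n), function(i) {
      if (with_cand[i]) sample(candidate_families(), 1) else character(0)
    })
    tibble(
      genome_id = sprintf("genome_%04d", gidx),
      locus_id = sprintf("genome_%04d_locus_%d", gidx, lidx),
      subtype = ifelse(hybrid, paste0(subtype, "/I-C"), subtype),
      multi_locus = multi[gidx],
      n_type3_loci_in_genome = n_loci[gidx],
      has_effector = present,
      families = fams,
      candidates = cands,
      has_cyclase = runif(n) < config$p_cyclase,
      cyclase_motif = sample(names(config$motif_variant_weights), n,
                             replace = TRUE,
                             prob = config$motif_variant_weights),
      has_hd = runif(n) < config$p_hd)
  })
}

# Build one Cas10 sequence with planted domains.
build_cas10_sequence <- function(blocks, has_cyclase, cyclase_motif, has_hd,
                                 config) {
  len <- sample(520:600, 1)
  s <- random_protein(len)
  if (has_hd) str_sub(s, 10, 40) <- blocks$hd_block
  str_sub(s, 60, 119) <- blocks$signature
  cyc_pos <- NA_integer_
  if (has_cyclase) {
    cyc_pos <- sample(140:(len - 160), 1)
    str_sub(s, cyc_pos, cyc_pos + 153) <- place_motif(blocks$cyclase_context,
                                                      cyclase_motif)
  }
  protect <- integer(0)
  if (config$protect_motifs) {
    if (has_hd) protect <- c(protect, 13:14)
    if (has_cyclase) protect <- c(protect, (cyc_pos + 50):(cyc_pos + 53))
  }
  mutate_sequence(s, config$noise, protect)
}

# Embed a family signature in a random protein of the family's typical size.
build_effector_sequence <- function(family, config) {
  menu <- effector_menu()
  tlen <- menu$typical_length[menu$family == family]
  sig <- family_signature(family, config$seed)
  len <- sample((tlen - 30):(tlen + 30), 1)
  s <- random_protein(len)
  pos <- sample(20:(len - nchar(sig) - 10), 1)
  str_sub(s, pos, pos + nchar(sig) - 1) <- sig
  mutate_sequence(s, config$noise)
}

#' Generate a synthetic census dataset with planted truth
#'
#' Lays out, per genome, one contig with loci separated by >20 kb.
#' Each locus carries core cas genes plus a Cas10 inside the operon
#' boundaries, effector genes placed inside the +/-4 kb neighbourhood (on
#' either side of the operon, with 200-2000 nt intergenic gaps so the
#' boundary rule is exercised), candidate-family and ancillary genes, and
#' background genes far outside any neighbourhood. Coordinates are 0-based
#' half-open on the contig.
#'
#' @param config a [synth_config()].
#' @return list with `proteins` (tibble: id, genome, contig, coordinates,
#'   strand, sequence), `annotations` (the locus annotation table),
#'   `seed_alignments` (from [make_seed_alignments()]), `truth` (list of
#'   `proteins`, `loci`, `genomes` truth tibbles) and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  census <- simulate_census(config)
  blocks <- cas10_blocks(config$seed)
  alignments <- make_seed_alignments(config)
  prot_rows <- list()
  ann_rows <- list()
  truth_prot <- list()
  truth_loci <- list()
  gba_partner <- family_reference("gba_partner", config$seed)
  withr::with_seed(derive_seed(config$seed, "genomes"), {
    for (g in unique(census$genome_id)) {
      gloci <- census |> filter(.data$genome_id == g)
      contig <- paste0(g, "_c1")
      cursor <- 1000L
      gene_n <- 0L
      emit <- function(role, label, evalue, seq, locus, subtype,
                       family = NA_character_, gap_range = 200:2000) {
        gene_n <<- gene_n + 1L
        pid <- sprintf("%s_p%03d", g, gene_n)
        start <- cursor + sample(gap_range, 1)
        end <- start + 3L * nchar(seq)
        cursor <<- end
        prot_rows[[length(prot_rows) + 1L]] <<- tibble(
          protein_id = pid, genome_id = g, contig_id = contig,
          start = start, end = end, strand = sample(c("+", "-"), 1),
          sequence = seq)
        ann_rows[[length(ann_rows) + 1L]] <<- tibble(
          protein_id = pid, genome_id = g, contig_id = contig,
          start = start, end = end, strand = NA_character_,
          locus_id = locus, annotation_label = label,
          annotation_evalue = evalue, subtype = subtype,
          operon_start = NA_integer_, operon_end = NA_integer_)
        truth_prot[[length(truth_prot) + 1L]] <<- tibble(
          protein_id = pid, genome_id = g, locus_id = locus %||% NA_character_,
          role = role, family = family)
        pid
      }
      add_locus <- function(lr, extra_cas10 = FALSE, non_iii = FALSE) {
        locus <- lr$locus_id
        subtype <- lr$subtype
        # neighbourhood genes: effectors plus, in CorA loci, ancillaries;
        # split over both sides of the operon with tight gaps so every one
        # of them intersects the +/-4 kb window
        nb <- list()
        for (fam in lr$families[[1]]) {
          nb[[length(nb) + 1L]] <- list(fam = fam, role = "effector",
                                        seq = build_effector_sequence(fam, config))
        }
        if ("CorA" %in% lr$families[[1]]) {
          for (anc in ancillary_families()) {
            if (runif(1) < config$p_ancillary) {
              nb[[length(nb) + 1L]] <- list(
                fam = anc, role = "ancillary",
                seq = mutate_sequence(family_reference(anc, config$seed,
                                                       len = 250L),
                                      config$seed_divergence))
            }
          }
        }
        n_before <- min(length(nb), 2L)
        for (er in head(nb, n_before)) {
          emit(er$role, "Unknown", NA_real_, er$seq, NA_character_,
               NA_character_, family = er$fam, gap_range = 100:300)
        }
        # the operon proper: core cas genes, Cas10(s), candidate genes
        emit("core", "Csm3", 1e-40, random_protein(sample(150:300, 1)),
             locus, subtype)
        cas10_ids <- character(0)
        if (!non_iii) {
          cseq <- build_cas10_sequence(blocks, lr$has_cyclase,
                                       lr$cyclase_motif, lr$has_hd, config)
          cas10_ids <- emit("cas10", "Cas10", 1e-60, cseq, locus, subtype,
                            family = "Cas10")
          if (extra_cas10) {
            cseq2 <- build_cas10_sequence(blocks, lr$has_cyclase,
                                          lr$cyclase_motif, lr$has_hd, config)
            cas10_ids <- c(cas10_ids,
                           emit("cas10", "Cas10", 1e-55, cseq2, locus,
                                subtype, family = "Cas10"))
          }
        }
        emit("core", "Csm4", 1e-35, random_protein(sample(150:300, 1)),
             locus, subtype)
        # candidate genes sit inside the operon, annotated Unknown
        for (fam in lr$candidates[[1]]) {
          cand_seq <- mutate_sequence(family_reference(fam, config$seed),
                                      config$seed_divergence)
          emit("candidate", "Unknown", NA_real_, cand_seq, locus, subtype,
               family = fam)
          if (fam == candidate_families()[1]) {
            # recurrent colocalized partner, annotated like an
            # uncharacterized cas gene: found only by guilt-by-association
            emit("partner", "CasR", 1e-30,
                 mutate_sequence(gba_partner, config$seed_divergence),
                 locus, subtype, family = "gba_partner")
          }
        }
        for (er in nb[seq_len(length(nb)) > n_before]) {
          emit(er$role, "Unknown", NA_real_, er$seq, NA_character_,
               NA_character_, family = er$fam, gap_range = 100:300)
        }
        # background gene far beyond the neighbourhood
        cursor <<- cursor + 20000L
        emit("background", "Unknown", NA_real_,
             random_protein(sample(120:300, 1)), NA_character_, NA_character_)
        cursor <<- cursor + 20000L
        # operon bounds = span of the member genes, recorded verbatim in
        # the annotation table
        idx <- which(vapply(ann_rows, function(r) identical(r$locus_id, locus),
                            logical(1)))
        op_start <- min(vapply(ann_rows[idx], function(r) r$start, integer(1)))
        op_end <- max(vapply(ann_rows[idx], function(r) r$end, integer(1)))
        for (i in idx) {
          ann_rows[[i]]$operon_start <<- op_start
          ann_rows[[i]]$operon_end <<- op_end
        }
        truth_loci[[length(truth_loci) + 1L]] <<- lr |>
          mutate(n_cas10 = length(cas10_ids),
                 filtered_out = extra_cas10 || non_iii,
                 cas10_id = list(cas10_ids))
      }
      for (k in seq_len(nrow(gloci))) add_locus(gloci[k, ])
      # rare constructs exercising the locus filters (outside the census truth)
      if (runif(1) < config$p_two_cas10) {
        add_locus(tibble(locus_id = paste0(g, "_hybrid2cas10"),
                         subtype = paste0(sample(names(config$subtype_weights), 1,
                                                 prob = config$subtype_weights),
                                          "/I-B"),
                         has_cyclase = FALSE, cyclase_motif = "GGDD",
                         has_hd = FALSE, multi_locus = NA,
                         n_type3_loci_in_genome = NA_integer_,
                         has_effector = FALSE,
                         families = list(character(0)),
                         candidates = list(character(0)),
                         genome_id = g),
                  extra_cas10 = TRUE)
      }
      if (runif(1) < config$p_non_iii) {
        add_locus(tibble(locus_id = paste0(g, "_nonIII"), subtype = "I-E",
                         has_cyclase = FALSE, cyclase_motif = "GGDD",
                         has_hd = FALSE, multi_locus = NA,
                         n_type3_loci_in_genome = NA_integer_,
                         has_effector = FALSE,
                         families = list(character(0)),
                         candidates = list(character(0)),
                         genome_id = g),
                  non_iii = TRUE)
      }
    }
  })
  annotations <- bind_rows(ann_rows) |>
    select("protein_id", "genome_id", "contig_id", "start", "end", "strand",
           "locus_id", "operon_start", "operon_end", "annotation_label",
           "annotation_evalue", "subtype")
  proteins <- bind_rows(prot_rows)
  list(proteins = proteins,
       annotations = annotations |>
         left_join(proteins |> select("protein_id", "sequence"),
                   by = "protein_id"),
       seed_alignments = alignments,
       truth = list(proteins = bind_rows(truth_prot),
                    loci = bind_rows(truth_loci),
                    genomes = census |>
                      distinct(.data$genome_id, .data$n_type3_loci_in_genome)),
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits the formats the pipeline consumes: a protein FASTA, the annotation
#' TSV, one aligned FASTA per profile family under `seed_alignments/`, and a
#' truth-label JSON.
#'
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "seed_alignments"), recursive = TRUE,
             showWarnings = FALSE)
  write_protein_fasta(dataset$proteins, file.path(dir, "proteins.faa"))
  readr::write_tsv(dataset$annotations |> select(-"sequence"),
                   file.path(dir, "annotations.tsv"), progress = FALSE)
  for (fam in names(dataset$seed_alignments)) {
    write_protein_fasta(
      tibble(protein_id = sprintf("%s_seed%d", fam,
                                  seq_along(dataset$seed_alignments[[fam]])),
             sequence = dataset$seed_alignments[[fam]]),
      file.path(dir, "seed_alignments", paste0(gsub("[^A-Za-z0-9_-]", "_", fam),
                                               ".afa")))
  }
  truth <- dataset$truth
  truth$loci <- truth$loci |>
    mutate(families = map_chr(.data$families, paste, collapse = ","),
           candidates = map_chr(.data$candidates, paste, collapse = ","),
           cas10_id = map_chr(.data$cas10_id, paste, collapse = ","))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
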