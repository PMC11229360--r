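# Reading and writing the formats the census pipeline touches: protein FASTA,
# the locus annotation table (the contract with upstream locus callers such as
# CCTyper, converted by a thin adapter), and the final census TSV/JSON.
#
# Coordinates are 0-based half-open nucleotide intervals throughout. Strand
# never reorients amino-acid sequences (they are already translated); it only
# documents gene orientation.

#' Read a protein FASTA file
#'
#' Parses an amino-acid FASTA file into a tibble, preserving record order.
#' Sequences are uppercased, `*` stop characters are stripped from the ends,
#' and ambiguous residues other than `X` are mapped to `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `protein_id` and `sequence`; zero rows for an
#'   empty file.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1", "MHDAC", ">p2", "mkly*"), f)
#' read_protein_fasta(f)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  # Validate structure first so errors can name the offending line; the
  # actual parse is Biostrings'.
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0) {
    return(tibble(protein_id = character(0), sequence = character(0)))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("malformed FASTA: line %d does not start with '>'",
                  nonblank[1]))
  }
  headers <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[headers]))
  if (any(ids == "")) {
    abort(sprintf("malformed FASTA: empty header at line %d",
                  headers[which(ids == "")[1]]))
  }
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    block <- lines[seq(bounds[k] + 1L, length.out = bounds[k + 1L] - bounds[k] - 1L)]
    if (!any(nchar(gsub("\\s", "", block)) > 0)) {
      abort(sprintf("malformed FASTA: empty record '%s' at line %d",
                    ids[k], headers[k]))
    }
  }
  aa <- Biostrings::readBStringSet(path)
  tibble(protein_id = sub("\\s.*$", "", names(aa)),
         sequence = canonicalize_aa(as.character(aa)))
}

#' Write a protein FASTA file
#'
#' @param proteins tibble with columns `protein_id` and `sequence`.
#' @param path output path.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path, width = 70L) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$protein_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a locus annotation table and join it to protein sequences
#'
#' The annotation table is the pipeline's contract with an upstream locus
#' caller. It is a TSV with one row per gene and a header naming at least:
#' `protein_id`, `genome_id`, `contig_id`, `start`, `end`, `strand`,
#' `locus_id`, `operon_start`, `operon_end`, `annotation_label`,
#' `annotation_evalue`, `subtype`. Unknown columns are ignored. Genes outside
#' any locus have empty `locus_id`/`operon_*`/`subtype` fields, and genes
#' annotated `Unknown` have an empty `annotation_evalue`.
#'
#' @param path path to the TSV.
#' @param proteins tibble from [read_protein_fasta()]; every `protein_id` in
#'   the table must be present here.
#' @return a tibble of gene annotations joined to sequences.
#' @export
read_annotation_table <- function(path, proteins) {
  required <- c("protein_id", "genome_id", "contig_id", "start", "end",
                "strand", "locus_id", "operon_start", "operon_end",
                "annotation_label", "annotation_evalue", "subtype")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("annotation table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann <- tab |>
    select(all_of(required)) |>
    mutate(across(c("start", "end", "operon_start", "operon_end"),
                  ~ suppressWarnings(as.integer(.x))),
           annotation_evalue = suppressWarnings(as.numeric(.data$annotation_evalue)),
           locus_id = na_if(.data$locus_id, ""),
           subtype = na_if(.data$subtype, ""))
  missing_ids <- setdiff(ann$protein_id, proteins$protein_id)
  if (length(missing_ids)) {
    abort(paste0("annotation rows reference proteins absent from the FASTA: ",
                 paste(missing_ids, collapse = ", ")))
  }
  if (any(ann$end <= ann$start, na.rm = TRUE)) {
    abort("annotation table contains genes with end <= start")
  }
  unk <- ann$annotation_label == "Unknown"
  if (any(!is.na(ann$annotation_evalue[unk]))) {
    warn("E-values on 'Unknown' annotations were discarded")
    ann$annotation_evalue[unk] <- NA_real_
  }
  ann |> left_join(proteins, by = "protein_id")
}

#' Assemble per-locus records from gene annotations
#'
#' Groups annotated genes by `locus_id` and keeps the operon boundaries
#' verbatim from the table (boundary computation belongs to the upstream
#' locus caller, not this package).
#'
#' @param annotations tibble from [read_annotation_table()].
#' @return a tibble with one row per locus: `locus_id`, `genome_id`,
#'   `contig_id`, `subtype`, `operon_start`, `operon_end`, `member_proteins`
#'   (list-column), `n_cas10` (count of members annotated `Cas10`).
#' @export
build_locus_table <- function(annotations) {
  annotations |>
    filter(!is.na(.data$locus_id)) |>
    group_by(.data$locus_id) |>
    summarise(genome_id = .data$genome_id[1],
              contig_id = .data$contig_id[1],
              subtype = .data$subtype[1],
              operon_start = min(.data$operon_start),
              operon_end = max(.data$operon_end),
              member_proteins = list(.data$protein_id),
              n_cas10 = sum(.data$annotation_label == "Cas10"),
              .groups = "drop") |>
    arrange(.data$locus_id)
}

#' Write the census table as TSV plus a JSON mirror
#'
#' One row per locus; loci with no effectors keep their row with empty
#' fields. Given identical input the two files are byte-stable, which is the
#' basis of the pipeline's determinism guarantee.
#'
#' @param census a census tibble (see [build_census()]).
#' @param tsv_path output TSV path.
#' @param json_path output JSON path; defaults to `tsv_path` with a `.json`
#'   extension.
#' @return invisibly, the two paths.
#' @export
write_census <- function(census, tsv_path,
                         json_path = sub("\\.tsv$", ".json", tsv_path)) {
  flat <- census |>
    mutate(families = map_chr(.data$families, ~ paste(sort(.x), collapse = ",")),
           candidates = map_chr(.data$candidates, ~ paste(sort(.x), collapse = ",")),
           activators = map_chr(.data$activators, ~ paste(sort(.x), collapse = ",")))
  readr::write_tsv(flat, tsv_path, progress = FALSE)
  jsonlite::write_json(flat, json_path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv_path, json = json_path))
}
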