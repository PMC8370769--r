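#' Read a phosphopeptide quantification table
#'
#' One row per (peptide, multiplex). Site-level fields (`site_positions`,
#' `acceptor_residues`, `localization_probs`) are `;`-joined in the file and
#' parsed into parallel list-columns; multiply phosphorylated peptides are
#' one record with parallel lists. Intensity columns are named by channel
#' label; empty cells are kept as `NA`, never coerced to zero. Rows with
#' negative intensities or invalid site fields are rejected with a message.
#'
#' @param path Path to a tab-separated file with columns `peptide_id`,
#'   `protein_id`, `multiplex_id`, `site_positions`, `acceptor_residues`,
#'   `localization_probs`, plus one numeric column per channel.
#' @param design Optional [stage_design()]; when given, the table is checked
#'   against it with [validate_design()] and inconsistencies are messaged.
#' @param columns Optional named character vector mapping the required
#'   schema names onto the file's actual column names, e.g.
#'   `c(peptide_id = "Peptide.ID")`, for importing third-party exports.
#' @return A tibble of validated records.
#' @export
read_phospho_table <- function(path, design = NULL, columns = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(columns)) {
    for (schema_name in names(columns)) {
      names(tbl)[names(tbl) == columns[[schema_name]]] <- schema_name
    }
  }
  required <- c("peptide_id", "protein_id", "multiplex_id",
                "site_positions", "acceptor_residues", "localization_probs")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Phospho table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl |>
    mutate(
      peptide_id = as.character(.data$peptide_id),
      protein_id = as.character(.data$protein_id),
      multiplex_id = as.character(.data$multiplex_id),
      site_positions = split_field(.data$site_positions, as.integer),
      acceptor_residues = split_field(.data$acceptor_residues, as.character),
      localization_probs = split_field(.data$localization_probs, as.numeric)
    )
  validate_phospho_records(tbl, design)
}

validate_phospho_records <- function(tbl, design = NULL) {
  chans <- intensity_cols(tbl)
  n_sites <- lengths(tbl$site_positions)
  ok <- n_sites == lengths(tbl$acceptor_residues) &
    n_sites == lengths(tbl$localization_probs) &
    vapply(tbl$site_positions, function(p) all(!is.na(p) & p >= 1L), logical(1)) &
    vapply(tbl$acceptor_residues, function(a) all(a %in% c("S", "T", "Y")), logical(1)) &
    vapply(tbl$localization_probs, function(p) all(!is.na(p) & p >= 0 & p <= 1), logical(1))
  if (length(chans)) {
    neg <- Reduce(`|`, lapply(tbl[chans], function(x) !is.na(x) & x < 0))
    ok <- ok & !neg
  }
  if (any(!ok)) {
    inform(paste0("Rejected ", sum(!ok),
                  " phospho record(s) failing validation (parallel site fields, ",
                  "positions >= 1, S/T/Y acceptors, probabilities in [0,1], ",
                  "nonnegative intensities)."))
    tbl <- tbl[ok, , drop = FALSE]
  }
  if (!is.null(design)) {
    report <- validate_design(design, phospho = tbl)
    if (nrow(report)) {
      inform(paste0("Design/table inconsistencies: ",
                    paste(report$issue, report$what, sep = "=", collapse = "; ")))
    }
  }
  tbl
}

#' @rdname read_phospho_table
#' @param tbl A phospho table as returned by [read_phospho_table()] or
#'   [simulate_phospho_timecourse()].
#' @export
write_phospho_table <- function(tbl, path) {
  out <- tbl |>
    mutate(
      site_positions = join_field(.data$site_positions),
      acceptor_residues = join_field(.data$acceptor_residues),
      localization_probs = join_field(.data$localization_probs)
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(tbl)
}

#' Read or write a protein quantification table
#'
#' One row per (protein, multiplex), wide intensity columns named by channel
#' label. Negative intensities are rejected row-wise with a message; missing
#' cells stay `NA`.
#'
#' @param path Path to a tab-separated file with columns `protein_id`,
#'   `multiplex_id`, plus one numeric column per channel.
#' @return A tibble.
#' @export
read_protein_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("protein_id", "multiplex_id")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Protein table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- mutate(tbl,
                protein_id = as.character(.data$protein_id),
                multiplex_id = as.character(.data$multiplex_id))
  chans <- intensity_cols(tbl)
  if (length(chans)) {
    neg <- Reduce(`|`, lapply(tbl[chans], function(x) !is.na(x) & x < 0))
    if (any(neg)) {
      inform(paste0("Rejected ", sum(neg), " protein record(s) with negative intensities."))
      tbl <- tbl[!neg, , drop = FALSE]
    }
  }
  tbl
}

#' @rdname read_protein_table
#' @param tbl A protein table.
#' @export
write_protein_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Read or write protein sequences in FASTA
#'
#' Wraps `Biostrings` FASTA I/O with the checks the motif analyses rely on:
#' unique identifiers and a strict 20-letter amino-acid alphabet. Sequences
#' are returned uppercase as a named character vector.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- stringr::str_locate(seqs, paste0("[^", paste(AA20, collapse = ""), "]"))[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(paste0("Non-amino-acid character in sequence '", ids[i],
                 "' at position ", bad[i], "."))
  }
  seqs
}

#' @rdname read_fasta
#' @param sequences Named character vector of amino-acid sequences.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(sequences)
}
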