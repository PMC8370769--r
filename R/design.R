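#' Stage design: channel-to-stage maps for a set of multiplexes
#'
#' A stage design records the ordered stage (or condition) labels, which
#' reporter channel carries which stage within each multiplex, and which
#' channel carries the pooled internal-standard reference. Every multiplex
#' must map every stage to exactly one channel, and the reference channel
#' must be distinct from all stage channels.
#'
#' @param stages Ordered character vector of stage/condition labels
#'   (length >= 2; the six-stage meiotic default is
#'   `c("Pro","GVBD","MI","MII","2-PN","FC")`).
#' @param n_multiplexes Number of replicate multiplexes (used when
#'   `multiplexes` is not given; all get the same default channel layout).
#' @param channels Channel labels carrying the stages, in stage order.
#'   Defaults to `C1..Cn`.
#' @param reference Label of the internal-standard reference channel
#'   (default `"REF"`).
#' @param multiplexes Optional named list, one element per multiplex, each a
#'   list with `channels` (named character: channel label -> stage label)
#'   and `reference`.
#'
#' @return An object of class `stage_design`.
#' @examples
#' d <- stage_design(c("Pro", "GVBD", "MI", "MII", "2-PN", "FC"), n_multiplexes = 3)
#' design_stages(d)
#' @export
stage_design <- function(stages, n_multiplexes = 3, channels = NULL,
                         reference = "REF", multiplexes = NULL) {
  stages <- as.character(stages)
  if (length(stages) < 2) abort("A stage design needs at least two ordered stages.")
  if (anyDuplicated(stages)) abort("Stage labels must be unique.")
  if (is.null(multiplexes)) {
    channels <- channels %||% paste0("C", seq_along(stages))
    if (length(channels) != length(stages)) {
      abort("`channels` must have one label per stage.")
    }
    one <- list(channels = setNames(stages, channels), reference = reference)
    multiplexes <- setNames(
      replicate(n_multiplexes, one, simplify = FALSE),
      paste0("M", seq_len(n_multiplexes))
    )
  }
  out <- structure(
    list(stages = stages, multiplexes = multiplexes),
    class = "stage_design"
  )
  validate_stage_design(out)
  out
}

validate_stage_design <- function(design) {
  stopifnot(inherits(design, "stage_design"))
  for (m in names(design$multiplexes)) {
    mx <- design$multiplexes[[m]]
    if (is.null(mx$reference) || !nzchar(mx$reference)) {
      abort(paste0("Multiplex ", m, " has no reference channel."))
    }
    mapped <- unname(mx$channels)
    if (!setequal(mapped, design$stages) || length(mapped) != length(design$stages)) {
      abort(paste0("Multiplex ", m, " must map every stage to exactly one channel."))
    }
    if (mx$reference %in% names(mx$channels)) {
      abort(paste0("Multiplex ", m, ": reference channel must be distinct from stage channels."))
    }
  }
  invisible(design)
}

#' @export
print.stage_design <- function(x, ...) {
  cat("<stage_design> ", length(x$stages), " stages: ",
      paste(x$stages, collapse = " > "), "\n", sep = "")
  cat("  multiplexes: ", paste(names(x$multiplexes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Accessors for stage designs
#'
#' @param design A [stage_design()].
#' @param multiplex Multiplex label.
#' @return `design_stages()` the ordered stage labels; `design_multiplexes()`
#'   the multiplex labels; `design_channel_map()` a named character vector
#'   (channel label -> stage label) for one multiplex; `design_reference()`
#'   that multiplex's reference channel label.
#' @export
design_stages <- function(design) design$stages

#' @rdname design_stages
#' @export
design_multiplexes <- function(design) names(design$multiplexes)

#' @rdname design_stages
#' @export
design_channel_map <- function(design, multiplex) {
  mx <- design$multiplexes[[multiplex]]
  if (is.null(mx)) abort(paste0("Unknown multiplex: ", multiplex))
  mx$channels
}

#' @rdname design_stages
#' @export
design_reference <- function(design, multiplex) {
  mx <- design$multiplexes[[multiplex]]
  if (is.null(mx)) abort(paste0("Unknown multiplex: ", multiplex))
  mx$reference
}

#' Read or write a stage design as JSON
#'
#' @param path File path.
#' @param design A [stage_design()].
#' @return `read_stage_design()` returns a `stage_design`;
#'   `write_stage_design()` returns `design` invisibly.
#' @export
read_stage_design <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  multiplexes <- lapply(raw$multiplexes, function(mx) {
    list(
      channels = unlist(mx$channels),
      reference = mx$reference
    )
  })
  stage_design(unlist(raw$stages), multiplexes = multiplexes)
}

#' @rdname read_stage_design
#' @export
write_stage_design <- function(design, path) {
  validate_stage_design(design)
  payload <- list(
    stages = design$stages,
    multiplexes = lapply(design$multiplexes, function(mx) {
      list(channels = as.list(mx$channels), reference = mx$reference)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(design)
}

#' Cross-check a design against quantification tables
#'
#' Reports (does not error on) multiplexes or channels present in the tables
#' but absent from the design, and vice versa.
#'
#' @param design A [stage_design()].
#' @param phospho,proteins Optional quantification tables as returned by
#'   [read_phospho_table()] / [rollup_proteins()].
#' @return A tibble with columns `table`, `issue`, `what` (empty when
#'   everything is consistent).
#' @export
validate_design <- function(design, phospho = NULL, proteins = NULL) {
  validate_stage_design(design)
  check_one <- function(tbl, label) {
    if (is.null(tbl)) return(tibble(table = character(), issue = character(), what = character()))
    findings <- list()
    design_mux <- design_multiplexes(design)
    tab_mux <- unique(tbl$multiplex_id)
    for (m in setdiff(tab_mux, design_mux)) {
      findings <- c(findings, list(tibble(
        table = label, issue = "multiplex_not_in_design", what = m
      )))
    }
    for (m in setdiff(design_mux, tab_mux)) {
      findings <- c(findings, list(tibble(
        table = label, issue = "multiplex_not_in_table", what = m
      )))
    }
    chans <- intensity_cols(tbl)
    for (m in intersect(tab_mux, design_mux)) {
      expected <- c(names(design_channel_map(design, m)), design_reference(design, m))
      for (ch in setdiff(expected, chans)) {
        findings <- c(findings, list(tibble(
          table = label, issue = "channel_not_in_table", what = paste0(m, ":", ch)
        )))
      }
      for (ch in setdiff(chans, expected)) {
        findings <- c(findings, list(tibble(
          table = label, issue = "channel_not_in_design", what = paste0(m, ":", ch)
        )))
      }
    }
    bind_rows(findings)
  }
  bind_rows(
    check_one(phospho, "phospho"),
    check_one(proteins, "proteins")
  )
}
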